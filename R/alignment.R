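## Tissue-scale nematic order statistics: Gaussian local axis averaging,
## the nematic alignment parameter
##   S = (1/N) sum_i [ (3/2) (e_i . g_i)^2 - 1/2 ],
## its uniaxial maximum-likelihood baseline S2_ML = -S1/2, the biaxiality
## excess over that baseline, and group comparisons.

#' Nematic alignment parameter S
#'
#' Mean of `(3/2) cos^2(theta_i) - 1/2` between each axis and its paired
#' reference axis: `S = 1` for perfectly parallel, `0` for isotropic,
#' `-1/2` for perfectly perpendicular relative alignment. Axes are
#' sign-free, so the sign of each row does not matter.
#'
#' @param axes n x 3 matrix of unit axes (or a length-3 vector).
#' @param reference_axes n x 3 matrix of paired unit reference axes, or a
#'   single length-3 axis recycled for all rows.
#' @return scalar S in `[-1/2, 1]`.
#' @export
alignment_parameter <- function(axes, reference_axes) {
  E <- rbind(axes)
  G <- rbind(reference_axes)
  if (nrow(G) == 1) G <- G[rep(1, nrow(E)), , drop = FALSE]
  if (nrow(E) != nrow(G))
    stop("axes and reference_axes must have the same length")
  mean(1.5 * rowSums(E * G)^2 - 0.5)
}

#' Uniaxial maximum-likelihood baseline for the secondary axis
#'
#' For an ensemble of biaxial objects whose three axes have alignment
#' parameters S1, S2, S3 with S1 + S2 + S3 = 0, the maximum-likelihood
#' estimate of S2 given S1 alone (no biaxial order, so S2_ML = S3_ML) is
#' `S2_ML = -S1 / 2`.
#'
#' @param S1 alignment parameter of the primary axis, in `[-1/2, 1]`.
#' @return baseline value `-S1/2`.
#' @export
uniaxial_baseline <- function(S1) {
  if (any(S1 < -0.5 - 1e-12 | S1 > 1 + 1e-12))
    stop("S1 must lie in [-1/2, 1]")
  -S1 / 2
}

#' Gaussian local averaging of polarity axes
#'
#' At each cell position `x`, builds the weighted nematic tensor
#' `(3/2) sum_j w(|x_j - x|) (a_j a_j^T - I/3)` with an isotropic Gaussian
#' kernel `w` (standard deviation `kernel_sd`, default 20 um, approximately
#' one hepatocyte diameter) and returns its principal (largest-eigenvalue)
#' axis. Weights are normalized by their sum so the principal eigenvalue is
#' an interpretable local order weight in `[0, 1]`. A cell whose total
#' kernel weight from the ensemble is negligible keeps its own axis and is
#' flagged isolated.
#'
#' @param positions n x 3 matrix of cell centers (um).
#' @param axes n x 3 matrix of unit axes (one per cell).
#' @param kernel_sd Gaussian kernel standard deviation (um); default 20.
#' @param eval_positions positions at which to evaluate the averaged field;
#'   defaults to `positions`.
#' @return list with `axes` (k x 3 unit rows), `order_weight` (principal
#'   eigenvalue of the normalized tensor) and `isolated` (logical).
#' @export
local_average_axes <- function(positions, axes, kernel_sd = 20,
                               eval_positions = positions) {
  positions <- rbind(positions); axes <- rbind(axes)
  eval_positions <- rbind(eval_positions)
  stopifnot(nrow(positions) == nrow(axes), kernel_sd > 0)
  k <- nrow(eval_positions)
  out_axes <- matrix(NA_real_, k, 3)
  weight <- numeric(k)
  isolated <- logical(k)
  for (i in seq_len(k)) {
    d2 <- rowSums(sweep(positions, 2, eval_positions[i, ])^2)
    w <- exp(-d2 / (2 * kernel_sd^2))
    W <- sum(w)
    if (W < 1e-12) {
      isolated[i] <- TRUE
      j <- which.min(d2)
      out_axes[i, ] <- axes[j, ]
      weight[i] <- NA_real_
      next
    }
    N <- axis_nematic_tensor(axes, w)
    e <- eigen(unclass(N), symmetric = TRUE)
    out_axes[i, ] <- canonical_axis(e$vectors[, 1])
    weight[i] <- e$values[1]
  }
  list(axes = out_axes, order_weight = weight, isolated = isolated)
}

#' Biaxiality excess over the uniaxial baseline
#'
#' Per replicate (animal), the excess of the measured secondary-axis
#' alignment over the uniaxial prediction: `excess = S2 - (-S1/2)`. With two
#' or more replicates, tests `mean(excess) > 0` with a paired one-sided
#' t-test (default) or a sign-flip permutation test.
#'
#' @param S1,S2 per-replicate alignment parameters of the primary and
#'   secondary axes (equal lengths).
#' @param method `"t"` (paired one-sided t-test) or `"permutation"`
#'   (sign-flip, `n_perm` resamples).
#' @param n_perm permutation count; default 10000.
#' @return list with `excess` (per replicate), `mean_excess`, `p_value`
#'   (`NA` with a single replicate) and `method`.
#' @export
biaxiality_excess <- function(S1, S2, method = c("t", "permutation"),
                              n_perm = 10000) {
  method <- match.arg(method)
  if (length(S1) != length(S2)) stop("S1 and S2 must be paired")
  excess <- S2 - uniaxial_baseline(S1)
  if (length(excess) < 2)
    return(list(excess = excess, mean_excess = mean(excess),
                p_value = NA_real_, method = method))
  if (method == "t") {
    p <- stats::t.test(excess, alternative = "greater")$p.value
  } else {
    obs <- mean(excess)
    signs <- matrix(sample(c(-1, 1), n_perm * length(excess), replace = TRUE),
                    n_perm)
    null <- rowMeans(sweep(signs, 2, abs(excess), "*"))
    p <- (sum(null >= obs) + 1) / (n_perm + 1)
  }
  list(excess = excess, mean_excess = mean(excess), p_value = p,
       method = method)
}

#' Welch two-sample comparison
#'
#' Two-sided t-test assuming unequal variances between two groups of
#' per-replicate values.
#'
#' @param values_a,values_b numeric vectors (length >= 2 each).
#' @return the p-value.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0)
    stop("degenerate test: zero variance in both groups")
  stats::t.test(values_a, values_b, var.equal = FALSE)$p.value
}
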