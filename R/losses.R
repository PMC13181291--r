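# The SSIM-weighted cycleGAN loss arithmetic. Slices are 2D matrices on the
# normalized [-1, 1] intensity scale. The local SSIM map between a CBCT slice
# and its registered-CT slice, thresholded at alpha, weights the paired L1
# residual: where the two images structurally disagree (SSIM < alpha) the
# weight is zero and the generator receives no paired supervision there, so
# the cycle-consistency term dominates and CBCT structure is preserved.

# Windowed box sums with edge-inclusive mirror padding, via integral images.
.boxSum <- function(m, r) {
  n1 <- nrow(m); n2 <- ncol(m)
  pi1 <- c(r:1, 1:n1, n1:(n1 - r + 1))
  pi2 <- c(r:1, 1:n2, n2:(n2 - r + 1))
  p <- m[pi1, pi2, drop = FALSE]
  cs <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  Z <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  Z[-1, -1] <- cs
  w <- 2L * r + 1L
  i <- (r + 1L):(r + n1); j <- (r + 1L):(r + n2)
  Z[i + r + 1L, j + r + 1L, drop = FALSE] -
    Z[i - r, j + r + 1L, drop = FALSE] -
    Z[i + r + 1L, j - r, drop = FALSE] +
    Z[i - r, j - r, drop = FALSE]
}

#' Local SSIM map between two registered slices
#'
#' For every pixel, the SSIM of the `window x window` patches centred there
#' (uniform, unweighted window; edge-inclusive mirror padding at the
#' boundary), using population means, variances and covariance with stability
#' constants `c1`, `c2`:
#' `SSIM = (2 mux muy + C1)(2 sxy + C2) / ((mux^2 + muy^2 + C1)(sx^2 + sy^2 + C2))`.
#' Values lie in `[-1, 1]`, with 1 exactly where the patches are identical.
#'
#' @param x,y numeric matrices of equal shape on the `[-1, 1]` scale.
#' @param cfg a [LossConfig-class] (window and constants).
#' @return Matrix of local SSIM values, same shape as `x`.
#' @examples
#' x <- matrix(rnorm(256, sd = 0.2), 16)
#' range(localSSIMMap(x, x))   # identically 1
#' @export
localSSIMMap <- function(x, y, cfg = lossConfig()) {
  if (!identical(dim(x), dim(y))) stop("'x' and 'y' must have the same shape")
  r <- (cfg@window - 1L) %/% 2L
  n <- as.numeric(cfg@window)^2
  sx <- .boxSum(x, r); sy <- .boxSum(y, r)
  sxx <- .boxSum(x * x, r); syy <- .boxSum(y * y, r); sxy <- .boxSum(x * y, r)
  mux <- sx / n; muy <- sy / n
  vx <- sxx / n - mux^2; vy <- syy / n - muy^2
  cxy <- sxy / n - mux * muy
  ((2 * mux * muy + cfg@c1) * (2 * cxy + cfg@c2)) /
    ((mux^2 + muy^2 + cfg@c1) * (vx + vy + cfg@c2))
}

#' Threshold an SSIM map into an L1 weight map
#'
#' SSIM values below `alpha` are set to zero; values at or above the
#' threshold are kept as the weight.
#'
#' @param s SSIM map (matrix).
#' @param alpha threshold in `[0, 1]`.
#' @return Weight matrix of the same shape.
#' @export
ssimWeightMap <- function(s, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  s * (s >= alpha)
}

#' SSIM-weighted L1 loss (one translation direction)
#'
#' Mean over pixels of `w * |gx - y|`, where `w` is the thresholded local
#' SSIM between the registered input pair `(x, y)` and `gx` is the generator
#' output for `x`. Used symmetrically for both translation directions.
#'
#' @param x input slice (e.g. CBCT).
#' @param y registered target slice (e.g. deformed planning CT).
#' @param gx generator output for `x`.
#' @param cfg a [LossConfig-class].
#' @param weights optional precomputed weight map (skips the SSIM
#'   computation; used by the training loop, where weights are fixed
#'   constants of the input pair).
#' @return Nonnegative scalar.
#' @export
ssimWeightedL1 <- function(x, y, gx, cfg = lossConfig(), weights = NULL) {
  if (!identical(dim(x), dim(y)) || !identical(dim(x), dim(gx)))
    stop("'x', 'y' and 'gx' must have the same shape")
  if (is.null(weights))
    weights <- ssimWeightMap(localSSIMMap(x, y, cfg), cfg@alpha)
  mean(weights * abs(gx - y))
}

#' Cycle-consistency loss
#'
#' `mean |F(G(x)) - x| + mean |G(F(y)) - y|` over pixels, for the two
#' reconstruction directions.
#'
#' @param x,y original slices.
#' @param fgx reconstruction `F(G(x))` of `x`.
#' @param gfy reconstruction `G(F(y))` of `y`.
#' @return Nonnegative scalar.
#' @export
cycleConsistencyLoss <- function(x, y, fgx, gfy) {
  if (!identical(dim(x), dim(fgx)) || !identical(dim(y), dim(gfy)))
    stop("reconstructions must match their originals in shape")
  mean(abs(fgx - x)) + mean(abs(gfy - y))
}

#' Least-squares adversarial losses
#'
#' The least-squares GAN formulation of the reference cycleGAN
#' discriminator: `disc = mean((Dreal - 1)^2) + mean(Dfake^2)` and
#' `gen = mean((Dfake - 1)^2)` over patch score maps.
#'
#' @param dReal discriminator scores on real slices.
#' @param dFake discriminator scores on generated slices.
#' @return `list(gen = ..., disc = ...)`.
#' @export
adversarialLosses <- function(dReal, dFake) {
  stopifnot(all(is.finite(dReal)), all(is.finite(dFake)))
  list(gen = mean((dFake - 1)^2),
       disc = mean((dReal - 1)^2) + mean(dFake^2))
}

#' Compose the total generator loss
#'
#' @param parts `list(ssimWeightedL1 = , cycle = , adversarial = )` of finite
#'   scalars.
#' @param cfg a [LossConfig-class] supplying the lambda weights.
#' @return `list` (class `LossBreakdown`) with the three parts and
#'   `total = lambdaSSIM * ssimWeightedL1 + lambdaCycle * cycle +
#'   lambdaAdv * adversarial`.
#' @export
totalGeneratorLoss <- function(parts, cfg = lossConfig()) {
  vals <- c(parts$ssimWeightedL1, parts$cycle, parts$adversarial)
  if (length(vals) != 3L || any(is.na(vals)) || any(!is.finite(vals)))
    stop("all loss parts must be finite scalars")
  out <- list(ssimWeightedL1 = parts$ssimWeightedL1, cycle = parts$cycle,
              adversarial = parts$adversarial,
              total = cfg@lambdaSSIM * parts$ssimWeightedL1 +
                      cfg@lambdaCycle * parts$cycle +
                      cfg@lambdaAdv * parts$adversarial)
  class(out) <- "LossBreakdown"
  out
}

#' @export
print.LossBreakdown <- function(x, ...) {
  cat(sprintf("LossBreakdown: ssimL1 %.4g + cycle %.4g + adv %.4g -> total %.4g\n",
              x$ssimWeightedL1, x$cycle, x$adversarial, x$total))
  invisible(x)
}
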