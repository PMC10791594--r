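#' Localized normalized cross-correlation configuration
#'
#' @param sigma_px standard deviation of the Gaussian window, in detector
#'   pixels at the resolution the images are compared at.
#' @param variance_floor small positive constant added to the local variances
#'   (and covariance) to stabilise flat windows; interpreted as a fraction of
#'   the squared dynamic range of the measured image.
#' @return a list of class `lncc_config`.
#' @export
lncc_config <- function(sigma_px = 5, variance_floor = 1e-8) {
  stopifnot(sigma_px > 0, variance_floor > 0)
  structure(list(sigma_px = sigma_px, variance_floor = variance_floor),
            class = "lncc_config")
}

# dense 1-D Gaussian convolution matrix (truncated at 3.5 sigma)
gauss_conv_matrix <- function(n, sigma) {
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-0.5 * (d / sigma)^2)
  k[abs(d) > ceiling(3.5 * sigma)] <- 0
  k
}

# local windowed statistics shared by lncc() and lncc_gradient().
# Window weights at center x are Gaussian * mask, normalised over in-bounds
# masked pixels, so masked-out pixels neither contribute to nor receive loss.
lncc_stats <- function(P, Pp, cfg, mask) {
  if (!all(dim(P) == dim(Pp))) stop("projection images differ in shape")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(P), ncol(P))
  if (!all(dim(mask) == dim(P))) stop("mask shape mismatch")
  if (!any(mask)) stop("empty validity mask")
  Ku <- gauss_conv_matrix(nrow(P), cfg$sigma_px)
  Kv <- gauss_conv_matrix(ncol(P), cfg$sigma_px)
  cv <- function(X) Ku %*% X %*% Kv
  M <- mask * 1
  N <- cv(M)
  N[N < .Machine$double.eps] <- .Machine$double.eps
  mP <- cv(P * M) / N
  mQ <- cv(Pp * M) / N
  vP <- pmax(cv(P * P * M) / N - mP^2, 0)
  vQ <- pmax(cv(Pp * Pp * M) / N - mQ^2, 0)
  cPQ <- cv(P * Pp * M) / N - mP * mQ
  dr <- diff(range(P[mask]))
  eps <- cfg$variance_floor * (if (dr > 0) dr^2 else 1)
  s <- sqrt((vP + eps) * (vQ + eps))
  L <- (cPQ + eps) / s
  list(L = L, mP = mP, mQ = mQ, vQ = vQ, s = s, eps = eps, N = N, M = M,
       mask = mask, cv = cv)
}

#' Localized normalized cross-correlation of two projection images
#'
#' The mean, over valid pixels, of the windowed correlation coefficient
#' computed from Gaussian-weighted local means, variances and covariance.
#' Locally affine intensity relationships between the two images score 1;
#' the value always lies in `[-1, 1]` and is symmetric in its two image
#' arguments. Averaging (rather than summing) over valid pixels keeps FOV
#' masking from biasing frames with fewer valid pixels.
#'
#' @param P,Pp measured and estimated projection images (matrices, same shape).
#' @param cfg a [lncc_config()].
#' @param mask logical matrix of valid pixels (rays staying inside the FOV);
#'   `NULL` for all-valid.
#' @return scalar in `[-1, 1]`.
#' @export
lncc <- function(P, Pp, cfg = lncc_config(), mask = NULL) {
  st <- lncc_stats(P, Pp, cfg, mask)
  mean(st$L[st$mask])
}

#' Analytic gradient of the LNCC with respect to the estimated image
#'
#' Gradient of [lncc()] (the masked mean of windowed correlations) with
#' respect to each pixel of `Pp`. Entries at masked-out pixels are exactly
#' zero, since those pixels are excluded from every window.
#'
#' @inheritParams lncc
#' @return matrix of the same shape as `Pp`.
#' @export
lncc_gradient <- function(P, Pp, cfg = lncc_config(), mask = NULL) {
  st <- lncc_stats(P, Pp, cfg, mask)
  nm <- sum(st$mask)
  A <- st$M / (st$N * st$s)
  B <- st$M * st$L / (st$N * (st$vQ + st$eps))
  g <- P * st$cv(A) - st$cv(A * st$mP) - Pp * st$cv(B) + st$cv(B * st$mQ)
  g <- g * st$M / nm
  g
}
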