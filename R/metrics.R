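#' Mean motion-field error
#'
#' Mean, over frames and the volume of interest, of the Euclidean norm of the
#' difference between estimated and ground-truth displacement fields (mm).
#'
#' @param est,gt lists of `dense_dvf` (matched frames and grids).
#' @param voi logical array marking the volume of interest (conventionally
#'   the body within the reconstruction FOV).
#' @return scalar, mm.
#' @export
dvf_error <- function(est, gt, voi) {
  if (length(est) != length(gt)) stop("frame count mismatch")
  tot <- 0
  for (t in seq_along(est)) {
    if (!all(dim(est[[t]]) == dim(gt[[t]]))) stop("grid mismatch at frame ", t)
    d <- est[[t]] - gt[[t]]
    mag <- sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2)
    tot <- tot + mean(mag[voi])
  }
  tot / length(est)
}

#' Dice similarity coefficient of tumor masks
#'
#' `2|A n B| / (|A| + |B|)` per frame, averaged over frames.
#'
#' @param est_masks,gt_masks lists of logical arrays (matched frames).
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(est_masks, gt_masks) {
  if (length(est_masks) != length(gt_masks)) stop("frame count mismatch")
  mean(vapply(seq_along(est_masks), function(t) {
    a <- est_masks[[t]]; b <- gt_masks[[t]]
    na <- sum(a); nb <- sum(b)
    if (na == 0 || nb == 0) stop("empty mask at frame ", t)
    2 * sum(a & b) / (na + nb)
  }, 0))
}

mask_centroid <- function(mask) {
  g <- vol_grid(mask)
  idx <- which(unclass(mask) > 0.5, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  g$origin + (colMeans(idx) - 1) * g$spacing
}

#' Mean tumor centroid error
#'
#' Euclidean distance between the estimated and ground-truth mask centroids
#' (mm), averaged over frames.
#'
#' @inheritParams dice_coefficient
#' @return scalar, mm.
#' @export
centroid_error <- function(est_masks, gt_masks) {
  if (length(est_masks) != length(gt_masks)) stop("frame count mismatch")
  mean(vapply(seq_along(est_masks), function(t) {
    sqrt(sum((mask_centroid(est_masks[[t]]) - mask_centroid(gt_masks[[t]]))^2))
  }, 0))
}

#' Normalized root-mean-square error between two volumes
#'
#' RMS difference over the volume of interest, normalized to the maximum
#' value of the ground-truth volume.
#'
#' @param est,gt volumes on the same grid.
#' @param voi logical array; default all voxels finite in both.
#' @return scalar ratio.
#' @export
nrmse <- function(est, gt, voi = NULL) {
  if (!all(dim(est) == dim(gt))) stop("grid mismatch")
  if (is.null(voi)) voi <- is.finite(est) & is.finite(gt)
  mx <- max(gt[is.finite(gt)])
  if (mx <= 0) stop("ground truth maximum must be positive")
  sqrt(mean((est[voi] - gt[voi])^2)) / mx
}

#' Volumetric structural similarity index
#'
#' Mean SSIM over the volume of interest, computed from Gaussian-windowed
#' local statistics with the standard constants `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2`.
#'
#' @param est,gt volumes on the same grid (null voxels treated as 0).
#' @param voi logical array (default: all voxels).
#' @param sigma Gaussian window standard deviation in voxels.
#' @param dynamic_range `L`; default the ground truth's finite range.
#' @return scalar in `[-1, 1]`.
#' @export
ssim_volume <- function(est, gt, voi = NULL, sigma = 1.5, dynamic_range = NULL) {
  if (!all(dim(est) == dim(gt))) stop("grid mismatch")
  d <- dim(est)
  a <- as.numeric(est); a[!is.finite(a)] <- 0
  b <- as.numeric(gt); b[!is.finite(b)] <- 0
  if (is.null(dynamic_range))
    dynamic_range <- diff(range(gt[is.finite(gt)]))
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  ones <- cpp_gauss3d(rep(1, length(a)), d, sigma)
  gz <- function(v) cpp_gauss3d(v, d, sigma) / ones
  mu1 <- gz(a); mu2 <- gz(b)
  v1 <- pmax(gz(a * a) - mu1^2, 0)
  v2 <- pmax(gz(b * b) - mu2^2, 0)
  cv <- gz(a * b) - mu1 * mu2
  smap <- ((2 * mu1 * mu2 + C1) * (2 * cv + C2)) /
    ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2))
  if (is.null(voi)) mean(smap) else mean(smap[voi])
}
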