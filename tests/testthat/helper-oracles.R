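# brute-force windowed-correlation oracle: explicit per-window loops over
# Gaussian weights, mask-aware, floored variances — independent of the
# convolution-based implementation
lncc_oracle <- function(P, Pp, cfg, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(P), ncol(P))
  n <- nrow(P); m <- ncol(P)
  rad <- ceiling(3.5 * cfg$sigma_px)
  dr <- diff(range(P[mask]))
  eps <- cfg$variance_floor * (if (dr > 0) dr^2 else 1)
  vals <- c()
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!mask[i, j]) next
    wsum <- 0; sP <- 0; sQ <- 0; sPP <- 0; sQQ <- 0; sPQ <- 0
    for (a in max(1, i - rad):min(n, i + rad))
      for (b in max(1, j - rad):min(m, j + rad)) {
        if (!mask[a, b]) next
        da <- a - i; db <- b - j
        if (abs(da) > rad || abs(db) > rad) next
        w <- exp(-0.5 * (da / cfg$sigma_px)^2) * exp(-0.5 * (db / cfg$sigma_px)^2)
        wsum <- wsum + w
        sP <- sP + w * P[a, b]; sQ <- sQ + w * Pp[a, b]
        sPP <- sPP + w * P[a, b]^2; sQQ <- sQQ + w * Pp[a, b]^2
        sPQ <- sPQ + w * P[a, b] * Pp[a, b]
      }
    mP <- sP / wsum; mQ <- sQ / wsum
    vP <- max(sPP / wsum - mP^2, 0); vQ <- max(sQQ / wsum - mQ^2, 0)
    cv <- sPQ / wsum - mP * mQ
    vals <- c(vals, (cv + eps) / sqrt((vP + eps) * (vQ + eps)))
  }
  mean(vals)
}
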