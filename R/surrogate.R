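#' Respiratory trace
#'
#' A 1-D signal sampled at the projection timestamps.
#'
#' @param values numeric vector.
#' @param times sample times in seconds (strictly increasing).
#' @param label short signal name.
#' @return an object of class `resp_trace`.
#' @export
resp_trace <- function(values, times, label = "signal") {
  stopifnot(length(values) == length(times))
  if (any(diff(times) <= 0)) stop("sample times must be strictly increasing")
  structure(list(values = as.numeric(values), times = as.numeric(times),
                 label = label), class = "resp_trace")
}

#' @export
print.resp_trace <- function(x, ...) {
  cat(sprintf("resp_trace '%s': %d samples over %.1f s, range [%.3g, %.3g]\n",
              x$label, length(x$values), diff(range(x$times)),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Intensity-analysis surrogate extraction
#'
#' Computes the sum of pixel intensities of each projection and splits the
#' resulting 1-D signal into a low-frequency component (slow gantry-rotation
#' trend) and a high-frequency component (respiration). The high-frequency
#' residual, obtained with a zero-phase 2nd-order Butterworth high-pass at
#' `band_split_hz`, is returned as the surrogate signal.
#'
#' @param projs a [projection_stack()] of line integrals.
#' @param band_split_hz frequency separating gantry drift from respiration
#'   (default 0.1 Hz: above the ~1/60 Hz rotation, below ~0.2-0.5 Hz
#'   breathing).
#' @return a [resp_trace()].
#' @export
ia_extract <- function(projs, band_split_hz = 0.1) {
  stopifnot(inherits(projs, "projection_stack"))
  nt <- n_frames(projs)
  if (nt < 16) stop("too few frames for surrogate extraction (need >= 16)")
  sums <- apply(projs$data, 3, sum)
  if (any(!is.finite(sums))) stop("non-finite projection sums")
  times <- projs$geometry$times
  fs <- 1 / mean(diff(times))
  wn <- band_split_hz / (fs / 2)
  if (wn <= 0 || wn >= 1) stop("band_split_hz outside the representable band")
  bf <- signal::butter(2, wn, type = "high")
  x <- sums - mean(sums)
  # point-reflected padding suppresses the filter's edge transients, which
  # otherwise leak the gantry trend back into the extracted signal
  npad <- min(nt - 1, round(1.5 * fs / band_split_hz))
  xp <- c(2 * x[1] - rev(x[2:(npad + 1)]), x,
          2 * x[nt] - rev(x[(nt - npad):(nt - 1)]))
  hi <- signal::filtfilt(bf, xp)[(npad + 1):(npad + nt)]
  resp_trace(hi, times, "IA")
}

#' Temporal gradient of a trace
#'
#' Central differences over the sample times (one-sided at the ends), lightly
#' smoothed with a 3-sample moving average to curb noise amplification. Used
#' as the second surrogate signal (a breathing-rate proxy).
#'
#' @param trace a [resp_trace()].
#' @return a [resp_trace()].
#' @export
temporal_gradient <- function(trace) {
  v <- trace$values; tt <- trace$times
  n <- length(v)
  if (n < 3) stop("need at least 3 samples")
  g <- numeric(n)
  g[1] <- (v[2] - v[1]) / (tt[2] - tt[1])
  g[n] <- (v[n] - v[n - 1]) / (tt[n] - tt[n - 1])
  g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  sm <- g
  sm[2:(n - 1)] <- (g[1:(n - 2)] + g[2:(n - 1)] + g[3:n]) / 3
  resp_trace(sm, tt, paste0("d/dt ", trace$label))
}

#' Normalize a trace to zero mean and unit standard deviation
#'
#' Uses the sample (n-1) standard deviation convention.
#'
#' @param trace a [resp_trace()].
#' @return a [resp_trace()].
#' @export
normalize_signal <- function(trace) {
  v <- trace$values
  s <- sd(v)
  if (!is.finite(s) || s == 0) stop("cannot normalize a constant trace")
  resp_trace((v - mean(v)) / s, trace$times, trace$label)
}

#' Assemble a normalized surrogate matrix
#'
#' Binds traces column-wise into the `N_t x N_s` surrogate matrix, normalizing
#' each column to mean 0 and (sample) standard deviation 1.
#'
#' @param ... [resp_trace()] objects or numeric vectors of equal length.
#' @return numeric matrix with one normalized column per signal.
#' @export
surrogate_matrix <- function(...) {
  sigs <- list(...)
  cols <- lapply(sigs, function(s) {
    if (inherits(s, "resp_trace")) s <- s$values
    as.numeric(s)
  })
  labs <- vapply(seq_along(sigs), function(i) {
    if (inherits(sigs[[i]], "resp_trace")) sigs[[i]]$label else paste0("s", i)
  }, character(1))
  m <- do.call(cbind, cols)
  m <- scale(m)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  colnames(m) <- labs
  m
}

#' Extract both surrogate signals from a projection stack
#'
#' Convenience pipeline: IA extraction, temporal gradient as the second
#' signal, both normalized.
#'
#' @inheritParams ia_extract
#' @return normalized surrogate matrix `(N_t, 2)` with columns `IA` and its
#'   temporal gradient.
#' @export
extract_surrogates <- function(projs, band_split_hz = 0.1) {
  s1 <- ia_extract(projs, band_split_hz)
  s2 <- temporal_gradient(s1)
  surrogate_matrix(s1, s2)
}
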