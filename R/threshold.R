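#' IsoData (iterative intermeans) automatic threshold
#'
#' Classical histogram-based automatic threshold: starting from the global
#' mean, iterate t <- (mean(x <= t) + mean(x > t)) / 2 until the fixed point.
#' This is the default automatic method of common image-analysis software.
#'
#' @param x numeric vector or array of intensities.
#' @param n_bins number of histogram bins used for the iteration.
#' @param max_iter iteration cap.
#' @return the threshold, in intensity units.
#' @export
isodata_threshold <- function(x, n_bins = 256L, max_iter = 1000L) {
  x <- as.numeric(x)
  lo <- min(x)
  hi <- max(x)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("degenerate histogram: constant-intensity image has no IsoData threshold",
         call. = FALSE)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  centers <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  t <- sum(counts * centers) / sum(counts)
  for (i in seq_len(max_iter)) {
    below <- centers <= t
    n0 <- sum(counts[below]); n1 <- sum(counts[!below])
    if (n0 == 0 || n1 == 0) break
    m0 <- sum(counts[below] * centers[below]) / n0
    m1 <- sum(counts[!below] * centers[!below]) / n1
    t_new <- (m0 + m1) / 2
    if (abs(t_new - t) < (hi - lo) * 1e-12) { t <- t_new; break }
    t <- t_new
  }
  t
}

#' Compute a channel threshold
#'
#' Three policies mirror common practice for these stacks: `auto` runs the
#' IsoData intermeans algorithm on the channel; `manual` uses a supplied
#' value; `cross` copies a previously computed threshold value verbatim onto
#' this channel (used when software-recommended tdTomato thresholds drift
#' between experimental conditions and the vessel-channel threshold is applied
#' to tdTomato instead).
#'
#' @param volume a [render_volume()] result (or any list with `$channels`).
#' @param channel channel name, one of `"FITC"`, `"tdTomato"`, `"DAPI"`.
#' @param method `"auto"`, `"manual"` or `"cross"`.
#' @param manual_value required for `method = "manual"`.
#' @param source_threshold a `channel_threshold` previously computed on the
#'   source channel; required for `method = "cross"`.
#' @return An object of class `channel_threshold` with fields `channel`,
#'   `method`, `value` and (for cross) `source_channel`.
#' @export
compute_threshold <- function(volume, channel,
                              method = c("auto", "manual", "cross"),
                              manual_value = NULL, source_threshold = NULL) {
  method <- match.arg(method)
  if (!channel %in% names(volume$channels))
    stop("unknown channel '", channel, "'", call. = FALSE)
  value <- switch(method,
    auto = isodata_threshold(volume$channels[[channel]]),
    manual = {
      if (is.null(manual_value)) stop("method 'manual' requires 'manual_value'",
                                      call. = FALSE)
      as.numeric(manual_value)
    },
    cross = {
      if (!inherits(source_threshold, "channel_threshold"))
        stop("method 'cross' requires a previously computed 'source_threshold'",
             call. = FALSE)
      source_threshold$value
    })
  structure(list(channel = channel, method = method, value = value,
                 source_channel = if (method == "cross") source_threshold$channel
                                  else NA_character_),
            class = "channel_threshold")
}

#' @export
print.channel_threshold <- function(x, ...) {
  cat(sprintf("Threshold %s = %.6g (%s%s)\n", x$channel, x$value, x$method,
              if (!is.na(x$source_channel)) paste0(" from ", x$source_channel) else ""))
  invisible(x)
}
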