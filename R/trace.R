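# FluorescenceTrace: one ROI's sampled intensity time series with a scalar
# background reference (measured in a cell-free region of the same recording).

#' Fluorescence trace
#'
#' @param times Sample times (s), strictly increasing.
#' @param values Fluorescence intensities (a.u.), finite.
#' @param background Scalar background fluorescence f0 (a.u.), non-negative.
#' @param label ROI/cell identifier.
#' @param genotype Group label (e.g. a connexin variant).
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(times, values, background = 0,
                               label = "", genotype = NA_character_) {
  check_times(times)
  if (length(values) != length(times)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  if (!is.numeric(background) || length(background) != 1 || background < 0) {
    stop("background must be a non-negative scalar", call. = FALSE)
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 background = as.numeric(background),
                 label = as.character(label),
                 genotype = as.character(genotype)),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_trace> %s%s: %d samples, t = [%g, %g] s, f0 = %g a.u.\n",
    x$label, if (is.na(x$genotype)) "" else paste0(" (", x$genotype, ")"),
    length(x$times), x$times[1], x$times[length(x$times)], x$background))
  invisible(x)
}

# background-subtracted values
bg_sub <- function(trace) trace$values - trace$background

# TRUE for samples falling inside any of the given [start, end] intervals
# (used to mask blocker applications out of fit windows)
in_intervals <- function(times, intervals) {
  inside <- rep(FALSE, length(times))
  for (iv in intervals) {
    stopifnot(length(iv) == 2, iv[1] <= iv[2])
    inside <- inside | (times >= iv[1] & times <= iv[2])
  }
  inside
}
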