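# Electrophysiology: macroscopic conductance from voltage ramps, unitary
# conductance from all-point amplitude histograms of single-channel records,
# and the open-channel count n*Po = g/gamma that links conductance to flux.

#' Voltage-ramp record
#'
#' @param times Sample times (s), ordered.
#' @param voltage Membrane voltage (mV); the ramp must cross 0 mV.
#' @param current Whole-cell current (pA).
#' @return An object of class `ramp_record`.
#' @export
ramp_record <- function(times, voltage, current) {
  check_times(times)
  stopifnot(length(voltage) == length(times), length(current) == length(times))
  if (min(voltage) > 0 || max(voltage) < 0) {
    stop("ramp must cover 0 mV", call. = FALSE)
  }
  structure(list(times = as.numeric(times), voltage = as.numeric(voltage),
                 current = as.numeric(current)), class = "ramp_record")
}

#' Constant-voltage single-channel record
#'
#' @param times Sample times (s), ordered.
#' @param current Current (pA).
#' @param holding_mv Holding voltage (mV), non-zero for conductance
#'   conversion.
#' @return An object of class `unitary_record`.
#' @export
unitary_record <- function(times, current, holding_mv) {
  check_times(times)
  stopifnot(length(current) == length(times), is.numeric(holding_mv),
            length(holding_mv) == 1)
  if (holding_mv == 0) stop("holding voltage must be non-zero", call. = FALSE)
  structure(list(times = as.numeric(times), current = as.numeric(current),
                 holding_mv = as.numeric(holding_mv)),
            class = "unitary_record")
}

#' Channel population summary
#'
#' Couples a macroscopic conductance `g` with a unitary conductance `gamma`;
#' their ratio is the open-channel count `n*Po` (channel number times open
#' probability — only the product is identifiable from conductance).
#'
#' @param g_ns Macroscopic conductance (nS), non-negative.
#' @param gamma_ps Unitary conductance (pS), positive.
#' @param genotype Optional group label.
#' @return An object of class `channel_population` with field `n_po = g/gamma`.
#' @export
channel_population <- function(g_ns, gamma_ps, genotype = NA_character_) {
  stopifnot(is.numeric(g_ns), g_ns >= 0, is.numeric(gamma_ps), gamma_ps > 0)
  structure(list(g_ns = g_ns, gamma_ps = gamma_ps,
                 n_po = estimate_channel_count(g_ns, gamma_ps),
                 genotype = as.character(genotype)),
            class = "channel_population")
}

#' Slope conductance at zero membrane voltage
#'
#' Local linear regression of current on voltage within `window_mv` of 0 mV;
#' the slope dI/dV (pA/mV = nS) is the membrane conductance at Vm = 0, the
#' operating point of the dye-flux assays. Slope (not chord) conductance is
#' used because the chord ratio I/V is singular at 0 mV.
#'
#' @param record A [ramp_record()].
#' @param window_mv Half-width of the voltage window (mV), default 5.
#' @return Conductance in nS.
#' @export
conductance_at_zero <- function(record, window_mv = 5) {
  stopifnot(inherits(record, "ramp_record"), window_mv > 0)
  sel <- abs(record$voltage) <= window_mv
  if (sum(sel) < 10) {
    stop(sprintf("fewer than 10 samples within +/-%g mV of 0", window_mv),
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, record$voltage[sel]), record$current[sel])
  unname(fit$coefficients[2])
}

#' Fit a normal mixture to an all-point amplitude histogram
#'
#' Maximum-likelihood Gaussian mixture fit (via EM, unequal variances) to all
#' current samples of a single-channel record. Components are returned sorted
#' by mean. Adjacent components whose means are closer than twice the pooled
#' SD are flagged as unresolved, since their level spacing is not reliable.
#'
#' @param record A [unitary_record()] (or bare numeric current vector).
#' @param n_components Number of mixture components (>= 2): closed level plus
#'   one per simultaneously open channel.
#' @param seed Integer seed controlling the (subsampled) EM initialization.
#' @return An `amplitude_mixture` with fields `means` (pA), `sds` (pA),
#'   `weights`, `loglik`, `unresolved`.
#' @export
fit_amplitude_histogram <- function(record, n_components = 2, seed = 1) {
  x <- if (inherits(record, "unitary_record")) record$current else
    as.numeric(record)
  stopifnot(n_components >= 2)
  if (length(x) < 5000) {
    stop("record too short for amplitude-histogram fitting (< 5000 samples)",
         call. = FALSE)
  }
  fit <- withr::with_seed(seed,
    mclust::Mclust(x, G = n_components, modelNames = "V", verbose = FALSE))
  if (is.null(fit)) stop("mixture fit did not converge", call. = FALSE)
  ord <- order(fit$parameters$mean)
  means <- as.numeric(fit$parameters$mean)[ord]
  sds <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sds) == 1) sds <- rep(sds, n_components)
  sds <- sds[ord]
  weights <- fit$parameters$pro[ord]
  spacing <- diff(means)
  pooled <- sqrt((sds[-length(sds)]^2 + sds[-1]^2) / 2)
  structure(list(means = means, sds = sds, weights = weights,
                 loglik = fit$loglik,
                 unresolved = any(spacing < 2 * pooled)),
            class = "amplitude_mixture")
}

#' @export
print.amplitude_mixture <- function(x, ...) {
  cat("<amplitude_mixture>", length(x$means), "components",
      if (x$unresolved) "(UNRESOLVED)" else "", "\n")
  print(data.frame(mean_pa = x$means, sd_pa = x$sds, weight = x$weights))
  invisible(x)
}

#' Leak-subtract a single-channel record
#'
#' Shifts the record so the closed level sits at 0 pA. The closed level is
#' the mixture component of smallest absolute mean current (channel openings
#' carry the signal away from the leak baseline in the direction set by the
#' holding voltage).
#'
#' @param record A [unitary_record()].
#' @param mixture Optional precomputed [fit_amplitude_histogram()] result;
#'   fitted with `n_components = 2` otherwise.
#' @param seed Seed forwarded to [fit_amplitude_histogram()].
#' @return The record with `current` shifted and attribute `closed_mean_pa`.
#' @export
leak_subtract <- function(record, mixture = NULL, seed = 1) {
  stopifnot(inherits(record, "unitary_record"))
  if (is.null(mixture)) {
    mixture <- fit_amplitude_histogram(record, n_components = 2, seed = seed)
  }
  if (length(mixture$means) == 0 || !all(is.finite(mixture$means))) {
    stop("no closed level identifiable", call. = FALSE)
  }
  closed <- mixture$means[which.min(abs(mixture$means))]
  out <- record
  out$current <- record$current - closed
  attr(out, "closed_mean_pa") <- closed
  out
}

#' Unitary conductance from an amplitude mixture
#'
#' The single-channel conductance is the mean spacing of adjacent mixture
#' levels divided by the absolute holding voltage (pA/mV = nS, reported in
#' pS). Multi-channel records, whose equally spaced levels reflect
#' superposition, therefore contribute through the mean adjacent spacing.
#'
#' @param mixture An `amplitude_mixture` with at least 2 resolved components.
#' @param holding_mv Holding voltage (mV), non-zero.
#' @return Unitary conductance gamma in pS.
#' @export
unitary_conductance <- function(mixture, holding_mv) {
  stopifnot(inherits(mixture, "amplitude_mixture"), holding_mv != 0)
  if (length(mixture$means) < 2) {
    stop("need at least two mixture components", call. = FALSE)
  }
  if (isTRUE(mixture$unresolved)) {
    stop("mixture components unresolved; cannot measure level spacing",
         call. = FALSE)
  }
  mean(diff(mixture$means)) / abs(holding_mv) * 1000
}

#' Open-channel count from conductances
#'
#' `n*Po = g/gamma` with explicit nS-to-pS conversion. Open probability and
#' channel number are never separated; only their product enters the
#' permeability normalization.
#'
#' @param g_ns Macroscopic conductance (nS).
#' @param gamma_ps Unitary conductance (pS), positive.
#' @return Dimensionless open-channel count.
#' @export
estimate_channel_count <- function(g_ns, gamma_ps) {
  if (!is.numeric(gamma_ps) || any(gamma_ps <= 0)) {
    stop("gamma_ps must be positive", call. = FALSE)
  }
  g_ns * 1000 / gamma_ps
}
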