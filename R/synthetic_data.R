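# Synthetic-data generators: efflux and transfer fluorescence traces,
# two-state single-channel current records, and multi-genotype cohorts with a
# ground-truth manifest. Every generator is deterministic under its seed and
# collapses to the closed-form forward model at zero noise.

#' Calcein-efflux recording scenario
#'
#' Defaults emulate the study conditions of the efflux assay: one frame every
#' 10 s for ~30 min.
#'
#' @param params An [efflux_params()] object (ground truth).
#' @param calibration A [fluorescence_calibration()] object.
#' @param interval_s Sampling interval (s), default 10.
#' @param duration_s Recording duration (s), default 1800; at least
#'   10 intervals.
#' @param noise_cv Multiplicative Gaussian noise coefficient of variation on
#'   fluorescence, default 0.
#' @param seed Integer seed.
#' @return An object of class `efflux_scenario`.
#' @export
efflux_scenario <- function(params, calibration, interval_s = 10,
                            duration_s = 1800, noise_cv = 0, seed = 1) {
  stopifnot(inherits(params, "efflux_params"),
            inherits(calibration, "fluorescence_calibration"),
            interval_s > 0, duration_s >= 10 * interval_s, noise_cv >= 0)
  structure(list(params = params, calibration = calibration,
                 interval_s = interval_s, duration_s = duration_s,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "efflux_scenario")
}

#' Generate a calcein-efflux fluorescence trace
#'
#' `F(t) = f C_in(t) + f0` from the closed-form efflux solution, with
#' multiplicative Gaussian noise. Ground truth is attached as attribute
#' `truth`.
#'
#' @param scenario An [efflux_scenario()].
#' @return A [fluorescence_trace()]; `attr(, "truth")` holds the generating
#'   parameters.
#' @export
generate_efflux_trace <- function(scenario) {
  stopifnot(inherits(scenario, "efflux_scenario"))
  times <- seq(0, scenario$duration_s, by = scenario$interval_s)
  conc <- efflux_solution(scenario$params, times)
  f <- scenario$calibration$f * conc + scenario$calibration$f0
  if (scenario$noise_cv > 0) {
    f <- withr::with_seed(scenario$seed,
      f * (1 + scenario$noise_cv * stats::rnorm(length(f))))
  }
  tr <- fluorescence_trace(times, f, background = scenario$calibration$f0)
  attr(tr, "truth") <- list(
    params = scenario$params, calibration = scenario$calibration,
    slope_k = scenario$calibration$f *
      (scenario$params$alpha -
         scenario$params$c_in_0 * scenario$params$perm) /
      scenario$params$vol_in)
  tr
}

#' Lucifer-Yellow transfer scenario
#'
#' Defaults emulate the dye-transfer assay: 15-min recordings sampled every
#' 30 s, a donor cell loading from the patch pipette toward a 2 mM working
#' concentration with a single-exponential time constant, and optional
#' channel-blocker intervals during which junctional flux is suspended.
#'
#' @param rate Transfer rate `P_j/Vol_2` (1/s), ground truth.
#' @param calibration A [fluorescence_calibration()] object.
#' @param tau_load_s Donor loading time constant (s), default 80 (steady
#'   state around 350 s).
#' @param plateau_um Donor plateau concentration (uM), default 2000.
#' @param interval_s Sampling interval (s), default 30.
#' @param duration_s Recording duration (s), default 900.
#' @param blockers List of `c(start, end)` intervals (s) with the junctional
#'   rate forced to 0 (idealized, fully reversible block).
#' @param noise_cv Multiplicative Gaussian noise CV, default 0.
#' @param seed Integer seed.
#' @return An object of class `transfer_scenario`.
#' @export
transfer_scenario <- function(rate, calibration, tau_load_s = 80,
                              plateau_um = 2000, interval_s = 30,
                              duration_s = 900, blockers = list(),
                              noise_cv = 0, seed = 1) {
  stopifnot(rate >= 0, inherits(calibration, "fluorescence_calibration"),
            tau_load_s > 0, plateau_um > 0, interval_s > 0,
            duration_s >= 10 * interval_s, noise_cv >= 0)
  for (iv in blockers) {
    stopifnot(length(iv) == 2, iv[1] >= 0, iv[2] <= duration_s, iv[1] < iv[2])
  }
  if (length(blockers) > 1) {
    o <- order(vapply(blockers, `[`, numeric(1), 1))
    b <- blockers[o]
    for (k in seq_len(length(b) - 1)) {
      if (b[[k]][2] > b[[k + 1]][1]) {
        stop("blocker intervals must not overlap", call. = FALSE)
      }
    }
  }
  structure(list(rate = rate, calibration = calibration,
                 tau_load_s = tau_load_s, plateau_um = plateau_um,
                 interval_s = interval_s, duration_s = duration_s,
                 blockers = blockers, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "transfer_scenario")
}

#' Generate donor/recipient transfer traces
#'
#' Donor concentration follows `plateau (1 - exp(-t/tau))`; the recipient is
#' integrated against the time-varying donor with fixed-step fourth-order
#' Runge-Kutta (step `min(1, interval/10)` s), with the junctional rate set
#' to 0 inside blocker intervals. Fluorescence is `f C + f0` plus
#' multiplicative noise.
#'
#' @param scenario A [transfer_scenario()].
#' @return List with elements `donor` and `recipient`
#'   ([fluorescence_trace()]s); `attr(, "truth")` holds the generating
#'   parameters.
#' @export
generate_transfer_traces <- function(scenario) {
  stopifnot(inherits(scenario, "transfer_scenario"))
  times <- seq(0, scenario$duration_s, by = scenario$interval_s)
  c1 <- scenario$plateau_um * (1 - exp(-times / scenario$tau_load_s))
  h <- min(1, scenario$interval_s / 10)
  c2 <- rk4_recipient(scenario, times, h)
  cal <- scenario$calibration
  f1 <- cal$f * c1 + cal$f0
  f2 <- cal$f * c2 + cal$f0
  if (scenario$noise_cv > 0) {
    noisy <- withr::with_seed(scenario$seed, {
      list(f1 = f1 * (1 + scenario$noise_cv * stats::rnorm(length(f1))),
           f2 = f2 * (1 + scenario$noise_cv * stats::rnorm(length(f2))))
    })
    f1 <- noisy$f1; f2 <- noisy$f2
  }
  out <- list(
    donor = fluorescence_trace(times, f1, background = cal$f0,
                               label = "donor"),
    recipient = fluorescence_trace(times, f2, background = cal$f0,
                                   label = "recipient"))
  attr(out, "truth") <- list(rate = scenario$rate,
                             plateau_um = scenario$plateau_um,
                             tau_load_s = scenario$tau_load_s,
                             blockers = scenario$blockers)
  out
}

# recipient concentration by fixed-step RK4 against the loading donor,
# junctional rate gated to zero inside blocker intervals
rk4_recipient <- function(scenario, times, h) {
  donor_c <- function(t) {
    scenario$plateau_um * (1 - exp(-t / scenario$tau_load_s))
  }
  rate_at <- function(t) {
    if (length(scenario$blockers) &&
        any(vapply(scenario$blockers,
                   function(iv) t >= iv[1] && t <= iv[2], logical(1)))) {
      return(0)
    }
    scenario$rate
  }
  deriv <- function(t, c2) rate_at(t) * (donor_c(t) - c2)
  out <- numeric(length(times))
  c2 <- 0
  t <- times[1]
  out[1] <- c2
  for (k in 2:length(times)) {
    while (t < times[k] - 1e-12) {
      step <- min(h, times[k] - t)
      k1 <- deriv(t, c2)
      k2 <- deriv(t + step / 2, c2 + step / 2 * k1)
      k3 <- deriv(t + step / 2, c2 + step / 2 * k2)
      k4 <- deriv(t + step, c2 + step * k3)
      c2 <- c2 + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + step
    }
    out[k] <- c2
  }
  out
}

#' Generate a two-state single-channel current record
#'
#' Independent two-state Markov gating per channel: open and closed dwell
#' times are exponential with means `mean_dwell_s` and
#' `mean_dwell_s (1 - p_open)/p_open`, giving stationary open probability
#' `p_open`. The current is the number of open channels times
#' `gamma * V / 1000` (pA), plus a baseline offset and additive Gaussian
#' noise.
#'
#' @param gamma_ps Unitary conductance (pS).
#' @param holding_mv Holding voltage (mV), non-zero.
#' @param p_open Stationary open probability, in (0, 1).
#' @param mean_dwell_s Mean open dwell time (s).
#' @param sampling_hz Sampling rate (Hz), default 1000.
#' @param duration_s Record duration (s), default 10.
#' @param noise_sd_pa Additive Gaussian noise SD (pA), default 0.
#' @param n_channels Number of independent channels, default 1.
#' @param baseline_pa Leak/baseline current offset (pA), default 0.
#' @param seed Integer seed.
#' @return A [unitary_record()]; `attr(, "truth")` holds the generating
#'   parameters including the per-channel open fraction.
#' @export
generate_unitary_record <- function(gamma_ps, holding_mv, p_open,
                                    mean_dwell_s, sampling_hz = 1000,
                                    duration_s = 10, noise_sd_pa = 0,
                                    n_channels = 1, baseline_pa = 0,
                                    seed = 1) {
  stopifnot(gamma_ps > 0, holding_mv != 0, p_open > 0, p_open < 1,
            mean_dwell_s > 0, sampling_hz > 0, duration_s > 0,
            noise_sd_pa >= 0, n_channels >= 1)
  times <- seq(0, duration_s, by = 1 / sampling_hz)
  n <- length(times)
  tau_open <- mean_dwell_s
  tau_closed <- mean_dwell_s * (1 - p_open) / p_open
  i_unit <- gamma_ps * holding_mv / 1000  # pA
  withr::with_seed(seed, {
    n_open <- integer(n)
    for (ch in seq_len(n_channels)) {
      state <- stats::runif(1) < p_open
      t_cur <- 0
      open_ch <- logical(n)
      idx <- 1
      while (t_cur < duration_s) {
        dwell <- stats::rexp(1, 1 / if (state) tau_open else tau_closed)
        t_next <- t_cur + dwell
        upto <- min(n, floor(t_next * sampling_hz) + 1)
        if (upto >= idx) open_ch[idx:upto] <- state
        idx <- upto + 1
        t_cur <- t_next
        state <- !state
      }
      n_open <- n_open + open_ch
    }
    current <- baseline_pa + n_open * i_unit
    if (noise_sd_pa > 0) current <- current + stats::rnorm(n, 0, noise_sd_pa)
    rec <- unitary_record(times, current, holding_mv)
    attr(rec, "truth") <- list(gamma_ps = gamma_ps, p_open = p_open,
                               n_channels = n_channels,
                               baseline_pa = baseline_pa,
                               open_fraction = mean(n_open) / n_channels)
    rec
  })
}

#' Cohort specification for the four-genotype study design
#'
#' Describes a synthetic cohort emulating the efflux study: per genotype, a
#' set of calcein-loaded cells with known single-channel permeability
#' `p_gamma` (pl/s per channel) whose total permeability is
#' `p_gamma * n_po`, plus an independent set of patched cells providing
#' conductance-based `n_po = g/gamma` estimates. The open-channel-count
#' distribution is shared across genotypes by default, so group differences
#' in efflux reflect per-channel permeability only.
#'
#' @param genotypes data.frame with columns `label`, `p_gamma_pl_s`,
#'   `gamma_ps`. The default is a four-variant design (two high-permeability
#'   and two low-permeability genotypes, 10-fold apart, with unitary
#'   conductances around 283-340 pS).
#' @param n_cells Efflux cells per genotype, default 30.
#' @param n_ephys Patched cells per genotype, default 8.
#' @param n_po_meanlog,n_po_sdlog Log-normal parameters of the open-channel
#'   count (default median 10, sdlog 0.3).
#' @param vol_meanlog,vol_sdlog Log-normal cell-volume parameters (pl;
#'   default median 3 pl, sdlog 0.2).
#' @param c0_um Initial intracellular dye concentration (uM), default 100.
#' @param calibration A [fluorescence_calibration()]; default f = 5 a.u./uM,
#'   f0 = 50 a.u.
#' @param noise_cv Multiplicative fluorescence noise CV, default 0.02.
#' @param interval_s,duration_s Efflux sampling design, default 10 s / 1800 s.
#' @param seed Master seed; per-cell seeds are derived deterministically.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(genotypes = NULL, n_cells = 30, n_ephys = 8,
                        n_po_meanlog = log(10), n_po_sdlog = 0.3,
                        vol_meanlog = log(3), vol_sdlog = 0.2,
                        c0_um = 100,
                        calibration = fluorescence_calibration(5, 50),
                        noise_cv = 0.02, interval_s = 10, duration_s = 1800,
                        seed = 1) {
  if (is.null(genotypes)) {
    genotypes <- data.frame(
      label = c("Cx26", "Cx26-A49E", "Cx30", "Cx30-E49A"),
      p_gamma_pl_s = c(3e-4, 3e-5, 3e-5, 3e-4),
      gamma_ps = c(340, 340, 283, 295))
  }
  stopifnot(is.data.frame(genotypes),
            all(c("label", "p_gamma_pl_s", "gamma_ps") %in% names(genotypes)),
            nrow(genotypes) >= 2, n_cells >= 3, n_ephys >= 3,
            !anyDuplicated(genotypes$label))
  structure(list(genotypes = genotypes, n_cells = n_cells, n_ephys = n_ephys,
                 n_po_meanlog = n_po_meanlog, n_po_sdlog = n_po_sdlog,
                 vol_meanlog = vol_meanlog, vol_sdlog = vol_sdlog,
                 c0_um = c0_um, calibration = calibration,
                 noise_cv = noise_cv, interval_s = interval_s,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic multi-genotype cohort
#'
#' Draws per-cell volumes and open-channel counts, builds one efflux trace
#' per cell via [generate_efflux_trace()], and emits an electrophysiology
#' table (macroscopic conductance `g = n_po * gamma` per patched cell) plus
#' a ground-truth manifest.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `efflux` (list of
#'   traces with genotype labels), `ephys` (data.frame `genotype`, `cell`,
#'   `g_ns`, `gamma_ps`, `n_po`), `truth` (per-cell manifest), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  gts <- spec$genotypes
  draws <- withr::with_seed(spec$seed, {
    lapply(seq_len(nrow(gts)), function(gi) {
      list(vol = stats::rlnorm(spec$n_cells, spec$vol_meanlog, spec$vol_sdlog),
           n_po = stats::rlnorm(spec$n_cells, spec$n_po_meanlog,
                                spec$n_po_sdlog),
           n_po_ephys = stats::rlnorm(spec$n_ephys, spec$n_po_meanlog,
                                      spec$n_po_sdlog))
    })
  })
  traces <- list()
  truth <- list()
  ephys <- list()
  cell_counter <- 0L
  for (gi in seq_len(nrow(gts))) {
    d <- draws[[gi]]
    for (ci in seq_len(spec$n_cells)) {
      cell_counter <- cell_counter + 1L
      p_total <- gts$p_gamma_pl_s[gi] * d$n_po[ci]
      sc <- efflux_scenario(
        efflux_params(vol_in = d$vol[ci], perm = p_total,
                      c_in_0 = spec$c0_um),
        spec$calibration, interval_s = spec$interval_s,
        duration_s = spec$duration_s, noise_cv = spec$noise_cv,
        seed = (spec$seed * 1000L + cell_counter) %% 2147483647L)
      tr <- generate_efflux_trace(sc)
      tr$label <- sprintf("%s_cell%02d", gts$label[gi], ci)
      tr$genotype <- gts$label[gi]
      traces[[cell_counter]] <- tr
      truth[[cell_counter]] <- data.frame(
        genotype = gts$label[gi], cell = tr$label, vol_pl = d$vol[ci],
        n_po = d$n_po[ci], p_gamma_pl_s = gts$p_gamma_pl_s[gi],
        p_total_pl_s = p_total,
        true_slope_au_s = attr(tr, "truth")$slope_k)
    }
    ephys[[gi]] <- data.frame(
      genotype = gts$label[gi],
      cell = sprintf("%s_ephys%02d", gts$label[gi], seq_len(spec$n_ephys)),
      g_ns = d$n_po_ephys * gts$gamma_ps[gi] / 1000,
      gamma_ps = gts$gamma_ps[gi],
      n_po = d$n_po_ephys)
  }
  structure(list(efflux = traces,
                 ephys = do.call(rbind, ephys),
                 truth = do.call(rbind, truth),
                 spec = spec), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d genotypes, %d efflux cells, %d patched cells\n",
    nrow(x$spec$genotypes), length(x$efflux), nrow(x$ephys)))
  invisible(x)
}
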