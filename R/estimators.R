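# Estimators: convert fluorescence traces into permeability metrics.
#
# Hemichannel arm: pick the linear phase of a calcein efflux trace, fit the
# slope k (a.u./s), and normalize by the open-channel count g/gamma to get a
# per-channel permeability proxy.  GJ arm: fit the recipient-cell exponential
# (or the ODE-discretization estimator) to Lucifer-Yellow transfer traces to
# get P_j/Vol_2 (1/s), then normalize per channel via g_j/gamma_j.

#' Select the linear phase of a fluorescence trace
#'
#' Finds the longest contiguous window of at least `min_points` samples whose
#' ordinary-least-squares fit shows no lack of fit: the residual variance may
#' not exceed `resid_factor` times the local noise variance estimated from
#' second differences (which cancel any linear trend but respond to curvature
#' and kinks). Unlike an r-squared threshold, this criterion accepts windows
#' whose slope is indistinguishable from zero or shallow relative to noise,
#' and rejects windows that straddle a changepoint even when a steep segment
#' inflates their r-squared. Exactly linear noise-free data pass via a small
#' numerical floor. Ties in window length are broken toward the earliest
#' window, i.e. the phase immediately after solution exchange.
#'
#' @param trace A [fluorescence_trace()].
#' @param min_points Minimum number of samples in a window (default 12).
#' @param resid_factor Allowed ratio of linear-fit residual variance to the
#'   second-difference noise variance (default 3).
#' @param exclude Optional list of `c(start, end)` time intervals (s), e.g.
#'   channel-blocker applications, masked out of all candidate windows.
#' @return Numeric `c(t_start, t_end)` (s) delimiting the selected window.
#' @export
select_linear_window <- function(trace, min_points = 12,
                                 resid_factor = 3, exclude = NULL) {
  stopifnot(inherits(trace, "fluorescence_trace"), min_points >= 3)
  if (length(trace$times) < min_points) {
    stop("trace has fewer samples than min_points", call. = FALSE)
  }
  keep <- !in_intervals(trace$times, exclude %||% list())
  runs <- split(seq_along(trace$times)[keep],
                cumsum(c(TRUE, diff(seq_along(trace$times)[keep]) > 1)))
  best <- NULL  # list(len, start_time, idx)
  for (run in runs) {
    if (length(run) < min_points) next
    cand <- best_window_in_run(trace$times[run], trace$values[run],
                               min_points, resid_factor)
    if (is.null(cand)) next
    cand$idx <- run[cand$idx]
    if (is.null(best) || cand$len > best$len ||
        (cand$len == best$len && trace$times[cand$idx[1]] < best$start_time)) {
      cand$start_time <- trace$times[cand$idx[1]]
      best <- cand
    }
  }
  if (is.null(best)) {
    stop(sprintf(
      "no window of >= %d samples met the linearity (lack-of-fit) criterion",
      min_points), call. = FALSE)
  }
  c(t_start = trace$times[best$idx[1]], t_end = trace$times[best$idx[2]])
}

# Longest qualifying window within one contiguous run; windows of a fixed
# length are screened simultaneously with cumulative sums, scanning lengths
# from longest to shortest so the first hit is the answer.
best_window_in_run <- function(t, y, min_points, resid_factor) {
  n <- length(t)
  tc <- t - mean(t)  # centered for numerical stability
  ct  <- cumsum(c(0, tc));   ct2 <- cumsum(c(0, tc^2))
  cy  <- cumsum(c(0, y));    cy2 <- cumsum(c(0, y^2))
  cty <- cumsum(c(0, tc * y))
  # second differences cancel a linear trend, leaving ~ 6*sigma^2 per entry
  d2 <- if (n >= 3) diff(y, differences = 2) else numeric(0)
  cs2 <- cumsum(c(0, 0, 0, d2^2))  # sum over window i..j: cs2[j+1]-cs2[i+2]
  floor_scale <- 1e-10 * mean(y^2)  # admits exact lines despite rounding
  for (len in n:min_points) {
    i <- 1:(n - len + 1)
    j <- i + len - 1
    st  <- ct[j + 1] - ct[i];   st2 <- ct2[j + 1] - ct2[i]
    sy  <- cy[j + 1] - cy[i];   sy2 <- cy2[j + 1] - cy2[i]
    sty <- cty[j + 1] - cty[i]
    sxx <- st2 - st^2 / len
    syy <- pmax(sy2 - sy^2 / len, 0)
    sxy <- sty - st * sy / len
    # lack of fit: linear-fit residual variance vs the second-difference
    # noise estimate (blind to a linear trend, sensitive to curvature)
    s2 <- pmax(syy - sxy^2 / sxx, 0) / (len - 2)
    nvar <- (cs2[j + 1] - cs2[i + 2]) / (6 * (len - 2))
    ok <- s2 <= resid_factor * pmax(nvar, 0) + floor_scale
    if (any(ok)) {
      k <- which(ok)[1]
      return(list(len = len, idx = c(i[k], j[k])))
    }
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the efflux slope over a linear window
#'
#' Ordinary least squares of fluorescence on time inside the window. The slope
#' `k` (a.u./s) estimates `f (alpha - C_in(t0) P) / Vol_in`; more negative
#' values indicate higher total membrane permeability.
#'
#' @param trace A [fluorescence_trace()].
#' @param window Numeric `c(t_start, t_end)` (s); selected with
#'   [select_linear_window()] when `NULL`.
#' @param ... Passed to [select_linear_window()] when `window` is `NULL`.
#' @return An object of class `linear_fit` with fields `slope_k`,
#'   `intercept_c`, `window`, `r_squared`, `slope_se`, `n`.
#' @export
fit_efflux_slope <- function(trace, window = NULL, ...) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (is.null(window)) window <- select_linear_window(trace, ...)
  stopifnot(length(window) == 2, window[2] > window[1])
  sel <- trace$times >= window[1] & trace$times <= window[2]
  if (sum(sel) < 3) stop("fewer than 3 samples in window", call. = FALSE)
  t <- trace$times[sel]
  y <- trace$values[sel]
  if (diff(range(t)) == 0) stop("degenerate window: constant time", call. = FALSE)
  fit <- stats::lm(y ~ t)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  structure(list(
    slope_k = unname(stats::coef(fit)[2]),
    intercept_c = unname(stats::coef(fit)[1]),
    window = c(t_start = window[[1]], t_end = window[[2]]),
    r_squared = sm$r.squared,
    slope_se = sm$coefficients[2, 2],
    n = length(t)), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "<linear_fit> k = %.4g +/- %.2g a.u./s over [%g, %g] s (n = %d, r^2 = %.4f)\n",
    x$slope_k, x$slope_se, x$window[1], x$window[2], x$n, x$r_squared))
  invisible(x)
}

#' Detect donor-cell steady state
#'
#' Earliest sample time after which the donor fluorescence is effectively
#' flat: the OLS slope over the trailing `window_s` seconds, relative to the
#' mean fluorescence in that window, falls below `tol_per_min` (fractional
#' change per minute). The donor cell and the dye-filled patch pipette are
#' treated as one well-mixed compartment from this time on.
#'
#' @param donor A [fluorescence_trace()] spanning at least 5 minutes.
#' @param window_s Trailing-window length (s), default 120.
#' @param tol_per_min Relative-change threshold per minute, default 0.01 (1%).
#' @return Steady-state onset time (s), or `NA_real_` if never reached.
#' @export
detect_donor_steady_state <- function(donor, window_s = 120,
                                      tol_per_min = 0.01) {
  stopifnot(inherits(donor, "fluorescence_trace"))
  tt <- donor$times
  if (diff(range(tt)) < 300) {
    stop("donor trace must span at least 5 minutes", call. = FALSE)
  }
  t_end <- tt[length(tt)]
  for (i in seq_along(tt)) {
    if (tt[i] + window_s > t_end) break
    sel <- tt >= tt[i] & tt <= tt[i] + window_s
    if (sum(sel) < 3) next
    fit <- stats::lm.fit(cbind(1, tt[sel]), donor$values[sel])
    fbar <- mean(donor$values[sel])
    if (fbar <= 0) next
    if (abs(fit$coefficients[2]) * 60 / fbar < tol_per_min) return(tt[i])
  }
  NA_real_
}

#' Fit the recipient-cell exponential (transfer-rate estimator)
#'
#' Nonlinear least squares of the recipient-cell exponential to the
#' background-subtracted recipient trace from the donor steady-state time on.
#' The donor compartment concentration (times `f`) is anchored at the
#' measured background-subtracted donor plateau `F1`, and the model
#' \deqn{F_2(t) = F_1 - (F_1 - F_2(t_0)) e^{-(P_j/Vol_2)(t - t_0)}}
#' is fitted for the amplitude term `F_1 - F_2(t_0)` and the rate. This is
#' the relative-fluorescence model with its amplitude ratio
#' `R = C_1/C_2(t_ss)` co-fitted (reported in the diagnostics), but
#' parametrized in absolute fluorescence: normalizing by the single noisy
#' sample `F_2(t_ss)`, or letting the plateau float, leaves the rate poorly
#' identified on recordings that span less than a time constant, while the
#' donor plateau is measured with high precision from many samples. The rate
#' `P_j/Vol_2` (1/s) is the quantity of interest.
#'
#' @param donor,recipient [fluorescence_trace()] objects for the two cells.
#' @param t_ss Donor steady-state time (s); detected with
#'   [detect_donor_steady_state()] when `NULL`.
#' @param exclude Optional list of `c(start, end)` blocker intervals (s)
#'   masked from the fit.
#' @param min_ratio Minimum donor-plateau/recipient amplitude ratio below
#'   which the rate is declared unidentifiable (default 1.05).
#' @return A `rate_estimate` with fields `rate` (1/s), `method =
#'   "exponential_fit"`, `window`, and `diagnostics` (fitted amplitude ratio,
#'   residual SD, sample count).
#' @export
fit_recipient_exponential <- function(donor, recipient, t_ss = NULL,
                                      exclude = NULL, min_ratio = 1.05) {
  stopifnot(inherits(donor, "fluorescence_trace"),
            inherits(recipient, "fluorescence_trace"))
  if (is.null(t_ss)) {
    t_ss <- detect_donor_steady_state(donor)
    if (is.na(t_ss)) {
      stop("donor never reached steady state; use estimate_rate_discretized",
           call. = FALSE)
    }
  }
  f2 <- bg_sub(recipient)
  sel <- recipient$times >= t_ss & !in_intervals(recipient$times,
                                                 exclude %||% list())
  if (sum(sel) < 4) stop("too few recipient samples after t_ss", call. = FALSE)
  tt <- recipient$times[sel]
  t0 <- tt[1]
  f2_0 <- f2[sel][1]
  if (f2_0 <= 0) {
    stop("recipient fluorescence at or below background at t_ss", call. = FALSE)
  }
  plateau <- mean(bg_sub(donor)[donor$times >= t_ss])
  r0 <- plateau / f2_0
  if (!is.finite(r0) || r0 < min_ratio) {
    stop("rate unidentifiable: recipient already at the donor plateau",
         call. = FALSE)
  }
  y <- f2[sel]
  span <- tt[length(tt)] - t0
  frac <- (plateau - y[length(y)]) / (plateau - f2_0)
  rate0 <- if (is.finite(frac) && frac > 0 && frac < 1) {
    -log(frac) / span
  } else 1 / span
  fit <- minpack.lm::nlsLM(
    y ~ plateau - B * exp(-rate * (tt - t0)),
    start = list(B = plateau - f2_0, rate = max(rate0, 1e-6)),
    lower = c(B = 0, rate = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  structure(list(
    rate = unname(est["rate"]),
    method = "exponential_fit",
    window = c(t_start = t0, t_end = tt[length(tt)]),
    diagnostics = list(
      amplitude_ratio = plateau / (plateau - unname(est["B"])),
      amplitude_ratio_init = r0,
      donor_plateau = plateau,
      residual_sd = stats::sigma(fit),
      n = length(y),
      t_ss = t_ss)), class = "rate_estimate")
}

#' ODE-discretization transfer-rate estimator
#'
#' Finite-difference estimate of `P_j/Vol_2` that does not require the donor
#' to reach a plateau. At each step the recipient increment is divided by the
#' trapezoidally averaged donor-recipient gradient (background-subtracted)
#' times the step length:
#' \deqn{\frac{P_j}{Vol_2} \approx \frac{F_2(t_i) - F_2(t_{i-1})}
#'   {\tfrac{1}{2}\left[F_1(t_i) - F_2(t_i) + F_1(t_{i-1}) - F_2(t_{i-1})\right]
#'    (t_i - t_{i-1})}.}
#' Early estimates vary strongly, so the reported rate is the mean of the
#' per-step estimates at `t_i >= t_min` (default the 2-minute mark). Steps
#' with a zero averaged gradient are excluded and flagged.
#'
#' @param donor,recipient [fluorescence_trace()] objects; the donor is
#'   linearly interpolated onto the recipient time grid if needed.
#' @param t_min Earliest `t_i` (s) entering the average, default 120.
#' @param exclude Optional list of `c(start, end)` blocker intervals (s);
#'   steps touching them are dropped.
#' @return A `rate_estimate` with `method = "discretized"` and per-step
#'   estimates in `diagnostics$steps`.
#' @export
estimate_rate_discretized <- function(donor, recipient, t_min = 120,
                                      exclude = NULL) {
  stopifnot(inherits(donor, "fluorescence_trace"),
            inherits(recipient, "fluorescence_trace"))
  tt <- recipient$times
  f2 <- bg_sub(recipient)
  if (length(donor$times) == length(tt) && all(donor$times == tt)) {
    f1 <- bg_sub(donor)
  } else {
    f1 <- stats::approx(donor$times, bg_sub(donor), xout = tt)$y
    ok <- !is.na(f1)
    tt <- tt[ok]; f1 <- f1[ok]; f2 <- f2[ok]
  }
  if (length(tt) < 2) stop("no overlapping samples", call. = FALSE)
  i <- 2:length(tt)
  dt <- tt[i] - tt[i - 1]
  drive <- ((f1[i] - f2[i]) + (f1[i - 1] - f2[i - 1])) / 2
  est <- (f2[i] - f2[i - 1]) / (drive * dt)
  zero_drive <- drive == 0
  masked <- in_intervals(tt[i], exclude %||% list()) |
    in_intervals(tt[i - 1], exclude %||% list())
  used <- tt[i] >= t_min & !zero_drive & !masked
  if (!any(used)) {
    stop("no usable steps: all have zero donor-recipient gradient, are ",
         "masked, or precede t_min", call. = FALSE)
  }
  structure(list(
    rate = mean(est[used]),
    method = "discretized",
    window = c(t_start = max(t_min, tt[1]), t_end = tt[length(tt)]),
    diagnostics = list(
      steps = data.frame(t_s = tt[i], estimate = est, used = used,
                         zero_drive = zero_drive),
      n_used = sum(used),
      n_excluded_zero_drive = sum(zero_drive))), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> P/Vol = %.4g 1/s (%s, window [%g, %g] s)\n",
              x$rate, x$method, x$window[1], x$window[2]))
  invisible(x)
}

#' Normalize an efflux slope by the open-hemichannel count
#'
#' Divides the fitted slope `k` by `n P_o = g / gamma`, the macroscopic
#' hemichannel conductance over the unitary conductance, giving a per-channel
#' permeability proxy (sign carries direction: more negative means more
#' permeable). Because efflux cells are not patched, the count is typically a
#' genotype-group mean from separate electrophysiological recordings.
#'
#' @param fit A `linear_fit` from [fit_efflux_slope()] (or a bare slope).
#' @param population A [channel_population()] (or a bare `n_po` value).
#' @param source `"group_mean"` (default) or `"per_cell"`, recorded in the
#'   result.
#' @return A `normalized_permeability` with fields `value`, `n_po_used`,
#'   `source`.
#' @export
normalize_hemichannel <- function(fit, population, source = "group_mean") {
  slope <- if (inherits(fit, "linear_fit")) fit$slope_k else as.numeric(fit)
  n_po <- if (inherits(population, "channel_population")) {
    population$n_po
  } else as.numeric(population)
  if (!is.finite(n_po) || n_po <= 0) {
    stop("n_po must be positive", call. = FALSE)
  }
  structure(list(value = slope / n_po, n_po_used = n_po, source = source),
            class = "normalized_permeability")
}

#' Normalize a junctional transfer rate per GJ channel
#'
#' Divides the fitted `P_j/Vol_2` by the channel count `g_j/gamma_j`
#' (junctional conductance over single-channel conductance, both measured in
#' the same cell pair) to give the single-GJ-channel permeability metric
#' `P_j,gamma/Vol_2` in 1/s per channel.
#'
#' @param rate A `rate_estimate` (or bare rate in 1/s).
#' @param gj_ns Junctional conductance (nS), positive.
#' @param gamma_j_ps Single-channel conductance (pS), positive.
#' @return A `normalized_permeability`.
#' @export
normalize_gj <- function(rate, gj_ns, gamma_j_ps) {
  r <- if (inherits(rate, "rate_estimate")) rate$rate else as.numeric(rate)
  if (!is.finite(gj_ns) || gj_ns <= 0) stop("gj_ns must be positive", call. = FALSE)
  if (!is.finite(gamma_j_ps) || gamma_j_ps <= 0) {
    stop("gamma_j_ps must be positive", call. = FALSE)
  }
  n <- gj_ns * 1000 / gamma_j_ps
  structure(list(value = r / n, n_po_used = n, source = "per_cell"),
            class = "normalized_permeability")
}

#' @export
print.normalized_permeability <- function(x, ...) {
  cat(sprintf("<normalized_permeability> %.4g per channel (n*Po = %.3g, %s)\n",
              x$value, x$n_po_used, x$source))
  invisible(x)
}
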