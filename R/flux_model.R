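# Forward models: two-compartment Fickian dye flux, hemichannel efflux with an
# optional intracellular production term, and the recipient-cell solution for
# intercellular transfer. All shipped solutions are closed-form.
#
# Units throughout: time s, volume pl, concentration uM, permeability pl/s,
# fluorescence a.u., calibration f in a.u./uM. Rates P/Vol are 1/s.

#' Two-compartment flux parameters
#'
#' Parameters of the two-compartment model in which dye flux between
#' compartments is proportional to the concentration gradient (Fick's law):
#' \deqn{dC_1/dt = P (C_2 - C_1) / Vol_1, \quad dC_2/dt = P (C_1 - C_2) / Vol_2.}
#'
#' @param vol1,vol2 Compartment volumes (pl), strictly positive.
#' @param perm Total permeability P (pl/s), non-negative.
#' @param c1_0,c2_0 Initial concentrations (uM), non-negative.
#' @return An object of class `two_compartment_params`.
#' @export
two_compartment_params <- function(vol1, vol2, perm, c1_0, c2_0) {
  stopifnot(is.numeric(vol1), vol1 > 0, is.numeric(vol2), vol2 > 0,
            is.numeric(perm), perm >= 0, c1_0 >= 0, c2_0 >= 0)
  structure(list(vol1 = vol1, vol2 = vol2, perm = perm,
                 c1_0 = c1_0, c2_0 = c2_0),
            class = "two_compartment_params")
}

#' Hemichannel efflux parameters
#'
#' Parameters of the single-cell efflux model
#' \deqn{dC_{in}/dt = (\alpha - P C_{in}) / Vol_{in},}
#' where the bath is an effectively infinite sink and `alpha` is an optional
#' production term (amount per unit time, uM pl/s) accounting for continued
#' intracellular dye generation, e.g. residual esterase cleavage of the
#' membrane-permeant ester.
#'
#' @param vol_in Cell volume (pl), strictly positive.
#' @param perm Total membrane permeability P (pl/s), non-negative.
#' @param c_in_0 Initial intracellular concentration (uM), non-negative.
#' @param alpha Production rate (uM pl/s), non-negative. Default 0.
#' @return An object of class `efflux_params`.
#' @export
efflux_params <- function(vol_in, perm, c_in_0, alpha = 0) {
  stopifnot(is.numeric(vol_in), vol_in > 0, is.numeric(perm), perm >= 0,
            c_in_0 >= 0, alpha >= 0)
  structure(list(vol_in = vol_in, perm = perm, c_in_0 = c_in_0, alpha = alpha),
            class = "efflux_params")
}

#' Fluorescence calibration
#'
#' Linear fluorescence-concentration relationship `F(t) = f * C(t) + f0`.
#' Linearity holds in the working range of the anionic tracers modelled here
#' (calcein self-quenching only appears above ~4 mM).
#'
#' @param f Fluorescence per unit concentration (a.u./uM), strictly positive.
#' @param f0 Background fluorescence (a.u.), measured in a cell-free region.
#' @return An object of class `fluorescence_calibration`.
#' @export
fluorescence_calibration <- function(f, f0 = 0) {
  stopifnot(is.numeric(f), f > 0, is.numeric(f0), f0 >= 0)
  structure(list(f = f, f0 = f0), class = "fluorescence_calibration")
}

#' Simulate the two-compartment flux model
#'
#' Closed-form solution of the two-compartment system. The concentration
#' difference decays as `exp(-P (1/Vol1 + 1/Vol2) t)` while the total amount
#' `Vol1 C1 + Vol2 C2` is conserved.
#'
#' @param params A [two_compartment_params()] object.
#' @param times Strictly increasing vector of times (s) starting at 0.
#' @return A data.frame with columns `time_s`, `c1_um`, `c2_um`.
#' @export
simulate_two_compartment <- function(params, times) {
  stopifnot(inherits(params, "two_compartment_params"))
  check_times(times, require_zero = TRUE)
  lambda <- params$perm * (1 / params$vol1 + 1 / params$vol2)
  d0 <- params$c1_0 - params$c2_0
  amount <- params$vol1 * params$c1_0 + params$vol2 * params$c2_0
  vtot <- params$vol1 + params$vol2
  d <- d0 * exp(-lambda * times)
  c1 <- (amount + params$vol2 * d) / vtot
  c2 <- (amount - params$vol1 * d) / vtot
  data.frame(time_s = times, c1_um = c1, c2_um = c2)
}

#' Intracellular concentration during hemichannel efflux
#'
#' Analytical solution of `dC_in/dt = (alpha - P C_in)/Vol_in`:
#' \deqn{C_{in}(t) = \alpha/P - (\alpha/P - C_{in}(0)) e^{-(P/Vol_{in}) t},}
#' with the limit form `C_in(0) + (alpha/Vol_in) t` when P = 0.
#'
#' @param params An [efflux_params()] object.
#' @param t Time(s) since efflux onset (s), non-negative.
#' @return Concentration(s) in uM.
#' @export
efflux_solution <- function(params, t) {
  stopifnot(inherits(params, "efflux_params"), all(t >= 0))
  if (params$perm == 0) {
    return(params$c_in_0 + (params$alpha / params$vol_in) * t)
  }
  css <- params$alpha / params$perm
  css - (css - params$c_in_0) * exp(-(params$perm / params$vol_in) * t)
}

#' Linearized efflux fluorescence
#'
#' First-order Taylor expansion of the efflux solution about `t0`, expressed
#' in fluorescence units:
#' \deqn{F_{in}(t) = F_{in}(t_0) + f \frac{\alpha - C_{in}(t_0) P}{Vol_{in}} (t - t_0).}
#' The coefficient of `(t - t0)` is `f` times the exact time derivative of
#' [efflux_solution()] at `t0`; this is the line whose slope `k` is extracted
#' by [fit_efflux_slope()].
#'
#' @param params An [efflux_params()] object; `c_in_0` is interpreted as the
#'   concentration at the expansion point `t0`.
#' @param calib A [fluorescence_calibration()] object.
#' @param t0 Expansion time (s).
#' @param t Evaluation time(s) (s), `t >= t0`.
#' @return Fluorescence (a.u.).
#' @export
efflux_linear_approx <- function(params, calib, t0, t) {
  stopifnot(inherits(params, "efflux_params"),
            inherits(calib, "fluorescence_calibration"), all(t >= t0))
  f_t0 <- calib$f * params$c_in_0 + calib$f0
  slope <- calib$f * (params$alpha - params$c_in_0 * params$perm) / params$vol_in
  f_t0 + slope * (t - t0)
}

#' Recipient-cell concentration during intercellular transfer
#'
#' Once the donor cell has equilibrated with the patch pipette it holds a
#' constant concentration `c1`, and the recipient follows
#' \deqn{C_2(t) = C_1 - (C_1 - C_2(t_0)) e^{-(P_j/Vol_2)(t - t_0)}.}
#'
#' @param c1 Donor (source-cell) steady-state concentration (uM).
#' @param c2_t0 Recipient concentration at `t0` (uM).
#' @param rate Transfer rate `P_j/Vol_2` (1/s), non-negative.
#' @param t0 Reference time (s).
#' @param t Evaluation time(s) (s), `t >= t0`.
#' @return Concentration(s) in uM.
#' @export
recipient_solution <- function(c1, c2_t0, rate, t0, t) {
  stopifnot(rate >= 0, all(t >= t0))
  c1 - (c1 - c2_t0) * exp(-rate * (t - t0))
}

#' Relative recipient fluorescence during intercellular transfer
#'
#' The background-subtracted recipient fluorescence normalized to its value at
#' `t0` follows
#' \deqn{\frac{F_2(t)}{F_2(t_0)} = \frac{C_1}{C_2(t_0)} -
#'   \left(\frac{C_1}{C_2(t_0)} - 1\right) e^{-(P_j/Vol_2)(t - t_0)}.}
#' This is the curve fitted by [fit_recipient_exponential()]; it is exact only
#' for background-subtracted fluorescence.
#'
#' @inheritParams recipient_solution
#' @return Dimensionless ratio `F2(t)/F2(t0)`.
#' @export
relative_fluorescence <- function(c1, c2_t0, rate, t0, t) {
  if (c2_t0 <= 0) {
    stop("relative fluorescence is undefined for c2_t0 <= 0", call. = FALSE)
  }
  recipient_solution(c1, c2_t0, rate, t0, t) / c2_t0
}

# shared time-vector validation
check_times <- function(times, require_zero = FALSE) {
  if (!is.numeric(times) || length(times) < 1 || anyNA(times)) {
    stop("times must be a numeric vector without missing values", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (require_zero && times[1] != 0) {
    stop("times must start at 0", call. = FALSE)
  }
  invisible(times)
}
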