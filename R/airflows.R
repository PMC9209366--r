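#' Speed-induced passive ventilation airflow
#'
#' Ram pressure at speed drives outside air through the HVAC path even with
#' the fan off; this flow passes the filter and is therefore ventilation,
#' not infiltration. Measured passive ventilation is linear in driving
#' speed; the regression coefficient 0.21 is read as an air-change rate per
#' km of travel speed, i.e. ACH (1/h) = 0.21 x vspeed (km/h), so
#' `Qps[m3/h] = 0.21 * vspeed * Vcabin`. The coefficient is configurable.
#'
#' @param vspeed vehicle speed, km/h (>= 0).
#' @param Vcabin cabin volume, m3.
#' @param coef passive-ventilation coefficient, air changes per hour per
#'   km/h of speed.
#' @return passive ventilation flow Qps, m3/s.
#' @export
#' @examples
#' m3s_to_m3h(passive_ventilation(100, 4.1))  # 86.1 m3/h
passive_ventilation <- function(vspeed, Vcabin, coef = 0.21) {
  if (any(vspeed < 0)) stop("vehicle speed must be non-negative")
  if (Vcabin <= 0) stop("Vcabin must be positive")
  m3h_to_m3s(coef * vspeed * Vcabin)
}

#' Cabin pressurization from mechanical and passive ventilation
#'
#' Inverting the envelope leakage power law `Q = kf * dP^n`, the
#' overpressure sustained by the total filtered supply of outside air is
#' `dPmech = ((Qoa + Qps) / kf)^(1/n)`. At zero total flow the
#' pressurization is taken as the 0 Pa limit (no fan, standstill).
#'
#' @param Qoa outside-air flow, m3/h.
#' @param Qps passive ventilation flow, m3/h.
#' @param kf leakage flow coefficient, m3/h per Pa^n.
#' @param n leakage pressure exponent.
#' @return cabin overpressure, Pa.
#' @export
#' @examples
#' mechanical_pressure(75.12, 0, kf = 18.78, n = 0.5)  # 16 Pa
mechanical_pressure <- function(Qoa, Qps, kf, n) {
  if (kf <= 0 || n <= 0) stop("kf and n must be positive")
  q <- Qoa + Qps
  if (any(q < 0)) stop("ventilation flows must be non-negative")
  out <- (q / kf)^(1 / n)
  if (any(q == 0)) {
    message("zero total ventilation flow: cabin pressurization taken as 0 Pa")
    out[q == 0] <- 0
  }
  out
}

#' Aerodynamic pressure at the vehicle outer surface
#'
#' The speed-dependent exterior pressure at the leakage sites is modelled
#' as `dPaero = kp * a * exp(b * vspeed)` with vehicle-specific shape
#' parameters.
#'
#' @param vspeed vehicle speed, km/h (>= 0).
#' @param a pressure scale, Pa.
#' @param b speed coefficient, per km/h.
#' @param kp shape coefficient (dimensionless).
#' @return exterior aerodynamic pressure, Pa; equals `kp * a` at standstill.
#' @export
aero_pressure <- function(vspeed, a, b, kp) {
  if (any(vspeed < 0)) stop("vehicle speed must be non-negative")
  kp * a * exp(b * vspeed)
}

#' Infiltration flow through envelope leaks
#'
#' Infiltration occurs only when the exterior aerodynamic pressure exceeds
#' the cabin pressurization (`dPinf = dPaero - dPmech > 0`); the resulting
#' leakage flow follows the same power law as pressurization, scaled by the
#' reverse-leakage correction `Frev`. The flow is continuous (and zero) at
#' `dPinf = 0`.
#'
#' @param dPinf infiltration pressure difference, Pa (may be negative).
#' @param kf leakage flow coefficient, m3/h per Pa^n.
#' @param n leakage pressure exponent.
#' @param Frev reverse-leakage correction factor in \[0, 1\].
#' @return infiltration flow Qinf, m3/h (zero when `dPinf <= 0`).
#' @export
#' @examples
#' infiltration_flow(4, kf = 18.78, n = 0.5, Frev = 0.5)  # 18.78 m3/h
infiltration_flow <- function(dPinf, kf, n, Frev) {
  if (kf <= 0 || n <= 0) stop("kf and n must be positive")
  if (Frev < 0 || Frev > 1) stop("Frev must lie in [0, 1]")
  ifelse(dPinf > 0, Frev * kf * dPinf^n, 0)
}

#' Full infiltration pressure balance for a vehicle at speed
#'
#' Chains the pressurization, aerodynamic-pressure and leakage-flow
#' submodels for a vehicle driving at `vspeed` with outside-air supply
#' `Qoa`. Passive ventilation is included on the pressurization side, since
#' it enters through the HVAC path and adds to the supply.
#'
#' @param vehicle a [vehicle_spec()].
#' @param Qoa outside-air flow, m3/s.
#' @param vspeed vehicle speed, km/h.
#' @param Qps optional passive ventilation flow, m3/s; computed from
#'   `vspeed` and the cabin volume when `NULL`.
#' @return a list of class `cabin_infiltration_result` with elements
#'   `dPmech`, `dPaero`, `dPinf` (Pa) and `Qinf` (m3/s).
#' @export
infiltration <- function(vehicle, Qoa, vspeed, Qps = NULL) {
  stopifnot(inherits(vehicle, "cabin_vehicle_spec"))
  if (is.null(Qps)) Qps <- passive_ventilation(vspeed, vehicle$Vcabin)
  dPmech <- mechanical_pressure(m3s_to_m3h(Qoa), m3s_to_m3h(Qps),
                                kf = vehicle$kf, n = vehicle$n)
  dPaero <- aero_pressure(vspeed, a = vehicle$a, b = vehicle$b,
                          kp = vehicle$kp)
  dPinf <- dPaero - dPmech
  Qinf <- m3h_to_m3s(infiltration_flow(dPinf, kf = vehicle$kf, n = vehicle$n,
                                       Frev = vehicle$Frev))
  structure(list(dPmech = dPmech, dPaero = dPaero, dPinf = dPinf, Qinf = Qinf),
            class = "cabin_infiltration_result")
}

#' Deposition-equivalent airflow
#'
#' First-order particle loss to interior surfaces at rate `beta` (1/h) is
#' equivalent to a particle-free flow `Qdep = Vcabin * beta` leaving the
#' cabin, per size channel.
#'
#' @param Vcabin cabin volume, m3.
#' @param beta per-channel deposition rates, 1/h.
#' @return per-channel deposition flow, m3/s.
#' @export
#' @examples
#' m3s_to_m3h(deposition_flow(4.1, 12.6))  # 51.66 m3/h
deposition_flow <- function(Vcabin, beta) {
  if (Vcabin <= 0) stop("Vcabin must be positive")
  if (any(beta < 0)) stop("deposition rates must be non-negative")
  m3h_to_m3s(Vcabin * beta)
}

#' HVAC ventilation state
#'
#' The fan-driven flows of the HVAC system: outside-air supply `Qoa` and
#' recirculated flow `Qrec`, plus the vehicle speed that drives passive
#' ventilation and aerodynamic pressure.
#'
#' @param Qoa outside-air flow, m3/s.
#' @param Qrec recirculated flow, m3/s.
#' @param vspeed vehicle speed, km/h.
#' @return an object of class `cabin_ventilation_state`.
#' @export
#' @examples
#' # Low fan level at 50% recirculation
#' v <- ventilation_state(Qoa = 0.5 * fan_level_flow("low"),
#'                        Qrec = 0.5 * fan_level_flow("low"), vspeed = 60)
#' recirculation_degree(v)  # 0.5
ventilation_state <- function(Qoa, Qrec = 0, vspeed = 0) {
  if (Qoa < 0 || Qrec < 0) stop("flows must be non-negative")
  if (vspeed < 0) stop("vehicle speed must be non-negative")
  structure(list(Qoa = Qoa, Qrec = Qrec, vspeed = vspeed),
            class = "cabin_ventilation_state")
}

#' @rdname ventilation_state
#' @param vent a `cabin_ventilation_state`.
#' @return `recirculation_degree` returns `Qrec / (Qrec + Qoa)` in \[0, 1\]
#'   (0 for zero total supply).
#' @export
recirculation_degree <- function(vent) {
  tot <- vent$Qoa + vent$Qrec
  if (tot == 0) return(0)
  vent$Qrec / tot
}

#' @rdname ventilation_state
#' @param total total supply flow `Qoa + Qrec`, m3/s.
#' @param degree recirculation degree in \[0, 1\] (fraction, not percent).
#' @return `ventilation_from_degree` returns a `cabin_ventilation_state`
#'   splitting `total` according to `degree`.
#' @export
ventilation_from_degree <- function(total, degree, vspeed = 0) {
  if (degree < 0 || degree > 1) stop("recirculation degree must lie in [0, 1]")
  ventilation_state(Qoa = (1 - degree) * total, Qrec = degree * total,
                    vspeed = vspeed)
}
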