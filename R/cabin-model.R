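#' Cabin simulation scenario
#'
#' Bundles everything the balance equations need: the vehicle envelope
#' parameters, the HVAC ventilation state, the filter efficiency set, the
#' occupant CO2 source, and the outdoor boundary concentrations.
#'
#' Because the filter table provides an upper and a lower efficiency limit,
#' the particle solution is itself a range; `eta_mode` selects which bound
#' feeds the balance equation, or `"average"` to report the mean of the
#' upper-bound and lower-bound solutions (the averaging is over solutions,
#' not over efficiencies, since the steady state is nonlinear in eta).
#'
#' @param vehicle a [vehicle_spec()].
#' @param vent a [ventilation_state()].
#' @param filter a [filter_spec()], e.g. from [load_filter_fixture()].
#' @param occupants an [occupant_load()].
#' @param Cenv_particles outdoor [size_distribution()] (count or mass basis).
#' @param Cenv_co2 outdoor CO2 concentration, ppm.
#' @param eta_mode `"average"`, `"upper"` or `"lower"`.
#' @param density particle density for basis conversions, kg/m3.
#' @return an object of class `cabin_scenario`.
#' @export
scenario <- function(vehicle, vent, filter, occupants = occupant_load(0),
                     Cenv_particles, Cenv_co2 = 420,
                     eta_mode = c("average", "upper", "lower"),
                     density = 1000) {
  stopifnot(inherits(vehicle, "cabin_vehicle_spec"),
            inherits(vent, "cabin_ventilation_state"),
            inherits(filter, "cabin_filter_spec"),
            inherits(occupants, "cabin_occupant_load"),
            inherits(Cenv_particles, "cabin_size_distribution"))
  eta_mode <- match.arg(eta_mode)
  if (Cenv_co2 < 0) stop("outdoor CO2 must be non-negative")
  nch <- length(vehicle$grid)
  if (length(filter$grid) != nch || length(Cenv_particles$grid) != nch)
    stop("vehicle, filter and outdoor distribution must share one size grid")
  structure(list(vehicle = vehicle, vent = vent, filter = filter,
                 occupants = occupants, Cenv_particles = Cenv_particles,
                 Cenv_co2 = Cenv_co2, eta_mode = eta_mode, density = density),
            class = "cabin_scenario")
}

#' @export
print.cabin_scenario <- function(x, ...) {
  fl <- scenario_flows(x)
  cat("<cabin scenario>\n")
  cat(sprintf("  vehicle: %.1f m3 cabin, filter %s / ionization %s (eta %s)\n",
              x$vehicle$Vcabin, x$filter$status, x$filter$ionization,
              x$eta_mode))
  cat(sprintf("  flows: Qoa %.1f, Qrec %.1f, Qps %.1f, Qinf %.2f m3/h; speed %.0f km/h\n",
              m3s_to_m3h(x$vent$Qoa), m3s_to_m3h(x$vent$Qrec),
              m3s_to_m3h(fl$Qps), m3s_to_m3h(fl$Qinf), x$vent$vspeed))
  cat(sprintf("  occupants: %d; outdoor CO2 %.0f ppm\n",
              x$occupants$N, x$Cenv_co2))
  invisible(x)
}

#' Derived airflows of a scenario
#'
#' Evaluates the airflow submodels for a scenario: passive ventilation from
#' speed, the infiltration pressure balance, and the per-channel
#' deposition-equivalent flow.
#'
#' @param sc a [scenario()].
#' @return list with `Qoa`, `Qrec`, `Qps`, `Qinf` (m3/s), `Qdep`
#'   (per-channel, m3/s), and the pressures `dPmech`, `dPaero`, `dPinf` (Pa).
#' @export
scenario_flows <- function(sc) {
  stopifnot(inherits(sc, "cabin_scenario"))
  Qps <- passive_ventilation(sc$vent$vspeed, sc$vehicle$Vcabin)
  inf <- infiltration(sc$vehicle, sc$vent$Qoa, sc$vent$vspeed, Qps = Qps)
  list(Qoa = sc$vent$Qoa, Qrec = sc$vent$Qrec, Qps = Qps, Qinf = inf$Qinf,
       Qdep = deposition_flow(sc$vehicle$Vcabin, sc$vehicle$beta),
       dPmech = inf$dPmech, dPaero = inf$dPaero, dPinf = inf$dPinf)
}

# efficiency sets implied by an eta mode: one set for upper/lower,
# both sets for "average" (solutions are averaged downstream)
.eta_sets <- function(sc, eta_mode = sc$eta_mode) {
  switch(eta_mode,
         upper = list(sc$filter$eta_upper),
         lower = list(sc$filter$eta_lower),
         average = list(sc$filter$eta_upper, sc$filter$eta_lower))
}

#' Particle mass-balance rate of change
#'
#' The per-channel balance: filtered outside air (mechanical plus passive)
#' and crack-penetrating infiltration supply particles; outflow, deposition
#' and filtration of the recirculated flow remove them:
#' \deqn{V \frac{dC_{in}}{dt} = [(Q_{oa}+Q_{ps})(1-\eta) + Q_{inf}\alpha]
#'   C_{env} - [Q_{oa}+Q_{ps}+Q_{inf}+Q_{dep}+Q_{rec}\eta] C_{in}}
#' The equation holds on either concentration basis because all particles
#' in a channel are assumed to share one diameter and density.
#'
#' @param Cin per-channel cabin concentrations (same basis as the
#'   scenario's outdoor distribution).
#' @param sc a [scenario()].
#' @param eta per-channel filter efficiencies in \[0, 1\]; defaults to the
#'   bound selected by the scenario's `eta_mode`. A scenario with
#'   `eta_mode = "average"` has no single rate, so `eta` must be given
#'   explicitly there.
#' @return per-channel `dCin/dt` (concentration units per second).
#' @export
particle_rhs <- function(Cin, sc, eta = NULL) {
  stopifnot(inherits(sc, "cabin_scenario"))
  if (is.null(eta)) {
    if (sc$eta_mode == "average")
      stop("eta_mode 'average' averages solutions, not rates; ",
           "pass eta explicitly or use eta_mode 'upper'/'lower'")
    eta <- .eta_sets(sc)[[1]]
  }
  if (any(eta < 0 | eta > 1)) stop("filter efficiencies must lie in [0, 1]")
  fl <- scenario_flows(sc)
  Qsup <- fl$Qoa + fl$Qps
  src <- (Qsup * (1 - eta) + fl$Qinf * sc$vehicle$alpha) * sc$Cenv_particles$values
  loss <- (Qsup + fl$Qinf + fl$Qdep + fl$Qrec * eta) * Cin
  (src - loss) / sc$vehicle$Vcabin
}

#' Closed-form steady-state cabin particle concentrations
#'
#' Setting the particle balance to zero gives, per channel,
#' \deqn{C_{in} = \frac{(Q_{oa}+Q_{ps})(1-\eta) + Q_{inf}\alpha}
#'   {Q_{oa}+Q_{ps}+Q_{inf}+Q_{dep}+Q_{rec}\eta} \; C_{env}.}
#' With `eta_mode = "average"` the upper-bound and lower-bound solutions
#' are averaged, giving the reported mean cabin concentration.
#'
#' @inheritParams particle_rhs
#' @param eta_mode overrides the scenario's efficiency-bound selection.
#' @return a [size_distribution()] of steady-state cabin concentrations, on
#'   the same basis as the outdoor boundary.
#' @export
steady_state_particles <- function(sc, eta_mode = sc$eta_mode) {
  stopifnot(inherits(sc, "cabin_scenario"))
  fl <- scenario_flows(sc)
  Qsup <- fl$Qoa + fl$Qps
  sols <- lapply(.eta_sets(sc, eta_mode), function(eta) {
    den <- Qsup + fl$Qinf + fl$Qdep + fl$Qrec * eta
    if (any(den <= 0)) {
      ch <- as.numeric(sc$vehicle$grid)[which(den <= 0)[1]]
      stop("no particle removal or exchange in channel ", ch,
           " nm: steady state undefined")
    }
    (Qsup * (1 - eta) + fl$Qinf * sc$vehicle$alpha) *
      sc$Cenv_particles$values / den
  })
  size_distribution(Reduce(`+`, sols) / length(sols),
                    basis = sc$Cenv_particles$basis,
                    grid = sc$Cenv_particles$grid)
}

#' CO2 mass-balance rate of change
#'
#' CO2 passes the filter unchanged and does not deposit, so recirculation
#' drops out of the balance; only the outside-air exchange
#' `Qoa + Qps + Qinf` and the occupant breath source remain:
#' \deqn{V \frac{dC_{in}}{dt} = (Q_{oa}+Q_{ps}+Q_{inf})(C_{env} - C_{in})
#'   + N\,V_{br}\,C_{br}}
#'
#' @param Cin cabin CO2 concentration, ppm.
#' @param sc a [scenario()].
#' @return `dCin/dt`, ppm/s.
#' @export
co2_rhs <- function(Cin, sc) {
  stopifnot(inherits(sc, "cabin_scenario"))
  fl <- scenario_flows(sc)
  Qtot <- fl$Qoa + fl$Qps + fl$Qinf
  occ <- sc$occupants
  (Qtot * (sc$Cenv_co2 - Cin) + occ$N * lmin_to_m3s(occ$Vbr) * occ$Cbr) /
    sc$vehicle$Vcabin
}

#' Steady-state cabin CO2 concentration
#'
#' `Cin = Cenv + N * Vbr * Cbr / (Qoa + Qps + Qinf)`: outdoor CO2 plus the
#' breath source diluted by the outside-air exchange. At 100%
#' recirculation with occupants there is no outside-air exchange and CO2
#' accumulates without bound; that case is an error here — use
#' [transient_solve()] to study the accumulation.
#'
#' @param sc a [scenario()].
#' @return steady-state cabin CO2, ppm.
#' @export
steady_state_co2 <- function(sc) {
  stopifnot(inherits(sc, "cabin_scenario"))
  fl <- scenario_flows(sc)
  Qtot <- fl$Qoa + fl$Qps + fl$Qinf
  if (Qtot <= 0) {
    stop("no outside-air exchange (100% recirculation at standstill): ",
         if (sc$occupants$N > 0) "CO2 accumulates without bound; " else
           "cabin CO2 is indeterminate; ",
         "use transient_solve() for this case")
  }
  occ <- sc$occupants
  sc$Cenv_co2 + occ$N * lmin_to_m3s(occ$Vbr) * occ$Cbr / Qtot
}

#' Transient integration of the cabin balance equations
#'
#' Integrates the coupled particle and CO2 balances from an initial cabin
#' state over a time grid, under constant boundary conditions and flows.
#' The system is linear and mildly stiff when deposition or filtration
#' rates differ strongly between channels, so a stiff-capable solver
#' (lsoda) is used with tight tolerances (atol 1e-9, rtol 1e-8). With
#' `eta_mode = "average"` the upper-bound and lower-bound trajectories are
#' integrated separately and averaged.
#'
#' @param sc a [scenario()].
#' @param t_grid strictly increasing times, s (first element is the initial
#'   time).
#' @param Cin0_particles initial per-channel cabin concentrations; scalar
#'   broadcast; defaults to 0 (particle-free cabin).
#' @param Cin0_co2 initial cabin CO2, ppm; defaults to the outdoor value.
#' @return a data.frame of class `cabin_trajectory` with columns `t`, one
#'   `d<midpoint>` column per channel, `co2`, and the aggregate (`pm25` on
#'   the mass basis, `ufp` on the count basis).
#' @export
transient_solve <- function(sc, t_grid, Cin0_particles = 0,
                            Cin0_co2 = sc$Cenv_co2) {
  stopifnot(inherits(sc, "cabin_scenario"))
  if (length(t_grid) < 2 || is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing with at least two times")
  nch <- length(sc$vehicle$grid)
  Cin0 <- as.numeric(Cin0_particles)
  if (length(Cin0) == 1L) Cin0 <- rep(Cin0, nch)
  if (length(Cin0) != nch) stop("Cin0_particles must be scalar or per-channel")
  if (any(Cin0 < 0) || Cin0_co2 < 0) stop("initial state must be non-negative")

  fl <- scenario_flows(sc)
  Qsup <- fl$Qoa + fl$Qps
  Qtot_co2 <- Qsup + fl$Qinf
  occ <- sc$occupants
  co2_src <- occ$N * lmin_to_m3s(occ$Vbr) * occ$Cbr
  V <- sc$vehicle$Vcabin

  run_one <- function(eta) {
    loss <- (Qsup + fl$Qinf + fl$Qdep + fl$Qrec * eta) / V
    src <- (Qsup * (1 - eta) + fl$Qinf * sc$vehicle$alpha) *
      sc$Cenv_particles$values / V
    deriv <- function(t, y, parms) {
      dp <- src - loss * y[seq_len(nch)]
      dc <- (Qtot_co2 * (sc$Cenv_co2 - y[nch + 1]) + co2_src) / V
      list(c(dp, dc))
    }
    out <- deSolve::ode(y = c(Cin0, Cin0_co2), times = t_grid, func = deriv,
                        parms = NULL, method = "lsoda",
                        atol = 1e-9, rtol = 1e-8)
    attr_diag <- attributes(out)$istate
    if (!is.null(attr_diag) && attr_diag[1] < 0)
      stop("transient solver failed to converge (istate = ", attr_diag[1], ")")
    unclass(out)[, -1, drop = FALSE]
  }

  sols <- lapply(.eta_sets(sc), run_one)
  y <- Reduce(`+`, sols) / length(sols)
  res <- data.frame(t = t_grid, y[, seq_len(nch), drop = FALSE],
                    co2 = y[, nch + 1])
  names(res)[1 + seq_len(nch)] <- paste0("d", as.numeric(sc$vehicle$grid))
  agg <- apply(y[, seq_len(nch), drop = FALSE], 1, function(v)
    aggregate_distribution(
      size_distribution(pmax(v, 0), sc$Cenv_particles$basis,
                        sc$Cenv_particles$grid),
      if (sc$Cenv_particles$basis == "mass") "pm25" else "ufp"))
  res[[if (sc$Cenv_particles$basis == "mass") "pm25" else "ufp"]] <- agg
  class(res) <- c("cabin_trajectory", "data.frame")
  res
}

#' Indoor-to-outdoor concentration ratio
#'
#' @param Cin aggregate cabin concentration.
#' @param Cenv aggregate outdoor concentration (> 0).
#' @return `Cin / Cenv` (dimensionless).
#' @export
io_ratio <- function(Cin, Cenv) {
  if (any(Cenv <= 0)) stop("outdoor concentration must be positive")
  Cin / Cenv
}

#' Steady-state scenario summary
#'
#' Solves both balances at steady state and reports the aggregates and
#' indoor-to-outdoor ratios alongside the derived flows.
#'
#' @param sc a [scenario()].
#' @return a list with elements `particles` (a [size_distribution()]),
#'   `pm25`/`ufp` (whichever the boundary basis supports), the
#'   corresponding `io_ratio`, `co2` (ppm), and `flows`
#'   (from [scenario_flows()]).
#' @export
cabin_steady_state <- function(sc) {
  stopifnot(inherits(sc, "cabin_scenario"))
  cin <- steady_state_particles(sc)
  agg_kind <- if (cin$basis == "mass") "pm25" else "ufp"
  cin_agg <- aggregate_distribution(cin, agg_kind)
  cenv_agg <- aggregate_distribution(sc$Cenv_particles, agg_kind)
  out <- list(particles = cin, co2 = steady_state_co2(sc),
              flows = scenario_flows(sc))
  out[[agg_kind]] <- cin_agg
  out$io_ratio <- if (cenv_agg > 0) io_ratio(cin_agg, cenv_agg) else NA_real_
  out
}
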