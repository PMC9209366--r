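#' Reference outdoor CO2 concentrations
#'
#' Road-tunnel air carries elevated CO2 relative to open roads because
#' vehicular emissions accumulate under weak dispersion. Two comparable
#' published tunnel measurements give 710 and 722 ppm; their mean, 716 ppm,
#' is the tunnel boundary default. The open-road default is the nominal
#' ambient 420 ppm.
#'
#' @param cited_ppm the two tunnel literature values, ppm.
#' @return boundary CO2 concentration, ppm.
#' @export
#' @examples
#' default_tunnel_co2()  # 716
default_tunnel_co2 <- function(cited_ppm = c(710, 722)) {
  mean(cited_ppm)
}

#' @rdname default_tunnel_co2
#' @export
default_open_road_co2 <- function() 420

#' Multimodal lognormal outdoor aerosol model
#'
#' Traffic-influenced outdoor aerosol number distributions are well
#' described by a mixture of lognormal modes, with most of the particle
#' count below 100 nm (fresh exhaust nucleation and soot modes). The
#' default model has a 30 nm mode (55% of counts), a 90 nm mode (44%) and
#' a small 500 nm accumulation/coarse tail (1%) which carries most of the
#' mass, at a tunnel-like total of 30,000 N/cm3.
#'
#' @param modes data.frame with columns `fraction` (number fractions,
#'   summing to 1), `gmd_nm` (geometric mean diameters, nm) and `gsd`
#'   (geometric standard deviations, > 1).
#' @param total_count total number concentration, N/cm3.
#' @param noise_sd lognormal channel-noise sigma (0 = noise-free).
#' @param seed integer seed making any noise reproducible.
#' @return an object of class `cabin_outdoor_model`.
#' @export
outdoor_aerosol_model <- function(modes = data.frame(
                                    fraction = c(0.55, 0.44, 0.01),
                                    gmd_nm = c(30, 90, 500),
                                    gsd = c(1.8, 2.0, 2.2)),
                                  total_count = 30000, noise_sd = 0,
                                  seed = 1L) {
  stopifnot(is.data.frame(modes),
            all(c("fraction", "gmd_nm", "gsd") %in% names(modes)))
  if (abs(sum(modes$fraction) - 1) > 1e-8)
    stop("mode number fractions must sum to 1")
  if (any(modes$gsd <= 1)) stop("geometric standard deviations must exceed 1")
  if (any(modes$gmd_nm <= 0)) stop("mode diameters must be positive")
  if (total_count < 0) stop("total_count must be non-negative")
  structure(list(modes = modes, total_count = total_count,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cabin_outdoor_model")
}

#' Discretize an outdoor aerosol model onto the size grid
#'
#' Integrates the lognormal mixture density over each channel (between
#' geometric-mean channel edges) and scales to the model's total count.
#' Probability mass falling outside the grid span is truncated; the
#' channel masses are renormalized so the discretized distribution
#' conserves the total count, and the truncated fraction is reported via a
#' message (a warning if a mode center lies outside the grid span
#' entirely). With `noise_sd > 0`, reproducible multiplicative lognormal
#' noise is applied per channel and the total re-conserved.
#'
#' @param model a [outdoor_aerosol_model()].
#' @param grid a [size_grid()].
#' @return a count-basis [size_distribution()].
#' @export
#' @examples
#' d <- generate_outdoor_distribution(outdoor_aerosol_model())
#' aggregate_distribution(d, "ufp") / sum(d$values)  # UFP fraction > 0.5
generate_outdoor_distribution <- function(model, grid = size_grid()) {
  stopifnot(inherits(model, "cabin_outdoor_model"))
  edges <- size_grid_edges(grid)
  if (model$total_count == 0)
    return(size_distribution(numeric(length(grid)), "count", grid))
  outside <- model$modes$gmd_nm < edges[1] | model$modes$gmd_nm > edges[length(edges)]
  if (any(outside))
    warning("mode diameter(s) ",
            paste(model$modes$gmd_nm[outside], collapse = ", "),
            " nm outside the grid span; mass renormalized over the grid")
  p <- numeric(length(grid))
  for (k in seq_len(nrow(model$modes))) {
    cdf <- stats::plnorm(edges, meanlog = log(model$modes$gmd_nm[k]),
                         sdlog = log(model$modes$gsd[k]))
    p <- p + model$modes$fraction[k] * diff(cdf)
  }
  covered <- sum(p)
  if (covered <= 0) stop("no probability mass falls on the size grid")
  if (1 - covered > 1e-3)
    message(sprintf("%.2f%% of the mixture truncated outside the grid span",
                    100 * (1 - covered)))
  values <- p / covered * model$total_count
  if (model$noise_sd > 0) {
    values <- withr::with_seed(model$seed, {
      noisy <- values * stats::rlnorm(length(values), -model$noise_sd^2 / 2,
                                      model$noise_sd)
      noisy / sum(noisy) * model$total_count
    })
  }
  size_distribution(values, "count", grid)
}

#' Packaged illustrative cabin scenario
#'
#' A ready-made scenario mirroring a common poor-air-quality use case:
#' aged filter, no ionization, Low fan airflow (about 40 L/s), two
#' occupants and tunnel-like outdoor air (synthetic traffic aerosol,
#' 716 ppm CO2). It is illustrative — the outdoor aerosol is generated,
#' not measured.
#'
#' @param recirculation recirculation degree in \[0, 1\].
#' @param vspeed vehicle speed, km/h.
#' @param fan fan level name, see [fan_level_flow()].
#' @param filter_status,ionization filter selection for
#'   [load_filter_fixture()].
#' @param occupants an [occupant_load()].
#' @param outdoor_model a [outdoor_aerosol_model()].
#' @param Cenv_co2 outdoor CO2, ppm.
#' @param vehicle a [vehicle_spec()].
#' @param eta_mode efficiency-bound selection, see [scenario()].
#' @return a [scenario()].
#' @export
#' @examples
#' sc <- example_scenario(recirculation = 0.5)
#' cabin_steady_state(sc)$co2
example_scenario <- function(recirculation = 0, vspeed = 0, fan = "low",
                             filter_status = "aged_500h", ionization = "off",
                             occupants = occupant_load(2),
                             outdoor_model = outdoor_aerosol_model(),
                             Cenv_co2 = default_tunnel_co2(),
                             vehicle = vehicle_spec(Vcabin = 4.1),
                             eta_mode = "average") {
  scenario(
    vehicle = vehicle,
    vent = ventilation_from_degree(fan_level_flow(fan), recirculation,
                                   vspeed = vspeed),
    filter = load_filter_fixture(filter_status, ionization),
    occupants = occupants,
    Cenv_particles = generate_outdoor_distribution(outdoor_model,
                                                   vehicle$grid),
    Cenv_co2 = Cenv_co2,
    eta_mode = eta_mode)
}

# PM2.5 I/O ratio of a scenario, converting count-basis boundaries to mass
.pm25_io <- function(sc) {
  cin <- steady_state_particles(sc)
  cenv <- sc$Cenv_particles
  if (cin$basis == "count") {
    cin <- count_to_mass(cin, sc$density)
    cenv <- count_to_mass(cenv, sc$density)
  }
  io_ratio(aggregate_distribution(cin, "pm25"),
           aggregate_distribution(cenv, "pm25"))
}

.with_provenance <- function(df, base, parameter, values) {
  attr(df, "provenance") <- list(base_hash = rlang::hash(base),
                                 parameter = parameter, values = values)
  df
}

#' Filter-efficiency sensitivity sweep
#'
#' Perturbs the filter efficiency by `+/- delta` in the channels between
#' `range_nm[1]` and `range_nm[2]` inclusive (default 52-352 nm, the range
#' holding most of the particle counts and the most penetrating particle
#' sizes), clipping to \[0, 1\], and reports the steady-state PM2.5
#' indoor-to-outdoor ratio for the original and both perturbed scenarios.
#'
#' @param base a [scenario()].
#' @param delta absolute efficiency perturbation.
#' @param range_nm inclusive diameter range of perturbed channels, nm.
#' @return data.frame with columns `perturbation` (`-delta`, `0`,
#'   `+delta`) and `pm25_io`; sweep provenance (base scenario hash,
#'   parameter, values) is attached as the `"provenance"` attribute.
#' @export
sweep_eta <- function(base, delta = 0.05, range_nm = c(52, 352)) {
  stopifnot(inherits(base, "cabin_scenario"))
  mid <- as.numeric(base$filter$grid)
  in_range <- mid >= range_nm[1] & mid <= range_nm[2]
  perturb <- function(d) {
    f <- base$filter
    f$eta_upper[in_range] <- pmin(1, pmax(0, f$eta_upper[in_range] + d))
    f$eta_lower[in_range] <- pmin(1, pmax(0, f$eta_lower[in_range] + d))
    sc <- base
    sc$filter <- f
    sc
  }
  deltas <- c(-delta, 0, delta)
  res <- data.frame(
    perturbation = deltas,
    pm25_io = vapply(deltas, function(d) .pm25_io(perturb(d)), numeric(1)))
  .with_provenance(res, base, "eta_52_352", deltas)
}

#' Ventilation-airflow sensitivity sweep
#'
#' Scales `Qoa` and `Qrec` together by each factor (preserving the
#' recirculation degree) and reports the steady-state PM2.5
#' indoor-to-outdoor ratio.
#'
#' @param base a [scenario()].
#' @param factors relative flow changes; the default is the
#'   `+/- 10/30/50/70%` grid plus the unperturbed case.
#' @return data.frame with columns `factor` and `pm25_io`, with sweep
#'   provenance attached (see [sweep_eta()]).
#' @export
sweep_airflow <- function(base, factors = c(-0.7, -0.5, -0.3, -0.1, 0,
                                            0.1, 0.3, 0.5, 0.7)) {
  stopifnot(inherits(base, "cabin_scenario"))
  res <- data.frame(
    factor = factors,
    pm25_io = vapply(factors, function(f) {
      sc <- base
      sc$vent <- ventilation_state(base$vent$Qoa * (1 + f),
                                   base$vent$Qrec * (1 + f),
                                   base$vent$vspeed)
      .pm25_io(sc)
    }, numeric(1)))
  .with_provenance(res, base, "airflow", factors)
}

#' Recirculation-degree sweep
#'
#' Varies the recirculation degree at fixed total supply flow
#' `Qoa + Qrec` and reports the steady-state cabin PM2.5 and CO2: the
#' recirculation trade-off, where re-filtering cabin air lowers particle
#' levels while the reduced outside-air fraction lets breath CO2
#' accumulate.
#'
#' @param base a [scenario()] (its total supply flow and speed are kept).
#' @param degrees recirculation degrees in \[0, 1\]; default the
#'   0/30/50/70% grid.
#' @return data.frame with columns `degree`, `pm25` (ug/m3), `co2` (ppm)
#'   and `pm25_io`, with sweep provenance attached (see [sweep_eta()]).
#' @export
#' @examples
#' tab <- sweep_recirculation(example_scenario())
#' # PM2.5 falls and CO2 rises as recirculation increases
sweep_recirculation <- function(base, degrees = c(0, 0.3, 0.5, 0.7)) {
  stopifnot(inherits(base, "cabin_scenario"))
  total <- base$vent$Qoa + base$vent$Qrec
  rows <- lapply(degrees, function(deg) {
    sc <- base
    sc$vent <- ventilation_from_degree(total, deg, base$vent$vspeed)
    cin <- steady_state_particles(sc)
    if (cin$basis == "count") cin <- count_to_mass(cin, sc$density)
    data.frame(degree = deg,
               pm25 = aggregate_distribution(cin, "pm25"),
               co2 = steady_state_co2(sc),
               pm25_io = .pm25_io(sc))
  })
  .with_provenance(do.call(rbind, rows), base, "recirculation", degrees)
}
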