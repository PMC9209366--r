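# Scenario builders shared across tests.

# Flat, fully controllable scenario: uniform filter efficiency and outdoor
# concentration, optional zero deposition, and kp = 0 so the aerodynamic
# pressure (hence infiltration) vanishes unless requested.
flat_scenario <- function(Qoa = 0.02, Qrec = 0, vspeed = 0, Vcabin = 4.1,
                          eta = 0.5, beta = 0, Cenv = 100, basis = "count",
                          N = 0, Vbr = 6.5, Cbr = 40000, Cenv_co2 = 716,
                          eta_mode = "upper", kp = 0, kf = 18.78, n = 0.66,
                          Frev = 0.8, alpha = 0.6, density = 1000) {
  grid <- size_grid()
  filt <- suppressWarnings(
    filter_spec("new", "off", eta_upper = rep(eta, 25),
                eta_lower = rep(eta, 25), grid = grid))
  scenario(
    vehicle = vehicle_spec(Vcabin = Vcabin, kf = kf, n = n, kp = kp,
                           Frev = Frev, beta = beta, alpha = alpha,
                           grid = grid),
    vent = ventilation_state(Qoa, Qrec, vspeed),
    filter = filt,
    occupants = occupant_load(N, Vbr = Vbr, Cbr = Cbr),
    Cenv_particles = size_distribution(rep(Cenv, 25), basis, grid),
    Cenv_co2 = Cenv_co2, eta_mode = eta_mode, density = density)
}

# Randomized but reproducible scenario over realistic driving conditions.
rand_scenario <- function(i) {
  set.seed(1000 + i)
  combos <- expand.grid(status = c("new", "aged_500h"),
                        ionization = c("off", "on"),
                        stringsAsFactors = FALSE)
  k <- sample(4, 1)
  vehicle <- vehicle_spec(Vcabin = sample(c(2.9, 4.1), 1))
  cenv <- generate_outdoor_distribution(
    outdoor_aerosol_model(total_count = runif(1, 5e3, 8e4)))
  scenario(
    vehicle = vehicle,
    vent = ventilation_state(Qoa = runif(1, 0.006, 0.09),
                             Qrec = runif(1, 0, 0.06),
                             vspeed = runif(1, 0, 120)),
    filter = load_filter_fixture(combos$status[k], combos$ionization[k]),
    occupants = occupant_load(sample(0:3, 1)),
    Cenv_particles = cenv,
    Cenv_co2 = runif(1, 400, 750),
    eta_mode = sample(c("average", "upper", "lower"), 1))
}

# Time horizon long enough for the slowest channel to relax to steady state.
relaxation_horizon <- function(sc, n_folds = 40) {
  fl <- scenario_flows(sc)
  rates <- (fl$Qoa + fl$Qps + fl$Qinf + fl$Qdep +
              fl$Qrec * pmin(sc$filter$eta_lower, sc$filter$eta_upper)) /
    sc$vehicle$Vcabin
  co2_rate <- (fl$Qoa + fl$Qps + fl$Qinf) / sc$vehicle$Vcabin
  n_folds / min(rates, co2_rate)
}
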