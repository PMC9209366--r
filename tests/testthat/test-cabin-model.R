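# speed giving a passive ventilation flow of exactly 0.005 m3/s in a 4.1 m3
# cabin under the default coefficient
.v_qps005 <- 0.005 * 3600 / (0.21 * 4.1)
# deposition rate giving Qdep = 0.002 m3/s in a 4.1 m3 cabin
.beta_qdep002 <- 0.002 * 3600 / 4.1

test_that("particle balance rate matches hand arithmetic and vanishes at equilibrium", {
  sc0 <- flat_scenario(Qoa = 0, Qrec = 0, vspeed = 0, eta = 0, Cenv = 0)
  expect_equal(suppressMessages(particle_rhs(rep(0, 25), sc0)), rep(0, 25))

  # (Qoa+Qps) = 0.025, eta = 0.5, Qdep = 0.002, Qrec = 0.01, Cenv = 100,
  # Cin = 0 -> dCin/dt = 1.25 / 4.1
  sc <- flat_scenario(Qoa = 0.02, Qrec = 0.01, vspeed = .v_qps005,
                      eta = 0.5, beta = .beta_qdep002, Cenv = 100)
  expect_equal(particle_rhs(rep(0, 25), sc), rep(1.25 / 4.1, 25),
               tolerance = 1e-12)
  # fixed point
  css <- steady_state_particles(sc)
  expect_equal(particle_rhs(css$values, sc), rep(0, 25), tolerance = 1e-12)
  expect_error(particle_rhs(rep(0, 25), sc, eta = rep(1.5, 25)),
               "\\[0, 1\\]")
  sc$eta_mode <- "average"
  expect_error(particle_rhs(rep(0, 25), sc), "averages solutions")
})

test_that("closed-form particle steady state reproduces limiting cases and hand value", {
  # perfect filter, no infiltration: particle-free cabin
  sc1 <- flat_scenario(eta = 1)
  expect_equal(steady_state_particles(sc1)$values, rep(0, 25))
  # no removal at all: cabin tracks outdoor (I/O ratio 1)
  sc2 <- flat_scenario(eta = 0, beta = 0)
  expect_equal(steady_state_particles(sc2)$values, rep(100, 25))
  # hand-computed case: 1.25 / 0.032 = 39.0625
  sc3 <- flat_scenario(Qoa = 0.02, Qrec = 0.01, vspeed = .v_qps005,
                       eta = 0.5, beta = .beta_qdep002, Cenv = 100)
  expect_equal(steady_state_particles(sc3)$values, rep(39.0625, 25),
               tolerance = 1e-9)
  expect_equal(io_ratio(steady_state_particles(sc3)$values[1], 100),
               0.390625, tolerance = 1e-9)
  # a channel with no loss or exchange has no steady state
  sc4 <- flat_scenario(Qoa = 0, Qrec = 0, vspeed = 0, beta = 0)
  expect_error(suppressMessages(steady_state_particles(sc4)), "channel 10 nm")
})

test_that("averaged-bound solution is the mean of the bound solutions", {
  grid <- size_grid()
  filt <- filter_spec("new", "off", eta_upper = rep(0.8, 25),
                      eta_lower = rep(0.4, 25), grid = grid)
  base <- flat_scenario(Qoa = 0.02, Qrec = 0.015, beta = 2)
  for (m in c("upper", "lower", "average")) {
    sc <- base
    sc$filter <- filt
    sc$eta_mode <- m
    assign(paste0("s_", m), steady_state_particles(sc)$values)
  }
  expect_equal(s_average, (s_upper + s_lower) / 2, tolerance = 1e-12)
  # nonlinearity in eta: averaging solutions differs from averaging eta
  sc_mid <- base
  sc_mid$filter <- filter_spec("new", "off", eta_upper = rep(0.6, 25),
                               eta_lower = rep(0.6, 25), grid = grid)
  expect_false(isTRUE(all.equal(s_average,
                                steady_state_particles(sc_mid)$values)))
})

test_that("CO2 balance matches hand arithmetic in rate and steady state", {
  sc <- flat_scenario(Qoa = 0.02, Vcabin = 2.9, N = 2, Cenv_co2 = 716)
  # at Cin = Cenv the breath source alone drives the rate
  expect_equal(co2_rhs(716, sc), 2 * (6.5 / 60000) * 40000 / 2.9,
               tolerance = 1e-12)
  expect_equal(co2_rhs(716, sc), 2.989, tolerance = 1e-3)
  css <- steady_state_co2(sc)
  expect_equal(css, 716 + 2 * (6.5 / 60000) * 40000 / 0.02, tolerance = 1e-12)
  expect_equal(css, 1149.33, tolerance = 1e-5)
  expect_equal(co2_rhs(css, sc), 0, tolerance = 1e-12)
  # no occupants: cabin tracks outdoor
  expect_equal(steady_state_co2(flat_scenario(N = 0)), 716)
  # dilution limit
  expect_equal(steady_state_co2(flat_scenario(Qoa = 50, N = 2)), 716,
               tolerance = 1e-3)
  # no outside-air exchange: unbounded accumulation is an error
  expect_error(suppressMessages(
    steady_state_co2(flat_scenario(Qoa = 0, Qrec = 0.02, N = 2))),
    "transient_solve")
})

test_that("CO2 is increasing in occupancy and decreasing in outside airflow", {
  co2_at <- function(N, Qoa) steady_state_co2(flat_scenario(Qoa = Qoa, N = N))
  expect_true(all(diff(vapply(0:4, co2_at, numeric(1), Qoa = 0.02)) > 0))
  expect_true(all(diff(vapply(c(0.01, 0.02, 0.04, 0.08), co2_at,
                              numeric(1), N = 2)) < 0))
})

test_that("transient solution converges to the closed form and conserves", {
  # stationary initial condition stays put
  sc <- flat_scenario(Qoa = 0.02, Qrec = 0.01, eta = 0.6, beta = 1.5, N = 2)
  css <- steady_state_particles(sc)
  traj <- transient_solve(sc, seq(0, 600, 60), Cin0_particles = css$values,
                          Cin0_co2 = steady_state_co2(sc))
  expect_equal(unlist(traj[nrow(traj), 2:26], use.names = FALSE),
               css$values, tolerance = 1e-6)
  expect_equal(traj$co2[nrow(traj)], steady_state_co2(sc), tolerance = 1e-6)

  # nothing flows, nothing changes
  sc0 <- flat_scenario(Qoa = 0, Qrec = 0, vspeed = 0, beta = 0, N = 0,
                       Cenv = 50)
  tr0 <- suppressMessages(
    transient_solve(sc0, seq(0, 3600, 600), Cin0_particles = 7,
                    Cin0_co2 = 500))
  expect_equal(unlist(tr0[nrow(tr0), 2:26], use.names = FALSE), rep(7, 25),
               tolerance = 1e-9)
  expect_equal(tr0$co2, rep(500, 7), tolerance = 1e-9)

  # CO2 trajectory equals the analytic single-exponential solution
  sc2 <- flat_scenario(Qoa = 0.03, Vcabin = 4.1, N = 3, Cenv_co2 = 420)
  t <- seq(0, 1200, 30)
  traj2 <- transient_solve(sc2, t, Cin0_co2 = 420)
  css2 <- steady_state_co2(sc2)
  analytic <- css2 + (420 - css2) * exp(-0.03 * t / 4.1)
  expect_equal(traj2$co2, analytic, tolerance = 1e-6)

  # invalid inputs
  expect_error(transient_solve(sc, c(3, 2, 1)), "strictly increasing")
  expect_error(transient_solve(sc, t, Cin0_particles = -1), "non-negative")
})

test_that("brute-force Euler iteration of the balance matches the closed form", {
  sc <- flat_scenario(Qoa = 0.025, Qrec = 0.012, eta = 0.45, beta = 2.3,
                      Cenv = 80)
  cin <- rep(0, 25)
  dt <- 4
  for (step in 1:5000) cin <- cin + dt * particle_rhs(cin, sc)
  expect_equal(cin, steady_state_particles(sc)$values, tolerance = 1e-6)
})

test_that("cabin concentrations never exceed outdoor without an indoor source", {
  for (i in 1:25) {
    sc <- rand_scenario(i)
    cin <- steady_state_particles(sc)
    expect_true(all(cin$values <= sc$Cenv_particles$values + 1e-12))
  }
})

test_that("steady state is linear in the outdoor boundary", {
  sc <- rand_scenario(101)
  cin1 <- steady_state_particles(sc)$values
  sc2 <- sc
  sc2$Cenv_particles <- size_distribution(2 * sc$Cenv_particles$values,
                                          sc$Cenv_particles$basis,
                                          sc$Cenv_particles$grid)
  expect_equal(steady_state_particles(sc2)$values, 2 * cin1,
               tolerance = 1e-12)
})

test_that("steady state decreases with filtration, deposition and recirculation", {
  base <- flat_scenario(Qoa = 0.02, Qrec = 0.01, eta = 0.3, beta = 1)
  at_eta <- function(e) steady_state_particles(
    flat_scenario(Qoa = 0.02, Qrec = 0.01, eta = e, beta = 1))$values[1]
  expect_true(all(diff(vapply(c(0, 0.25, 0.5, 0.75, 1), at_eta,
                              numeric(1))) < 0))
  at_beta <- function(b) steady_state_particles(
    flat_scenario(Qoa = 0.02, Qrec = 0.01, eta = 0.3, beta = b))$values[1]
  expect_true(all(diff(vapply(c(0, 1, 4, 12.6), at_beta, numeric(1))) < 0))
  at_qrec <- function(q) steady_state_particles(
    flat_scenario(Qoa = 0.02, Qrec = q, eta = 0.3, beta = 1))$values[1]
  expect_true(all(diff(vapply(c(0, 0.01, 0.02, 0.04), at_qrec,
                              numeric(1))) < 0))
})

test_that("indoor-outdoor ratio handles its edge cases", {
  expect_equal(io_ratio(5, 5), 1)
  expect_equal(io_ratio(0, 5), 0)
  expect_error(io_ratio(1, 0), "positive")
})
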