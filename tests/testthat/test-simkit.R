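# simkit: maturation operator, linear map, lineage generator ground truth

test_that("apply_maturation: identity at tau = 0 and closed-form pulse response", {
  # tau = 0: M is cumulative production; a unit pulse jumps and stays
  dt <- 0.1
  M <- apply_maturation(c(1 / dt, 0, 0, 0), tau_mat = 0, dt = dt)
  expect_equal(M, c(1, 1, 1, 1))

  # pulse of mass A at t = 0 with tau > 0: M(t) = A (1 - exp(-t/tau))
  # (oracle: closed-form solution of the two-compartment ODE; discretisation
  # error is O(dt/tau) because the pulse is spread over the first bin)
  A <- 2; tau <- 5; dt <- 0.05
  P <- c(A / dt, rep(0, 999))
  M <- apply_maturation(P, tau, dt)
  tt <- seq_len(1000) * dt
  expect_lt(max(abs(M - A * (1 - exp(-tt / tau)))), 0.02 * A)

  expect_error(apply_maturation(c(1, -1), 5, 1), "non-negative")
  expect_error(apply_maturation(c(1, 1), 5, 0), "dt")
})

test_that("apply_maturation is a linear operator", {
  set.seed(7)
  P1 <- runif(200, 0, 5); P2 <- runif(200, 0, 5)
  for (tau in c(0, 7)) {
    lhs <- apply_maturation(P1 + P2, tau, 0.5)
    rhs <- apply_maturation(P1, tau, 0.5) + apply_maturation(P2, tau, 0.5)
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("simulate_linear_map: deterministic steps and stationary variance", {
  expect_equal(simulate_linear_map(0.5, 40, 0, 1, V0 = 60)[2], 50)
  v <- simulate_linear_map(0, 40, 0, 5, V0 = 60)
  expect_equal(v[-1], rep(40, 5))
  # AR(1) stationary variance eta^2/(1 - p^2) = 4/(1 - 0.36) = 6.25
  v <- simulate_linear_map(0.6, 40, 2, 1e5, seed = 3)
  v <- v[-(1:1000)]
  expect_lt(abs(stats::var(v) / 6.25 - 1), 0.05)
  expect_lt(abs(mean(v) - 40), 0.1)
  expect_error(simulate_linear_map(-0.1, 40, 1, 10), "p")
})

test_that("ideal Sizer ground truth: end-of-G1 volume is the target exactly", {
  sim <- simulate_lineage(sim_config(n_cells = 5, n_generations = 2, a_G1 = 0,
                                     eta_sd = 0, seed = 4), traces = FALSE)
  d <- sim$truth[sim$truth$replicative_age == 0, ]
  expect_equal(d$true_V_G1, rep(75, nrow(d)), tolerance = 1e-12)
})

test_that("fluorescence is conserved at nuclear division", {
  cfg <- sim_config(n_cells = 2, n_generations = 2, n_mother_cycles = 1,
                    tau_mat_min = 0, sigma_F = 0, sigma_V = 0, seed = 8)
  sim <- simulate_lineage(cfg)
  tru <- sim$truth
  tr <- sim$traces
  # mother cell c0001_g01, cycle 1 divides producing daughter c0001_g02
  row <- tru[tru$cell_id == "c0001_g01" & tru$cycle_index == 1, ]
  trm <- tr[tr$cell_id == "c0001_g01", ]
  pre <- trm$fluo_au[max(which(trm$t_min < row$t_ana_onset))]
  post_m <- trm$fluo_au[min(which(trm$t_min >= row$t_cyto))]
  post_d <- tr$fluo_au[tr$cell_id == "c0001_g02"][1]
  expect_lt(abs((post_m + post_d) / pre - 1), 1e-6)

  # with maturing pool (tau = 5) conservation across frames is approximate
  # (the mature pool still grows slightly between the compared frames)
  cfg5 <- sim_config(n_cells = 2, n_generations = 2, tau_mat_min = 5,
                     sigma_F = 0, sigma_V = 0, seed = 8)
  sim5 <- simulate_lineage(cfg5)
  tru5 <- sim5$truth; tr5 <- sim5$traces
  row <- tru5[tru5$cell_id == "c0001_g01" & tru5$cycle_index == 1, ]
  trm <- tr5[tr5$cell_id == "c0001_g01", ]
  pre <- trm$fluo_au[max(which(trm$t_min < row$t_ana_onset))]
  post_m <- trm$fluo_au[min(which(trm$t_min >= row$t_cyto))]
  post_d <- tr5$fluo_au[tr5$cell_id == "c0001_g02"][1]
  expect_lt(abs((post_m + post_d) / pre - 1), 0.02)
})

test_that("volume bookkeeping: daughter birth volume is the bud at cytokinesis", {
  sim <- simulate_lineage(sim_config(n_cells = 4, n_generations = 3, seed = 12),
                          traces = FALSE)
  tru <- sim$truth
  for (chain in 1:4) for (gen in 1:2) {
    mother <- tru[tru$chain == chain & tru$generation == gen & tru$cycle_index == 1, ]
    daught <- tru[tru$chain == chain & tru$generation == gen + 1 & tru$cycle_index == 1, ]
    expect_equal(daught$true_V_birth, mother$true_Vb_cyto, tolerance = 1e-12)
  }
  # realized asymmetry of age-0 divisions matches the nominal r_div
  d <- tru[tru$replicative_age == 0, ]
  expect_lt(abs(mean(d$true_Vb_cyto / d$true_V_div) - sim$config$r_div), 0.01)
})

test_that("ground-truth compensation slope: Delta V_G1 on V_birth recovers a_G1 - 1", {
  sim <- simulate_lineage(sim_config(n_cells = 1300, n_generations = 4,
                                     n_mother_cycles = 0, seed = 33),
                          traces = FALSE)
  d <- sim$truth[sim$truth$replicative_age == 0, ]
  expect_gte(nrow(d), 5000)
  f <- stats::lm((true_V_G1 - true_V_birth) ~ true_V_birth, d)
  ci <- stats::confint(f)["true_V_birth", ]
  expect_gt(-0.3, ci[1])
  expect_lt(-0.3, ci[2])
})

test_that("simulation is deterministic and per-chain streams are stable", {
  s1 <- simulate_lineage(sim_config(n_cells = 4, n_generations = 2, seed = 9))
  s2 <- simulate_lineage(sim_config(n_cells = 4, n_generations = 2, seed = 9))
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$truth, s2$truth)
  # adding chains must not perturb existing ones
  s3 <- simulate_lineage(sim_config(n_cells = 6, n_generations = 2, seed = 9))
  expect_equal(s1$truth, s3$truth[s3$truth$chain <= 4, ],
               ignore_attr = TRUE)
})

test_that("configuration validation rejects unreachable/invalid worlds", {
  expect_error(sim_config(mu_unb = 0), "linear growth")
  expect_error(sim_config(growth_mode = "exponential", k_growth = 0), "exponential")
  expect_error(sim_config(r_div = 0.6), "r_div")
  expect_error(sim_config(a_G1 = 2.5), "retention")
  expect_error(sim_config(T_Ana_mean = 3), "cyto_offset")
  expect_error(sim_config(tau_mat_min = -1))
})

test_that("fraction division rule hands the daughter exactly r_div of the volume", {
  sim <- simulate_lineage(sim_config(n_cells = 3, n_generations = 3,
                                     division_rule = "fraction", seed = 5),
                          traces = FALSE)
  tru <- sim$truth
  for (chain in 1:3) for (gen in 1:2) {
    mother <- tru[tru$chain == chain & tru$generation == gen & tru$cycle_index == 1, ]
    daught <- tru[tru$chain == chain & tru$generation == gen + 1 & tru$cycle_index == 1, ]
    expect_equal(daught$true_V_birth, sim$config$r_div * mother$true_V_div,
                 tolerance = 1e-12)
  }
})
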