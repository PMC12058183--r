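# Multiple gonotrophic cycles: coverage partitioning, per-cycle selection,
# cycle-weighted responses and age profiles.

test_that("natural survival is daily survival to the power of cycle length", {
  expect_equal(natural_survival(1, 7), 1)
  expect_equal(natural_survival(0.9, 3), 0.729)
  expect_equal(natural_survival(0.8, 3), 0.512)
  expect_equal(cycle_params(d = 0.9, g = 3)$rho, 0.729)
})

test_that("encounter partition covers the de-facto limits and sums to one", {
  x <- 0.7
  mono <- encounter_partition(coverage_model(c_i = 1), x)
  expect_equal(unname(mono), c(x, 0, 0, 1 - x))
  mixt <- encounter_partition(
    coverage_model(c_i = 0, c_j = 0, c_ij = 1,
                   lambda_female = c(i = 0, j = 0, ij = 1)), x)
  expect_equal(unname(mixt), c(0, 0, x, 1 - x))
  mosaic <- encounter_partition(coverage_model(c_i = 0.5, c_j = 0.5), x)
  expect_equal(unname(mosaic), c(0.35, 0.35, 0, 0.3))
  set.seed(9)
  for (k in 1:10) {
    cv <- runif(3)
    cv <- cv / sum(cv)
    lam <- runif(3)
    lam <- lam / sum(lam)
    names(lam) <- c("i", "j", "ij")
    p <- encounter_partition(coverage_model(cv[1], cv[2], cv[3], lam),
                             runif(1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  expect_error(coverage_model(0.5, 0.6, 0.2), "sum to 1")
})

test_that("a cycle step conserves females across encounter classes", {
  d <- hatch_distribution(60, 30, n_bins = 501)
  K <- survival_on_grid(d$grid, insecticide("i"), 0.9)
  cov <- coverage_model(c_i = 0.3, c_j = 0.3, c_ij = 0.4,
                        lambda_female = c(i = 0.25, j = 0.25, ij = 0.5))
  st <- list(freq = d$freq_female, grid = d$grid, z_parent_mean = 60,
             cycle = 0)
  for (G in 1:4) {
    st <- cycle_step(st, K, Kbar_j = 0.4, coverage = cov, x = 0.7,
                     rho = 0.729)
    expect_equal(st$n_parents, st$n_i + st$n_j + st$n_ij + st$n_u,
                 tolerance = 1e-12)
    expect_equal(sum(st$freq), st$n_parents, tolerance = 1e-12)
  }
})

test_that("selection raises the female parental mean cycle on cycle", {
  d <- hatch_distribution(100, 30, n_bins = 1001)
  K <- survival_on_grid(d$grid, insecticide("i"))
  fem <- irmsim:::run_female_cycles(d, K, 1, coverage_model(c_i = 1),
                                    x = 0.7, rho = 0.729, gmax = 6)
  expect_true(all(diff(fem$z_parent) > 0))
  expect_true(all(diff(fem$n_parent) < 0))
})

test_that("natural survival scales counts but not means", {
  d <- hatch_distribution(100, 30, n_bins = 501)
  K <- survival_on_grid(d$grid, insecticide("i"))
  f1 <- irmsim:::run_female_cycles(d, K, 1, coverage_model(c_i = 1),
                                   x = 1, rho = 1, gmax = 3)
  f2 <- irmsim:::run_female_cycles(d, K, 1, coverage_model(c_i = 1),
                                   x = 1, rho = 0.5, gmax = 3)
  expect_equal(f1$z_parent, f2$z_parent, tolerance = 1e-12)
  expect_equal(f2$n_parent / f1$n_parent, c(1, 0.5, 0.25),
               tolerance = 1e-12)
})

test_that("no exposure and full survival leave the cohort untouched", {
  d <- hatch_distribution(100, 30, n_bins = 501)
  K <- survival_on_grid(d$grid, insecticide("i"))
  fem <- irmsim:::run_female_cycles(d, K, 1, coverage_model(c_i = 1),
                                    x = 0, rho = 1, gmax = 4)
  expect_equal(fem$z_parent, rep(100, 4), tolerance = 1e-9)
  expect_equal(fem$n_parent, rep(0.5, 4), tolerance = 1e-12)
})

test_that("one-cycle runs reproduce the single-generation branch exactly", {
  d <- hatch_distribution(80, 30, n_bins = 1001)
  K <- survival_on_grid(d$grid, insecticide("i"), 0.8)
  ex <- exposure_params(0.7, 0.7)
  fem <- irmsim:::run_female_cycles(d, K, 1, coverage_model(c_i = 1),
                                    x = ex$x, rho = 1, gmax = 1)
  out <- parental_pool(probabilistic_selection(d, K, ex), 80, ex)
  expect_equal(fem$z_parent, out$z_parent_mean[["female"]],
               tolerance = 1e-12)
  expect_equal(fem$n_parent, out$n_parents[["female"]], tolerance = 1e-12)
  # de-facto mixture through the coverage machinery
  mixcov <- coverage_model(c_i = 0, c_j = 0, c_ij = 1,
                           lambda_female = c(i = 0, j = 0, ij = 1))
  fem2 <- irmsim:::run_female_cycles(d, K, 0.4, mixcov, x = ex$x, rho = 1,
                                     gmax = 1)
  out2 <- parental_pool(probabilistic_selection(d, K, ex,
                                                partner_survival = 0.4),
                        80, ex)
  expect_equal(fem2$z_parent, out2$z_parent_mean[["female"]],
               tolerance = 1e-12)
})

test_that("male differential: single round, constant, zero when unexposed", {
  d <- hatch_distribution(80, 30, n_bins = 501)
  K <- survival_on_grid(d$grid, insecticide("i"))
  none <- male_selection_complex(d, K, 1, coverage_model(c_i = 1),
                                 exposure_params(0.7, 0))
  expect_equal(none$S_insecticide, 0)
  # de-facto mixture equals the generation-level mixture male differential
  mixcov <- coverage_model(c_i = 0, c_j = 0, c_ij = 1,
                           lambda_male = c(i = 0, j = 0, ij = 1),
                           lambda_female = c(i = 0, j = 0, ij = 1))
  ex <- exposure_params(0.7, 0.7)
  male <- male_selection_complex(d, K, 0.4, mixcov, ex)
  ref <- parental_pool(probabilistic_selection(d, K, ex,
                                               partner_survival = 0.4),
                       80, ex)
  expect_equal(male$S_insecticide, ref$S_insecticide[["male"]],
               tolerance = 1e-12)
})

test_that("a 50/50 micro-mosaic of identical insecticides equals
           monotherapy at the same total exposure", {
  d <- hatch_distribution(80, 30, n_bins = 501)
  K <- survival_on_grid(d$grid, insecticide("i"))
  Kbar <- mean_survival(80, insecticide("i"))
  mos <- irmsim:::run_female_cycles(d, K, Kbar,
                                    coverage_model(c_i = 0.5, c_j = 0.5),
                                    x = 0.7, rho = 0.729, gmax = 3)
  expect_true(all(diff(mos$z_parent) > 0))
  # exposure to the focal product is halved relative to monotherapy
  mono <- irmsim:::run_female_cycles(d, K, 1, coverage_model(c_i = 1),
                                     x = 0.35, rho = 0.729, gmax = 3)
  expect_equal(mos$z_exposed[1], mono$z_exposed[1], tolerance = 1e-9)
})

test_that("cycle-weighted response averages per-cycle responses by
           oviposition counts", {
  g <- genetics_params(1, 1)
  # identical responses collapse to the common value
  out <- multi_cycle_response(c(10, 10), c(80, 20), 0, 10, g)
  expect_equal(out$R_total, 10)
  # worked weighting: R = (0.1 * 80 + 0.3 * 20) / 100
  out2 <- multi_cycle_response(z_parent = c(0.1, 0.3) * 2,
                               n_parent = c(80, 20), z0 = 0, S_male = 0, g)
  expect_equal(out2$R_total, 0.14)
  expect_equal(out2$n_oviposition, 100)
  expect_error(multi_cycle_response(numeric(0), numeric(0), 0, 0, g),
               "extinct")
})

test_that("gmax = 1 multi-cycle simulation equals the single-cycle run", {
  scen <- two_insecticide_scenario(beta = 10, cost = 0.1,
                                   cycles = cycle_params(1, 3, 1))
  t1 <- run_simulation(scen, strategy_config("sequence", cap = 80),
                       cycles = "single")
  t2 <- run_simulation(scen, strategy_config("sequence", cap = 80),
                       cycles = "multi")
  expect_equal(t1$records$mean_prs, t2$records$mean_prs, tolerance = 1e-10)
})

test_that("age profiles: geometric baseline, intervention-dominated counts", {
  ap <- age_profile_snapshot(insecticide("i"), mean_prs = c(i = 100),
                             coverage = coverage_model(c_i = 1), x = 0.7)
  expect_equal(ap$no_intervention[1], 1e5)
  expect_equal(ap$no_intervention, 1e5 * 0.729^(0:9))
  expect_true(all(ap$with_intervention <= ap$no_intervention))
  expect_true(all(ap$with_intervention > 0))
  # resistance increases survivorship at every cycle
  ap0 <- age_profile_snapshot(insecticide("i"), mean_prs = c(i = 0),
                              coverage = coverage_model(c_i = 1), x = 0.7)
  expect_true(all(ap0$with_intervention <= ap$with_intervention))
})

test_that("full-dose mixtures suppress the age profile at least as much as
           half-dose mixtures", {
  mixcov <- coverage_model(c_i = 0, c_j = 0, c_ij = 1,
                           lambda_female = c(i = 0, j = 0, ij = 1))
  pair <- function(om) list(
    insecticide("i", decay = decay_profile(omega0 = om)),
    insecticide("j", decay = decay_profile(omega0 = om)))
  for (kb in c(0, 0.10, 0.50)) {
    z <- if (kb == 0) 0 else bioassay_to_prs(kb)
    full <- age_profile_snapshot(pair(1), mean_prs = c(i = z, j = z),
                                 omega = 1, coverage = mixcov, x = 0.7)
    half <- age_profile_snapshot(pair(0.5), mean_prs = c(i = z, j = z),
                                 omega = 0.5, coverage = mixcov, x = 0.7)
    expect_true(all(full$with_intervention <= half$with_intervention))
  }
})

test_that("per-cycle dispersal mode runs and reduces to the default when
           nobody disperses", {
  scen0 <- two_insecticide_scenario(beta = 10, cost = 0.1, dispersal = 0,
                                    cycles = cycle_params(0.9, 3, 3))
  scen1 <- scen0
  scen1$per_cycle_dispersal <- TRUE
  t0 <- run_simulation(scen0, strategy_config("mixture", cap = 40),
                       cycles = "multi")
  t1 <- run_simulation(scen1, strategy_config("mixture", cap = 40),
                       cycles = "multi")
  expect_equal(t1$records$mean_prs, t0$records$mean_prs, tolerance = 1e-6)
})
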