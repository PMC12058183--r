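# Deployment scheduling, thresholds with hysteresis, and the simulation
# loop.

test_that("deployment plans follow arsenal order and the thresholds", {
  strat <- strategy_config("sequence", arsenal = c("a", "b"))
  none_failed <- c(a = FALSE, b = FALSE)
  expect_equal(plan_deployment(strat, none_failed)$products, "a")
  # keep the current insecticide while it has not failed
  expect_equal(plan_deployment(strat, none_failed, current = "a")$products,
               "a")
  # move on once failed; exhaustion gives the no-option signal
  expect_equal(plan_deployment(strat, c(a = TRUE, b = FALSE),
                               current = "a")$products, "b")
  expect_null(plan_deployment(strat, c(a = TRUE, b = TRUE), current = "b"))
  expect_error(plan_deployment(strategy_config("sequence",
                                               arsenal = character(0)),
                               none_failed), "empty")
})

test_that("rotation cycles through eligible insecticides only", {
  strat <- strategy_config("rotation", arsenal = c("a", "b", "c"))
  ok <- c(a = FALSE, b = FALSE, c = FALSE)
  expect_equal(plan_deployment(strat, ok, current = "a")$products, "b")
  expect_equal(plan_deployment(strat, ok, current = "c")$products, "a")
  # a failed insecticide (>= withdrawal) is skipped until it returns
  expect_equal(plan_deployment(strat, c(a = FALSE, b = TRUE, c = FALSE),
                               current = "a")$products, "c")
  expect_null(plan_deployment(strat, c(a = TRUE, b = TRUE, c = TRUE),
                              current = "a"))
})

test_that("mixtures need both partners eligible", {
  strat <- strategy_config("mixture", arsenal = c("a", "b"))
  expect_equal(plan_deployment(strat, c(a = FALSE, b = FALSE))$products,
               c("a", "b"))
  expect_null(plan_deployment(strat, c(a = FALSE, b = TRUE)))
})

test_that("withdrawal and return thresholds show hysteresis in a run", {
  beta <- calibrated_beta()
  scen <- two_insecticide_scenario(beta = beta)
  traj <- run_simulation(scen, strategy_config("rotation", interval = 10,
                                               cap = 300))
  r <- traj$records
  dep <- r[r$deployed, ]
  # deployments only change at interval boundaries
  runs <- rle(paste(dep$trait[order(dep$generation)]))
  expect_true(all(runs$lengths[-length(runs$lengths)] %% 10 == 0))
  # once a trait fails it is not redeployed while at or above the return
  # threshold
  for (id in c("i", "j")) {
    fg <- traj$failure_generation[[id]]
    if (is.na(fg)) next
    after <- r[r$trait == id & r$generation > fg & r$deployed, ]
    if (nrow(after)) {
      redeploy_gen <- min(after$generation)
      kb_at <- r$bioassay_survival[r$trait == id & r$site == "intervention" &
                                     r$generation == redeploy_gen - 1]
      expect_lt(kb_at, 0.10)
    }
  }
})

test_that("efficacy follows a sawtooth when decay is on", {
  scen <- scenario(
    insecticides = list(insecticide("i",
                                    decay = decay_profile(1, 0.05, 0.05,
                                                          tau_b = 50))),
    h2 = 0.2, beta = 1, fitness_cost = fitness_cost("fixed", 0, 0),
    landscape = landscape_params(0.7, 0.3), start_prs = 0, n_bins = 501)
  traj <- run_simulation(scen, strategy_config("continuous", interval = 10,
                                               cap = 30))
  eff <- traj$records$efficacy[traj$records$deployed]
  # restarts at full dose at each redeployment
  expect_equal(eff[c(1, 11, 21)], rep(1, 3))
  expect_true(all(diff(eff[1:10]) < 0))
})

test_that("zero scaling factor freezes evolution and the run hits the cap", {
  scen <- two_insecticide_scenario(beta = 1e-12)
  traj <- run_simulation(scen, strategy_config("sequence", cap = 40))
  expect_equal(traj$termination, "generation_cap")
  expect_true(all(traj$records$mean_prs[traj$records$site ==
                                          "intervention"] < 1e-6))
})

test_that("durations convert generations to years", {
  scen <- two_insecticide_scenario(beta = 1e-12)
  traj <- run_simulation(scen, strategy_config("sequence", cap = 500))
  expect_equal(simulation_duration(traj), 50)
  traj2 <- run_simulation(scen, strategy_config("sequence", cap = 100,
                                                generations_per_year = 10))
  expect_equal(simulation_duration(traj2), 10)
})

test_that("invalid branch and strategy combinations are rejected", {
  scen <- two_insecticide_scenario()
  expect_error(run_simulation(scen, strategy_config("sequence"),
                              branch = "polytruncate", cycles = "multi"),
               "polysmooth")
  expect_error(run_simulation(scen, strategy_config("micromosaic"),
                              branch = "polytruncate"),
               "monotherapy and mixture")
  expect_error(run_simulation(scen,
                              strategy_config("sequence",
                                              arsenal = c("i", "zzz"))),
               "missing")
})

test_that("both branches terminate a sequence run before the cap under
           calibrated selection", {
  for (branch in c("polysmooth", "polytruncate")) {
    beta <- calibrated_beta(branch)
    scen <- two_insecticide_scenario(beta = beta)
    traj <- run_simulation(scen, strategy_config("sequence"),
                           branch = branch)
    expect_equal(traj$termination, "no_insecticide_available")
    expect_lt(traj$duration_years, 50)
    expect_gt(traj$duration_years, 5)
  }
})

test_that("combination deployments keep independent product clocks", {
  scen <- scenario(
    insecticides = list(
      insecticide("itn", decay = decay_profile(1, 0.02, 0.05, 20)),
      insecticide("irs", decay = decay_profile(1, 0.05, 0.1, 5))),
    h2 = 0.2, beta = 5, landscape = landscape_params(0.7, 0.3),
    start_prs = 0, n_bins = 501)
  traj <- run_simulation(scen,
                         strategy_config("combination",
                                         interval = c(30, 10), cap = 60),
                         cycles = "multi")
  r <- traj$records
  itn <- r$efficacy[r$deployed & r$trait == "itn"]
  irs <- r$efficacy[r$deployed & r$trait == "irs"]
  # the IRS is re-applied every 10 generations, the ITN every 30
  expect_equal(which(irs == 1), c(1, 11, 21, 31, 41, 51))
  expect_equal(which(itn == 1), c(1, 31))
})

test_that("immediate withdrawal removes a failed insecticide mid-interval", {
  beta <- calibrated_beta()
  scen <- two_insecticide_scenario(beta = beta)
  lazy <- run_simulation(scen, strategy_config("sequence", interval = 60,
                                               cap = 300))
  eager <- run_simulation(scen, strategy_config("sequence", interval = 60,
                                                cap = 300,
                                                immediate_withdrawal = TRUE))
  swap <- function(traj) {
    dep <- traj$records[traj$records$deployed & traj$records$trait == "j", ]
    min(dep$generation)
  }
  # the lazy scheduler waits for the next 50-generation boundary; the eager
  # one switches as soon as the first insecticide fails
  expect_lt(swap(eager), swap(lazy))
  expect_equal(swap(lazy) %% 60, 1)
})
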