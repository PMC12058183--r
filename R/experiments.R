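# Experiments layer: exposure-factor calibration, Latin-hypercube parameter
# sweeps, strategy comparisons, model-agreement classification, sigma
# sensitivity and the feature-toggle showcase.

#' Operational parameter ranges for sweeps
#'
#' Named uniform ranges sampled by [lhs_sample()]. Defaults are the standard
#' operational space: coverage 0.1-0.9, dispersal 0.1-0.9, fitness cost
#' 0.04-0.58 (both sexes), female exposure 0.4-0.9, male exposure 0-1,
#' heritability 0.05-0.3.
#'
#' @param ... named length-2 numeric vectors `c(lower, upper)` overriding or
#'   extending the defaults.
#' @return Named list of ranges of class `parameter_ranges`.
#' @export
parameter_ranges <- function(...) {
  rg <- list(coverage = c(0.1, 0.9), dispersal = c(0.1, 0.9),
             cost_female = c(0.04, 0.58), cost_male = c(0.04, 0.58),
             exposure_female = c(0.4, 0.9), exposure_male = c(0, 1),
             h2 = c(0.05, 0.3))
  over <- list(...)
  for (nm in names(over)) rg[[nm]] <- over[[nm]]
  bad <- vapply(rg, function(r) length(r) != 2 || r[1] > r[2], logical(1))
  if (any(bad)) stop("each range must be c(lower, upper) with lower <= upper")
  structure(rg, class = "parameter_ranges")
}

#' Latin-hypercube sample of a parameter space
#'
#' Draws `n` parameter sets with each marginal stratified into `n` equal
#' probability bins and exactly one draw per bin, then rescales to the given
#' ranges. Reproducible under the seed.
#'
#' @param ranges a [parameter_ranges()] (or compatible named list).
#' @param n number of parameter sets.
#' @param seed integer seed.
#' @return Data frame with one column per range and `n` rows.
#' @export
lhs_sample <- function(ranges = parameter_ranges(), n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  u <- lhs::randomLHS(n, length(ranges))
  out <- as.data.frame(mapply(function(col, r) r[1] + (r[2] - r[1]) * col,
                              as.data.frame(u), ranges, SIMPLIFY = FALSE))
  names(out) <- names(ranges)
  out
}

# Scenario for one row of an LHS table (two symmetric undecayed
# insecticides, starting fully susceptible).
lhs_scenario <- function(row, alpha = 0, beta = 1, n_bins = 2001) {
  scenario(
    insecticides = list(insecticide("i"), insecticide("j")),
    h2 = row$h2, beta = beta,
    exposure = exposure_params(row$exposure_female, row$exposure_male),
    fitness_cost = fitness_cost("fixed", row$cost_female, row$cost_male),
    landscape = landscape_params(row$coverage, row$dispersal),
    alpha = alpha, start_prs = 0, n_bins = n_bins)
}

#' Calibrate the exposure scaling factor to a target resistance timescale
#'
#' A "novel" insecticide deployed continuously is conventionally expected to
#' last about ten years (100 generations at 10 per year) before the treated
#' population reaches the 10% bioassay-survival withdrawal threshold. This
#' routine bisects on `beta` until the first-crossing generation of that
#' reference scenario (fixed sigma, starting mean PRS 0, no decay, no
#' fitness costs, representative landscape) matches `target_generations` to
#' within one generation. Larger `beta` means stronger effective selection
#' and an earlier crossing, so the objective is monotone.
#'
#' @param target_generations target first-crossing generation (default 100).
#' @param exposure an [exposure_params()] (defaults `x = 0.7`, `m = 0.7`).
#' @param h2 heritability of the reference scenario (default 0.2).
#' @param sigma fixed PRS standard deviation (default 30).
#' @param landscape a [landscape_params()]; the default (coverage 0.7,
#'   dispersal 0.3) calibrates under the representative operational
#'   conditions the model is typically run with, so the calibrated factor
#'   already reflects the susceptible influx from the refugia.
#' @param branch model branch used for the reference simulation.
#' @param threshold bioassay-survival threshold (default 0.10).
#' @param bracket initial beta search bracket (expanded if needed).
#' @param n_bins grid size of the probabilistic branch.
#' @param max_iter bisection iterations.
#' @param average_over optional data frame with columns `exposure_female`,
#'   `exposure_male` and `h2` (e.g. from [lhs_sample()]): the calibration
#'   then targets the *mean* first-crossing generation over those parameter
#'   sets instead of the single representative scenario.
#' @return An object of class `calibration_result`: list with `beta`, the
#'   `achieved_generations` of the re-simulated crossing, `target_generations`
#'   and the scenario description.
#' @export
calibrate_beta <- function(target_generations = 100,
                           exposure = exposure_params(),
                           h2 = 0.2, sigma = 30,
                           landscape = landscape_params(),
                           branch = c("polysmooth", "polytruncate"),
                           threshold = 0.10, bracket = c(1e-3, 1e3),
                           n_bins = 2001, max_iter = 60,
                           average_over = NULL) {
  branch <- match.arg(branch)
  cap <- max(4 * target_generations, 200)
  crossing_one <- function(beta, ex, h2_one) {
    scen <- scenario(
      insecticides = list(insecticide("novel")),
      h2 = h2_one, beta = beta, exposure = ex,
      fitness_cost = fitness_cost("fixed", 0, 0),
      sigma = sigma_model("fixed", sigma),
      landscape = landscape, start_prs = 0, n_bins = n_bins)
    traj <- run_simulation(scen, strategy_config("continuous", cap = cap),
                           branch = branch)
    g <- threshold_crossing(traj, threshold)
    if (is.na(g)) Inf else g
  }
  crossing <- if (is.null(average_over)) {
    function(beta) crossing_one(beta, exposure, h2)
  } else {
    function(beta) mean(vapply(seq_len(nrow(average_over)), function(s) {
      row <- average_over[s, ]
      crossing_one(beta, exposure_params(row$exposure_female,
                                         row$exposure_male), row$h2)
    }, numeric(1)))
  }
  lo <- bracket[1]; hi <- bracket[2]
  g_lo <- crossing(lo); g_hi <- crossing(hi)
  expand <- 0
  while (g_lo < target_generations && expand < 10) {
    lo <- lo / 10; g_lo <- crossing(lo); expand <- expand + 1
  }
  while (g_hi > target_generations && expand < 20) {
    hi <- hi * 10; g_hi <- crossing(hi); expand <- expand + 1
  }
  if (g_lo < target_generations || g_hi > target_generations)
    stop(sprintf(paste0("calibration target unattainable: crossing at ",
                        "beta=%g is %s, at beta=%g is %s"),
                 lo, g_lo, hi, g_hi))
  beta <- hi; achieved <- g_hi
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    g_mid <- crossing(mid)
    if (abs(g_mid - target_generations) <= 1) { beta <- mid
      achieved <- g_mid
      break
    }
    if (g_mid > target_generations) lo <- mid else hi <- mid
    beta <- mid; achieved <- g_mid
  }
  if (abs(achieved - target_generations) > 1)
    stop("calibration failed to converge within the iteration budget")
  structure(list(beta = beta, achieved_generations = achieved,
                 target_generations = target_generations,
                 branch = branch,
                 scenario = sprintf(
                   "continuous monotherapy, x=%g, m=%g, h2=%g, sigma=%g",
                   exposure$x, exposure$m, h2, sigma)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> beta = %.6g\n", x$beta))
  cat(sprintf("  %s (%s)\n", x$scenario, x$branch))
  cat(sprintf("  crossing at generation %s (target %d)\n",
              format(x$achieved_generations), x$target_generations))
  invisible(x)
}

#' Head-to-head strategy comparison over a parameter sweep
#'
#' Runs each strategy on each parameter set (same scenario and seeds for all
#' strategies) and records operational lifespans and pairwise winners.
#' Runs in which both strategies hit the generation cap are draws but flagged
#' censored, since either could prove superior on a longer horizon.
#'
#' @param param_sets data frame from [lhs_sample()].
#' @param strategies named list of [strategy_config()] objects (at least 2).
#' @param alpha cross-resistance correlation between the two insecticides.
#' @param branch model branch.
#' @param beta calibrated exposure factor (see [calibrate_beta()]).
#' @param n_bins grid size of the probabilistic branch.
#' @return List with `durations` (set x strategy matrix of years) and
#'   `comparisons`, a data frame of pairwise outcomes (`set`, `pair`,
#'   `winner` in A/B/draw, `difference_years`, `censored`).
#' @export
compare_strategies <- function(param_sets,
                               strategies = list(
                                 sequence = strategy_config("sequence"),
                                 rotation = strategy_config("rotation"),
                                 mixture = strategy_config("mixture")),
                               alpha = 0,
                               branch = c("polysmooth", "polytruncate"),
                               beta = 1, n_bins = 2001) {
  branch <- match.arg(branch)
  stopifnot(length(strategies) >= 2, !is.null(names(strategies)))
  ns <- nrow(param_sets)
  dur <- matrix(NA_real_, ns, length(strategies),
                dimnames = list(NULL, names(strategies)))
  capped <- matrix(FALSE, ns, length(strategies),
                   dimnames = list(NULL, names(strategies)))
  for (s in seq_len(ns)) {
    scen <- lhs_scenario(param_sets[s, ], alpha = alpha, beta = beta,
                         n_bins = n_bins)
    for (st in names(strategies)) {
      traj <- run_simulation(scen, strategies[[st]], branch = branch)
      dur[s, st] <- simulation_duration(traj)
      capped[s, st] <- traj$termination == "generation_cap"
    }
  }
  pairs <- utils::combn(names(strategies), 2, simplify = FALSE)
  comparisons <- do.call(rbind, lapply(pairs, function(p) {
    dA <- dur[, p[1]]; dB <- dur[, p[2]]
    data.frame(set = seq_len(ns), pair = paste(p[1], "vs", p[2]),
               strategy_a = p[1], strategy_b = p[2],
               winner = ifelse(dA > dB, "A", ifelse(dB > dA, "B", "draw")),
               difference_years = dA - dB,
               censored = capped[, p[1]] & capped[, p[2]],
               stringsAsFactors = FALSE)
  }))
  list(durations = dur, comparisons = comparisons)
}

#' Classify agreement between two model branches' comparison outcomes
#'
#' @param winner_a,winner_b vectors of `"A"`, `"B"` or `"draw"` outcomes from
#'   the same parameter sets under the two branches.
#' @return Factor with levels `full_agreement` (same non-draw winner),
#'   `agreement` (draw in both), `partial_disagreement` (draw in exactly
#'   one) and `full_disagreement` (opposite winners).
#' @export
classify_agreement <- function(winner_a, winner_b) {
  stopifnot(length(winner_a) == length(winner_b))
  cls <- ifelse(winner_a == "draw" & winner_b == "draw", "agreement",
         ifelse(xor(winner_a == "draw", winner_b == "draw"),
                "partial_disagreement",
         ifelse(winner_a == winner_b, "full_agreement",
                "full_disagreement")))
  factor(cls, levels = c("full_agreement", "agreement",
                         "partial_disagreement", "full_disagreement"))
}

#' Time to the withdrawal threshold as a function of the PRS spread
#'
#' For each standard deviation and parameter set, deploys a single
#' insecticide continuously (full coverage, no dispersal, no fitness costs,
#' no decay) and records the generation at which the treated population first
#' reaches the bioassay-survival threshold, capped at `cap`.
#'
#' @param sigmas standard deviations to test (default 5 to 100 by 5).
#' @param param_sets data frame with columns `exposure_female`,
#'   `exposure_male`, `h2`.
#' @param branch model branch.
#' @param beta calibrated exposure factor.
#' @param threshold bioassay-survival threshold (default 0.10).
#' @param cap generation cap (default 500).
#' @param n_bins grid size.
#' @return Data frame with columns `sigma`, `set` and
#'   `generations_to_threshold`.
#' @export
sigma_sensitivity <- function(sigmas = seq(5, 100, by = 5), param_sets,
                              branch = c("polysmooth", "polytruncate"),
                              beta = 1, threshold = 0.10, cap = 500,
                              n_bins = 2001) {
  branch <- match.arg(branch)
  out <- expand.grid(sigma = sigmas, set = seq_len(nrow(param_sets)))
  out$generations_to_threshold <- NA_real_
  strat <- strategy_config("continuous", cap = cap)
  for (r in seq_len(nrow(out))) {
    row <- param_sets[out$set[r], ]
    scen <- scenario(
      insecticides = list(insecticide("i")),
      h2 = row$h2, beta = beta,
      exposure = exposure_params(row$exposure_female, row$exposure_male),
      fitness_cost = fitness_cost("fixed", 0, 0),
      sigma = sigma_model("fixed", out$sigma[r]),
      landscape = landscape_params(coverage = 1, dispersal = 0),
      start_prs = 0, n_bins = n_bins)
    g <- threshold_crossing(run_simulation(scen, strat, branch = branch),
                            threshold)
    out$generations_to_threshold[r] <- if (is.na(g)) cap else g
  }
  out
}

#' Feature-toggle showcase of strategy rankings
#'
#' Runs five deployment strategies (monotherapy sequence and rotation,
#' micro-mosaic, full-dose mixture, half-dose mixture) under every on/off
#' permutation of insecticide decay, cross resistance and multiple
#' gonotrophic cycles, and ranks them by the mean intervention-site bioassay
#' survival (averaged over both insecticides and the whole run, lower =
#' better).
#'
#' The fixed parameters are the package's showcase set: heritabilities
#' 0.2/0.25, exposure x = m = 0.7, fixed fitness-cost differentials 0.2 for
#' both sexes, coverage 0.7, dispersal 0.3, starting mean PRS 50; when
#' toggled on: cross resistance 0.3, five cycles, decay (0.015, 0.08,
#' threshold 20 generations).
#'
#' @param beta calibrated exposure factor.
#' @param horizon generations per run (default 60, two 30-generation
#'   deployment intervals).
#' @param interval deployment interval (default 30).
#' @param n_bins grid size.
#' @return Data frame with one row per permutation x strategy: toggle flags,
#'   `mean_bioassay` and within-permutation `rank` (1 = best).
#' @export
showcase_feature_toggles <- function(beta = 1, horizon = 60, interval = 30,
                                     n_bins = 2001) {
  toggles <- expand.grid(decay = c(FALSE, TRUE), cross = c(FALSE, TRUE),
                         multi = c(FALSE, TRUE))
  strategies <- list(
    sequence = strategy_config("sequence", interval = interval,
                               cap = horizon),
    rotation = strategy_config("rotation", interval = interval,
                               cap = horizon),
    micromosaic = strategy_config("micromosaic", interval = interval,
                                  cap = horizon),
    mixture_full = strategy_config("mixture", interval = interval,
                                   cap = horizon),
    mixture_half = strategy_config("mixture", interval = interval,
                                   cap = horizon,
                                   doses = c(i = 0.5, j = 0.5)))
  res <- list()
  for (t in seq_len(nrow(toggles))) {
    dec <- if (toggles$decay[t]) {
      decay_profile(omega0 = 1, delta_b = 0.015, delta_r = 0.08, tau_b = 20)
    } else decay_profile(omega0 = 1)
    scen <- scenario(
      insecticides = list(insecticide("i", decay = dec),
                          insecticide("j", decay = dec)),
      h2 = c(0.2, 0.25), beta = beta,
      exposure = exposure_params(0.7, 0.7),
      fitness_cost = fitness_cost("fixed", 0.2, 0.2),
      landscape = landscape_params(0.7, 0.3),
      alpha = if (toggles$cross[t]) 0.3 else 0,
      cycles = cycle_params(d = 0.9, g = 3, gmax = 5),
      start_prs = 50, n_bins = n_bins)
    cycles_mode <- if (toggles$multi[t]) "multi" else "single"
    mb <- vapply(names(strategies), function(st) {
      traj <- run_simulation(scen, strategies[[st]], branch = "polysmooth",
                             cycles = cycles_mode)
      r <- traj$records
      mean(r$bioassay_survival[r$site == "intervention"])
    }, numeric(1))
    res[[t]] <- data.frame(decay = toggles$decay[t],
                           cross_resistance = toggles$cross[t],
                           multi_cycle = toggles$multi[t],
                           strategy = names(strategies),
                           mean_bioassay = unname(mb),
                           rank = rank(mb, ties.method = "min"),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Rotation versus micro-mosaic under different cycle assumptions
#'
#' For each parameter set, deploys two insecticides either in rotation or as
#' an even micro-mosaic, with no withdrawal thresholds, and reports the mean
#' difference in intervention-site bioassay survival to the first insecticide
#' (mosaic minus rotation; positive values favour rotation). Comparing the
#' `"single"` mode against `"multi_mortality"` exposes the mosaic's
#' "temporal mixture" benefit, which only emerges with multiple cycles and
#' natural mortality.
#'
#' @param param_sets data frame from [lhs_sample()].
#' @param mode `"single"` (one cycle), `"multi"` (five cycles, no natural
#'   mortality) or `"multi_mortality"` (five 3-day cycles, daily survival
#'   0.8).
#' @param beta calibrated exposure factor.
#' @param horizon generations per run.
#' @param interval rotation interval (default 10).
#' @param n_bins grid size.
#' @return Numeric vector of per-set mean survival differences (mosaic minus
#'   rotation).
#' @export
rotation_vs_mosaic <- function(param_sets,
                               mode = c("single", "multi",
                                        "multi_mortality"),
                               beta = 1, horizon = 150, interval = 10,
                               n_bins = 2001) {
  mode <- match.arg(mode)
  cyc <- switch(mode,
                single = cycle_params(d = 1, g = 3, gmax = 1),
                multi = cycle_params(d = 1, g = 3, gmax = 5),
                multi_mortality = cycle_params(d = 0.8, g = 3, gmax = 5))
  cycles_mode <- if (mode == "single") "single" else "multi"
  strat_rot <- strategy_config("rotation", interval = interval,
                               cap = horizon, withdrawal = 1 - 1e-9,
                               return_threshold = 1 - 2e-9)
  strat_mos <- strategy_config("micromosaic", interval = interval,
                               cap = horizon, withdrawal = 1 - 1e-9,
                               return_threshold = 1 - 2e-9)
  vapply(seq_len(nrow(param_sets)), function(s) {
    row <- param_sets[s, ]
    scen <- lhs_scenario(row, alpha = 0, beta = beta, n_bins = n_bins)
    scen$cycles <- cyc
    surv <- function(strategy) {
      traj <- run_simulation(scen, strategy, branch = "polysmooth",
                             cycles = cycles_mode)
      r <- traj$records
      mean(r$bioassay_survival[r$site == "intervention" & r$trait == "i"])
    }
    surv(strat_mos) - surv(strat_rot)
  }, numeric(1))
}
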