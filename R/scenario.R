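# Scenario container bundling the full model configuration, YAML
# (de)serialisation and deterministic scenario fixtures.

#' Full simulation scenario
#'
#' Bundles the insecticide arsenal, genetics, exposure, fitness costs, sigma
#' model, landscape, cross resistance and cycle settings of a simulation.
#'
#' @param insecticides list of [insecticide()] objects with unique ids.
#' @param h2 per-trait heritabilities, recycled and named by insecticide id.
#' @param beta exposure scaling factor (see [calibrate_beta()]).
#' @param exposure an [exposure_params()].
#' @param fitness_cost a [fitness_cost()].
#' @param sigma a [sigma_model()].
#' @param landscape a [landscape_params()].
#' @param alpha a [cross_resistance()] matrix, or a single off-diagonal
#'   correlation.
#' @param cycles a [cycle_params()] (used by multi-cycle simulations).
#' @param start_prs starting mean PRS, recycled per trait (both sites).
#' @param n_bins PRS grid size for the probabilistic branch.
#' @param cal a [field_calibration()].
#' @param mean_survival_mode how population mean survival is evaluated:
#'   `"at_mean"` (default) or `"integrated"` (see [mean_survival()]).
#' @param dispersal_mode passed to [disperse()].
#' @param per_cycle_dispersal logical; if `TRUE`, multi-cycle simulations mix
#'   the female cohorts between sites after every cycle (a reconstructed
#'   extension, see the methods vignette). Default `FALSE`: dispersal happens
#'   once per generation, after mating.
#' @param beta_scales_costs logical; if `FALSE` (default) the exposure
#'   scaling factor `beta` rescales only the insecticide-selection component
#'   of the response — the fitness-cost differentials are specified directly
#'   on the PRS scale and enter unscaled. If `TRUE`, `beta` multiplies the
#'   summed differential.
#' @return An object of class `irm_scenario`.
#' @export
scenario <- function(insecticides = list(insecticide("i"), insecticide("j")),
                     h2 = 0.2, beta = 1,
                     exposure = exposure_params(),
                     fitness_cost = irmsim::fitness_cost(),
                     sigma = sigma_model(),
                     landscape = landscape_params(),
                     alpha = 0,
                     cycles = cycle_params(),
                     start_prs = 0,
                     n_bins = 2001,
                     cal = field_calibration(),
                     mean_survival_mode = c("at_mean", "integrated"),
                     dispersal_mode = c("conserving", "literal", "normalised"),
                     per_cycle_dispersal = FALSE,
                     beta_scales_costs = FALSE) {
  if (inherits(insecticides, "insecticide")) insecticides <- list(insecticides)
  ids <- vapply(insecticides, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("insecticide ids must be unique")
  names(insecticides) <- ids
  if (!is.matrix(alpha)) alpha <- cross_resistance(ids, offdiag = alpha)
  stopifnot(all(h2 >= 0), all(h2 <= 1), beta > 0)
  structure(list(
    insecticides = insecticides, ids = ids,
    h2 = setNames(rep_len(h2, length(ids)), ids), beta = beta,
    exposure = exposure, fitness_cost = fitness_cost, sigma = sigma,
    landscape = landscape, alpha = alpha, cycles = cycles,
    start_prs = setNames(rep_len(start_prs, length(ids)), ids),
    n_bins = n_bins, cal = cal,
    mean_survival_mode = match.arg(mean_survival_mode),
    dispersal_mode = match.arg(dispersal_mode),
    per_cycle_dispersal = isTRUE(per_cycle_dispersal),
    beta_scales_costs = isTRUE(beta_scales_costs)),
    class = "irm_scenario")
}

#' @export
print.irm_scenario <- function(x, ...) {
  cat(sprintf("<irm_scenario> %d insecticide(s): %s\n", length(x$ids),
              paste(x$ids, collapse = ", ")))
  cat(sprintf("  h2 = %s, beta = %g; x = %g, m = %g\n",
              paste(signif(x$h2, 3), collapse = "/"), x$beta,
              x$exposure$x, x$exposure$m))
  cat(sprintf("  sigma: %s; coverage C = %g, dispersal theta = %g\n",
              x$sigma$mode, x$landscape$coverage, x$landscape$dispersal))
  invisible(x)
}

#' Deployment strategy configuration
#'
#' Rules for which insecticides are deployed over time. Decisions are taken
#' at deployment-interval boundaries, using the intervention-site female mean
#' converted to bioassay survival: an insecticide at or above the withdrawal
#' threshold is failed; a failed insecticide becomes eligible again only
#' below the return threshold (hysteresis).
#'
#' @param kind one of `"sequence"`, `"rotation"`, `"mixture"`,
#'   `"micromosaic"`, `"combination"` or `"continuous"` (deploy the first
#'   insecticide for ever, ignoring thresholds — used for calibration and
#'   sensitivity runs).
#' @param arsenal ordered insecticide ids; defaults to the scenario's
#'   arsenal. Mixtures, mosaics and combinations use the first two.
#' @param withdrawal bioassay-survival withdrawal threshold (default 0.10).
#' @param return_threshold bioassay-survival return threshold (default 0.08,
#'   must be below `withdrawal`).
#' @param interval deployment interval in generations; for `"combination"` a
#'   length-2 vector gives the ITN and IRS products independent redeployment
#'   clocks.
#' @param cap maximum simulated generations (default 500).
#' @param generations_per_year generations per calendar year (default 10).
#' @param coverage optional [coverage_model()] for mosaics and combinations
#'   (defaults to an even 50/50 mosaic split, or an even combination split).
#' @param doses per-product initial efficacy overrides (named), e.g.
#'   `c(i = 0.5, j = 0.5)` for a half-dose mixture.
#' @param immediate_withdrawal logical; by default an insecticide crossing
#'   the withdrawal threshold between decision points stays deployed until
#'   the next interval boundary. If `TRUE`, a deployed insecticide is
#'   withdrawn (and the deployment re-planned) in the generation it
#'   crosses the threshold.
#' @return An object of class `strategy_config`.
#' @export
strategy_config <- function(kind = c("sequence", "rotation", "mixture",
                                     "micromosaic", "combination",
                                     "continuous"),
                            arsenal = NULL, withdrawal = 0.10,
                            return_threshold = 0.08, interval = 10,
                            cap = 500, generations_per_year = 10,
                            coverage = NULL, doses = NULL,
                            immediate_withdrawal = FALSE) {
  kind <- match.arg(kind)
  stopifnot(return_threshold < withdrawal, all(interval >= 1), cap >= 1,
            generations_per_year >= 1)
  if (kind == "combination") {
    interval <- rep_len(interval, 2)
  } else {
    interval <- interval[[1]]
  }
  if (is.null(coverage)) {
    coverage <- switch(kind,
      micromosaic = coverage_model(c_i = 0.5, c_j = 0.5, c_ij = 0),
      combination = coverage_model(c_i = 0.25, c_j = 0.25, c_ij = 0.5),
      NULL)
  }
  structure(list(kind = kind, arsenal = arsenal, withdrawal = withdrawal,
                 return_threshold = return_threshold, interval = interval,
                 cap = cap, generations_per_year = generations_per_year,
                 coverage = coverage, doses = doses,
                 immediate_withdrawal = isTRUE(immediate_withdrawal)),
            class = "strategy_config")
}

# ---- YAML configuration files -------------------------------------------

as_config_list <- function(scen, strategy = NULL) {
  ins <- lapply(scen$insecticides, function(p) {
    list(id = p$id,
         z50 = p$scale$z50, kmax = p$scale$kmax, n = p$scale$n,
         omega0 = p$decay$omega0, delta_b = p$decay$delta_b,
         delta_r = p$decay$delta_r, tau_b = p$decay$tau_b,
         decay_exponent = p$decay$exponent)
  })
  out <- list(
    insecticides = unname(ins),
    genetics = list(h2 = as.list(scen$h2), beta = scen$beta),
    exposure = list(x = scen$exposure$x, m = scen$exposure$m),
    fitness_cost = unclass(scen$fitness_cost),
    sigma = unclass(scen$sigma),
    landscape = list(coverage = scen$landscape$coverage,
                     dispersal = scen$landscape$dispersal),
    alpha = apply(unclass(scen$alpha), 1, as.list, simplify = FALSE),
    cycles = list(d = scen$cycles$d, g = scen$cycles$g,
                  gmax = scen$cycles$gmax),
    start_prs = as.list(scen$start_prs),
    n_bins = scen$n_bins,
    calibration = list(phi1 = scen$cal$phi1, phi2 = scen$cal$phi2),
    options = list(mean_survival_mode = scen$mean_survival_mode,
                   dispersal_mode = scen$dispersal_mode,
                   per_cycle_dispersal = scen$per_cycle_dispersal,
                   beta_scales_costs = scen$beta_scales_costs))
  if (!is.null(strategy)) {
    st <- unclass(strategy)
    if (!is.null(st$coverage)) {
      cv <- st$coverage
      st$coverage <- list(c_i = cv$c_i, c_j = cv$c_j, c_ij = cv$c_ij,
                          lambda_female = as.list(cv$lambda_female),
                          lambda_male = as.list(cv$lambda_male))
    }
    if (!is.null(st$doses)) st$doses <- as.list(st$doses)
    out$strategy <- st
  }
  out
}

#' Write a scenario (and optional strategy) to a YAML configuration file
#'
#' @param scen an [scenario()].
#' @param path output file path.
#' @param strategy optional [strategy_config()].
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scen, path, strategy = NULL) {
  yaml::write_yaml(as_config_list(scen, strategy), path, precision = 12)
  invisible(path)
}

#' Read a scenario (and optional strategy) from a YAML configuration file
#'
#' @param path path to a YAML file written by [write_scenario()] or
#'   hand-authored with the same keys (`z50`, `omega0`, `delta_b`, ...).
#' @return List with elements `scenario` and (if present in the file)
#'   `strategy`.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  ins <- lapply(cfg$insecticides, function(p) {
    insecticide(p$id,
                scale = hill_scale(z50 = p$z50 %||% 900,
                                   kmax = p$kmax %||% 1, n = p$n %||% 1),
                decay = decay_profile(omega0 = p$omega0 %||% 1,
                                      delta_b = p$delta_b %||% 0,
                                      delta_r = p$delta_r %||% 0,
                                      tau_b = p$tau_b %||% 0,
                                      exponent = p$decay_exponent %||% 1))
  })
  ids <- vapply(ins, `[[`, character(1), "id")
  al <- cfg$alpha
  alpha <- if (is.null(al)) 0 else {
    m <- do.call(rbind, lapply(al, function(r) unlist(r[ids])))
    cross_resistance(ids, matrix = m)
  }
  opts <- cfg$options %||% list()
  scen <- scenario(
    insecticides = ins,
    h2 = unlist(cfg$genetics$h2)[ids],
    beta = cfg$genetics$beta %||% 1,
    exposure = exposure_params(cfg$exposure$x %||% 0.7,
                               cfg$exposure$m %||% 0.7),
    fitness_cost = fitness_cost(cfg$fitness_cost$mode %||% "fixed",
                                cfg$fitness_cost$female %||% 0,
                                cfg$fitness_cost$male %||% 0),
    sigma = sigma_model(cfg$sigma$mode %||% "fixed",
                        sigma = cfg$sigma$sigma %||% 30,
                        phi3 = cfg$sigma$phi3 %||% 0.1,
                        phi4 = cfg$sigma$phi4 %||% 20),
    landscape = landscape_params(cfg$landscape$coverage %||% 0.7,
                                 cfg$landscape$dispersal %||% 0.3),
    alpha = alpha,
    cycles = cycle_params(cfg$cycles$d %||% 1, cfg$cycles$g %||% 3,
                          cfg$cycles$gmax %||% 5),
    start_prs = unlist(cfg$start_prs)[ids] %||% 0,
    n_bins = cfg$n_bins %||% 2001,
    cal = field_calibration(cfg$calibration$phi1 %||% 0.48,
                            cfg$calibration$phi2 %||% 0.15),
    mean_survival_mode = opts$mean_survival_mode %||% "at_mean",
    dispersal_mode = opts$dispersal_mode %||% "conserving",
    per_cycle_dispersal = opts$per_cycle_dispersal %||% FALSE,
    beta_scales_costs = opts$beta_scales_costs %||% FALSE)
  out <- list(scenario = scen)
  if (!is.null(cfg$strategy)) {
    st <- cfg$strategy
    cov <- if (!is.null(st$coverage)) {
      coverage_model(st$coverage$c_i, st$coverage$c_j, st$coverage$c_ij,
                     lambda_female = unlist(st$coverage$lambda_female),
                     lambda_male = unlist(st$coverage$lambda_male))
    } else NULL
    out$strategy <- strategy_config(
      kind = st$kind, arsenal = st$arsenal %||% NULL,
      withdrawal = st$withdrawal %||% 0.10,
      return_threshold = st$return_threshold %||% 0.08,
      interval = unlist(st$interval) %||% 10,
      cap = st$cap %||% 500,
      generations_per_year = st$generations_per_year %||% 10,
      coverage = cov,
      doses = if (!is.null(st$doses)) unlist(st$doses) else NULL)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic scenario fixture
#'
#' Generates a fully valid scenario-plus-strategy pair from a seed, used in
#' tests, examples and documentation. Parameters are drawn from the package's
#' standard operational ranges (coverage 0.1-0.9, dispersal 0.1-0.9, fitness
#' cost 0.04-0.58, female exposure 0.4-0.9, male exposure 0-1, heritability
#' 0.05-0.3).
#'
#' @param seed integer seed; the same seed always yields the same config.
#' @param template one of `"monotherapy"`, `"mixture"`, `"mosaic"`,
#'   `"combination"`.
#' @param reduced_dose logical; for mixtures, deploy both partners below the
#'   recommended monotherapy dose (`omega0 = 0.5`).
#' @return List with elements `scenario` and `strategy`.
#' @export
scenario_fixture <- function(seed, template = c("monotherapy", "mixture",
                                                "mosaic", "combination"),
                             reduced_dose = FALSE) {
  template <- match.arg(template)
  set.seed(seed)
  runif_in <- function(lo, hi) lo + (hi - lo) * stats::runif(1)
  omega0 <- if (reduced_dose) 0.5 else 1
  ins <- list(
    insecticide("i", decay = decay_profile(omega0 = omega0)),
    insecticide("j", decay = decay_profile(omega0 = omega0)))
  scen <- scenario(
    insecticides = ins,
    h2 = runif_in(0.05, 0.3), beta = 1,
    exposure = exposure_params(runif_in(0.4, 0.9), runif_in(0, 1)),
    fitness_cost = fitness_cost("fixed", runif_in(0.04, 0.58),
                                runif_in(0.04, 0.58)),
    landscape = landscape_params(runif_in(0.1, 0.9), runif_in(0.1, 0.9)),
    alpha = sample(seq(-0.3, 0.3, by = 0.1), 1),
    start_prs = 0)
  strat <- switch(template,
    monotherapy = strategy_config("sequence"),
    mixture = strategy_config("mixture",
                              doses = c(i = omega0, j = omega0)),
    mosaic = strategy_config("micromosaic"),
    combination = strategy_config("combination", interval = c(30, 10)))
  list(scenario = scen, strategy = strat)
}
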