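# Strategy engine: deployment scheduling under withdrawal/return
# thresholds, the per-generation simulation loop for both model branches,
# and trajectory scoring.

#' Plan the next deployment at a decision point
#'
#' Applies the strategy rules at a deployment-interval boundary, given the
#' current failed/eligible status of each insecticide. `failed` must already
#' reflect the hysteresis rule (an insecticide fails at or above the
#' withdrawal threshold and becomes eligible again only below the return
#' threshold); [run_simulation()] maintains it via the thresholds in the
#' [strategy_config()].
#'
#' @param strategy a [strategy_config()].
#' @param failed named logical vector over the arsenal (TRUE = currently
#'   failed).
#' @param current id(s) of the currently deployed insecticide(s), or `NULL`
#'   at the first deployment.
#' @return A deployment list (`products`, `structure` = one of "mono",
#'   "mixture", "coverage", and `coverage` where relevant), or `NULL` when no
#'   insecticide is available (the no-option signal).
#' @export
plan_deployment <- function(strategy, failed, current = NULL) {
  arsenal <- strategy$arsenal
  if (length(arsenal) == 0) stop("empty arsenal")
  ok <- !failed[arsenal]
  switch(strategy$kind,
    continuous = list(products = arsenal[[1]], structure = "mono"),
    sequence = {
      if (!is.null(current) && ok[current[[1]]]) {
        list(products = current[[1]], structure = "mono")
      } else if (any(ok)) {
        list(products = arsenal[which(ok)[1]], structure = "mono")
      } else NULL
    },
    rotation = {
      n <- length(arsenal)
      start <- if (is.null(current)) 0 else match(current[[1]], arsenal)
      pick <- NULL
      for (step in seq_len(n)) {
        cand <- arsenal[((start + step - 1) %% n) + 1]
        if (ok[cand]) { pick <- cand; break }
      }
      if (is.null(pick)) NULL else list(products = pick, structure = "mono")
    },
    mixture = {
      pair <- arsenal[1:2]
      if (all(ok[pair])) list(products = pair, structure = "mixture")
      else NULL
    },
    micromosaic = {
      pair <- arsenal[1:2]
      if (all(ok[pair]))
        list(products = pair, structure = "coverage",
             coverage = strategy$coverage)
      else NULL
    },
    combination = {
      pair <- arsenal[1:2]
      act <- pair[ok[pair]]
      if (length(act) == 2)
        list(products = pair, structure = "coverage",
             coverage = strategy$coverage)
      else if (length(act) == 1)
        list(products = act, structure = "mono")
      else NULL
    })
}

# Selection differentials and responses for one generation.
# Returns named response vectors for both sites; deployed traits carry
# R^{S+cost}, undeployed traits and all refugia traits carry the cost-only
# response.
generation_responses <- function(scen, z_int, z_ref, deployment, omegas,
                                 branch, cycles_mode) {
  ids <- scen$ids
  sig_int <- setNames(sigma_of_mean(z_int, scen$sigma), ids)
  sig_ref <- setNames(sigma_of_mean(z_ref, scen$sigma), ids)
  sc <- scen$beta_scales_costs
  R_int <- R_ref <- setNames(numeric(length(ids)), ids)
  for (id in ids) {
    gen_par <- genetics_params(scen$h2[[id]], scen$beta)
    cost_ref <- fitness_cost_differential(scen$fitness_cost, sig_ref[[id]])
    R_ref[[id]] <- compose_response(0, 0, cost_ref[["female"]],
                                    cost_ref[["male"]], gen_par, sc)
    cost_int <- fitness_cost_differential(scen$fitness_cost, sig_int[[id]])
    R_int[[id]] <- compose_response(0, 0, cost_int[["female"]],
                                    cost_int[["male"]], gen_par, sc)
  }
  products <- deployment$products
  for (id in products) {
    partner <- setdiff(products, id)
    partner <- if (length(partner)) partner[[1]] else NULL
    gen_par <- genetics_params(scen$h2[[id]], scen$beta)
    cost_int <- fitness_cost_differential(scen$fitness_cost, sig_int[[id]])
    Kbar_j <- if (!is.null(partner)) {
      mean_survival(z_int[[partner]], scen$insecticides[[partner]],
                    omegas[[partner]], scen$cal,
                    mode = scen$mean_survival_mode,
                    sigma = sig_int[[partner]])
    } else 1
    R <- tryCatch({
      if (branch == "polytruncate") {
        Kbar_i <- mean_survival(z_int[[id]], scen$insecticides[[id]],
                                omegas[[id]], scen$cal,
                                mode = scen$mean_survival_mode,
                                sigma = sig_int[[id]])
        part <- truncation_selection(
          z_int[[id]], sig_int[[id]], Kbar_i, scen$exposure,
          partner_survival = if (!is.null(partner)) Kbar_j else NULL)
        out <- parental_pool(part, z_int[[id]], scen$exposure)
        S <- out$S_insecticide
        compose_response(S[["female"]], S[["male"]], cost_int[["female"]],
                         cost_int[["male"]], gen_par, sc)
      } else if (cycles_mode == "single" &&
                 deployment$structure %in% c("mono", "mixture")) {
        dist <- hatch_distribution(z_int[[id]], sig_int[[id]], scen$n_bins)
        K <- survival_on_grid(dist$grid, scen$insecticides[[id]],
                              omegas[[id]], scen$cal)
        part <- probabilistic_selection(
          dist, K, scen$exposure,
          partner_survival = if (!is.null(partner)) Kbar_j else NULL)
        out <- parental_pool(part, z_int[[id]], scen$exposure)
        S <- out$S_insecticide
        compose_response(S[["female"]], S[["male"]], cost_int[["female"]],
                         cost_int[["male"]], gen_par, sc)
      } else if (scen$per_cycle_dispersal && cycles_mode == "multi") {
        # reconstructed mode: females disperse between sites every cycle
        cov <- deployment_coverage(deployment, id, products)
        sigs <- c(sig_int[[id]], sig_ref[[id]])
        grid <- seq(min(z_int[[id]], z_ref[[id]]) - 6 * max(sigs),
                    max(z_int[[id]], z_ref[[id]]) + 6 * max(sigs),
                    length.out = scen$n_bins)
        C <- scen$landscape$coverage
        w_int <- dnorm(grid, z_int[[id]], sig_int[[id]])
        w_ref <- dnorm(grid, z_ref[[id]], sig_ref[[id]])
        F_int <- w_int / sum(w_int) * C / 2
        F_ref <- w_ref / sum(w_ref) * (1 - C) / 2
        K_i <- survival_on_grid(grid, scen$insecticides[[id]],
                                omegas[[id]], scen$cal)
        two <- run_two_site_cycles(grid, F_int, F_ref, K_i, Kbar_j, cov,
                                   scen$exposure$x, rho = scen$cycles$rho,
                                   gmax = scen$cycles$gmax,
                                   theta = scen$landscape$dispersal, C = C)
        dist_int <- trait_distribution(grid, F_int, F_int)
        male <- male_selection_complex(dist_int, K_i, Kbar_j, cov,
                                       scen$exposure)
        cost_ref <- fitness_cost_differential(scen$fitness_cost,
                                              sig_ref[[id]])
        R_ref[[id]] <- multi_cycle_response(
          two$z_parent_ref, two$n_parent_ref, two$z0_ref, 0, gen_par,
          S_cost_female = cost_ref[["female"]],
          S_cost_male = cost_ref[["male"]],
          beta_scales_costs = sc)$R_total
        multi_cycle_response(two$z_parent_int, two$n_parent_int, two$z0_int,
                             male$S_insecticide, gen_par,
                             S_cost_female = cost_int[["female"]],
                             S_cost_male = cost_int[["male"]],
                             beta_scales_costs = sc)$R_total
      } else {
        # general coverage structure and/or multiple gonotrophic cycles
        cov <- deployment_coverage(deployment, id, products)
        gmax <- if (cycles_mode == "multi") scen$cycles$gmax else 1
        rho <- if (cycles_mode == "multi") scen$cycles$rho else 1
        dist <- hatch_distribution(z_int[[id]], sig_int[[id]], scen$n_bins)
        K_i <- survival_on_grid(dist$grid, scen$insecticides[[id]],
                                omegas[[id]], scen$cal)
        fem <- run_female_cycles(dist, K_i, Kbar_j, cov, scen$exposure$x,
                                 rho = rho, gmax = gmax)
        if (fem$extinct && length(fem$n_parent) == 0)
          stop("degenerate cohort: no surviving females")
        male <- male_selection_complex(dist, K_i, Kbar_j, cov, scen$exposure)
        multi_cycle_response(fem$z_parent, fem$n_parent, fem$z0,
                             male$S_insecticide, gen_par,
                             S_cost_female = cost_int[["female"]],
                             S_cost_male = cost_int[["male"]],
                             beta_scales_costs = sc)$R_total
      }
    }, error = function(e) {
      warning(sprintf("trait %s: %s; treating generation as unexposed-only",
                      id, conditionMessage(e)), call. = FALSE)
      compose_response(0, 0, cost_int[["female"]], cost_int[["male"]],
                       gen_par, sc)
    })
    R_int[[id]] <- R
  }
  list(R_int = R_int, R_ref = R_ref, sigma_int = sig_int,
       sigma_ref = sig_ref)
}

# Coverage model for the focal product: product listed first in the
# deployment is "i". For the second product the roles of i and j swap.
deployment_coverage <- function(deployment, id, products) {
  base <- switch(deployment$structure,
    mono = coverage_model(c_i = 1),
    mixture = coverage_model(c_i = 0, c_j = 0, c_ij = 1,
                             lambda_female = c(i = 0, j = 0, ij = 1)),
    coverage = deployment$coverage)
  if (length(products) < 2 || id == products[[1]]) return(base)
  coverage_model(c_i = base$c_j, c_j = base$c_i, c_ij = base$c_ij,
                 lambda_female = c(i = base$lambda_female[["j"]],
                                   j = base$lambda_female[["i"]],
                                   ij = base$lambda_female[["ij"]]),
                 lambda_male = c(i = base$lambda_male[["j"]],
                                 j = base$lambda_male[["i"]],
                                 ij = base$lambda_male[["ij"]]))
}

#' Run an insecticide-resistance management simulation
#'
#' Advances the two-patch model generation by generation. Each generation:
#' deployment decisions are taken at interval boundaries (before selection,
#' from the intervention-site mean converted to bioassay survival);
#' insecticide efficacies are evaluated from the generations-since-deployment
#' clocks; selection differentials are computed per the chosen branch;
#' fitness costs are added; responses update both sites with cross
#' resistance; females disperse; clocks advance. The run stops when no
#' insecticide is available at a decision point or at the generation cap.
#'
#' @param scen an [scenario()].
#' @param strategy a [strategy_config()].
#' @param branch `"polysmooth"` (probabilistic selection, default) or
#'   `"polytruncate"` (truncation selection).
#' @param cycles `"single"` (one gonotrophic cycle per generation) or
#'   `"multi"` (polysmooth only; uses the scenario's [cycle_params()]).
#' @return An `irm_trajectory`: a list with the per-generation `records` data
#'   frame (generation, trait, site, mean_prs, bioassay_survival, deployed,
#'   efficacy), `termination` reason, `duration_generations`,
#'   `duration_years` and per-insecticide `failure_generation`.
#' @export
run_simulation <- function(scen, strategy, branch = c("polysmooth",
                                                      "polytruncate"),
                           cycles = c("single", "multi")) {
  branch <- match.arg(branch)
  cycles <- match.arg(cycles)
  if (branch == "polytruncate" && cycles == "multi")
    stop("multiple gonotrophic cycles are only defined for polysmooth")
  if (branch == "polytruncate" &&
      strategy$kind %in% c("micromosaic", "combination"))
    stop("polytruncate supports monotherapy and mixture deployments only")
  if (is.null(strategy$arsenal)) strategy$arsenal <- scen$ids
  if (!all(strategy$arsenal %in% scen$ids))
    stop("strategy arsenal names an insecticide missing from the scenario")
  ids <- scen$ids
  z_int <- z_ref <- scen$start_prs
  failed <- setNames(rep(FALSE, length(ids)), ids)
  failure_gen <- setNames(rep(NA_real_, length(ids)), ids)
  tau <- setNames(rep(0, length(ids)), ids)
  current <- NULL
  active <- character(0)
  termination <- "generation_cap"
  duration <- strategy$cap
  n_ids <- length(ids)
  Z_int <- Z_ref <- matrix(NA_real_, strategy$cap, n_ids,
                           dimnames = list(NULL, ids))
  DEP <- matrix(FALSE, strategy$cap, n_ids, dimnames = list(NULL, ids))
  EFF <- matrix(NA_real_, strategy$cap, n_ids, dimnames = list(NULL, ids))
  k <- 0
  intervals <- if (strategy$kind == "combination") {
    setNames(strategy$interval, strategy$arsenal[1:2])
  } else NULL
  for (gen in 0:(strategy$cap - 1)) {
    decision <- if (strategy$kind == "combination") {
      any(gen %% intervals == 0)
    } else {
      gen %% strategy$interval == 0
    }
    if (!decision && strategy$immediate_withdrawal &&
        length(current$products)) {
      kb_now <- vapply(current$products, function(i)
        bioassay_survival(z_int[[i]], scen$insecticides[[i]]$scale),
        numeric(1))
      decision <- any(kb_now >= strategy$withdrawal)
    }
    if (decision) {
      kb <- vapply(ids, function(i)
        bioassay_survival(z_int[[i]], scen$insecticides[[i]]$scale),
        numeric(1))
      newly <- !failed & kb >= strategy$withdrawal
      failure_gen[newly & is.na(failure_gen)] <- gen
      failed[newly] <- TRUE
      failed[failed & kb < strategy$return_threshold] <- FALSE
      if (strategy$kind == "combination") {
        # each product is (re)assessed only at its own boundary
        due <- names(intervals)[gen %% intervals == 0]
        for (p in due) {
          if (failed[[p]]) active <- setdiff(active, p)
          else { active <- union(active, p); tau[[p]] <- 0 }
        }
        current <- if (length(active) == 0) NULL
          else if (length(active) == 2)
            list(products = strategy$arsenal[1:2], structure = "coverage",
                 coverage = strategy$coverage)
          else list(products = active, structure = "mono")
      } else {
        current <- plan_deployment(strategy, failed,
                                   current = current$products)
        if (!is.null(current)) tau[current$products] <- 0
      }
      if (is.null(current)) {
        termination <- "no_insecticide_available"
        duration <- gen
        break
      }
    }
    omegas <- vapply(current$products, function(p) {
      dec <- scen$insecticides[[p]]$decay
      if (!is.null(strategy$doses) && p %in% names(strategy$doses)) {
        dec$omega0 <- strategy$doses[[p]]
      }
      efficacy_at(tau[[p]], dec)
    }, numeric(1))
    resp <- generation_responses(scen, z_int, z_ref, current, omegas,
                                 branch, cycles)
    z_int <- apply_responses_core(z_int, resp$R_int, current$products,
                                  scen$alpha, ids)
    z_ref <- apply_responses_core(z_ref, resp$R_ref, character(0),
                                  scen$alpha, ids)
    if (!(scen$per_cycle_dispersal && cycles == "multi")) {
      # per-cycle dispersal already mixes the sites within the generation
      d <- disperse(z_int, z_ref, scen$landscape, scen$dispersal_mode)
      z_int <- d$intervention
      z_ref <- d$refugia
    }
    tau[current$products] <- tau[current$products] + 1
    k <- gen + 1
    Z_int[k, ] <- z_int
    Z_ref[k, ] <- z_ref
    DEP[k, current$products] <- TRUE
    EFF[k, current$products] <- omegas
  }
  g <- seq_len(k)
  records <- data.frame(
    generation = rep(g, times = 2 * n_ids),
    trait = rep(rep(ids, each = k), times = 2),
    site = rep(c("intervention", "refugia"), each = k * n_ids),
    mean_prs = c(Z_int[g, ], Z_ref[g, ]),
    deployed = c(DEP[g, ], matrix(FALSE, k, n_ids)),
    efficacy = c(EFF[g, ], matrix(NA_real_, k, n_ids)),
    stringsAsFactors = FALSE)
  records$bioassay_survival <- NA_real_
  for (id in ids) {
    idx <- records$trait == id
    records$bioassay_survival[idx] <-
      bioassay_survival(records$mean_prs[idx], scen$insecticides[[id]]$scale)
  }
  structure(list(records = records, termination = termination,
                 duration_generations = duration,
                 duration_years = duration / strategy$generations_per_year,
                 failure_generation = failure_gen,
                 strategy = strategy$kind, branch = branch, cycles = cycles),
            class = "irm_trajectory")
}

#' @export
print.irm_trajectory <- function(x, ...) {
  cat(sprintf("<irm_trajectory> %s / %s / %s cycles\n", x$strategy, x$branch,
              x$cycles))
  cat(sprintf("  %s after %d generations (%.1f years)\n", x$termination,
              x$duration_generations, x$duration_years))
  invisible(x)
}

#' @export
as.data.frame.irm_trajectory <- function(x, ...) x$records

#' Operational lifespan of a simulated strategy
#'
#' @param traj an `irm_trajectory` from [run_simulation()].
#' @return Duration in years (generations elapsed divided by the strategy's
#'   generations per year).
#' @export
simulation_duration <- function(traj) traj$duration_years

#' First generation at which a trait reaches a bioassay-survival threshold
#'
#' @param traj an `irm_trajectory`.
#' @param threshold bioassay-survival level (default the 10% withdrawal
#'   criterion).
#' @param trait trait id (default the first recorded).
#' @param site site to inspect (default the intervention site).
#' @return Generation index of the first crossing, or `NA` if never reached.
#' @export
threshold_crossing <- function(traj, threshold = 0.10, trait = NULL,
                               site = "intervention") {
  r <- traj$records
  if (is.null(trait)) trait <- r$trait[1]
  r <- r[r$trait == trait & r$site == site, ]
  hit <- which(r$bioassay_survival >= threshold)
  if (length(hit) == 0) NA_real_ else r$generation[hit[1]]
}
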