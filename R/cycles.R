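# Multiple gonotrophic cycles for the probabilistic branch: coverage and
# encounter partitioning, natural survival, per-cycle selection, cycle-
# weighted responses and mosquito age profiles.

#' Household coverage and within-house encounter model
#'
#' For deployments of two products i and j, `c_i`, `c_j` and `c_ij` are the
#' proportions of treated houses carrying only i, only j, or both (summing to
#' 1). Within dual-treated houses, a mosquito encounters i only, j only, or
#' both with the sex-specific probabilities `lambda = c(i, j, ij)` (each sex's
#' lambda summing to 1); mosquitoes contacting both are treated as
#' encountering a mixture. `c_i = 1` is de facto a monotherapy; `c_ij = 1`
#' with `lambda["ij"] = 1` is de facto a mixture; `c_ij = 0` is a
#' micro-mosaic.
#'
#' @param c_i,c_j,c_ij house-coverage proportions, summing to 1.
#' @param lambda_female,lambda_male named encounter probabilities
#'   `c(i = , j = , ij = )` within dual-treated houses, each summing to 1.
#' @return An object of class `coverage_model`.
#' @export
coverage_model <- function(c_i = 1, c_j = 0, c_ij = 0,
                           lambda_female = c(i = 1 / 3, j = 1 / 3, ij = 1 / 3),
                           lambda_male = lambda_female) {
  chk_simplex <- function(v, what) {
    # tolerance accommodates round-tripping through text configs
    if (any(v < 0) || abs(sum(v) - 1) > 1e-6)
      stop(sprintf("%s must be non-negative and sum to 1", what))
    v / sum(v)
  }
  cv <- chk_simplex(c(c_i, c_j, c_ij), "house coverages c_i, c_j, c_ij")
  c_i <- cv[1]; c_j <- cv[2]; c_ij <- cv[3]
  lambda_female <- lambda_female[c("i", "j", "ij")]
  lambda_male <- lambda_male[c("i", "j", "ij")]
  if (c_ij > 0) {
    lambda_female <- chk_simplex(lambda_female, "female encounter split")
    lambda_male <- chk_simplex(lambda_male, "male encounter split")
  }
  structure(list(c_i = c_i, c_j = c_j, c_ij = c_ij,
                 lambda_female = lambda_female, lambda_male = lambda_male),
            class = "coverage_model")
}

#' Gonotrophic cycle parameters
#'
#' @param d daily "natural" (non-insecticidal) survival probability.
#' @param g cycle length in days (integer, at least 1).
#' @param gmax maximum number of cycles a female can complete (default 5).
#' @return An object of class `cycle_params` including the derived per-cycle
#'   survival `rho = d^g`.
#' @export
cycle_params <- function(d = 1, g = 3, gmax = 5) {
  stopifnot(d >= 0, d <= 1, g >= 1, g == round(g), gmax >= 1,
            gmax == round(gmax))
  structure(list(d = d, g = g, gmax = gmax, rho = d^g),
            class = "cycle_params")
}

#' Natural survival over one gonotrophic cycle
#'
#' @param d daily survival probability.
#' @param g cycle length in days.
#' @return `d^g`, the proportion of females surviving natural mortality
#'   between consecutive cycles.
#' @export
natural_survival <- function(d, g) {
  stopifnot(all(d >= 0), all(d <= 1), all(g >= 0))
  d^g
}

#' Encounter probabilities implied by a coverage model
#'
#' Aggregates house coverages and within-house splits into the probability
#' that a mosquito encounters product i only, product j only, both, or
#' nothing, in one cycle.
#'
#' @param coverage a [coverage_model()].
#' @param x probability of encountering the intervention at all.
#' @param sex `"female"` or `"male"` (selects the lambda split).
#' @return Named numeric vector `c(i, j, both, none)` summing to 1.
#' @export
encounter_partition <- function(coverage, x, sex = c("female", "male")) {
  sex <- match.arg(sex)
  lam <- if (sex == "female") coverage$lambda_female else coverage$lambda_male
  lam[is.na(lam)] <- 0
  p <- c(i = x * (coverage$c_i + coverage$c_ij * lam[["i"]]),
         j = x * (coverage$c_j + coverage$c_ij * lam[["j"]]),
         both = x * coverage$c_ij * lam[["ij"]],
         none = 1 - x)
  p
}

# Female cycle loop for one focal trait I. K_i: per-bin field survival to
# product i on dist$grid; Kbar_j: scalar population mean survival to the
# partner product (1 when absent). Survival to the partner does not select
# on trait I within an individual, so it enters as a scalar. Counts are the
# sums of the corresponding frequency components, which makes the per-cycle
# bookkeeping identity N_P = N_iE + N_jE + N_ijE + N_u exact and reduces to
# the single-generation probabilistic branch at gmax = 1 with c_i = 1.
run_female_cycles <- function(dist, K_i, Kbar_j = 1,
                              coverage = coverage_model(), x = 0.7,
                              rho = 1, gmax = 1) {
  lam <- coverage$lambda_female
  lam[is.na(lam)] <- 0
  grid <- dist$grid
  F_prev <- dist$freq_female
  z0 <- sum(F_prev * grid) / sum(F_prev)
  z_parent <- n_parent <- z_exposed <- numeric(0)
  p_i <- x * (coverage$c_i + coverage$c_ij * lam[["i"]])     # i-only encounter
  p_jscale <- x * Kbar_j * (coverage$c_j + coverage$c_ij * lam[["j"]])
  p_both <- x * coverage$c_ij * lam[["ij"]]
  zbar_prev <- z0
  extinct <- FALSE
  for (G in seq_len(gmax)) {
    s <- if (G == 1) 1 else rho
    A_i <- F_prev * K_i * p_i * s                 # survived i-only encounter
    A_ij <- F_prev * K_i * Kbar_j * p_both * s    # survived both (mixture)
    fE <- A_i + A_ij
    n_iE <- sum(A_i)
    n_ijE <- sum(A_ij)
    n_jE <- p_jscale * s * sum(F_prev)            # survived j-only encounter
    n_u <- (1 - x) * s * sum(F_prev)
    nP <- n_iE + n_jE + n_ijE + n_u
    if (nP <= .Machine$double.eps^2) {
      extinct <- TRUE
      break
    }
    zE <- if (n_iE + n_ijE > 0) sum(fE * grid) / (n_iE + n_ijE) else zbar_prev
    zP <- ((n_iE + n_ijE) * zE + (n_jE + n_u) * zbar_prev) / nP
    F_prev <- (fE + F_prev * (p_jscale + (1 - x)) * s)
    z_parent <- c(z_parent, zP)
    n_parent <- c(n_parent, nP)
    z_exposed <- c(z_exposed, zE)
    zbar_prev <- zP
  }
  list(z0 = z0, z_parent = z_parent, n_parent = n_parent,
       z_exposed = z_exposed, freq_final = F_prev, extinct = extinct)
}

#' Advance the female cohort through one gonotrophic cycle
#'
#' One step of the per-cycle selection process for the focal trait: the
#' surviving females are partitioned into those that encountered product i
#' only, product j only, both, or nothing. Encounters with the focal
#' product select per PRS bin; encounters with the partner product scale all
#' bins by the partner's population mean survival. From the second cycle
#' onwards every term is additionally multiplied by the natural survival
#' `rho`, which scales counts but leaves within-cycle means untouched.
#'
#' @param state list with elements `freq` (female frequency vector on
#'   `grid`), `grid`, `z_parent_mean` (mean at the end of the previous cycle)
#'   and `cycle` (index of the last completed cycle; 0 before the first).
#' @param K_i per-bin field survival to the focal product on `grid`.
#' @param Kbar_j partner product population mean survival (1 when absent).
#' @param coverage a [coverage_model()].
#' @param x female encounter probability.
#' @param rho per-cycle natural survival (applied from cycle 2 onwards).
#' @return The updated state, augmented with the cycle's survivor counts
#'   (`n_i`, `n_j`, `n_ij`, `n_u`), the parental count `n_parents`, the
#'   exposed-survivor mean `z_exposed_mean` and the parental mean
#'   `z_parent_mean`, or with `extinct = TRUE` if the cohort died out.
#' @export
cycle_step <- function(state, K_i, Kbar_j = 1, coverage = coverage_model(),
                       x = 0.7, rho = 1) {
  lam <- coverage$lambda_female
  lam[is.na(lam)] <- 0
  G <- state$cycle + 1
  s <- if (G == 1) 1 else rho
  F_prev <- state$freq
  grid <- state$grid
  p_i <- x * (coverage$c_i + coverage$c_ij * lam[["i"]])
  p_jscale <- x * Kbar_j * (coverage$c_j + coverage$c_ij * lam[["j"]])
  p_both <- x * coverage$c_ij * lam[["ij"]]
  A_i <- F_prev * K_i * p_i * s
  A_ij <- F_prev * K_i * Kbar_j * p_both * s
  n_i <- sum(A_i)
  n_ij <- sum(A_ij)
  n_j <- p_jscale * s * sum(F_prev)
  n_u <- (1 - x) * s * sum(F_prev)
  nP <- n_i + n_j + n_ij + n_u
  if (nP <= .Machine$double.eps^2)
    return(modifyList(state, list(cycle = G, extinct = TRUE)))
  zprev <- state$z_parent_mean
  zE <- if (n_i + n_ij > 0) sum((A_i + A_ij) * grid) / (n_i + n_ij) else zprev
  zP <- ((n_i + n_ij) * zE + (n_j + n_u) * zprev) / nP
  modifyList(state, list(
    freq = A_i + A_ij + F_prev * (p_jscale + (1 - x)) * s,
    cycle = G, extinct = FALSE,
    n_i = n_i, n_j = n_j, n_ij = n_ij, n_u = n_u, n_parents = nP,
    z_exposed_mean = zE, z_parent_mean = zP))
}

# Reconstructed two-site cycle loop with dispersal after every cycle
# (optional mode; default machinery disperses once per generation). Both
# sites share one PRS grid. Intervention females undergo the coverage
# selection terms; refugia females are unexposed. After each cycle a
# proportion theta of each patch disperses and is redistributed in
# proportion to patch size. Egg laying follows dispersal, so parental means
# and counts are recorded post-mixing.
run_two_site_cycles <- function(grid, F_int, F_ref, K_i, Kbar_j = 1,
                                coverage = coverage_model(), x = 0.7,
                                rho = 1, gmax = 1, theta = 0, C = 0.5) {
  lam <- coverage$lambda_female
  lam[is.na(lam)] <- 0
  p_i <- x * (coverage$c_i + coverage$c_ij * lam[["i"]])
  p_jscale <- x * Kbar_j * (coverage$c_j + coverage$c_ij * lam[["j"]])
  p_both <- x * coverage$c_ij * lam[["ij"]]
  z0_int <- sum(F_int * grid) / sum(F_int)
  z0_ref <- sum(F_ref * grid) / sum(F_ref)
  zP_int <- nP_int <- zP_ref <- nP_ref <- numeric(0)
  for (G in seq_len(gmax)) {
    s <- if (G == 1) 1 else rho
    F_int <- (F_int * K_i * p_i + F_int * K_i * Kbar_j * p_both +
                F_int * (p_jscale + (1 - x))) * s
    F_ref <- F_ref * s
    pool <- theta * (F_int + F_ref)
    F_int <- (1 - theta) * F_int + C * pool
    F_ref <- (1 - theta) * F_ref + (1 - C) * pool
    n_int <- sum(F_int)
    n_ref <- sum(F_ref)
    if (n_int + n_ref <= .Machine$double.eps^2) break
    zP_int <- c(zP_int, if (n_int > 0) sum(F_int * grid) / n_int else NA)
    nP_int <- c(nP_int, n_int)
    zP_ref <- c(zP_ref, if (n_ref > 0) sum(F_ref * grid) / n_ref else NA)
    nP_ref <- c(nP_ref, n_ref)
  }
  list(z0_int = z0_int, z0_ref = z0_ref,
       z_parent_int = zP_int, n_parent_int = nP_int,
       z_parent_ref = zP_ref, n_parent_ref = nP_ref)
}

#' Male selection differential under complex insecticide encounters
#'
#' Males undergo a single round of selection before mating (females mate only
#' once, in their first cycle), so the male differential is the male analogue
#' of the female first-cycle equations: encounter probabilities use `x * m`
#' with the male encounter split, focal-product encounters select per bin and
#' partner-product encounters enter as the population mean survival. The
#' resulting differential is held constant across all female cycles.
#'
#' @param dist a [trait_distribution()] (male frequencies are used).
#' @param K_i per-bin field survival to the focal product on `dist$grid`.
#' @param Kbar_j partner product population mean survival (1 when absent).
#' @param coverage a [coverage_model()].
#' @param exposure an [exposure_params()].
#' @return List with the male insecticide selection differential
#'   `S_insecticide`, parental mean `z_parent_mean` and count `n_parents`.
#' @export
male_selection_complex <- function(dist, K_i, Kbar_j = 1,
                                   coverage = coverage_model(),
                                   exposure = exposure_params()) {
  lam <- coverage$lambda_male
  lam[is.na(lam)] <- 0
  xm <- exposure$x * exposure$m
  grid <- dist$grid
  Fm <- dist$freq_male
  z0 <- sum(Fm * grid) / sum(Fm)
  B_i <- Fm * K_i * xm * (coverage$c_i + coverage$c_ij * lam[["i"]])
  B_ij <- Fm * K_i * Kbar_j * xm * coverage$c_ij * lam[["ij"]]
  n_iE <- sum(B_i)
  n_ijE <- sum(B_ij)
  n_jE <- xm * Kbar_j * (coverage$c_j + coverage$c_ij * lam[["j"]]) * sum(Fm)
  n_u <- (1 - xm) * sum(Fm)
  nP <- n_iE + n_jE + n_ijE + n_u
  if (nP <= 0) stop("degenerate cohort: no male parents")
  zE <- if (n_iE + n_ijE > 0) sum((B_i + B_ij) * grid) / (n_iE + n_ijE) else z0
  zP <- ((n_iE + n_ijE) * zE + (n_jE + n_u) * z0) / nP
  list(S_insecticide = zP - z0, z_parent_mean = zP, n_parents = nP)
}

#' Cycle-weighted total response to selection
#'
#' Each cycle's overall female differential is the parental mean minus the
#' hatching mean plus the (constant, first-cycle) fitness-cost differential;
#' the male differential is fixed across cycles. The per-cycle responses from
#' the sex-specific Breeder's equation are then weighted by the number of
#' females laying eggs in each cycle (oviposition events), since later cycles
#' contribute fewer, more resistant eggs.
#'
#' @param z_parent per-cycle female parental means.
#' @param n_parent per-cycle female parental counts (the oviposition
#'   weights).
#' @param z0 mean PRS at hatching.
#' @param S_male male insecticide selection differential (constant).
#' @param genetics a [genetics_params()].
#' @param S_cost_female,S_cost_male fitness-cost differentials per sex
#'   (non-positive; see [fitness_cost_differential()]).
#' @param beta_scales_costs logical; if `FALSE` (default) the exposure
#'   scaling factor rescales only the insecticide component of each cycle's
#'   response, with the cost differentials entering unscaled.
#' @return List with the weighted total response `R_total`, the per-cycle
#'   responses `R_cycle` and the total oviposition count `n_oviposition`.
#' @export
multi_cycle_response <- function(z_parent, n_parent, z0, S_male,
                                 genetics = genetics_params(),
                                 S_cost_female = 0, S_cost_male = 0,
                                 beta_scales_costs = FALSE) {
  if (length(n_parent) == 0 || sum(n_parent) <= 0)
    stop("cohort extinct: no oviposition events")
  R_cycle <- compose_response(z_parent - z0, S_male, S_cost_female,
                              S_cost_male, genetics, beta_scales_costs)
  list(R_total = sum(R_cycle * n_parent) / sum(n_parent),
       R_cycle = R_cycle, n_oviposition = sum(n_parent))
}

#' Mosquito age profile under an insecticidal intervention
#'
#' Runs a single-generation, no-evolution snapshot of the female cycle loop
#' (full coverage, no refugia) and reports how many females complete each
#' gonotrophic cycle, alongside the geometric no-intervention profile.
#' Counts are scaled so that, without intervention, `baseline_n` females
#' complete the first cycle. Females surviving four or more cycles serve as
#' a proxy for surviving the roughly ten-day extrinsic incubation period of
#' Plasmodium falciparum.
#'
#' @param insecticides list of one or two [insecticide()] objects (the focal
#'   product first).
#' @param mean_prs named mean PRS per trait (same order as `insecticides`).
#' @param omega efficacy per product (recycled).
#' @param coverage a [coverage_model()] describing the deployment.
#' @param x per-cycle encounter probability (default 0.7).
#' @param cycles a [cycle_params()]; defaults to ten 3-day cycles with daily
#'   survival 0.9 (`rho = 0.729`).
#' @param sigma PRS standard deviation of the cohort.
#' @param baseline_n females completing cycle 1 without intervention.
#' @param cal a [field_calibration()].
#' @param n_bins distribution grid size.
#' @return An object of class `age_profile`: a data frame with columns
#'   `cycle`, `with_intervention` and `no_intervention`, with the count of
#'   females surviving at least four cycles in attribute `surviving_eip`.
#' @export
age_profile_snapshot <- function(insecticides, mean_prs, omega = 1,
                                 coverage = coverage_model(), x = 0.7,
                                 cycles = cycle_params(d = 0.9, g = 3,
                                                       gmax = 10),
                                 sigma = 30, baseline_n = 1e5,
                                 cal = field_calibration(), n_bins = 2001) {
  if (inherits(insecticides, "insecticide")) insecticides <- list(insecticides)
  omega <- rep_len(omega, length(insecticides))
  dist <- hatch_distribution(mean_prs[[1]], sigma, n_bins = n_bins,
                             total = 2 * baseline_n)
  K_i <- survival_on_grid(dist$grid, insecticides[[1]], omega[[1]], cal)
  Kbar_j <- if (length(insecticides) > 1) {
    mean_survival(mean_prs[[2]], insecticides[[2]], omega[[2]], cal)
  } else 1
  res <- run_female_cycles(dist, K_i, Kbar_j, coverage, x,
                           rho = cycles$rho, gmax = cycles$gmax)
  with_int <- c(res$n_parent, rep(0, cycles$gmax - length(res$n_parent)))
  no_int <- baseline_n * cycles$rho^(seq_len(cycles$gmax) - 1)
  out <- data.frame(cycle = seq_len(cycles$gmax),
                    with_intervention = with_int,
                    no_intervention = no_int)
  attr(out, "surviving_eip") <- c(
    with_intervention = sum(with_int[out$cycle >= 4]),
    no_intervention = sum(no_int[out$cycle >= 4]))
  class(out) <- c("age_profile", class(out))
  out
}

#' @export
print.age_profile <- function(x, ...) {
  cat("Mosquito age profile (females completing each gonotrophic cycle)\n")
  print.data.frame(x, row.names = FALSE, ...)
  eip <- attr(x, "surviving_eip")
  cat(sprintf("Surviving >= 4 cycles: %.0f with intervention, %.0f without\n",
              eip[["with_intervention"]], eip[["no_intervention"]]))
  invisible(x)
}
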