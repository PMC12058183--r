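# Within-generation selection differentials (truncation and probabilistic
# branches) and the between-generation response via the sex-specific
# Breeder's equation.

# cache of standardised hatching grids and weights, keyed by bin count
.hatch_cache <- new.env(parent = emptyenv())

#' Genetics parameters for the Breeder's equation
#'
#' @param h2 narrow-sense heritability of the resistance trait, in `[0, 1]`.
#' @param beta exposure scaling factor (> 0), the calibration constant that
#'   scales the response so resistance to a novel insecticide emerges over a
#'   realistic operational timescale (see [calibrate_beta()]).
#' @return An object of class `genetics_params`.
#' @export
genetics_params <- function(h2 = 0.2, beta = 1) {
  stopifnot(h2 >= 0, h2 <= 1, beta > 0)
  structure(list(h2 = h2, beta = beta), class = "genetics_params")
}

#' Insecticide exposure parameters
#'
#' @param x proportion of females encountering the deployed insecticide(s)
#'   in a gonotrophic cycle, in `[0, 1]`.
#' @param m male exposure as a fraction of female exposure (males do not
#'   blood-feed so typically `m < 1`); `m * x` must not exceed 1.
#' @return An object of class `exposure_params`.
#' @export
exposure_params <- function(x = 0.7, m = 0.7) {
  stopifnot(x >= 0, x <= 1, m >= 0, m * x <= 1)
  structure(list(x = x, m = m), class = "exposure_params")
}

#' Fitness cost of resistance
#'
#' Fitness costs act as a sex-specific selection differential that reduces
#' the mean PRS. Magnitudes are stored positive and applied with a negative
#' sign. In `"fixed"` mode the magnitudes are PRS units (used with a fixed
#' sigma); in `"scaled"` mode they are fractions of the current standard
#' deviation (used when sigma varies with the mean).
#'
#' @param mode `"fixed"` or `"scaled"`.
#' @param female,male non-negative cost magnitudes per sex.
#' @return An object of class `fitness_cost`.
#' @export
fitness_cost <- function(mode = c("fixed", "scaled"), female = 0.2,
                         male = 0.2) {
  mode <- match.arg(mode)
  stopifnot(female >= 0, male >= 0)
  structure(list(mode = mode, female = female, male = male),
            class = "fitness_cost")
}

#' Binned PRS trait distribution
#'
#' The probabilistic ("polysmooth") branch represents the population as a
#' discretised PRS distribution: a grid of bin centres with per-sex
#' frequencies. Construct fresh normal distributions with
#' [hatch_distribution()]; this low-level constructor is exported for toy
#' distributions in examples and tests.
#'
#' @param grid strictly increasing PRS bin centres.
#' @param freq_female,freq_male non-negative frequencies per bin; their sums
#'   are the per-sex cohort sizes.
#' @param sigma optional PRS standard deviation annotation.
#' @return An object of class `trait_distribution` with elements `grid`,
#'   `freq_female`, `freq_male`, `mean` (recomputed from the frequencies) and
#'   `sigma`.
#' @export
trait_distribution <- function(grid, freq_female,
                               freq_male = freq_female, sigma = NA_real_) {
  stopifnot(length(grid) == length(freq_female),
            length(grid) == length(freq_male),
            all(diff(grid) > 0), all(freq_female >= 0), all(freq_male >= 0))
  tot <- sum(freq_female) + sum(freq_male)
  structure(list(grid = grid, freq_female = freq_female,
                 freq_male = freq_male,
                 mean = sum((freq_female + freq_male) * grid) / tot,
                 sigma = sigma),
            class = "trait_distribution")
}

#' @export
print.trait_distribution <- function(x, ...) {
  cat(sprintf("<trait_distribution> %d bins on [%g, %g], mean %.4g, n = %.4g\n",
              length(x$grid), min(x$grid), max(x$grid), x$mean,
              sum(x$freq_female) + sum(x$freq_male)))
  invisible(x)
}

#' Normal PRS distribution of a hatching cohort
#'
#' Frequencies are proportional to the normal density at the bin centres,
#' renormalised so each sex holds half of `total` (a 1:1 hatching sex ratio).
#' The grid spans the mean plus/minus six standard deviations.
#'
#' @param mean mean PRS at hatching.
#' @param sigma PRS standard deviation (> 0).
#' @param n_bins number of grid bins (at least 100; default 2001).
#' @param total total cohort size across both sexes (default 1, i.e.
#'   frequencies are proportions).
#' @return A [trait_distribution()].
#' @export
hatch_distribution <- function(mean, sigma, n_bins = 2001, total = 1) {
  stopifnot(sigma > 0, n_bins >= 100, total > 0)
  # the standardised grid and normalised weights only depend on n_bins
  key <- as.character(n_bins)
  hc <- get0(key, envir = .hatch_cache, inherits = FALSE)
  if (is.null(hc)) {
    u <- seq(-6, 6, length.out = n_bins)
    w0 <- dnorm(u)
    hc <- list(u = u, w0 = w0 / sum(w0))
    assign(key, hc, envir = .hatch_cache)
  }
  w <- hc$w0 * (total / 2)
  structure(list(grid = mean + sigma * hc$u, freq_female = w, freq_male = w,
                 mean = mean, sigma = sigma),
            class = "trait_distribution")
}

#' Intensity of truncation selection
#'
#' For truncation selection where a proportion `p_survive` of a unit normal
#' population survives (the upper tail), the mean of the survivors exceeds
#' the population mean by `dnorm(q) / p_survive` standard deviations, where
#' `q` is the truncation point. Returns 0 at `p_survive = 1` (no selection).
#'
#' @param p_survive surviving proportion(s) in `(0, 1]`.
#' @return Selection intensity in standard-deviation units.
#' @export
truncation_intensity <- function(p_survive) {
  if (any(p_survive <= 0))
    stop("all exposed mosquitoes die: truncation intensity undefined")
  stopifnot(all(p_survive <= 1))
  ifelse(p_survive == 1, 0, dnorm(qnorm(1 - p_survive)) / p_survive)
}

#' Truncation selection of an exposed cohort
#'
#' Implements the "polytruncate" branch for the exposed fraction of one
#' generation: only mosquitoes above the truncation point implied by the
#' population mean field survival survive their insecticide encounter. The
#' survivor mean is `dist_mean + sigma * truncation_intensity(K)` and the
#' survivor counts scale the exposed numbers by `K` (and by the partner
#' insecticide's mean survival for mixtures).
#'
#' @param dist_mean,sigma mean and standard deviation of the PRS at hatching.
#' @param mean_field_survival population mean field survival `K` to the
#'   deployed insecticide (evaluated at the population mean PRS).
#' @param exposure an [exposure_params()].
#' @param n_total named vector `c(female = , male = )` of cohort sizes.
#' @param partner_survival mean field survival to the mixture partner, or
#'   `NULL` for monotherapy.
#' @return A partial selection outcome: list with `z_exposed_mean` and
#'   `n_exposed` (per sex); complete it with [parental_pool()].
#' @export
truncation_selection <- function(dist_mean, sigma, mean_field_survival,
                                 exposure,
                                 n_total = c(female = 0.5, male = 0.5),
                                 partner_survival = NULL) {
  K <- mean_field_survival
  zE <- dist_mean + sigma * truncation_intensity(K)
  mult <- if (is.null(partner_survival)) 1 else partner_survival
  list(z_exposed_mean = c(female = zE, male = zE),
       n_exposed = c(
         female = exposure$x * n_total[["female"]] * K * mult,
         male = exposure$x * exposure$m * n_total[["male"]] * K * mult))
}

#' Probabilistic selection of an exposed cohort
#'
#' Implements the "polysmooth" branch for the exposed fraction of one
#' generation: each bin of the PRS distribution survives its insecticide
#' encounter with the bin's own field survival probability. For mixtures the
#' partner insecticide enters as the population mean survival (the model
#' carries no individual-level correlation between traits).
#'
#' @param dist a [trait_distribution()].
#' @param survival per-bin survival probabilities: a numeric vector over
#'   `dist$grid` or a function of PRS (see [survival_on_grid()]).
#' @param exposure an [exposure_params()].
#' @param partner_survival mean survival to the mixture partner, or `NULL`.
#' @return A partial selection outcome: list with `z_exposed_mean`,
#'   `n_exposed` (per sex) and the per-sex exposed-survivor frequency vectors
#'   `freq_exposed_female` / `freq_exposed_male`.
#' @export
probabilistic_selection <- function(dist, survival, exposure,
                                    partner_survival = NULL) {
  K <- if (is.function(survival)) survival(dist$grid) else survival
  stopifnot(length(K) == length(dist$grid), all(K >= 0), all(K <= 1))
  mult <- if (is.null(partner_survival)) 1 else partner_survival
  fE_f <- dist$freq_female * K * exposure$x * mult
  fE_m <- dist$freq_male * K * exposure$x * exposure$m * mult
  nE_f <- sum(fE_f)
  nE_m <- sum(fE_m)
  if (exposure$x > 0 && nE_f <= 0)
    stop("degenerate cohort: all exposed females died")
  zE_f <- if (nE_f > 0) sum(fE_f * dist$grid) / nE_f else dist$mean
  zE_m <- if (nE_m > 0) sum(fE_m * dist$grid) / nE_m else dist$mean
  list(z_exposed_mean = c(female = zE_f, male = zE_m),
       n_exposed = c(female = nE_f, male = nE_m),
       freq_exposed_female = fE_f, freq_exposed_male = fE_m)
}

#' Form the breeding parental pool and insecticide selection differential
#'
#' Combines exposed survivors (from either selection branch) with the
#' unexposed fraction. Parents number `N_P = N_E + N_u` per sex; their mean is
#' the count-weighted mean of survivor and unexposed means, and the
#' insecticide selection differential is `S = z_parent_mean - dist_mean`.
#'
#' @param partial outcome of [truncation_selection()] or
#'   [probabilistic_selection()].
#' @param dist_mean mean PRS at hatching.
#' @param exposure an [exposure_params()].
#' @param n_total named per-sex cohort sizes at hatching.
#' @return A `selection_outcome` list with per-sex `S_insecticide`,
#'   `z_exposed_mean`, `n_exposed`, `n_unexposed`, `n_parents` and
#'   `z_parent_mean`.
#' @export
parental_pool <- function(partial, dist_mean, exposure,
                          n_total = c(female = 0.5, male = 0.5)) {
  nu <- c(female = n_total[["female"]] * (1 - exposure$x),
          male = n_total[["male"]] * (1 - exposure$m * exposure$x))
  nE <- partial$n_exposed
  nP <- nE + nu
  if (any(nP <= 0)) stop("degenerate cohort: no breeding parents")
  zP <- (nE * partial$z_exposed_mean + nu * dist_mean) / nP
  structure(list(S_insecticide = zP - dist_mean,
                 z_exposed_mean = partial$z_exposed_mean,
                 n_exposed = nE, n_unexposed = nu, n_parents = nP,
                 z_parent_mean = zP),
            class = "selection_outcome")
}

#' Fitness-cost selection differential
#'
#' @param cost a [fitness_cost()].
#' @param sigma current PRS standard deviation (used by `"scaled"` mode).
#' @return Named per-sex differential in PRS units, non-positive (costs
#'   reduce resistance).
#' @export
fitness_cost_differential <- function(cost, sigma = NULL) {
  if (cost$mode == "fixed")
    return(c(female = -cost$female, male = -cost$male))
  stopifnot(!is.null(sigma), sigma > 0)
  c(female = -cost$female * sigma, male = -cost$male * sigma)
}

#' Between-generation response via the sex-specific Breeder's equation
#'
#' `R = h2 * (S_female + S_male) / 2 * beta`.
#'
#' @param S_female,S_male overall per-sex selection differentials (PRS units).
#' @param genetics a [genetics_params()].
#' @return Response in PRS units.
#' @export
breeders_response <- function(S_female, S_male, genetics = genetics_params()) {
  genetics$h2 * (S_female + S_male) / 2 * genetics$beta
}

# Combine insecticide-selection and fitness-cost differentials into a
# response. By default the exposure scaling factor rescales only the
# insecticide component: beta calibrates the uncertain strength of
# insecticide selection, whereas the cost differentials are specified
# directly on the PRS scale. scale_costs = TRUE applies beta to the summed
# differential instead.
compose_response <- function(S_sel_female, S_sel_male, S_cost_female,
                             S_cost_male, genetics, scale_costs = FALSE) {
  if (scale_costs)
    return(breeders_response(S_sel_female + S_cost_female,
                             S_sel_male + S_cost_male, genetics))
  breeders_response(S_sel_female, S_sel_male, genetics) +
    genetics$h2 * (S_cost_female + S_cost_male) / 2
}
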