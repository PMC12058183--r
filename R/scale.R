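# Polygenic resistance score (PRS) scale: Hill map to bioassay survival,
# bioassay-to-field regression, post-deployment efficacy decay and the
# PRS standard-deviation model.

#' Hill scale linking the polygenic resistance score to bioassay survival
#'
#' The polygenic resistance score (PRS) is an arbitrary quantitative scale of
#' insecticide resistance. It is mapped to the proportion of females surviving
#' a standardised discriminating-dose bioassay by a Hill (Michaelis-Menten
#' variant) curve with half-saturation `z50`, maximum `kmax` and exponent `n`.
#'
#' @param z50 PRS giving 50% bioassay survival (must be positive). The
#'   conventional parameterisation `z50 = 900` places 10% bioassay survival
#'   (the usual "confirmed resistance" criterion) at a PRS of 100.
#' @param kmax maximum bioassay survival proportion (1 by convention).
#' @param n Hill exponent (1 by convention).
#' @return An object of class `hill_scale`.
#' @seealso [bioassay_survival()], [bioassay_to_prs()]
#' @export
#' @examples
#' bioassay_survival(100, hill_scale(z50 = 900))  # 0.10
hill_scale <- function(z50 = 900, kmax = 1, n = 1) {
  stopifnot(is.numeric(z50), length(z50) == 1, z50 > 0,
            is.numeric(kmax), length(kmax) == 1, kmax > 0,
            is.numeric(n), length(n) == 1, n > 0)
  structure(list(z50 = z50, kmax = kmax, n = n), class = "hill_scale")
}

#' @export
print.hill_scale <- function(x, ...) {
  cat(sprintf("<hill_scale> z50 = %g, kmax = %g, n = %g\n", x$z50, x$kmax, x$n))
  invisible(x)
}

#' Bioassay-to-field survival calibration coefficients
#'
#' Field survival against a deployed insecticide (experimental-hut proxy) is
#' modelled as linear in bioassay survival, `phi1 * K_B + phi2`, raised to the
#' power of the insecticide's current efficacy. The default coefficients are
#' `phi1 = 0.48`, `phi2 = 0.15`.
#'
#' @param phi1 slope of the bioassay-to-hut regression (non-negative).
#' @param phi2 intercept (non-negative); `phi1 + phi2` must not exceed 1 so
#'   field survival stays a proportion.
#' @return An object of class `field_calibration`.
#' @export
field_calibration <- function(phi1 = 0.48, phi2 = 0.15) {
  stopifnot(is.numeric(phi1), length(phi1) == 1, phi1 >= 0,
            is.numeric(phi2), length(phi2) == 1, phi2 >= 0)
  if (phi1 + phi2 > 1 + 1e-12)
    stop("phi1 + phi2 must be <= 1 (field survival is a proportion)")
  structure(list(phi1 = phi1, phi2 = phi2), class = "field_calibration")
}

#' Two-phase insecticide efficacy decay profile
#'
#' Efficacy is the insecticide's ability to kill fully susceptible mosquitoes,
#' relative to the manufacturer's recommended dose (1 = recommended dose,
#' < 1 reduced dose as in reduced-dose mixtures, > 1 over-spraying). After
#' deployment, efficacy decays in two phases: a basal phase at rate `delta_b`
#' up to the longevity threshold `tau_b` (in mosquito generations since
#' deployment), then a rapid phase at rate `delta_r`. Within each phase the
#' decay follows `exp(-t^exponent * delta)` in the time `t` spent in that
#' phase, so the curve is continuous at `tau_b`. Setting both rates to zero
#' switches decay off; setting `delta_b = delta_r` collapses the profile to a
#' single phase.
#'
#' @param omega0 initial deployed efficacy (dose), non-negative.
#' @param delta_b basal decay rate (per generation^exponent), non-negative.
#' @param delta_r rapid decay rate after `tau_b`, non-negative.
#' @param tau_b generations until the rapid phase begins, non-negative.
#' @param exponent positive exponent of the decay law. The default of 1
#'   (simple exponential decay in time) keeps a basal rate of 0.015 per
#'   generation consistent with a product that loses only about a quarter of
#'   its efficacy over a two-year basal phase; `exponent = 2` gives a
#'   Gaussian-shaped profile that is near-flat initially and then collapses.
#'   See the methods vignette for the reasoning behind the default.
#' @return An object of class `decay_profile`.
#' @seealso [efficacy_at()]
#' @export
decay_profile <- function(omega0 = 1, delta_b = 0, delta_r = 0, tau_b = 0,
                          exponent = 1) {
  stopifnot(omega0 >= 0, delta_b >= 0, delta_r >= 0, tau_b >= 0, exponent > 0)
  structure(list(omega0 = omega0, delta_b = delta_b, delta_r = delta_r,
                 tau_b = tau_b, exponent = exponent),
            class = "decay_profile")
}

#' Model for the standard deviation of the polygenic resistance score
#'
#' The PRS is normally distributed with standard deviation `sigma`. Two
#' options are supported: a fixed sigma (the usual choice when resistance is
#' kept below the withdrawal threshold) or a sigma that grows linearly with
#' the mean PRS, `sigma = phi3 * mean + phi4`, evaluated separately per site.
#'
#' @param mode `"fixed"` or `"linear"`.
#' @param sigma PRS-unit standard deviation used in fixed mode. The default of
#'   30 matches the package's illustrative low-resistance scenarios.
#' @param phi3,phi4 slope and intercept of the linear mode. No field-validated
#'   values are shipped; the defaults are illustrative placeholders and should
#'   be replaced with values estimated from bioassay data before use.
#' @return An object of class `sigma_model`.
#' @export
sigma_model <- function(mode = c("fixed", "linear"), sigma = 30,
                        phi3 = 0.1, phi4 = 20) {
  mode <- match.arg(mode)
  if (mode == "fixed") stopifnot(sigma > 0)
  structure(list(mode = mode, sigma = sigma, phi3 = phi3, phi4 = phi4),
            class = "sigma_model")
}

#' Insecticide definition
#'
#' Bundles an insecticide's identifier, its Hill scale (the PRS level of
#' resistance to it) and its deployment dose / decay profile.
#'
#' @param id character label, unique within an arsenal.
#' @param scale a [hill_scale()].
#' @param decay a [decay_profile()].
#' @return An object of class `insecticide`.
#' @export
insecticide <- function(id, scale = hill_scale(), decay = decay_profile()) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id),
            inherits(scale, "hill_scale"), inherits(decay, "decay_profile"))
  structure(list(id = id, scale = scale, decay = decay), class = "insecticide")
}

#' @export
print.insecticide <- function(x, ...) {
  cat(sprintf("<insecticide> %s: z50 = %g, omega0 = %g, decay (%g, %g, tau_b %g)\n",
              x$id, x$scale$z50, x$decay$omega0, x$decay$delta_b,
              x$decay$delta_r, x$decay$tau_b))
  invisible(x)
}

#' Bioassay survival at a given PRS
#'
#' Hill map from PRS to the proportion surviving a discriminating-dose
#' bioassay. Scores at or below zero denote fully susceptible mosquitoes and
#' map to zero survival.
#'
#' @param z PRS value(s).
#' @param scale a [hill_scale()].
#' @return Survival proportion(s) in `[0, kmax)`.
#' @export
bioassay_survival <- function(z, scale = hill_scale()) {
  k <- numeric(length(z))
  pos <- z > 0
  if (any(pos)) {
    zp <- z[pos]^scale$n
    k[pos] <- scale$kmax * zp / (scale$z50 + zp)
  }
  k
}

#' PRS giving a target bioassay survival
#'
#' Algebraic inverse of [bioassay_survival()], used to initialise scenarios
#' stated in terms of bioassay survival.
#'
#' @param k bioassay survival proportion(s), `0 <= k < kmax`.
#' @param scale a [hill_scale()].
#' @return PRS value(s) with `bioassay_survival(result) == k`.
#' @export
bioassay_to_prs <- function(k, scale = hill_scale()) {
  if (any(k < 0)) stop("bioassay survival must be non-negative")
  if (any(k >= scale$kmax))
    stop("no finite PRS gives bioassay survival at or above kmax")
  (scale$z50 * k / (scale$kmax - k))^(1 / scale$n)
}

#' Field survival given bioassay survival and insecticide efficacy
#'
#' Survival of a real insecticide encounter, `(phi1 * k_bioassay + phi2) ^
#' omega`, clamped to `[0, 1]`. A fully decayed insecticide (`omega = 0`)
#' kills nothing; higher efficacy (over-spray, `omega > 1`) lowers survival at
#' every resistance level.
#'
#' @param k_bioassay bioassay survival proportion(s) in `[0, 1]`.
#' @param omega insecticide efficacy (non-negative scalar).
#' @param cal a [field_calibration()].
#' @return Field survival proportion(s).
#' @export
field_survival <- function(k_bioassay, omega = 1, cal = field_calibration()) {
  stopifnot(length(omega) == 1, omega >= 0)
  if (omega == 0) return(rep(1, length(k_bioassay)))
  s <- (cal$phi1 * k_bioassay + cal$phi2)^omega
  # with phi1 + phi2 <= 1 the result is already a proportion
  if (any(s < 0 | s > 1)) s <- pmin(pmax(s, 0), 1)
  s
}

#' Insecticide efficacy at a time since deployment
#'
#' Evaluates the two-phase decay profile at `tau` generations after
#' deployment. The basal phase applies up to `tau_b`; the rapid phase decay is
#' applied to the efficacy remaining at the threshold, so the curve is
#' continuous there and non-increasing throughout.
#'
#' @param tau generations since deployment (non-negative, vectorised).
#' @param decay a [decay_profile()].
#' @return Efficacy value(s); equals `omega0` at `tau = 0`.
#' @export
efficacy_at <- function(tau, decay = decay_profile()) {
  stopifnot(all(tau >= 0))
  p <- decay$exponent
  s1 <- decay$omega0 * exp(-tau^p * decay$delta_b)
  s2 <- decay$omega0 * exp(-decay$tau_b^p * decay$delta_b) *
    exp(-pmax(tau - decay$tau_b, 0)^p * decay$delta_r)
  ifelse(tau <= decay$tau_b, s1, s2)
}

#' Standard deviation of the PRS at a given mean
#'
#' @param z_mean mean PRS value(s).
#' @param model a [sigma_model()].
#' @return Standard deviation(s) in PRS units (always positive).
#' @export
sigma_of_mean <- function(z_mean, model = sigma_model()) {
  s <- switch(model$mode,
              fixed = rep(model$sigma, length(z_mean)),
              linear = model$phi3 * z_mean + model$phi4)
  if (any(s <= 0))
    stop("sigma model produced a non-positive standard deviation")
  s
}

#' Mean field survival of a population
#'
#' The population-level survival to an insecticide used in the selection
#' equations. By default it is evaluated at the population mean PRS (the
#' "proportion expected to survive based on the mean PRS"); the
#' `"integrated"` mode instead takes the expectation of per-individual field
#' survival over the normal PRS distribution, for sensitivity analysis.
#'
#' @param z_mean population mean PRS.
#' @param ins an [insecticide()].
#' @param omega current efficacy of the insecticide.
#' @param cal a [field_calibration()].
#' @param mode `"at_mean"` (default) or `"integrated"`.
#' @param sigma PRS standard deviation (required for `"integrated"`).
#' @param n_bins grid size for the integrated mode.
#' @return Mean survival proportion.
#' @export
mean_survival <- function(z_mean, ins, omega = 1, cal = field_calibration(),
                          mode = c("at_mean", "integrated"), sigma = NULL,
                          n_bins = 501) {
  mode <- match.arg(mode)
  if (mode == "at_mean")
    return(field_survival(bioassay_survival(z_mean, ins$scale), omega, cal))
  stopifnot(!is.null(sigma), sigma > 0)
  grid <- seq(z_mean - 6 * sigma, z_mean + 6 * sigma, length.out = n_bins)
  w <- dnorm(grid, z_mean, sigma)
  w <- w / sum(w)
  sum(w * field_survival(bioassay_survival(grid, ins$scale), omega, cal))
}

#' Per-individual field survival over a PRS grid
#'
#' Convenience helper composing the Hill map and the bioassay-to-field map
#' over a vector of PRS values, as used by the probabilistic selection branch.
#'
#' @param z PRS values (e.g. the grid of a [trait_distribution()]).
#' @param ins an [insecticide()].
#' @param omega current efficacy.
#' @param cal a [field_calibration()].
#' @return Vector of field survival proportions.
#' @export
survival_on_grid <- function(z, ins, omega = 1, cal = field_calibration()) {
  field_survival(bioassay_survival(z, ins$scale), omega, cal)
}
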