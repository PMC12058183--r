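# Shared builders for the test suite. Sweep-style tests use a reduced grid
# (501 bins) for speed; exactness tests use the default resolution.

two_insecticide_scenario <- function(beta = 1, alpha = 0, cost = 0,
                                     coverage = 0.7, dispersal = 0.3,
                                     start = 0, n_bins = 501, ...) {
  scenario(
    insecticides = list(insecticide("i"), insecticide("j")),
    h2 = 0.2, beta = beta,
    exposure = exposure_params(0.7, 0.7),
    fitness_cost = fitness_cost("fixed", cost, cost),
    landscape = landscape_params(coverage, dispersal),
    alpha = alpha, start_prs = start, n_bins = n_bins, ...)
}

# calibrated exposure factors, computed once per test run
.beta_cache <- new.env(parent = emptyenv())
calibrated_beta <- function(branch = "polysmooth", n_bins = 501) {
  key <- paste(branch, n_bins, sep = "_")
  got <- get0(key, envir = .beta_cache, inherits = FALSE)
  if (is.null(got)) {
    got <- calibrate_beta(branch = branch, n_bins = n_bins)$beta
    assign(key, got, envir = .beta_cache)
  }
  got
}

intervention_survival <- function(traj, trait = NULL) {
  r <- traj$records
  keep <- r$site == "intervention"
  if (!is.null(trait)) keep <- keep & r$trait == trait
  r$bioassay_survival[keep]
}
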