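# Two-patch landscape: between-generation mean updates with cross
# resistance, and female dispersal between intervention site and refugia.

#' Cross-resistance matrix
#'
#' Genetic correlations `alpha[G, I]` through which selection on trait `G`
#' produces a correlated response in trait `I`. Positive values mean
#' resistance to one insecticide confers resistance to another; negative
#' values mean it confers susceptibility.
#'
#' @param ids character vector of trait/insecticide identifiers.
#' @param offdiag common off-diagonal correlation, in `[-1, 1]` (default 0).
#' @param matrix optional full matrix (row/column names must be `ids`);
#'   overrides `offdiag`. Diagonal entries must equal 1.
#' @return A square numeric matrix of class `cross_resistance`.
#' @export
cross_resistance <- function(ids, offdiag = 0, matrix = NULL) {
  if (is.null(matrix)) {
    stopifnot(offdiag >= -1, offdiag <= 1)
    m <- base::matrix(offdiag, length(ids), length(ids),
                      dimnames = list(ids, ids))
    diag(m) <- 1
  } else {
    m <- matrix
    stopifnot(is.matrix(m), nrow(m) == length(ids), ncol(m) == length(ids))
    dimnames(m) <- list(ids, ids)
    if (any(abs(diag(m) - 1) > 1e-12))
      stop("cross-resistance diagonal must be 1")
    if (any(m < -1 | m > 1))
      stop("cross-resistance entries must lie in [-1, 1]")
  }
  class(m) <- c("cross_resistance", class(m))
  m
}

#' Landscape coverage and dispersal parameters
#'
#' @param coverage proportion `C` of the mosquito population in the
#'   intervention site (the remainder is in the untreated refugia).
#' @param dispersal proportion `theta` of females dispersing each generation.
#' @return An object of class `landscape_params`.
#' @export
landscape_params <- function(coverage = 0.7, dispersal = 0.3) {
  stopifnot(coverage >= 0, coverage <= 1, dispersal >= 0, dispersal <= 1)
  structure(list(coverage = coverage, dispersal = dispersal),
            class = "landscape_params")
}

#' Apply per-trait responses to a site, with cross resistance
#'
#' Updates a vector of per-trait mean PRS values. Each trait receives its own
#' response (insecticide-plus-cost response for deployed traits, cost-only
#' response otherwise) plus the correlated responses `alpha[G, I] * R_G`
#' summed over the other deployed traits `G`. Results are floored at zero:
#' fitness costs cannot drive the mean PRS negative.
#'
#' @param z named vector of per-trait mean PRS for one site.
#' @param responses named vector of per-trait responses (`R` values); deployed
#'   traits must carry their selection-plus-cost response.
#' @param deployed character vector of deployed trait ids (empty for the
#'   refugia).
#' @param alpha a [cross_resistance()] matrix (ignored when nothing is
#'   deployed).
#' @return Updated named vector of means.
#' @export
apply_responses <- function(z, responses, deployed = character(),
                            alpha = cross_resistance(names(z))) {
  ids <- names(z)
  if (is.null(ids) || !setequal(ids, names(responses)))
    stop("responses must be named for every tracked trait")
  if (!all(deployed %in% ids)) stop("deployed trait missing a response")
  apply_responses_core(z, responses[ids], deployed, alpha, ids)
}

# validated fast path used by the simulation loop
apply_responses_core <- function(z, responses, deployed, alpha, ids) {
  out <- z + responses
  if (length(deployed)) {
    cross <- colSums(alpha[deployed, ids, drop = FALSE] *
                       responses[deployed])
    cross <- cross - ifelse(ids %in% deployed, responses, 0)
    out <- out + cross
  }
  pmax(out, 0)
}

#' Female dispersal between intervention site and refugia
#'
#' Mixes the post-mating mean PRS of the two patches. With `theta` the
#' proportion of females dispersing and `C` the intervention coverage, the
#' exchange rates are `r_Int = theta * C` (females arriving in the refugia
#' from the intervention site) and `r_Ref = (1 - C) * theta` (the reverse).
#' The default `"conserving"` mode weights each site's new mean as
#' `(1 - immigrant rate)` of its own mean plus the immigrant rate of the
#' other site's, which follows from global dispersal in proportion to patch
#' size and keeps the weights summing to one. The `"literal"` mode instead
#' reproduces the source equations exactly as printed (whose weights only sum
#' to one at `C = 0.5`), and `"normalised"` rescales the literal weights to
#' sum to one. All three coincide at `C = 0.5`.
#'
#' @param z_int,z_ref per-trait mean PRS vectors (or scalars) of the
#'   intervention site and refugia after selection and mating.
#' @param params a [landscape_params()].
#' @param mode `"conserving"` (default), `"literal"` or `"normalised"`.
#' @return List with elements `intervention` and `refugia`.
#' @export
disperse <- function(z_int, z_ref, params = landscape_params(),
                     mode = c("conserving", "literal", "normalised")) {
  mode <- match.arg(mode)
  r_ref <- (1 - params$coverage) * params$dispersal
  r_int <- params$dispersal * params$coverage
  out <- switch(mode,
    conserving = list(intervention = z_int * (1 - r_ref) + z_ref * r_ref,
                      refugia = z_ref * (1 - r_int) + z_int * r_int),
    literal = list(intervention = z_int * (1 - r_int) + z_ref * r_ref,
                   refugia = z_ref * (1 - r_ref) + z_int * r_int),
    normalised = list(
      intervention = (z_int * (1 - r_int) + z_ref * r_ref) /
        (1 - r_int + r_ref),
      refugia = (z_ref * (1 - r_ref) + z_int * r_int) /
        (1 - r_ref + r_int)))
  out
}
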