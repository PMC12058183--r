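# Within-generation selection differentials and the sex-specific response.

test_that("hatching distribution is a discretised normal split 1:1 by sex", {
  d <- hatch_distribution(100, 30)
  expect_equal(sum(d$freq_female), 0.5)
  expect_equal(sum(d$freq_male), 0.5)
  m <- sum((d$freq_female + d$freq_male) * d$grid)
  expect_lt(abs(m - 100), 1e-6 * 30)
  # grid refinement leaves the mean essentially unchanged
  d2 <- hatch_distribution(100, 30, n_bins = 4001)
  m2 <- sum((d2$freq_female + d2$freq_male) * d2$grid)
  expect_lt(abs(m2 - m), 1e-8)
})

test_that("truncation intensity matches the closed forms", {
  expect_equal(truncation_intensity(1), 0)
  expect_equal(truncation_intensity(0.5), sqrt(2 / pi), tolerance = 1e-6)
  expect_equal(truncation_intensity(0.1), 1.75498, tolerance = 1e-4)
  expect_error(truncation_intensity(0), "die")
})

test_that("truncation selection shifts the survivor mean by sigma times
           the intensity and scales counts by survival", {
  ex <- exposure_params(x = 1, m = 0)
  out <- truncation_selection(100, 30, 0.5, ex)
  expect_equal(out$z_exposed_mean[["female"]], 123.937, tolerance = 1e-3)
  # no selection when everyone survives
  out1 <- truncation_selection(100, 30, 1, exposure_params(0.6, 0.5),
                               n_total = c(female = 0.5, male = 0.5))
  expect_equal(out1$z_exposed_mean[["female"]], 100)
  expect_equal(out1$n_exposed[["female"]], 0.6 * 0.5)
  # mixture: counts multiply the partner's survival
  mix <- truncation_selection(100, 30, 0.5, exposure_params(1, 0),
                              n_total = c(female = 1000, male = 1000),
                              partner_survival = 0.4)
  expect_equal(mix$n_exposed[["female"]], 200)
})

test_that("probabilistic selection reproduces the two-bin worked example", {
  d <- trait_distribution(c(0, 200), c(0.5, 0.5))
  K <- survival_on_grid(d$grid, insecticide("i"))
  expect_equal(K, c(0.15, 0.48 * (200 / 1100) + 0.15))
  out <- probabilistic_selection(d, K, exposure_params(1, 0))
  expect_equal(out$n_exposed[["female"]], 0.19364, tolerance = 1e-4)
  expect_equal(out$z_exposed_mean[["female"]], 122.53, tolerance = 1e-3)
})

test_that("constant per-bin survival applies no selection", {
  d <- hatch_distribution(80, 25, n_bins = 501)
  out <- probabilistic_selection(d, rep(0.4, 501), exposure_params(0.7, 0.7))
  expect_equal(out$z_exposed_mean[["female"]], 80, tolerance = 1e-8)
  expect_equal(out$z_exposed_mean[["male"]], 80, tolerance = 1e-8)
})

test_that("step-function survival converges to the truncation result", {
  K <- 0.3
  mu <- 100
  sig <- 30
  q <- qnorm(1 - K, mu, sig)
  d <- hatch_distribution(mu, sig, n_bins = 4000)
  step <- ifelse(d$grid >= q, 0.7, 0)
  out <- probabilistic_selection(d, step, exposure_params(1, 0))
  zE_trunc <- mu + sig * truncation_intensity(K)
  expect_lt(abs(out$z_exposed_mean[["female"]] / zE_trunc - 1), 0.005)
})

test_that("parental pool combines survivors and avoiders (worked example)", {
  d <- trait_distribution(c(0, 200), c(0.5, 0.5))
  K <- survival_on_grid(d$grid, insecticide("i"))
  ex <- exposure_params(0.5, 0)
  out <- parental_pool(probabilistic_selection(d, K, ex), 100, ex,
                       n_total = c(female = 1, male = 1))
  expect_equal(out$n_exposed[["female"]], 0.096818, tolerance = 1e-4)
  expect_equal(out$n_unexposed[["female"]], 0.5)
  expect_equal(out$z_parent_mean[["female"]], 103.66, tolerance = 1e-3)
  expect_equal(out$S_insecticide[["female"]], 3.66, tolerance = 1e-2)
  # nobody exposed: no insecticide selection
  ex0 <- exposure_params(0, 0.5)
  out0 <- parental_pool(probabilistic_selection(d, K, ex0), 100, ex0,
                        n_total = c(female = 1, male = 1))
  expect_equal(out0$S_insecticide[["female"]], 0)
  # m = 0 freezes the male differential regardless of female exposure
  expect_equal(out$S_insecticide[["male"]], 0)
})

test_that("parent counts conserve exposed plus unexposed", {
  set.seed(42)
  for (rep in 1:25) {
    x <- runif(1)
    m <- runif(1)
    mu <- runif(1, 0, 400)
    sig <- runif(1, 5, 80)
    om <- runif(1, 0.2, 1.5)
    ex <- exposure_params(x, m)
    d <- hatch_distribution(mu, sig, n_bins = 501)
    K <- survival_on_grid(d$grid, insecticide("i"), om)
    out <- parental_pool(probabilistic_selection(d, K, ex), mu, ex)
    expect_equal(out$n_parents, out$n_exposed + out$n_unexposed,
                 tolerance = 1e-12)
    # survival non-decreasing in PRS and x > 0 imply non-negative selection
    if (x > 0) expect_gte(out$S_insecticide[["female"]], 0)
  }
})

test_that("fitness costs reduce the mean, on either scale", {
  expect_equal(fitness_cost_differential(fitness_cost("fixed", 0, 0)),
               c(female = 0, male = 0))
  expect_equal(fitness_cost_differential(fitness_cost("fixed", 0.2, 0.3)),
               c(female = -0.2, male = -0.3))
  expect_equal(
    fitness_cost_differential(fitness_cost("scaled", 0.01, 0.02), sigma = 30),
    c(female = -0.3, male = -0.6))
})

test_that("the sex-specific response is linear and gated by heritability", {
  expect_equal(breeders_response(0, 0, genetics_params(0.2, 1)), 0)
  expect_equal(breeders_response(0.3, 0.1, genetics_params(0.2, 1)), 0.04)
  g1 <- genetics_params(0.2, 2)
  expect_equal(breeders_response(0.3, 0.1, g1),
               2 * breeders_response(0.3, 0.1, genetics_params(0.2, 1)))
  expect_equal(breeders_response(5, 3, genetics_params(0, 4)), 0)
})
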