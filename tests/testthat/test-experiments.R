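test_that("latin hypercube draws occupy every stratum exactly once", {
  set.seed(51)
  n <- 100
  ranges <- list(gamma = c(0.5, 1), S = c(0, 0.5), theta = c(0.05, 5))
  x <- lhs_sample(n, ranges)
  expect_identical(dim(x), c(100L, 3L))
  for (v in names(ranges)) {
    lo <- ranges[[v]][1]; hi <- ranges[[v]][2]
    expect_true(all(x[[v]] >= lo & x[[v]] <= hi))
    strata <- floor((x[[v]] - lo) / (hi - lo) * n)
    expect_identical(sort(strata), as.numeric(0:(n - 1)))
  }
  one <- lhs_sample(1, ranges)
  expect_true(all(mapply(function(v, r) v >= r[1] && v <= r[2], one, ranges)))
})

test_that("latin hypercube samples are stratified-uniform in expectation", {
  set.seed(52)
  x <- lhs_sample(10000, list(gamma = c(0.5, 1)))
  expect_equal(mean(x$gamma), 0.75, tolerance = 0.005)
})

test_that("evolutionary rate sums absolute phenotype steps", {
  expect_identical(evolutionary_rate(rep(0.5, 50)), 0)
  expect_equal(evolutionary_rate(rep(c(0.4, 0.6), 25)), 49 * 0.2)
  # telescoping: a monotone path's rate is the endpoint distance
  expect_equal(evolutionary_rate(seq(0.3, 0.7, length.out = 50)), 0.4)
  expect_error(evolutionary_rate(0.5), "at least 2")
})

test_that("the extinction GLM recovers known logistic coefficients", {
  set.seed(53)
  n <- 2000
  rows <- lhs_sample(n)
  b <- c(`(Intercept)` = -8, gamma = 10, S = 1.5, theta = -0.3)
  eta <- b[1] + b[2] * rows$gamma + b[3] * rows$S + b[4] * rows$theta
  rows$extinct <- runif(n) < plogis(eta)
  fit <- fit_extinction_model(rows)
  expect_false(fit$degenerate)
  co <- fit$coefficients
  for (term in names(b)) {
    i <- match(term, co$term)
    expect_lt(abs(co$estimate[i] - b[term]), 2 * co$std_error[i])
  }
  # prediction curves live on the probability scale and follow the signs
  expect_true(all(fit$curves$gamma$predicted >= 0 &
                    fit$curves$gamma$predicted <= 1))
  expect_true(all(diff(fit$curves$gamma$predicted) >= 0))
  expect_true(all(diff(fit$curves$theta$predicted) <= 0))
})

test_that("degenerate extinction tables are flagged, not fitted", {
  rows <- data.frame(gamma = runif(20, 0.5, 1), S = runif(20, 0, 0.5),
                     theta = runif(20, 0.05, 5), extinct = FALSE)
  fit <- fit_extinction_model(rows)
  expect_true(fit$degenerate)
  expect_identical(nrow(fit$coefficients), 0L)
})

test_that("separated data fall back to a flagged penalised fit", {
  set.seed(54)
  rows <- lhs_sample(200)
  rows$extinct <- rows$gamma > 0.75  # perfectly separable in gamma
  fit <- fit_extinction_model(rows)
  expect_true(fit$penalized)
  expect_true(all(is.finite(fit$coefficients$estimate)))
  expect_gt(fit$coefficients$estimate[fit$coefficients$term == "gamma"], 0)
  expect_true(all(diff(fit$curves$gamma$predicted) >= 0))
})

test_that("the prevalence linear model recovers a planted surface", {
  set.seed(55)
  rows <- lhs_sample(1000)
  rows$mean_prevalence <- 0.1 + 0.6 * rows$gamma - 0.2 * rows$S +
    rnorm(1000, sd = 0.02)
  fit <- fit_prevalence_model(rows)
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "gamma"], 0.6, tolerance = 0.02)
  expect_equal(co$estimate[co$term == "S"], -0.2, tolerance = 0.05)
})

test_that("the polynomial smoother recovers a known quartic and its slope", {
  set.seed(56)
  x <- runif(500, -2, 3)
  f <- function(x) 1 - 0.5 * x + 0.3 * x^2 - 0.1 * x^3 + 0.02 * x^4
  y <- f(x) + rnorm(500, sd = 0.01)
  fit <- fit_growth_polynomial(x, y)
  xs <- seq(-1.5, 2.5, length.out = 21)
  expect_equal(poly_predict(fit, xs), f(xs), tolerance = 0.01)
  slope_true <- -0.5 + 0.6 * xs - 0.3 * xs^2 + 0.08 * xs^3
  sl <- poly_slope(fit, xs)
  expect_equal(sl$slope, slope_true, tolerance = 0.05)
  expect_true(all(sl$se > 0))
})

test_that("sensitivity runs without the microbe never go extinct", {
  sens <- sensitivity_experiment(
    scenario = "high", mode = "cyclical", n_reps = 8, n_generations = 15,
    base_seed = 61, ranges = param_ranges()[c("S", "theta")],
    fixed = list(gamma = 0, init_prevalence = 0),
    params = sim_params(init_size = 200))
  expect_identical(sum(sens$rows$extinct), 0L)
  expect_true(all(sens$rows$gamma == 0))
  expect_true(all(sens$rows$mean_prevalence == 0))
  expect_true(sens$extinction_fit$degenerate)
})

test_that("experiment tables are reproducible and carry distinct seeds", {
  a <- ecological_experiment(gammas = 0.9, scenarios = "high",
                             n_generations = 10, n_reps = 3, base_seed = 62,
                             params = sim_params(init_size = 200))
  b <- ecological_experiment(gammas = 0.9, scenarios = "high",
                             n_generations = 10, n_reps = 3, base_seed = 62,
                             params = sim_params(init_size = 200))
  expect_identical(a, b)
  expect_identical(sort(unique(a$seed)), 62 + 1:3)
})

test_that("evolutionary experiment summarises cells and flags exclusions", {
  tab <- evolutionary_experiment(
    scenarios = c("constant", "high"), gammas = 0.5, n_reps = 4,
    n_generations = 12, base_seed = 63, params = sim_params(init_size = 200))
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$n_used + tab$n_excluded == tab$n_reps))
  expect_true(all(tab$mean_rate[!tab$all_extinct] >= 0))
})
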