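test_that("founding population honours prevalence and phenotype mode", {
  set.seed(41)
  p0 <- initialize_population(quick_params(init_prevalence = 0))
  expect_identical(sum(p0$infected), 0L)

  p1 <- initialize_population(quick_params(init_prevalence = 1))
  expect_true(all(p1$infected[p1$sex == "female"]))
  expect_false(any(p1$infected[p1$sex == "male"]))

  pm <- initialize_population(
    quick_params(init_phenotype_mode = "matched"), env_scenario("constant"))
  expect_true(all(pm$phenotype == 0.5))

  big <- initialize_population(sim_params(init_size = 10000))
  expect_equal(mean(big$sex == "male"), 0.5, tolerance = 0.02)

  expect_error(sim_params(init_size = 1), "init_size")
})

test_that("a perfectly adapted uninfected season has no adult deaths", {
  set.seed(42)
  p <- sim_params(gamma = 0, phi = 0, S = 0, init_prevalence = 0)
  adults <- make_adults(rep(0.5, 400), rep(c(TRUE, FALSE), 200))
  out <- run_season(adults, E = 0.5, p)
  expect_false(out$extinct)
  rec <- out$record
  # with D = 0 the number of broods is the number of matings, J = sigma * matings
  expect_identical(rec$n_juveniles, rec$matings * p$sigma)
  expect_gt(rec$matings, 0)
  expect_lte(rec$matings, rec$n_females_start * p$delta)
  # next cohort is the binomially culled juvenile pool
  J <- rec$n_juveniles
  expected <- J * (1 - juvenile_death_prob(J, p$X))
  expect_lt(abs(nrow(out$adults) - expected), 5 * sqrt(expected))
  # all offspring of matched uninfected parents share the midpoint phenotype
  expect_true(all(out$adults$phenotype == 0.5))
  expect_false(any(out$adults$infected))
})

test_that("a single-sex cohort is a contract violation for run_season", {
  adults <- make_adults(runif(10), rep(TRUE, 10))
  expect_error(run_season(adults, 0.5, quick_params()), "each sex")
})

test_that("certain transmission from a lone infected female dooms the line", {
  set.seed(43)
  p <- sim_params(gamma = 1, phi = 0, init_size = 20)
  adults <- make_adults(rep(0.5, 21), c(rep(TRUE, 20), FALSE),
                        c(rep(FALSE, 20), TRUE))
  out <- run_season(adults, E = 0.5, p)
  expect_gt(nrow(out$adults), 0)
  # every surviving juvenile is an infected female -> extinct next season
  expect_true(all(out$adults$infected))
  expect_true(all(out$adults$sex == "female"))
  expect_true(out$extinct)  # the all-female cohort cannot breed
  # and a full simulation attributes extinction to the failing census
  tr <- run_simulation(sim_params(gamma = 1, init_prevalence = 1, phi = 0,
                                  init_size = 50, n_generations = 10,
                                  init_phenotype_mode = "matched"),
                       env_scenario("constant"), seed = 13)
  expect_true(tr$extinct)
  expect_lte(tr$extinction_generation, 3)
})

test_that("trajectories are deterministic given a seed", {
  p <- quick_params(gamma = 0.9)
  t1 <- run_simulation(p, env_scenario("moderate"), seed = 7)
  t2 <- run_simulation(p, env_scenario("moderate"), seed = 7)
  expect_identical(t1$records, t2$records)
  expect_identical(t1$extinct, t2$extinct)
})

test_that("infection never appears in males and dies with gamma = 0", {
  set.seed(44)
  p <- quick_params(gamma = 0.9, init_prevalence = 0.3)
  env <- env_scenario("moderate")
  adults <- initialize_population(p, env)
  for (t in 1:8) {
    out <- run_season(adults, environment_value(t, env), p, generation = t)
    if (out$extinct || sum(out$adults$sex == "male") < 1 ||
        sum(out$adults$sex == "female") < 1) break
    adults <- out$adults
    expect_false(any(adults$infected & adults$sex == "male"))
  }

  tr0 <- run_simulation(quick_params(gamma = 0, init_prevalence = 0),
                        env_scenario("constant"), seed = 5)
  expect_false(tr0$extinct)
  expect_true(all(tr0$records$prevalence == 0))
  # with infected founders but no transmission, prevalence is 0 after gen 1
  trf <- run_simulation(quick_params(gamma = 0, init_prevalence = 0.5),
                        env_scenario("constant"), seed = 6)
  expect_true(all(trf$records$prevalence[-1] == 0))
})

test_that("an empty horizon yields an empty, non-extinct trajectory", {
  tr <- run_simulation(quick_params(n_generations = 0),
                       env_scenario("constant"), seed = 1)
  expect_identical(nrow(tr$records), 0L)
  expect_false(tr$extinct)
})

test_that("uninfected populations are regulated near the competition scale", {
  p <- sim_params(gamma = 0, init_prevalence = 0, n_generations = 60)
  tr <- run_simulation(p, env_scenario("constant"), seed = 8)
  expect_false(tr$extinct)
  r <- tr$records[tr$records$generation > 10, ]
  # adult counts fluctuate below a ceiling ~ X and the sex ratio is even
  expect_gt(mean(r$n_adults_start), 0.3 * p$X)
  expect_lt(mean(r$n_adults_start), 1.3 * p$X)
  expect_equal(mean(r$osr), 1, tolerance = 0.15)
  expect_true(all(r$matings <= r$n_females_start * p$delta))
})

test_that("season records are internally consistent", {
  tr <- run_simulation(quick_params(gamma = 0.8), env_scenario("high"),
                       seed = 9)
  r <- tr$records
  expect_true(all(r$n_males_start + r$n_females_start == r$n_adults_start))
  expect_true(all(r$prevalence >= 0 & r$prevalence <= 1))
  expect_true(all(r$n_infected_start <= r$n_females_start))
  expect_true(all(is.na(r$osr) | r$osr > 0))
  expect_identical(r$generation, seq_len(nrow(r)))
})

test_that("trajectories serialise to a commented CSV round-trip", {
  tr <- run_simulation(quick_params(n_generations = 5, gamma = 0,
                                    init_prevalence = 0),
                       env_scenario("constant"), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read.csv(path, comment.char = "#")
  expect_equal(back$n_adults_start, tr$records$n_adults_start)
  expect_equal(back$mean_phenotype, tr$records$mean_phenotype)
})
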