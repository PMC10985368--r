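#' Latin hypercube sample over parameter ranges
#'
#' Stratified multivariate sampling: each dimension is partitioned into `n`
#' equal strata and exactly one draw falls in each stratum per dimension,
#' with strata paired across dimensions by independent random permutations.
#'
#' @param n Number of draws (>= 1).
#' @param ranges Named list of `c(lo, hi)` ranges, one per parameter;
#'   defaults to the standard sensitivity ranges for `gamma`, `S`, `theta`.
#' @return Data frame with `n` rows and one column per parameter.
#' @examples
#' set.seed(1)
#' lhs_sample(5, list(gamma = c(0.5, 1), theta = c(0.05, 5)))
#' @export
lhs_sample <- function(n, ranges = param_ranges()) {
  stopifnot(n >= 1, length(ranges) >= 1)
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  if (any(lo >= hi)) stop("each range must satisfy lo < hi", call. = FALSE)
  u <- lhs::randomLHS(n, length(ranges))
  out <- as.data.frame(sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+"))
  names(out) <- names(ranges)
  out
}

# Build a replicate's parameter set from base params plus overrides.
params_with <- function(params, overrides) {
  p <- unclass(params)
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  do.call(sim_params, p)
}

replicate_log <- function(verbose, rep, seed, traj) {
  if (verbose) {
    final_n <- if (nrow(traj$records) > 0)
      utils::tail(traj$records$n_adults_start, 1) else 0L
    message(sprintf("replicate %d seed %d extinct=%s final_N=%d",
                    rep, seed, traj$extinct, final_n))
  }
}

#' Sensitivity analysis of extinction risk
#'
#' Latin-hypercube sampling of the epidemiological parameters (vertical
#' transmission `gamma`, infection survival benefit `S`, male dispersal
#' `theta`), one parameter triple per replicate, each replicate a full
#' simulation capped at `n_generations` generations. Records whether each
#' replicate went extinct and its mean infection prevalence across realised
#' generations, then fits a binomial (logit) GLM for extinction and an
#' ordinary least-squares model for mean prevalence, each with
#' model-predicted curves per parameter.
#'
#' @param scenario Environmental scenario name (see [env_scenario()]).
#' @param mode Environmental variation mode, `"cyclical"` or `"stochastic"`.
#' @param n_reps Number of replicate simulations (default 100).
#' @param n_generations Generation cap per replicate (default 50).
#' @param base_seed Base RNG seed; replicate `i` runs with
#'   `base_seed + seed_offset + i` (recorded in the output).
#' @param ranges Named list of sampling ranges; parameters omitted here are
#'   held at their values in `params`/`fixed`.
#' @param fixed Named list of parameter overrides applied to every replicate
#'   (e.g. `list(gamma = 0, init_prevalence = 0)` for the uninfected
#'   control).
#' @param params Base [sim_params()] object supplying all other parameters.
#' @param seed_offset Added to every replicate seed (used to give experiment
#'   cells disjoint seed blocks).
#' @param verbose Emit a one-line summary per replicate.
#' @return A list of class `srdm_sensitivity`: `rows` (per-replicate table
#'   with sampled values, `extinct`, `mean_prevalence`, `seed`),
#'   `extinction_fit` and `prevalence_fit` (see [fit_extinction_model()],
#'   [fit_prevalence_model()]), plus the scenario/mode metadata.
#' @export
sensitivity_experiment <- function(scenario = "high", mode = "cyclical",
                                   n_reps = 100, n_generations = 50,
                                   base_seed = 1, ranges = param_ranges(),
                                   fixed = list(), params = sim_params(),
                                   seed_offset = 0, verbose = FALSE) {
  env <- env_scenario(scenario, mode = mode)
  set.seed(base_seed + seed_offset)
  design <- lhs_sample(n_reps, ranges)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    ov <- c(as.list(design[i, , drop = FALSE]), fixed,
            list(n_generations = n_generations))
    p_i <- params_with(params, ov)
    seed_i <- base_seed + seed_offset + i
    traj <- run_simulation(p_i, env, seed = seed_i)
    replicate_log(verbose, i, seed_i, traj)
    rows[[i]] <- data.frame(
      replicate = i, seed = seed_i,
      gamma = p_i$gamma, S = p_i$S, theta = p_i$theta,
      extinct = traj$extinct,
      mean_prevalence = mean(traj$records$prevalence))
  }
  rows <- do.call(rbind, rows)
  structure(list(rows = rows,
                 extinction_fit = fit_extinction_model(rows),
                 prevalence_fit = fit_prevalence_model(rows),
                 scenario = scenario, mode = mode,
                 n_reps = n_reps, n_generations = n_generations,
                 base_seed = base_seed),
            class = "srdm_sensitivity")
}

#' @export
print.srdm_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity experiment: scenario=%s mode=%s reps=%d\n",
              x$scenario, x$mode, x$n_reps))
  cat(sprintf("  extinctions: %d / %d\n", sum(x$rows$extinct), x$n_reps))
  print(x$extinction_fit)
  invisible(x)
}

#' Mechanistic growth-rate analysis
#'
#' Examines what drives extinction by relating per-generation population
#' growth rate, `log N[t+1] - log N[t]` (natural log), to abundance and to
#' the operational sex ratio (females per male) at emergence. Transmission
#' is fixed high (default `gamma = 0.9`) so strong sex-ratio skew is
#' realised. Consecutive-generation pairs are pooled across replicates;
#' pairs adjacent to extinction (next-generation N = 0) are excluded and
#' counted. Fourth-degree polynomial smoothers ([fit_growth_polynomial()])
#' are fitted for growth against log N and against OSR.
#'
#' @inheritParams sensitivity_experiment
#' @param n_generations Generation cap (default 100).
#' @param gamma Fixed transmission probability (default 0.9).
#' @return A list of class `srdm_mechanistic`: `rows` (replicate,
#'   generation, `N`, `logN`, `osr`, `growth`), `n_excluded` (pairs dropped
#'   at extinction boundaries), and smoothers `fit_logN`, `fit_osr`.
#' @export
mechanistic_experiment <- function(scenario = "high", mode = "cyclical",
                                   n_reps = 100, n_generations = 100,
                                   gamma = 0.9, base_seed = 1,
                                   params = sim_params(), seed_offset = 0,
                                   verbose = FALSE) {
  env <- env_scenario(scenario, mode = mode)
  p <- params_with(params, list(gamma = gamma,
                                n_generations = n_generations))
  rows <- vector("list", n_reps)
  n_excluded <- 0L
  for (i in seq_len(n_reps)) {
    seed_i <- base_seed + seed_offset + i
    traj <- run_simulation(p, env, seed = seed_i)
    replicate_log(verbose, i, seed_i, traj)
    r <- traj$records
    k <- nrow(r)
    if (traj$extinct && k >= 1) n_excluded <- n_excluded + 1L
    if (k >= 2) {
      N <- r$n_adults_start
      rows[[i]] <- data.frame(
        replicate = i, seed = seed_i, generation = r$generation[-k],
        N = N[-k], logN = log(N[-k]), osr = r$osr[-k],
        growth = log(N[-1]) - log(N[-k]))
    }
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) < 6)
    stop("too few generation pairs for the mechanistic analysis",
         call. = FALSE)
  structure(list(rows = rows, n_excluded = n_excluded,
                 fit_logN = fit_growth_polynomial(rows$logN, rows$growth),
                 fit_osr = fit_growth_polynomial(rows$osr, rows$growth),
                 scenario = scenario, mode = mode, gamma = gamma,
                 n_reps = n_reps, base_seed = base_seed),
            class = "srdm_mechanistic")
}

#' @export
print.srdm_mechanistic <- function(x, ...) {
  cat(sprintf(
    "Mechanistic experiment: scenario=%s gamma=%g, %d pairs (%d excluded at extinction)\n",
    x$scenario, x$gamma, nrow(x$rows), x$n_excluded))
  invisible(x)
}

#' Rate of phenotypic evolution of a trajectory
#'
#' Sums the absolute generation-to-generation change in the population mean
#' phenotype, \eqn{\sum_i |\bar P_i - \bar P_{i+1}|}, over the realised
#' generations. Zero if and only if the mean phenotype never changes.
#'
#' @param x An `srdm_trajectory`, or a numeric vector of per-generation mean
#'   phenotypes (length >= 2).
#' @return Non-negative scalar.
#' @examples
#' evolutionary_rate(c(0.4, 0.6, 0.4, 0.6))  # 3 x 0.2
#' @export
evolutionary_rate <- function(x) {
  if (inherits(x, "srdm_trajectory")) x <- x$records$mean_phenotype
  if (!is.numeric(x) || length(x) < 2)
    stop("need at least 2 generations of mean phenotype", call. = FALSE)
  sum(abs(diff(x)))
}

#' Evolutionary-rate experiment
#'
#' Measures how environmental variation and transmission rate affect the
#' rate of host phenotypic evolution. For each (scenario, gamma) cell,
#' replicates are run for `n_generations` generations and the mean and
#' standard deviation of [evolutionary_rate()] are reported. Replicates that
#' went extinct before completing the protocol are excluded and counted
#' (their truncated sums are not comparable); cells with no surviving
#' replicates are flagged.
#'
#' @inheritParams sensitivity_experiment
#' @param scenarios Character vector of scenario names.
#' @param gammas Transmission probabilities to cross with the scenarios.
#' @return Data frame with one row per (scenario, gamma) cell: `mean_rate`,
#'   `sd_rate`, `n_used`, `n_excluded`, `all_extinct`.
#' @export
evolutionary_experiment <- function(scenarios = c("constant", "moderate", "high"),
                                    gammas = c(0.2, 0.5, 0.8),
                                    n_reps = 100, n_generations = 50,
                                    mode = "cyclical", base_seed = 1,
                                    params = sim_params(), verbose = FALSE) {
  cells <- expand.grid(scenario = scenarios, gamma = gammas,
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    sc <- cells$scenario[ci]
    g <- cells$gamma[ci]
    env <- env_scenario(sc, mode = mode)
    p <- params_with(params, list(gamma = g, n_generations = n_generations))
    rates <- rep(NA_real_, n_reps)
    for (i in seq_len(n_reps)) {
      seed_i <- base_seed + (ci - 1L) * n_reps + i
      traj <- run_simulation(p, env, seed = seed_i)
      replicate_log(verbose, i, seed_i, traj)
      if (!traj$extinct && nrow(traj$records) >= 2)
        rates[i] <- evolutionary_rate(traj)
    }
    used <- rates[!is.na(rates)]
    out[[ci]] <- data.frame(
      scenario = sc, gamma = g, n_reps = n_reps, n_used = length(used),
      n_excluded = n_reps - length(used),
      mean_rate = if (length(used)) mean(used) else NA_real_,
      sd_rate = if (length(used) > 1) stats::sd(used) else NA_real_,
      all_extinct = length(used) == 0)
  }
  do.call(rbind, out)
}

#' Ecological trajectory runs
#'
#' Runs the model across a grid of transmission rates and environmental
#' scenarios and returns tidy per-generation observables (population size,
#' mating rate per female per season, infection prevalence) suitable for
#' graphical analysis. No statistical fitting is performed.
#'
#' @inheritParams evolutionary_experiment
#' @param n_generations Generations per replicate (default 100).
#' @param n_reps Replicates per (gamma, scenario) cell.
#' @return Data frame with columns `scenario`, `gamma`, `replicate`, `seed`,
#'   `generation`, `E`, `N`, `mating_rate`, `prevalence`, `extinct`.
#' @export
ecological_experiment <- function(gammas = c(0, 0.5, 0.9),
                                  scenarios = c("constant", "moderate", "high"),
                                  mode = "cyclical", n_generations = 100,
                                  n_reps = 20, base_seed = 1,
                                  params = sim_params(), verbose = FALSE) {
  cells <- expand.grid(scenario = scenarios, gamma = gammas,
                       stringsAsFactors = FALSE)
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    sc <- cells$scenario[ci]
    g <- cells$gamma[ci]
    env <- env_scenario(sc, mode = mode)
    p <- params_with(params, list(gamma = g, n_generations = n_generations))
    for (i in seq_len(n_reps)) {
      seed_i <- base_seed + (ci - 1L) * n_reps + i
      traj <- run_simulation(p, env, seed = seed_i)
      replicate_log(verbose, i, seed_i, traj)
      r <- traj$records
      if (nrow(r) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        scenario = sc, gamma = g, replicate = i, seed = seed_i,
        generation = r$generation, E = r$E, N = r$n_adults_start,
        mating_rate = r$matings_per_female, prevalence = r$prevalence,
        extinct = traj$extinct)
    }
  }
  do.call(rbind, out)
}
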