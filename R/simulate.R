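#' Create a founding adult population
#'
#' Founders are sexed by a fair coin; a fraction `init_prevalence` of females
#' carry the infection (males are never infected, since the microbe is
#' maternally inherited and infected offspring are all female). Phenotypes are
#' drawn uniformly on \[0, 1\] (`init_phenotype_mode = "uniform"`) or all set
#' to the first generation's environmental optimum (`"matched"`).
#'
#' @param params An [sim_params()] object.
#' @param env An [env_config()] object; only consulted in `"matched"` mode to
#'   locate the initial optimum (the band midpoint is used in stochastic
#'   mode).
#' @return A data frame with one row per adult and columns `phenotype`
#'   (numeric), `sex` (`"male"`/`"female"`) and `infected` (logical).
#' @examples
#' set.seed(1)
#' pop <- initialize_population(sim_params(init_size = 100))
#' table(pop$sex)
#' @export
initialize_population <- function(params, env = env_scenario("constant")) {
  stopifnot(inherits(params, "srdm_params"))
  n <- as.integer(params$init_size)
  if (n < 2) stop("'init_size' must be >= 2", call. = FALSE)
  male <- stats::runif(n) < 0.5
  phenotype <- if (params$init_phenotype_mode == "matched") {
    e0 <- if (env$mode == "stochastic") (env$U + env$L) / 2
          else environment_value(1, env)
    rep(e0, n)
  } else {
    stats::runif(n)
  }
  infected <- !male & stats::runif(n) < params$init_prevalence
  data.frame(phenotype = phenotype,
             sex = ifelse(male, "male", "female"),
             infected = infected)
}

# One-row emergence census of an adult cohort.
emergence_record <- function(generation, E, phenotype, male, infected) {
  n <- length(phenotype)
  M <- sum(male)
  Fem <- n - M
  list(generation = generation, E = E, n_adults_start = n,
       n_males_start = M, n_females_start = Fem,
       n_infected_start = sum(infected),
       prevalence = if (n > 0) sum(infected) / n else NA_real_,
       osr = if (M > 0) Fem / M else NA_real_,
       matings = 0L, matings_per_female = NA_real_,
       mean_phenotype = if (n > 0) mean(phenotype) else NA_real_,
       n_juveniles = NA_real_)
}

#' Simulate one breeding season
#'
#' Runs the daily cycle for `delta` days: (1) every adult survives the day
#' with its phenotype-mismatch death probability ([adult_death_prob()], fixed
#' within the season since both P and E are fixed); (2) the daily encounter
#' probability m is computed from the living sex counts
#' ([mate_encounter_prob()]); (3) each living female independently mates with
#' probability m, at most once per day, with a father drawn uniformly from
#' the males alive that day; (4) each mating adds a brood of `sigma`
#' offspring laid at the end of the day. If either sex runs out of living
#' adults mid-season, mating ceases for the remainder of the season, but
#' broods already laid are unaffected: since generations are non-overlapping
#' and every adult is removed at season end regardless, adult die-off within
#' a season carries no consequence beyond the loss of further matings.
#' After day `delta` the pooled juveniles suffer one density-dependent cull
#' at probability `J/(J + X)`, and the survivors emerge as the next season's
#' adults. Population extinction is assessed on the emerging cohort (see
#' [run_simulation()]): a next generation lacking either sex cannot breed.
#'
#' Offspring attributes (maternal infection transmitted with probability
#' `gamma`, infected offspring all female, uninfected offspring sexed by a
#' fair coin, midparent phenotype with mutation probability `phi`) are
#' independent of the cull, so survivor attributes are drawn directly — an
#' exact, distribution-preserving shortcut around materialising every
#' juvenile.
#'
#' @param adults Adult cohort data frame as from [initialize_population()];
#'   must contain at least one individual of each sex.
#' @param E Environmental optimum for this season, in \[0, 1\].
#' @param params An [sim_params()] object.
#' @param generation Generation index stored in the returned record.
#' @return A list with elements `adults` (next season's cohort, possibly
#'   empty), `record` (one-row data frame of emergence-time observables plus
#'   season totals) and `extinct` (logical: the next cohort is empty or
#'   single-sex, so it cannot found a further generation).
#' @examples
#' set.seed(1)
#' p <- sim_params(init_size = 200)
#' pop <- initialize_population(p)
#' out <- run_season(pop, E = 0.5, params = p)
#' out$record
#' @export
run_season <- function(adults, E, params, generation = NA_integer_) {
  stopifnot(inherits(params, "srdm_params"))
  phen <- adults$phenotype
  male <- adults$sex == "male"
  inf <- adults$infected
  if (sum(male) < 1 || sum(!male) < 1)
    stop("'adults' must contain at least one individual of each sex",
         call. = FALSE)

  rec <- emergence_record(generation, E, phen, male, inf)

  # P and E are fixed within a season, so each adult's daily death
  # probability is a season constant.
  D <- adult_death_prob(phen, E, params$c, ifelse(inf, params$S, 0))

  mother_P <- vector("list", params$delta)
  father_P <- vector("list", params$delta)
  mother_inf <- vector("list", params$delta)
  matings <- 0L

  for (day in seq_len(params$delta)) {
    alive <- stats::runif(length(phen)) >= D
    phen <- phen[alive]; male <- male[alive]; inf <- inf[alive]; D <- D[alive]
    M <- sum(male)
    Fem <- length(phen) - M
    # once a sex is depleted no further matings can occur this season, and
    # adult fates no longer matter (all adults are removed at season end)
    if (M < 1 || Fem < 1) break
    m <- mate_encounter_prob(M, Fem, params$theta, params$beta, params$delta)
    mated <- stats::runif(Fem) < m
    nm <- sum(mated)
    if (nm > 0) {
      fem_idx <- which(!male)[mated]
      male_idx <- which(male)
      dads <- male_idx[sample.int(M, nm, replace = TRUE)]
      mother_P[[day]] <- phen[fem_idx]
      father_P[[day]] <- phen[dads]
      mother_inf[[day]] <- inf[fem_idx]
      matings <- matings + nm
    }
  }

  rec$matings <- matings
  rec$matings_per_female <- matings / rec$n_females_start

  empty <- adults[0, , drop = FALSE]
  momP <- unlist(mother_P, use.names = FALSE)
  n_broods <- length(momP)
  J <- n_broods * params$sigma
  rec$n_juveniles <- J
  if (n_broods == 0L)
    return(list(adults = empty, record = as.data.frame(rec), extinct = TRUE))

  dadP <- unlist(father_P, use.names = FALSE)
  momI <- unlist(mother_inf, use.names = FALSE)
  d <- juvenile_death_prob(J, params$X)
  surv <- stats::rbinom(n_broods, params$sigma, 1 - d)
  ns <- sum(surv)
  if (ns == 0L)
    return(list(adults = empty, record = as.data.frame(rec), extinct = TRUE))

  momP <- rep.int(momP, surv)
  dadP <- rep.int(dadP, surv)
  momI <- rep.int(momI, surv)
  child_inf <- momI & stats::runif(ns) < params$gamma
  child_male <- !child_inf & stats::runif(ns) < 0.5
  child_P <- offspring_phenotype(momP, dadP, params$phi)
  nxt <- data.frame(phenotype = child_P,
                    sex = ifelse(child_male, "male", "female"),
                    infected = child_inf)
  n_males_next <- sum(child_male)
  list(adults = nxt, record = as.data.frame(rec),
       extinct = n_males_next < 1 || ns - n_males_next < 1)
}

#' Run a multi-generation simulation
#'
#' Iterates [environment_value()] and [run_season()] for `n_generations`
#' breeding seasons or until extinction. The population is extinct when an
#' emerging adult cohort has fewer than one individual of either sex: a
#' season yielding no surviving juveniles, or survivors of only one sex, is
#' extinct at the next season's start (within a season, loss of a sex merely
#' ends mating for that season — see [run_season()]). All per-generation
#' observables are censused at adult emergence, before any mortality; an
#' extinct generation's record (if the terminal cohort is non-empty) keeps
#' its emergence-time observables.
#'
#' @param params An [sim_params()] object (`n_generations` is taken from it).
#' @param env An [env_config()] or [env_scenario()] object.
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called so
#'   the trajectory is fully reproducible.
#' @return An object of class `srdm_trajectory`: a list with `records` (data
#'   frame, one row per realised generation), `extinct` (logical),
#'   `extinction_generation` (integer or `NA`), and the `params`, `env` and
#'   `seed` used.
#' @examples
#' tr <- run_simulation(sim_params(gamma = 0, init_prevalence = 0,
#'                                 n_generations = 10),
#'                      env_scenario("constant"), seed = 1)
#' tr$extinct
#' head(tr$records)
#' @export
run_simulation <- function(params, env = env_scenario("constant"),
                           seed = NULL) {
  stopifnot(inherits(params, "srdm_params"), inherits(env, "srdm_env"))
  if (!is.null(seed)) set.seed(seed)
  adults <- initialize_population(params, env)
  records <- vector("list", params$n_generations)
  extinct <- FALSE
  ext_gen <- NA_integer_
  n_rec <- 0L
  for (t in seq_len(params$n_generations)) {
    male <- adults$sex == "male"
    if (sum(male) < 1 || sum(!male) < 1) {
      extinct <- TRUE
      ext_gen <- t
      if (nrow(adults) > 0) {
        E <- environment_value(t, env)
        n_rec <- n_rec + 1L
        records[[n_rec]] <- as.data.frame(
          emergence_record(t, E, adults$phenotype, male, adults$infected))
      }
      break
    }
    E <- environment_value(t, env)
    out <- run_season(adults, E, params, generation = t)
    n_rec <- n_rec + 1L
    records[[n_rec]] <- out$record
    adults <- out$adults
  }
  recs <- if (n_rec > 0) do.call(rbind, records[seq_len(n_rec)]) else
    as.data.frame(emergence_record(1L, 0.5, c(0.5, 0.5), c(TRUE, FALSE),
                                   c(FALSE, FALSE)))[0, ]
  structure(list(records = recs, extinct = extinct,
                 extinction_generation = ext_gen,
                 params = params, env = env, seed = seed),
            class = "srdm_trajectory")
}

#' @export
print.srdm_trajectory <- function(x, ...) {
  cat(sprintf(
    "Simulation trajectory: %d generation(s) recorded; %s\n",
    nrow(x$records),
    if (x$extinct) sprintf("EXTINCT at generation %d", x$extinction_generation)
    else "population persisted"))
  invisible(x)
}

#' @export
as.data.frame.srdm_trajectory <- function(x, ...) x$records

#' Serialise a trajectory to a delimited table
#'
#' Writes one row per generation with a provenance comment header (package
#' version, seed, extinction status). The file round-trips through
#' `read.csv(..., comment.char = "#")`.
#'
#' @param traj An `srdm_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "srdm_trajectory"))
  hdr <- c(
    sprintf("# srdmsim %s trajectory", as.character(utils::packageVersion("srdmsim"))),
    sprintf("# seed: %s", if (is.null(traj$seed)) "NA" else traj$seed),
    sprintf("# env: mode=%s U=%g L=%g R=%g", traj$env$mode, traj$env$U,
            traj$env$L, traj$env$R),
    sprintf("# extinct: %s  extinction_generation: %s", traj$extinct,
            traj$extinction_generation))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(traj$records, con, row.names = FALSE)
  invisible(path)
}
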