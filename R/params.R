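#' Simulation parameters
#'
#' Constructs and validates the full parameter set of the individual-based
#' model. Defaults follow the model's standard parameterisation: a 90-day
#' breeding season, selection coefficient 0.2, brood size 50, four lifetime
#' matings per female when males are in excess, mutation probability 0.01 and
#' juvenile competition parameter 500.
#'
#' @param delta Breeding season length in days (\eqn{\delta}). Must exceed
#'   `beta` so that the daily mate-encounter probability never exceeds 1.
#' @param c Selection coefficient controlling how steeply adult daily death
#'   probability rises with phenotype-environment mismatch.
#' @param S Proportional survival benefit of infection, in \[0, 0.5\]. Applied
#'   to infected adults only; uninfected adults always experience `S = 0`.
#' @param theta Male dispersal parameter (\eqn{\theta}), in \[0.05, 5\]. Larger
#'   values mean poorer effective dispersal and lower female encounter rates.
#' @param beta Average number of lifetime matings per female when males are in
#'   excess (\eqn{\beta}).
#' @param sigma Brood size (\eqn{\sigma}): offspring laid per mating.
#' @param gamma Vertical transmission probability (\eqn{\gamma}) in \[0, 1\]:
#'   the probability that an offspring of an infected mother inherits the
#'   infection (and therefore develops as a female).
#' @param phi Mutation probability (\eqn{\phi}): an offspring is a mutant with
#'   probability `phi` and then draws its phenotype uniformly on \[0, 1\]
#'   instead of inheriting the parental midpoint.
#' @param X Juvenile competition parameter: density-dependent juvenile death
#'   probability is `J / (J + X)` for `J` pooled juveniles.
#' @param n_generations Number of breeding seasons to simulate.
#' @param init_size Number of adults founding the population.
#' @param init_prevalence Fraction of founding females carrying the infection.
#' @param init_phenotype_mode `"uniform"` draws founder phenotypes uniformly on
#'   \[0, 1\] (supplies standing variation); `"matched"` sets every founder
#'   phenotype to the first generation's environmental optimum (useful for
#'   controlled tests with zero initial mismatch).
#'
#' @return An object of class `srdm_params`: a validated named list.
#' @examples
#' p <- sim_params(gamma = 0.7, n_generations = 50)
#' p$gamma
#' @export
sim_params <- function(delta = 90, c = 0.2, S = 0, theta = 1.5, beta = 4,
                       sigma = 50, gamma = 0.9, phi = 0.01, X = 500,
                       n_generations = 100, init_size = 500,
                       init_prevalence = 0.1,
                       init_phenotype_mode = c("uniform", "matched")) {
  init_phenotype_mode <- match.arg(init_phenotype_mode)
  p <- list(delta = delta, c = c, S = S, theta = theta, beta = beta,
            sigma = sigma, gamma = gamma, phi = phi, X = X,
            n_generations = n_generations, init_size = init_size,
            init_prevalence = init_prevalence,
            init_phenotype_mode = init_phenotype_mode)
  validate_params(p)
  structure(p, class = "srdm_params")
}

# Parameter ranges used for validation messages and for sensitivity sampling.
param_ranges <- function() {
  list(gamma = c(0.5, 1), S = c(0, 0.5), theta = c(0.05, 5))
}

validate_params <- function(p) {
  chk_num <- function(x, nm) {
    if (!is.numeric(p[[x]]) || length(p[[x]]) != 1 || !is.finite(p[[x]]))
      stop(sprintf("parameter '%s' must be a single finite number", x),
           call. = FALSE)
  }
  for (nm in setdiff(names(p), "init_phenotype_mode")) chk_num(nm, nm)
  chk_range <- function(nm, lo, hi, range_txt) {
    if (p[[nm]] < lo || p[[nm]] > hi)
      stop(sprintf("parameter '%s' = %g outside its range %s", nm, p[[nm]],
                   range_txt), call. = FALSE)
  }
  chk_range("gamma", 0, 1, "[0, 1]")
  chk_range("S", 0, 0.5, "[0, 0.5]")
  chk_range("phi", 0, 1, "[0, 1]")
  chk_range("init_prevalence", 0, 1, "[0, 1]")
  if (p$theta <= 0) stop("parameter 'theta' must be > 0 (range [0.05, 5])",
                         call. = FALSE)
  if (p$c <= 0) stop("parameter 'c' must be > 0", call. = FALSE)
  if (p$X <= 0) stop("parameter 'X' must be > 0", call. = FALSE)
  if (p$sigma < 1) stop("parameter 'sigma' must be >= 1", call. = FALSE)
  if (p$delta < 1) stop("parameter 'delta' must be >= 1", call. = FALSE)
  if (p$delta <= p$beta)
    stop("parameter 'delta' must exceed 'beta' (ensures daily encounter ",
         "probability m <= 1)", call. = FALSE)
  if (p$n_generations < 0) stop("'n_generations' must be >= 0", call. = FALSE)
  if (p$init_size < 2) stop("'init_size' must be >= 2", call. = FALSE)
  invisible(p)
}

#' @export
print.srdm_params <- function(x, ...) {
  cat("Simulation parameters (srdm_params)\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Environment configuration
#'
#' Describes how the environmental optimum E varies across generations.
#' In `cyclical` mode E follows a sine wave between the lower and upper
#' limits `L` and `U`; in `stochastic` mode E is drawn uniformly on
#' \[L, U\] each generation; in `constant` mode E is fixed at `U` (= `L`).
#'
#' @param mode One of `"cyclical"`, `"stochastic"`, `"constant"`.
#' @param U Upper limit of E, in \[0, 1\].
#' @param L Lower limit of E, in \[0, 1\]; must satisfy `L <= U`. The named
#'   scenarios use the symmetric convention `L = 1 - U`.
#' @param R Wave-frequency constant of the cyclical mode (default 10).
#' @return An object of class `srdm_env`.
#' @seealso [env_scenario()] for the named presets.
#' @examples
#' env_config("cyclical", U = 0.7, L = 0.3)
#' @export
env_config <- function(mode = c("cyclical", "stochastic", "constant"),
                       U = 0.5, L = 1 - U, R = 10) {
  if (length(mode) != 1 || !mode %in% c("cyclical", "stochastic", "constant"))
    mode <- match.arg(mode)
  if (!is.numeric(U) || !is.numeric(L) || U < 0 || U > 1 || L < 0 || L > 1)
    stop("'U' and 'L' must lie in [0, 1]", call. = FALSE)
  if (L > U) stop("'L' must not exceed 'U'", call. = FALSE)
  if (mode == "constant" && !isTRUE(all.equal(U, L)))
    stop("constant mode requires U == L", call. = FALSE)
  if (!is.numeric(R) || R <= 0) stop("'R' must be > 0", call. = FALSE)
  structure(list(mode = mode, U = U, L = L, R = R), class = "srdm_env")
}

#' Named environmental-variability scenarios
#'
#' Presets for the three standard levels of environmental variation:
#' `"constant"` (U = L = 0.5), `"moderate"` (U = 0.6, L = 0.4) and
#' `"high"` (U = 0.7, L = 0.3). `"low"` is accepted as an alias for
#' `"constant"` (the lowest-variation level).
#'
#' @param name Scenario name.
#' @param mode Variation mode passed to [env_config()]; the constant scenario
#'   is unaffected by the mode since U = L.
#' @return An `srdm_env` object.
#' @examples
#' env_scenario("high")
#' env_scenario("moderate", mode = "stochastic")
#' @export
env_scenario <- function(name = c("constant", "moderate", "high", "low"),
                         mode = "cyclical") {
  name <- match.arg(name)
  if (name == "low") name <- "constant"
  U <- switch(name, constant = 0.5, moderate = 0.6, high = 0.7)
  if (name == "constant") mode <- "constant"
  env_config(mode = mode, U = U, L = 1 - U, R = 10)
}

#' @export
print.srdm_env <- function(x, ...) {
  cat(sprintf("Environment (srdm_env): mode=%s U=%g L=%g R=%g\n",
              x$mode, x$U, x$L, x$R))
  invisible(x)
}
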