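#' Environmental optimum for a generation
#'
#' Returns the environmental state E (equal to the optimal adult phenotype)
#' for generation `t`. E is drawn once per generation and held fixed for all
#' days of that breeding season. In cyclical mode
#' \deqn{E_t = L + \frac{U-L}{2}\,(1 + \sin(t/R)),}
#' so E spans exactly \[L, U\]; in stochastic mode E is a fresh uniform draw
#' on \[L, U\]; in constant mode E = U = L.
#'
#' @param t Generation index (non-negative integer; vectorised).
#' @param cfg An [env_config()] object.
#' @return Numeric vector of environment values in \[L, U\]. Stochastic mode
#'   consumes random numbers from the R session RNG.
#' @examples
#' environment_value(0:5, env_scenario("high"))
#' @export
environment_value <- function(t, cfg) {
  if (!inherits(cfg, "srdm_env")) stop("'cfg' must be an srdm_env object",
                                       call. = FALSE)
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  switch(cfg$mode,
    cyclical = cfg$L + (cfg$U - cfg$L) / 2 * (1 + sin(t / cfg$R)),
    stochastic = stats::runif(length(t), cfg$L, cfg$U),
    constant = rep_len(cfg$U, length(t)),
    stop("invalid environment mode: ", cfg$mode, call. = FALSE)
  )
}

#' Daily adult death probability
#'
#' Adults die each day with probability determined by the mismatch between
#' their fixed phenotype P and the current environmental optimum E:
#' \deqn{D = \left(1 - \frac{1}{1 + c\,|P - E|}\right)(1 - S).}
#' D is zero exactly when the phenotype matches the optimum, increases with
#' mismatch, and is reduced proportionally by the infection survival benefit
#' S (uninfected individuals must be given `S = 0`).
#'
#' @param P Adult phenotype(s) in \[0, 1\].
#' @param E Environmental optimum in \[0, 1\].
#' @param c Selection coefficient (> 0).
#' @param S Survival benefit in \[0, 0.5\]; 0 for uninfected individuals.
#' @return Daily death probability in \[0, 1); vectorised over `P`, `E`, `S`.
#' @examples
#' adult_death_prob(P = 1, E = 0, c = 0.2, S = 0)    # maximal mismatch
#' adult_death_prob(P = 0.5, E = 0.5, c = 0.2, S = 0) # perfect match
#' @export
adult_death_prob <- function(P, E, c, S = 0) {
  if (any(P < 0 | P > 1)) stop("'P' must lie in [0, 1]", call. = FALSE)
  if (any(E < 0 | E > 1)) stop("'E' must lie in [0, 1]", call. = FALSE)
  if (any(c <= 0)) stop("'c' must be > 0", call. = FALSE)
  if (any(S < 0 | S > 0.5)) stop("'S' must lie in [0, 0.5]", call. = FALSE)
  (1 - 1 / (1 + c * abs(P - E))) * (1 - S)
}

#' Daily female mate-encounter probability
#'
#' Males are the questing sex; the probability that a given female is located
#' by a male on a given day depends on the male-to-female ratio r = M/F, not
#' on absolute male numbers:
#' \deqn{m = \frac{\beta}{\delta}\,\frac{r}{r + \theta}.}
#' Because \eqn{\delta > \beta}, m never exceeds 1; it decreases with the
#' dispersal parameter \eqn{\theta} and vanishes when no males remain.
#'
#' @param M Number of living males (>= 0).
#' @param F_ Number of living females (>= 1; extinction must be declared by
#'   the caller before reaching zero females).
#' @param theta Male dispersal parameter (> 0).
#' @param beta Lifetime matings per female when males are in excess.
#' @param delta Breeding season length in days; must exceed `beta`.
#' @return Daily per-female encounter probability in \[0, beta/delta\].
#' @examples
#' mate_encounter_prob(M = 100, F_ = 100, theta = 1.5, beta = 4, delta = 90)
#' @export
mate_encounter_prob <- function(M, F_, theta, beta, delta) {
  if (any(M < 0)) stop("'M' must be >= 0", call. = FALSE)
  if (any(F_ < 1))
    stop("'F_' < 1: population should already have been declared extinct",
         call. = FALSE)
  if (any(theta <= 0)) stop("'theta' must be > 0", call. = FALSE)
  if (any(delta <= beta)) stop("'delta' must exceed 'beta'", call. = FALSE)
  r <- M / F_
  (beta / delta) * r / (r + theta)
}

#' Density-dependent juvenile death probability
#'
#' Juveniles pooled at the end of a season die independently with probability
#' \deqn{d = \frac{J}{J + X},} a hyperbolic function of the juvenile count J
#' modulated by the competition parameter X. Juvenile mortality is
#' independent of the environmental state E.
#'
#' @param J Number of juveniles (>= 0).
#' @param X Competition parameter (> 0).
#' @return Death probability in \[0, 1).
#' @examples
#' juvenile_death_prob(J = 500, X = 500)  # 0.5 at the symmetry point
#' @export
juvenile_death_prob <- function(J, X) {
  if (any(J < 0)) stop("'J' must be >= 0", call. = FALSE)
  if (any(X <= 0)) stop("'X' must be > 0", call. = FALSE)
  J / (J + X)
}

#' Sex and infection composition of one brood
#'
#' A mated female lays a brood of `sigma` offspring. If she is infected, a
#' Binomial(`sigma`, `gamma`) number of offspring inherit the infection; all
#' infected offspring are female (feminisation). Uninfected offspring are
#' male or female with equal probability. Uninfected mothers never transmit.
#'
#' @param mother_infected Logical: is the mother infected?
#' @param sigma Brood size (>= 1).
#' @param gamma Vertical transmission probability in \[0, 1\].
#' @return A list with integer counts `n_infected_females`,
#'   `n_uninfected_females` and `n_males`, summing to `sigma`.
#' @examples
#' set.seed(1)
#' brood_composition(TRUE, sigma = 50, gamma = 0.9)
#' @export
brood_composition <- function(mother_infected, sigma, gamma) {
  if (sigma < 1) stop("'sigma' must be >= 1", call. = FALSE)
  if (gamma < 0 || gamma > 1) stop("'gamma' must lie in [0, 1]", call. = FALSE)
  k <- if (isTRUE(mother_infected)) stats::rbinom(1L, sigma, gamma) else 0L
  males <- stats::rbinom(1L, sigma - k, 0.5)
  list(n_infected_females = as.integer(k),
       n_uninfected_females = as.integer(sigma - k - males),
       n_males = as.integer(males))
}

#' Offspring phenotype under blending inheritance with mutation
#'
#' Each offspring inherits the mean of its parents' phenotypes unless it is a
#' mutant (probability `phi`), in which case it draws a fresh phenotype
#' uniformly on \[0, 1\].
#'
#' @param P_mother,P_father Parental phenotypes in \[0, 1\]; vectorised and
#'   recycled to a common length.
#' @param phi Mutation probability in \[0, 1\].
#' @return Numeric vector of offspring phenotypes in \[0, 1\].
#' @examples
#' offspring_phenotype(0.2, 0.6, phi = 0)  # midparent value 0.4
#' @export
offspring_phenotype <- function(P_mother, P_father, phi) {
  if (any(P_mother < 0 | P_mother > 1) || any(P_father < 0 | P_father > 1))
    stop("parental phenotypes must lie in [0, 1]", call. = FALSE)
  if (phi < 0 || phi > 1) stop("'phi' must lie in [0, 1]", call. = FALSE)
  n <- max(length(P_mother), length(P_father))
  out <- (rep_len(P_mother, n) + rep_len(P_father, n)) / 2
  if (phi > 0 && n > 0) {
    mut <- stats::runif(n) < phi
    if (any(mut)) out[mut] <- stats::runif(sum(mut))
  }
  out
}
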