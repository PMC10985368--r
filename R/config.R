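# Keys a run configuration may contain, with their defaults.
config_defaults <- function() {
  p <- sim_params()
  c(unclass(p)[setdiff(names(unclass(p)), "n_generations")],
    list(n_generations = 50,
         experiment = "single-run",
         scenario = "constant", mode = "cyclical",
         U = NA_real_, L = NA_real_, R = 10,
         n_reps = 100, base_seed = 1, out_dir = "."))
}

#' Load a run configuration
#'
#' Reads a YAML file whose keys mirror the model parameter symbols (`delta`,
#' `c`, `S`, `theta`, `beta`, `sigma`, `gamma`, `phi`, `X`, ...) plus
#' experiment settings (`experiment`, `scenario`, `mode`, `n_reps`,
#' `n_generations`, `base_seed`, `out_dir`, and optional explicit `U`/`L`/
#' `R`). Unknown keys are rejected; omitted keys take the standard defaults;
#' out-of-range values are rejected with the permissible range in the
#' message.
#'
#' @param path Path to a YAML file, or a named list of the same keys.
#' @return A fully resolved configuration of class `srdm_config`.
#' @seealso [dump_config()] for the canonical round-trip serialisation.
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop("malformed config file '", path, "': ",
                                      conditionMessage(e), call. = FALSE))
  } else if (is.list(path)) path else
    stop("'path' must be a file path or a named list", call. = FALSE)
  if (is.null(raw)) raw <- list()
  defs <- config_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- defs
  cfg[names(raw)] <- raw
  resolve_config(cfg)
}

resolve_config <- function(cfg) {
  experiments <- c("single-run", "ecological", "sensitivity", "mechanistic",
                   "evolutionary")
  if (!cfg$experiment %in% experiments)
    stop("'experiment' must be one of: ", paste(experiments, collapse = ", "),
         call. = FALSE)
  if (!cfg$mode %in% c("cyclical", "stochastic", "constant"))
    stop("'mode' must be cyclical, stochastic or constant", call. = FALSE)
  if (!cfg$scenario %in% c("constant", "moderate", "high", "low"))
    stop("'scenario' must be constant/low, moderate or high", call. = FALSE)
  rng <- param_ranges()
  if (cfg$gamma < 0 || cfg$gamma > 1)
    stop(sprintf("'gamma' = %g outside [0, 1] (sampled range %g-%g)",
                 cfg$gamma, rng$gamma[1], rng$gamma[2]), call. = FALSE)
  if (cfg$S < 0 || cfg$S > 0.5)
    stop(sprintf("'S' = %g outside its range [%g, %g]", cfg$S,
                 rng$S[1], rng$S[2]), call. = FALSE)
  if (cfg$theta <= 0)
    stop(sprintf("'theta' = %g must be > 0 (sampled range %g-%g)",
                 cfg$theta, rng$theta[1], rng$theta[2]), call. = FALSE)
  # full parameter validation (delta > beta etc.)
  config_params(cfg)
  if (cfg$n_reps < 1) stop("'n_reps' must be >= 1", call. = FALSE)
  if (!is.numeric(cfg$base_seed))
    stop("'base_seed' must be an integer", call. = FALSE)
  structure(cfg, class = "srdm_config")
}

# SimulationParams slice of a configuration.
config_params <- function(cfg) {
  nm <- setdiff(names(unclass(sim_params())), character(0))
  do.call(sim_params, unclass(cfg)[nm])
}

# EnvironmentConfig slice: explicit U/L override the named scenario.
config_env <- function(cfg) {
  if (!is.na(cfg$U) || !is.na(cfg$L)) {
    U <- if (is.na(cfg$U)) 1 - cfg$L else cfg$U
    L <- if (is.na(cfg$L)) 1 - cfg$U else cfg$L
    env_config(mode = cfg$mode, U = U, L = L, R = cfg$R)
  } else {
    env_scenario(cfg$scenario, mode = cfg$mode)
  }
}

#' Serialise a configuration canonically
#'
#' Writes the fully resolved configuration as YAML with keys in a fixed
#' order, so that `load_config(dump_config(cfg))` is the identity and two
#' equal configurations produce byte-identical files.
#'
#' @param cfg An `srdm_config` from [load_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "srdm_config"))
  ordered <- unclass(cfg)[names(config_defaults())]
  yaml::write_yaml(ordered, path, precision = 15)
  invisible(path)
}

# MD5 of the canonical serialisation; used in output provenance headers.
# The output directory is not part of the scientific configuration, so it is
# excluded: the same experiment written to two directories shares a hash.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  canon <- unclass(cfg)
  canon$out_dir <- "."
  dump_config(structure(canon, class = "srdm_config"), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.srdm_config <- function(x, ...) {
  cat(sprintf("Run configuration (%s): scenario=%s mode=%s reps=%d seed=%d\n",
              x$experiment, x$scenario, x$mode, x$n_reps,
              as.integer(x$base_seed)))
  invisible(x)
}
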