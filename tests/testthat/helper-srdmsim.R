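# Small parameter sets for fast simulator tests.
quick_params <- function(...) {
  do.call(sim_params, utils::modifyList(
    list(n_generations = 20, init_size = 200), list(...)))
}

# Build an adult cohort data frame directly.
make_adults <- function(phenotype, male, infected = rep(FALSE, length(male))) {
  data.frame(phenotype = phenotype,
             sex = ifelse(male, "male", "female"),
             infected = infected)
}

# Per-replicate extinction flags from an ecological_experiment table.
extinction_flags <- function(rows) {
  key <- interaction(rows$scenario, rows$gamma, rows$replicate, drop = TRUE)
  tapply(rows$extinct, key, any)
}
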