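# Run configuration: a documented YAML key-value schema binding the
# modules into reproducible runs.
#
# Schema (all blocks optional unless a command needs them):
#   seed: integer
#   paths: {pedigree, cultural_pedigree, phenotypes, contacts, out}
#   design: {n_cultures, n_environments, n_families_per_cell, brood_size,
#            n_generations, swap_fraction, control_swap_fraction}
#   variances: {A, C, M, CB, ENVT, R}
#   model: {fixed: [column names], random: [A, C, dam, brood, ...]}
#   inertia: {relation_class: weight, ...}
#   power: {swap_fractions: [..], replicates, alpha}

#' Read a run configuration (YAML)
#' @param path YAML file.
#' @return named list (the configuration).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  yaml::read_yaml(path)
}

#' Write a run configuration (YAML); round-trips losslessly
#' @param config named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build a DesignSpec from a configuration block
#' @param config configuration list with a `design` block (and optionally
#'   a top-level `seed`).
#' @return a [DesignSpec].
#' @export
designFromConfig <- function(config) {
  d <- config$design %||% list()
  designSpec(
    nCultures = d$n_cultures %||% 2L,
    nEnvironments = d$n_environments %||% 1L,
    nFamiliesPerCell = d$n_families_per_cell %||% 2L,
    broodSize = d$brood_size %||% 2L,
    nGenerations = d$n_generations %||% 1L,
    swapFraction = d$swap_fraction %||% 0,
    controlSwapFraction = d$control_swap_fraction %||% 0,
    seed = config$seed %||% 1L)
}

#' Build VarianceComponents from a configuration block
#' @param config configuration list with a `variances` block.
#' @return a [VarianceComponents].
#' @export
variancesFromConfig <- function(config) {
  v <- config$variances %||% list()
  varianceComponents(A = v$A %||% 0, C = v$C %||% 0, M = v$M %||% 0,
                     CB = v$CB %||% 0, ENVT = v$ENVT %||% 0, R = v$R %||% 1)
}

provenanceHeader <- function(seed, extra = character(0)) {
  c(paste0("dualped ", as.character(utils::packageVersion("dualped"))),
    paste0("seed ", seed), extra)
}
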