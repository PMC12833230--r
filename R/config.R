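#' Pipeline configuration
#'
#' Collects every tunable of the mapping pipeline with the conventional
#' defaults: 4 mm seed spheres, voxel-wise BH-FDR at q = 0.01, a 60%
#' probability threshold for the consensus network, positive connectivity
#' only, 10,000 permutations and an FDR alpha of 0.05 for the
#' neurotransmitter screen.
#'
#' @param radius_mm Seed sphere radius in mm.
#' @param fdr_q Voxel-wise FDR rate for the group test.
#' @param probability_threshold Consensus threshold on the probability map.
#' @param positive_only Restrict networks to positive connectivity.
#' @param alternative Sidedness of the group t-test.
#' @param unit Seed aggregation unit, `"study"` or `"contrast"`.
#' @param tal_method Talairach conversion, `"lancaster"` or `"brett"`.
#' @param n_permutations Permutations for the neurotransmitter screen.
#' @param nt_fdr_alpha FDR alpha across the neurotransmitter catalogue.
#' @param seed Integer RNG seed for all stochastic stages.
#' @return An `fcnm_config` list.
#' @export
fcnm_config <- function(radius_mm = 4, fdr_q = 0.01, probability_threshold = 0.60,
                        positive_only = TRUE,
                        alternative = c("two.sided", "greater"),
                        unit = c("study", "contrast"),
                        tal_method = c("lancaster", "brett"),
                        n_permutations = 10000, nt_fdr_alpha = 0.05,
                        seed = 1L) {
  stopifnot(
    radius_mm > 0, fdr_q > 0, fdr_q < 1,
    probability_threshold > 0, probability_threshold <= 1,
    n_permutations >= 100, nt_fdr_alpha > 0, nt_fdr_alpha < 1
  )
  structure(
    list(
      radius_mm = radius_mm,
      fdr_q = fdr_q,
      probability_threshold = probability_threshold,
      positive_only = isTRUE(positive_only),
      alternative = match.arg(alternative),
      unit = match.arg(unit),
      tal_method = match.arg(tal_method),
      n_permutations = as.integer(n_permutations),
      nt_fdr_alpha = nt_fdr_alpha,
      seed = as.integer(seed)
    ),
    class = "fcnm_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the package defaults.
#'
#' @param path Path to a YAML file whose keys match [fcnm_config()]
#'   arguments.
#' @return An `fcnm_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(fcnm_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(fcnm_config, vals)
}

#' @export
print.fcnm_config <- function(x, ...) {
  cat("<fcnm_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}
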