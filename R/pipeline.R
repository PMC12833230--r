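#' Run the full coordinate-to-network mapping pipeline
#'
#' Executes, for each acupoint in the foci table: seed construction per
#' study (or contrast), per-subject seed-to-whole-brain Fisher-z
#' connectivity across the normative connectome, a voxel-wise one-sample
#' t-test, BH-FDR thresholding with positive-only binarization, the
#' across-study probability overlay, and the final consensus threshold.
#'
#' @param foci Foci tibble (validated; Talairach rows are converted using
#'   `config$tal_method`).
#' @param connectome List of `fcnm_series`, one per subject, on `grid`.
#' @param grid Session `fcnm_grid`.
#' @param config An [fcnm_config()].
#' @param out_dir Optional directory; when given, per-stage NIfTI volumes
#'   and a provenance manifest are written under it.
#' @param keep_group Keep per-unit group t/p maps in the result (memory
#'   permitting); default `FALSE`.
#' @return An `fcnm_result` with elements `networks` (named list of
#'   `fcnm_network` per acupoint), `pmaps` (probability maps per acupoint),
#'   `unit_networks` (per-unit binary networks), `seeds`, `config`, and a
#'   `provenance` list (counts, ids, empty-unit log).
#' @export
run_fcnm <- function(foci, connectome, grid, config = fcnm_config(),
                     out_dir = NULL, keep_group = FALSE) {
  stopifnot(inherits(config, "fcnm_config"), length(connectome) >= 3)
  foci <- validate_foci(foci)
  foci <- convert_foci_to_mni(foci, method = config$tal_method)
  for (s in connectome) stopifnot_same_grid(grid, s$grid)

  acupoints <- unique(foci$acupoint)
  networks <- list()
  pmaps <- list()
  unit_networks <- list()
  groups <- list()
  all_seeds <- list()
  empty_units <- character()

  for (ap in acupoints) {
    ap_foci <- foci[foci$acupoint == ap, , drop = FALSE]
    seeds <- seeds_per_unit(ap_foci, grid,
      unit = config$unit,
      radius_mm = config$radius_mm
    )
    all_seeds[names(seeds)] <- seeds
    nets <- list()
    for (uid in names(seeds)) {
      subject_maps <- lapply(connectome, subject_fc_map, seed = seeds[[uid]])
      grp <- group_onesample(subject_maps, alternative = config$alternative)
      net <- binarize_positive(grp,
        q = config$fdr_q,
        positive_only = config$positive_only
      )
      if (length(net$linear) == 0) empty_units <- c(empty_units, uid)
      nets[[uid]] <- net
      if (keep_group) groups[[uid]] <- grp
    }
    # empty per-unit networks still count toward N in the overlay
    pmap <- probability_map(nets)
    pmaps[[ap]] <- pmap
    unit_networks[names(nets)] <- nets
    networks[[ap]] <- threshold_probability(pmap,
      threshold = config$probability_threshold, id = ap
    )
  }

  result <- structure(
    list(
      networks = networks,
      pmaps = pmaps,
      unit_networks = unit_networks,
      seeds = all_seeds,
      groups = if (keep_group) groups else NULL,
      config = config,
      provenance = list(
        n_subjects = length(connectome),
        n_foci = nrow(foci),
        acupoints = acupoints,
        units = names(unit_networks),
        empty_units = empty_units,
        tal_conversion = attr(foci, "tal_conversion")
      )
    ),
    class = "fcnm_result"
  )
  if (!is.null(out_dir)) write_result(result, out_dir)
  result
}

#' @export
print.fcnm_result <- function(x, ...) {
  cat("<fcnm_result>\n")
  for (ap in names(x$networks)) {
    cat(sprintf(
      "  %s: %d voxels from %d unit maps at >= %d%% agreement\n",
      ap, length(x$networks[[ap]]$linear),
      attr(x$pmaps[[ap]], "n_maps"),
      round(100 * x$config$probability_threshold)
    ))
  }
  invisible(x)
}

#' Write pipeline outputs and a provenance manifest
#'
#' Writes, under `out_dir`: one binary NIfTI per consensus network and per
#' unit network, one probability map per acupoint, and `manifest.json`
#' recording the configuration, file md5 hashes, and counts.
#'
#' @param result An `fcnm_result`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
write_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (ap in names(result$networks)) {
    p <- file.path(out_dir, paste0("network_", sanitize_id(ap), ".nii.gz"))
    write_volume(as_binary_map(result$networks[[ap]]), p)
    paths <- c(paths, p)
    p <- file.path(out_dir, paste0("probability_", sanitize_id(ap), ".nii.gz"))
    write_volume(result$pmaps[[ap]], p)
    paths <- c(paths, p)
  }
  for (uid in names(result$unit_networks)) {
    p <- file.path(out_dir, paste0("unit_", sanitize_id(uid), ".nii.gz"))
    write_volume(as_binary_map(result$unit_networks[[uid]]), p)
    paths <- c(paths, p)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("fcnm")),
    config = unclass(result$config),
    provenance = result$provenance,
    files = lapply(stats::setNames(paths, basename(paths)), function(p) {
      list(md5 = unname(tools::md5sum(p)), bytes = file.size(p))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Summarise a pipeline result per acupoint
#'
#' @param x An `fcnm_result`.
#' @param ... Unused.
#' @return A tibble with one row per acupoint: network size, number of unit
#'   maps, minimum agreeing count at the threshold, and probability-map
#'   extent.
#' @method tidy fcnm_result
#' @export
tidy.fcnm_result <- function(x, ...) {
  purrr::map_dfr(names(x$networks), function(ap) {
    n_maps <- attr(x$pmaps[[ap]], "n_maps")
    tibble::tibble(
      acupoint = ap,
      n_unit_maps = n_maps,
      threshold = x$config$probability_threshold,
      min_agreeing_units = min_surviving_count(n_maps, x$config$probability_threshold),
      network_voxels = length(x$networks[[ap]]$linear),
      nonzero_probability_voxels = sum(x$pmaps[[ap]]$data > 0)
    )
  })
}

#' One-row overview of a pipeline result
#'
#' @param x An `fcnm_result`.
#' @param ... Unused.
#' @return A one-row tibble: subjects, foci, units, acupoints, and the key
#'   thresholds used.
#' @method glance fcnm_result
#' @export
glance.fcnm_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$provenance$n_subjects,
    n_foci = x$provenance$n_foci,
    n_units = length(x$provenance$units),
    n_acupoints = length(x$provenance$acupoints),
    n_empty_units = length(x$provenance$empty_units),
    radius_mm = x$config$radius_mm,
    fdr_q = x$config$fdr_q,
    probability_threshold = x$config$probability_threshold
  )
}

#' Smallest agreeing-study count that survives a probability threshold
#'
#' @param n_maps Number of overlaid unit networks.
#' @param threshold Probability threshold (inclusive).
#' @return Integer: smallest k with k / n_maps >= threshold.
#' @export
min_surviving_count <- function(n_maps, threshold = 0.60) {
  as.integer(ceiling(n_maps * threshold - 1e-9))
}
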