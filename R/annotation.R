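#' Canonical-network atlas
#'
#' Hard parcellation of the brain into named canonical systems: the seven
#' cortical resting-state networks (visual, somatomotor, dorsal attention,
#' ventral attention, limbic, frontoparietal control, default) plus an
#' aggregate subcortical label. Label 0 is background. Probabilistic
#' atlases must be argmax-reduced before use.
#'
#' @param grid Session `fcnm_grid`.
#' @param labels Integer 3D array of label ids (0 = background).
#' @param label_names Named character vector or list mapping label id
#'   (as character) to network name.
#' @return An `fcnm_atlas`.
#' @export
fcnm_atlas <- function(grid, labels, label_names) {
  labels <- array(as.integer(labels), dim = dim(labels))
  if (!identical(dim(labels), grid$dim)) {
    stop("atlas labels shape does not match grid", call. = FALSE)
  }
  label_names <- unlist(label_names)
  present <- setdiff(unique(as.integer(labels)), 0L)
  named_ids <- as.integer(names(label_names))
  if (!all(named_ids %in% present)) {
    stop("atlas label(s) absent from the volume: ",
      paste(setdiff(named_ids, present), collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(grid = grid, labels = labels, label_names = label_names),
    class = "fcnm_atlas"
  )
}

#' Canonical-network composition of a consensus network
#'
#' For each canonical label L, the proportion of network voxels falling in
#' L: |network intersect L| / |network|. The denominator is always the
#' network size, so proportions plus the unassigned (background) fraction
#' sum to one. This is composition, not Dice and not atlas-relative
#' coverage.
#'
#' @param network An `fcnm_network` (non-empty).
#' @param atlas An `fcnm_atlas` on the same grid.
#' @return A tibble with one row per canonical label plus one `unassigned`
#'   row: `network`, `label`, `n_voxels`, `proportion`, sorted by
#'   descending proportion (ties broken by label name), with attribute
#'   `network_size_voxels`.
#' @export
overlap_profile <- function(network, atlas) {
  stopifnot_same_grid(network$grid, atlas$grid)
  if (length(network$linear) == 0) {
    stop("overlap profile undefined for an empty network", call. = FALSE)
  }
  net_labels <- atlas$labels[network$linear]
  size <- length(network$linear)
  counts <- vapply(
    as.integer(names(atlas$label_names)),
    function(id) sum(net_labels == id), integer(1)
  )
  out <- tibble::tibble(
    network = network$id,
    label = unname(atlas$label_names),
    n_voxels = unname(counts)
  )
  out <- dplyr::bind_rows(out, tibble::tibble(
    network = network$id,
    label = "unassigned",
    n_voxels = sum(!net_labels %in% as.integer(names(atlas$label_names)))
  ))
  out$proportion <- out$n_voxels / size
  out <- dplyr::arrange(out, dplyr::desc(.data$proportion), .data$label)
  attr(out, "network_size_voxels") <- size
  class(out) <- c("fcnm_overlap", class(out))
  out
}

#' Combined composition report over several networks
#'
#' Stacks the per-network profiles into one long table (shared label order,
#' ready for polar plots) and ranks within each network.
#'
#' @param profiles Named list of [overlap_profile()] tibbles, or a single
#'   profile.
#' @return A long tibble: `network`, `label`, `n_voxels`, `proportion`,
#'   `rank` (dense, descending proportion within network). Label levels are
#'   shared across networks.
#' @export
profile_report <- function(profiles) {
  if (inherits(profiles, "fcnm_overlap")) profiles <- list(profiles)
  out <- dplyr::bind_rows(lapply(profiles, tibble::as_tibble))
  labels <- sort(unique(out$label))
  out$label <- factor(out$label, levels = labels)
  out <- dplyr::group_by(out, .data$network)
  out <- dplyr::mutate(out,
    rank = dplyr::dense_rank(dplyr::desc(.data$proportion))
  )
  out <- dplyr::ungroup(out)
  dplyr::arrange(out, .data$network, .data$rank, .data$label)
}
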