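#' Synthetic mapping scene with known ground truth
#'
#' Builds the fixture every pipeline stage can be tested against: a small
#' 3 mm reference grid with an interior-box brain mask, and per acupoint a
#' planted seed region (where reported foci will fall) nested inside a
#' larger planted network region (the ground-truth consensus network). In
#' the generated connectome a per-acupoint latent signal drives seed and
#' network voxels jointly, so seed-based mapping should recover the planted
#' network.
#'
#' The connectivity model is a single shared latent factor per acupoint:
#' driven voxels follow x_v(t) = lambda * u(t) + eps_v(t) with u an AR(1)
#' process of unit marginal variance and eps iid Gaussian noise, giving an
#' expected correlation of lambda^2 / (lambda^2 + noise_sd^2) between any
#' two driven voxels. The default lambda = sqrt(2/3) with noise_sd = 1
#' plants a driven-pair correlation of 0.4, a realistic effect size for
#' seed-based resting-state connectivity.
#'
#' @param dim Grid shape in voxels (default 20 x 24 x 20 at 3 mm).
#' @param voxel_mm Isotropic voxel size (default 3).
#' @param acupoints Named list of region specs; each entry is a list with
#'   `seed_centre` (voxel index), `seed_half` (half-width of the seed box),
#'   `network_centre`, `network_half` (3 half-widths of the network box).
#'   Defaults plant two disjoint systems labelled ST36 and GB34.
#' @param lambda Latent loading (default `sqrt(2/3)`).
#' @param noise_sd Noise standard deviation (default 1).
#' @param ar1 AR(1) coefficient of the latent series in `[0, 1)` (default 0.3).
#' @param n_subjects Default connectome size (default 40).
#' @param n_timepoints Timepoints per subject (default 120).
#' @param seed Integer RNG seed; all generators derive sub-streams from it.
#' @return An `fcnm_scene`: `grid`, `networks` and `seed_regions` (named
#'   lists of linear voxel indices), and the generation parameters.
#' @export
gen_scene <- function(dim = c(20, 24, 20), voxel_mm = 3,
                      acupoints = default_acupoint_specs(),
                      lambda = sqrt(2 / 3), noise_sd = 1, ar1 = 0.3,
                      n_subjects = 40, n_timepoints = 120, seed = 1L) {
  dim <- as.integer(dim)
  if (any(dim < 12L)) stop("scene grid must be at least 12 voxels per axis", call. = FALSE)
  stopifnot(lambda >= 0, noise_sd > 0, ar1 >= 0, ar1 < 1)
  mask <- array(FALSE, dim = dim)
  mask[3:(dim[1] - 2), 3:(dim[2] - 2), 3:(dim[3] - 2)] <- TRUE
  grid <- fcnm_grid(dim, mni_affine(dim, voxel_mm), mask)
  networks <- list()
  seed_regions <- list()
  for (ap in names(acupoints)) {
    spec <- acupoints[[ap]]
    net <- box_linear(grid, spec$network_centre, spec$network_half)
    sr <- box_linear(grid, spec$seed_centre, rep(spec$seed_half, 3))
    if (!all(sr %in% net)) {
      stop("seed region of '", ap, "' must lie inside its network region", call. = FALSE)
    }
    networks[[ap]] <- net
    seed_regions[[ap]] <- sr
  }
  overlap <- length(Reduce(intersect, networks))
  if (length(networks) > 1 && overlap > 0) {
    stop("acupoint network regions overlap (", overlap, " voxels)", call. = FALSE)
  }
  structure(
    list(
      grid = grid, networks = networks, seed_regions = seed_regions,
      lambda = lambda, noise_sd = noise_sd, ar1 = ar1,
      n_subjects = as.integer(n_subjects),
      n_timepoints = as.integer(n_timepoints),
      seed = as.integer(seed)
    ),
    class = "fcnm_scene"
  )
}

default_acupoint_specs <- function() {
  list(
    ST36 = list(
      seed_centre = c(6, 10, 10), seed_half = 1,
      network_centre = c(6, 12, 10), network_half = c(2, 4, 2)
    ),
    GB34 = list(
      seed_centre = c(14, 10, 10), seed_half = 1,
      network_centre = c(14, 12, 10), network_half = c(2, 4, 2)
    )
  )
}

box_linear <- function(grid, centre, half) {
  lo <- pmax(1L, as.integer(centre - half))
  hi <- pmin(grid$dim, as.integer(centre + half))
  if (any(lo > hi)) stop("planted region falls outside the grid", call. = FALSE)
  box <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  lin <- box[, 1] + (box[, 2] - 1L) * grid$dim[1] +
    (box[, 3] - 1L) * grid$dim[1] * grid$dim[2]
  lin <- lin[grid$mask[lin]]
  if (length(lin) == 0) stop("planted region falls outside the brain mask", call. = FALSE)
  sort(lin)
}

#' @export
print.fcnm_scene <- function(x, ...) {
  cat(sprintf(
    "<fcnm_scene> %s grid, %d subjects x %d timepoints, driven-pair r = %.2f\n",
    paste(x$grid$dim, collapse = "x"), x$n_subjects, x$n_timepoints,
    x$lambda^2 / (x$lambda^2 + x$noise_sd^2)
  ))
  for (ap in names(x$networks)) {
    cat(sprintf(
      "  %s: %d network voxels, %d seed-region voxels\n",
      ap, length(x$networks[[ap]]), length(x$seed_regions[[ap]])
    ))
  }
  invisible(x)
}

#' Planted consensus network as an `fcnm_network`
#'
#' @param scene An `fcnm_scene`.
#' @param acupoint Acupoint name (default: first).
#' @return The ground-truth `fcnm_network` for that acupoint.
#' @export
scene_truth <- function(scene, acupoint = names(scene$networks)[1]) {
  new_network(scene$grid, scene$networks[[acupoint]], id = acupoint)
}

#' Generate a synthetic normative connectome
#'
#' One `fcnm_series` per subject under the scene's latent-factor model.
#' Each subject gets an independent sub-stream derived from the scene seed
#' (or `seed` if given), so subjects differ in data but share expectations,
#' and regeneration under the same seed is bit-identical.
#'
#' @param scene An `fcnm_scene`.
#' @param n_subjects Number of subjects (default `scene$n_subjects`).
#' @param seed Base seed (default `scene$seed`).
#' @param null_data If `TRUE`, omit the latent signal everywhere (pure
#'   noise connectome for false-positive calibration).
#' @return List of `fcnm_series`.
#' @export
gen_connectome <- function(scene, n_subjects = scene$n_subjects,
                           seed = scene$seed, null_data = FALSE) {
  grid <- scene$grid
  tt <- scene$n_timepoints
  mask_lin <- which(grid$mask)
  lapply(seq_len(n_subjects), function(s) {
    data <- with_seed(derive_seed(seed, s), {
      arr <- array(0, dim = c(grid$dim, tt))
      flat <- matrix(0, nrow = prod(grid$dim), ncol = tt)
      flat[mask_lin, ] <- stats::rnorm(length(mask_lin) * tt, sd = scene$noise_sd)
      if (!null_data && scene$lambda > 0) {
        for (ap in names(scene$networks)) {
          u <- ar1_series(tt, scene$ar1)
          driven <- scene$networks[[ap]]
          flat[driven, ] <- flat[driven, , drop = FALSE] +
            scene$lambda * matrix(u, nrow = length(driven), ncol = tt, byrow = TRUE)
        }
      }
      arr[] <- flat
      arr
    })
    fcnm_series(grid, data, subject_id = sprintf("sub-%03d", s))
  })
}

# AR(1) with unit marginal variance.
ar1_series <- function(tt, phi) {
  e <- stats::rnorm(tt)
  if (phi == 0) {
    return(e)
  }
  u <- numeric(tt)
  u[1] <- e[1]
  for (t in 2:tt) u[t] <- phi * u[t - 1] + sqrt(1 - phi^2) * e[t]
  u
}

#' Generate a synthetic foci table
#'
#' Emulates coordinates extracted from a literature search: per study
#' (unit), 1 to 5 foci drawn from the acupoint's planted seed-region voxel
#' centres with Gaussian mm jitter, and a per-study sample size of at least
#' 10. The default unit counts (14 ST36-like, 4 GB34-like) reproduce the
#' canonical two-acupoint scenario.
#'
#' @param scene An `fcnm_scene`.
#' @param n_units Named integer vector: studies per acupoint. Acupoints
#'   must exist in the scene.
#' @param jitter_sd_mm Coordinate jitter standard deviation in mm
#'   (default 1).
#' @param seed Base seed (default `scene$seed`).
#' @return A validated foci tibble (all rows MNI).
#' @export
gen_foci <- function(scene, n_units = c(ST36 = 14, GB34 = 4),
                     jitter_sd_mm = 1, seed = scene$seed) {
  stopifnot(all(names(n_units) %in% names(scene$networks)))
  rows <- list()
  unit_counter <- 0L
  for (ap in names(n_units)) {
    centres <- voxel_to_mm(scene$grid, arrayInd(scene$seed_regions[[ap]], scene$grid$dim))
    for (u in seq_len(n_units[[ap]])) {
      unit_counter <- unit_counter + 1L
      rows[[unit_counter]] <- with_seed(derive_seed(seed, 10000 + unit_counter), {
        k <- sample(1:5, 1)
        idx <- sample.int(nrow(centres), k, replace = TRUE)
        xyz <- centres[idx, , drop = FALSE] +
          matrix(stats::rnorm(3 * k, sd = jitter_sd_mm), ncol = 3)
        tibble::tibble(
          study_id = sprintf("%s_study%02d", ap, u),
          contrast_id = sprintf("c%02d", seq_len(k)),
          acupoint = ap,
          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
          space = "MNI",
          n_subjects = sample(10:40, 1)
        )
      })
    }
  }
  validate_foci(dplyr::bind_rows(rows))
}

CANONICAL_NAMES <- c(
  "visual", "somatomotor", "dorsal attention", "ventral attention",
  "limbic", "frontoparietal control", "default", "subcortical"
)

#' Generate a canonical atlas and a parcellation with known structure
#'
#' Space-filling Voronoi labels over the brain mask around randomly placed
#' centres: every label is non-empty by construction (each centre labels at
#' least its own voxel). Optionally, a configurable fraction of each
#' planted network's voxels is reassigned to a designated canonical label,
#' so composition profiles have a known dominant system.
#'
#' @param scene An `fcnm_scene`.
#' @param n_canonical Number of canonical labels (default 8: seven cortical
#'   networks plus subcortical).
#' @param n_parcels Number of parcellation regions (default 119).
#' @param network_label Optional named character vector mapping acupoint to
#'   the canonical name its planted network should predominantly carry.
#' @param network_label_frac Fraction of planted-network voxels forced to
#'   that label (default 0.8).
#' @param seed Base seed (default `scene$seed`).
#' @return A list with `atlas` (`fcnm_atlas`) and `parcellation`
#'   (`fcnm_parcellation`).
#' @export
gen_atlas_and_parcellation <- function(scene, n_canonical = 8, n_parcels = 119,
                                       network_label = NULL,
                                       network_label_frac = 0.8,
                                       seed = scene$seed) {
  grid <- scene$grid
  labels_canon <- voronoi_labels(grid, n_canonical, derive_seed(seed, 21))
  canon_names <- stats::setNames(
    CANONICAL_NAMES[seq_len(n_canonical)],
    as.character(seq_len(n_canonical))
  )
  if (!is.null(network_label)) {
    for (ap in names(network_label)) {
      target_id <- match(network_label[[ap]], canon_names)
      if (is.na(target_id)) stop("unknown canonical label: ", network_label[[ap]], call. = FALSE)
      net <- scene$networks[[ap]]
      n_force <- ceiling(network_label_frac * length(net))
      forced <- with_seed(derive_seed(seed, 22), sample(net, n_force))
      labels_canon[forced] <- target_id
    }
    # forcing can empty a small label; re-anchor every name on one voxel
    free <- setdiff(which(grid$mask), unlist(scene$networks))
    for (id in seq_len(n_canonical)) {
      if (!any(labels_canon == id)) {
        labels_canon[free[id]] <- id
      }
    }
  }
  parc_labels <- voronoi_labels(grid, n_parcels, derive_seed(seed, 23))
  list(
    atlas = fcnm_atlas(grid, labels_canon, canon_names),
    parcellation = fcnm_parcellation(grid, parc_labels)
  )
}

voronoi_labels <- function(grid, n_labels, seed) {
  mask_lin <- which(grid$mask)
  if (n_labels > length(mask_lin)) {
    stop("more labels than brain-mask voxels", call. = FALSE)
  }
  centres_lin <- with_seed(seed, sample(mask_lin, n_labels))
  centres <- arrayInd(centres_lin, grid$dim)
  vox <- arrayInd(mask_lin, grid$dim)
  labels <- array(0L, dim = grid$dim)
  # nearest centre per voxel; process in blocks to bound memory
  best <- integer(length(mask_lin))
  bestd <- rep(Inf, length(mask_lin))
  for (c_idx in seq_len(n_labels)) {
    d <- (vox[, 1] - centres[c_idx, 1])^2 + (vox[, 2] - centres[c_idx, 2])^2 +
      (vox[, 3] - centres[c_idx, 3])^2
    upd <- d < bestd
    best[upd] <- c_idx
    bestd[upd] <- d[upd]
  }
  labels[mask_lin] <- best
  labels[centres_lin] <- seq_len(n_labels)
  labels
}

#' Generate a neurotransmitter catalogue with planted correlations
#'
#' Draws, for each named receptor/transporter map, a parcel vector whose
#' Spearman correlation with a target spatial pattern is calibrated via a
#' Gaussian copula: y = rtilde * g + sqrt(1 - rtilde^2) * z with g the
#' normal scores of the target and rtilde = 2 sin(pi * rho_s / 6), the
#' bivariate-normal value whose Spearman correlation is `rho_s`. A
#' gray-matter covariate vector in (0, 1) is generated alongside
#' (independent by default).
#'
#' @param parc An `fcnm_parcellation` (defines R).
#' @param target Numeric parcel vector of length R: the spatial pattern the
#'   planted correlations refer to (e.g. the parcellated planted network).
#' @param rho_targets Named numeric vector of target Spearman correlations;
#'   unnamed catalogue entries default to 0. Defaults to the standard
#'   16-map catalogue, all null.
#' @param gm_loading Loading of the gray-matter covariate on the target
#'   pattern (default 0 = independent).
#' @param seed Integer seed.
#' @return A list with `catalogue` (R x maps matrix, columns named),
#'   `gm` (parcel vector), and `rho_targets`.
#' @export
gen_nt_catalogue <- function(parc, target,
                             rho_targets = stats::setNames(
                               rep(0, length(NT_MAP_NAMES)), NT_MAP_NAMES
                             ),
                             gm_loading = 0, seed = 1L) {
  r_regions <- parc$n_regions
  stopifnot(length(target) == r_regions)
  g <- stats::qnorm((rank_avg(target) - 0.5) / r_regions)
  g <- g / stats::sd(g)
  cat_mat <- with_seed(derive_seed(seed, 31), {
    vapply(seq_along(rho_targets), function(j) {
      rtilde <- 2 * sin(pi * rho_targets[[j]] / 6)
      rtilde * g + sqrt(1 - rtilde^2) * stats::rnorm(r_regions)
    }, numeric(r_regions))
  })
  colnames(cat_mat) <- names(rho_targets)
  gm <- with_seed(derive_seed(seed, 32), {
    raw <- gm_loading * g + sqrt(max(0, 1 - gm_loading^2)) * stats::rnorm(r_regions)
    stats::plogis(raw)
  })
  list(catalogue = cat_mat, gm = gm, rho_targets = rho_targets)
}
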