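#' Spherical seed mask around reported foci
#'
#' A seed mask is the union of spheres of radius `radius_mm` around each
#' focus of one study or contrast. A voxel belongs to a sphere when its
#' centre lies within the radius (Euclidean distance in mm) of the focus;
#' additionally, the voxel containing a focus is always included when
#' `include_containing_voxel` is `TRUE`, so small radii (e.g. 1 mm on a
#' 3 mm grid) still produce a usable single-voxel seed. Voxels outside the
#' brain mask are dropped with a warning when a whole focus falls outside.
#'
#' @param foci Foci tibble in MNI mm (see [convert_foci_to_mni()]), or an
#'   n x 3 matrix of mm coordinates.
#' @param grid Session `fcnm_grid`.
#' @param radius_mm Sphere radius in mm (default 4).
#' @param include_containing_voxel Always keep the voxel containing each
#'   focus (default `TRUE`).
#' @param id Seed identifier stored on the mask.
#' @return An `fcnm_seed`: voxel index matrix (`voxels`, 1-based), linear
#'   indices (`linear`), the grid, and the id.
#' @export
build_seed <- function(foci, grid, radius_mm = 4, include_containing_voxel = TRUE,
                       id = "seed") {
  stopifnot(radius_mm > 0)
  coords <- if (is.data.frame(foci)) {
    as.matrix(foci[, c("x", "y", "z")])
  } else {
    coerce_coord_matrix(foci)
  }
  inv <- solve(grid$affine)
  keep <- logical(prod(grid$dim))
  any_outside <- FALSE
  for (i in seq_len(nrow(coords))) {
    lin <- sphere_linear_indices(grid, inv, coords[i, ], radius_mm,
      include_containing_voxel,
      label = paste0(id, " focus ", i)
    )
    in_mask <- grid$mask[lin]
    if (!any(in_mask)) any_outside <- TRUE
    keep[lin[in_mask]] <- TRUE
  }
  if (any_outside) {
    warning("seed '", id, "': at least one focus lies entirely outside the brain mask",
      call. = FALSE
    )
  }
  linear <- which(keep)
  if (length(linear) == 0) {
    stop("seed '", id, "' is empty after brain masking", call. = FALSE)
  }
  new_seed(grid, linear, id)
}

new_seed <- function(grid, linear, id) {
  structure(
    list(
      grid = grid,
      linear = as.integer(linear),
      voxels = arrayInd(as.integer(linear), grid$dim),
      id = as.character(id)
    ),
    class = "fcnm_seed"
  )
}

#' @export
print.fcnm_seed <- function(x, ...) {
  cat(sprintf("<fcnm_seed %s> %d voxels\n", x$id, length(x$linear)))
  invisible(x)
}

# Candidate voxels for one sphere: bounding box in voxel space, then exact
# centre-distance test in mm.
sphere_linear_indices <- function(grid, inv, centre_mm, radius_mm,
                                  include_containing, label) {
  ijk0 <- (inv %*% c(centre_mm, 1))[1:3]
  half_span <- radius_mm / grid$voxel_size_mm + 1
  lo <- pmax(1L, as.integer(floor(ijk0 + 1 - half_span)))
  hi <- pmin(grid$dim, as.integer(ceiling(ijk0 + 1 + half_span)))
  if (any(lo > hi)) stop("coordinate outside the reference grid: ", label, call. = FALSE)
  box <- as.matrix(expand.grid(
    i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]
  ))
  centres <- voxel_to_mm(grid, box)
  d2 <- (centres[, 1] - centre_mm[1])^2 + (centres[, 2] - centre_mm[2])^2 +
    (centres[, 3] - centre_mm[3])^2
  inside <- d2 <= radius_mm^2 + 1e-9
  sel <- box[inside, , drop = FALSE]
  if (include_containing) {
    containing <- mm_to_voxel(grid, centre_mm, label = label)
    sel <- rbind(sel, containing)
  }
  if (nrow(sel) == 0) stop("coordinate outside the reference grid: ", label, call. = FALSE)
  unique(sel[, 1] + (sel[, 2] - 1L) * grid$dim[1] +
    (sel[, 3] - 1L) * grid$dim[1] * grid$dim[2])
}

#' Build one seed mask per study or per contrast
#'
#' The default unit is the study: all foci reported by a study, across its
#' contrasts, are pooled into one seed, so each included experiment
#' contributes exactly one map to the probability overlay. Per-contrast
#' mode builds one seed per (study, contrast) pair instead.
#'
#' @inheritParams build_seed
#' @param unit `"study"` (default) or `"contrast"`.
#' @return A named list of `fcnm_seed` objects, one per unit, in first-seen
#'   order. Unit ids are `study_id` or `study_id:contrast_id`.
#' @export
seeds_per_unit <- function(foci, grid, unit = c("study", "contrast"),
                           radius_mm = 4, include_containing_voxel = TRUE) {
  unit <- match.arg(unit)
  key <- if (unit == "study") {
    foci$study_id
  } else {
    paste(foci$study_id, foci$contrast_id, sep = ":")
  }
  ids <- unique(key)
  seeds <- lapply(ids, function(uid) {
    build_seed(foci[key == uid, , drop = FALSE], grid,
      radius_mm = radius_mm,
      include_containing_voxel = include_containing_voxel, id = uid
    )
  })
  stats::setNames(seeds, ids)
}

#' Convert a seed or network to a binary map
#'
#' @param x An `fcnm_seed` or `fcnm_network`.
#' @return An `fcnm_map` of kind `"binary"`.
#' @export
as_binary_map <- function(x) {
  data <- array(0, dim = x$grid$dim)
  data[x$linear] <- 1
  fcnm_map(x$grid, data, kind = "binary")
}
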