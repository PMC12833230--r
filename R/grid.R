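#' Reference grid for a mapping session
#'
#' All volumes in one analysis live on a single reference grid: a voxel array
#' shape, a 4x4 affine mapping 0-based voxel indices to RAS mm coordinates
#' (the NIfTI convention), and a brain mask. Volumes whose affine or shape
#' disagree with the session grid are rejected rather than silently resampled.
#'
#' Voxel indices exposed through the R API are 1-based, matching R arrays;
#' the affine itself acts on 0-based indices and the conversion helpers
#' handle the offset.
#'
#' @param dim Integer vector of length 3, voxels per axis.
#' @param affine 4x4 numeric matrix, voxel-index (0-based) to mm transform.
#' @param mask Logical 3D array of dimension `dim`, the brain mask. Defaults
#'   to all-`TRUE`.
#' @return An object of class `fcnm_grid` with elements `dim`, `affine`,
#'   `mask`, and `voxel_size_mm`.
#' @examples
#' g <- fcnm_grid(c(10, 10, 10), mni_affine(c(10, 10, 10)))
#' g$voxel_size_mm
#' @export
fcnm_grid <- function(dim, affine, mask = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim > 0L))
  affine <- unname(as.matrix(affine))
  stopifnot(identical(base::dim(affine), c(4L, 4L)))
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100) {
    stop("grid affine is singular", call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- array(TRUE, dim = dim)
  }
  mask <- array(as.logical(mask), dim = base::dim(mask))
  if (!identical(base::dim(mask), dim)) {
    stop("brain mask dimensions do not match grid shape", call. = FALSE)
  }
  if (!any(mask)) stop("brain mask is empty", call. = FALSE)
  structure(
    list(
      dim = dim,
      affine = affine,
      mask = mask,
      voxel_size_mm = sqrt(colSums(affine[1:3, 1:3]^2))
    ),
    class = "fcnm_grid"
  )
}

#' @export
print.fcnm_grid <- function(x, ...) {
  cat(sprintf(
    "<fcnm_grid> %s voxels, %s mm, %d in brain mask\n",
    paste(x$dim, collapse = "x"),
    paste(signif(x$voxel_size_mm, 3), collapse = "x"),
    sum(x$mask)
  ))
  invisible(x)
}

#' Standard MNI-style affine for an isotropic grid
#'
#' Builds a NIfTI-convention affine with negative x spacing (radiological
#' storage order, RAS coordinates) and a translation placing the origin
#' near the grid centre, mimicking the standard 3 mm MNI template layout.
#'
#' @param dim Grid shape (3 integers).
#' @param voxel_mm Isotropic voxel size in mm (default 3).
#' @param origin_voxel 0-based voxel index of the mm origin; defaults to the
#'   grid centre.
#' @return A 4x4 affine matrix.
#' @export
mni_affine <- function(dim, voxel_mm = 3, origin_voxel = NULL) {
  dim <- as.integer(dim)
  if (is.null(origin_voxel)) origin_voxel <- (dim - 1L) / 2
  aff <- diag(c(-voxel_mm, voxel_mm, voxel_mm, 1))
  aff[1:3, 4] <- -aff[1:3, 1:3] %*% origin_voxel
  aff
}

#' Check that two grids agree
#'
#' @param a,b `fcnm_grid` objects.
#' @param tol Numeric tolerance on affine entries.
#' @return `TRUE` invisibly, or an error naming the mismatch.
#' @export
stopifnot_same_grid <- function(a, b, tol = 1e-6) {
  if (!identical(a$dim, b$dim)) {
    stop("grid mismatch: shapes differ (", paste(a$dim, collapse = "x"),
      " vs ", paste(b$dim, collapse = "x"), ")",
      call. = FALSE
    )
  }
  if (max(abs(a$affine - b$affine)) > tol) {
    stop("grid mismatch: affines differ", call. = FALSE)
  }
  invisible(TRUE)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert mm coordinates to voxel indices
#'
#' Applies the inverse grid affine and rounds half-away-from-zero so seed
#' membership is reproducible across platforms. Returned indices are 1-based.
#'
#' @param grid An `fcnm_grid`.
#' @param coords Numeric vector of length 3, or an n x 3 matrix / data frame
#'   of mm coordinates.
#' @param label Optional label (e.g. a focus id) used in out-of-bounds errors.
#' @return An n x 3 integer matrix of voxel indices (1-based).
#' @examples
#' g <- fcnm_grid(c(61, 73, 61), mni_affine(c(61, 73, 61), origin_voxel = c(30, 42, 24)))
#' mm_to_voxel(g, c(0, 0, 0))
#' @export
mm_to_voxel <- function(grid, coords, label = NULL) {
  coords <- coerce_coord_matrix(coords)
  ijk0 <- t(solve(grid$affine) %*% rbind(t(coords), 1))[, 1:3, drop = FALSE]
  ijk <- round_half_away(ijk0) + 1
  bad <- ijk[, 1] < 1 | ijk[, 2] < 1 | ijk[, 3] < 1 |
    ijk[, 1] > grid$dim[1] | ijk[, 2] > grid$dim[2] | ijk[, 3] > grid$dim[3]
  if (any(bad)) {
    who <- if (is.null(label)) paste(which(bad), collapse = ", ") else label
    stop("coordinate outside the reference grid: ", who, call. = FALSE)
  }
  storage.mode(ijk) <- "integer"
  ijk
}

#' Convert voxel indices to mm coordinates
#'
#' @param grid An `fcnm_grid`.
#' @param ijk Voxel indices (1-based), vector of length 3 or n x 3 matrix.
#' @return An n x 3 numeric matrix of mm coordinates (voxel centres).
#' @export
voxel_to_mm <- function(grid, ijk) {
  ijk <- coerce_coord_matrix(ijk)
  t(grid$affine %*% rbind(t(ijk) - 1, 1))[, 1:3, drop = FALSE]
}

coerce_coord_matrix <- function(coords) {
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)))
  coords
}

# Lancaster et al. (2007) icbm_spm2tal affine (MNI/SPM space -> Talairach).
# The Talairach -> MNI direction used here is its inverse, computed once.
ICBM_SPM2TAL <- matrix(
  c(
    0.9254, 0.0024, -0.0118, -1.0207,
    -0.0048, 0.9316, -0.0871, -1.7667,
    0.0152, 0.0883, 0.8924, 4.0926,
    0, 0, 0, 1
  ),
  nrow = 4, byrow = TRUE
)

# Brett mni2tal pitch-and-squeeze transforms (z >= 0 and z < 0 branches).
BRETT_UP <- matrix(
  c(
    0.99, 0, 0, 0,
    0, 0.9688, 0.046, 0,
    0, -0.0485, 0.9189, 0,
    0, 0, 0, 1
  ),
  nrow = 4, byrow = TRUE
)
BRETT_DOWN <- matrix(
  c(
    0.99, 0, 0, 0,
    0, 0.9688, 0.042, 0,
    0, -0.0485, 0.839, 0,
    0, 0, 0, 1
  ),
  nrow = 4, byrow = TRUE
)

#' Convert Talairach coordinates to MNI space
#'
#' The default method applies the inverse of the Lancaster `icbm_spm2tal`
#' affine, the current standard for coordinate-based meta-analysis. The
#' alternative `"brett"` method inverts Brett's piecewise mni2tal transform
#' (separate matrices above and below the AC-PC plane).
#'
#' @param coords Talairach mm coordinates: length-3 vector or n x 3 matrix.
#' @param method `"lancaster"` (default, affine) or `"brett"` (piecewise).
#' @return An n x 3 matrix of MNI mm coordinates.
#' @examples
#' tal_to_mni(c(0, 0, 0))
#' @export
tal_to_mni <- function(coords, method = c("lancaster", "brett")) {
  method <- match.arg(method)
  coords <- coerce_coord_matrix(coords)
  if (method == "lancaster") {
    out <- t(solve(ICBM_SPM2TAL) %*% rbind(t(coords), 1))[, 1:3, drop = FALSE]
  } else {
    up <- t(solve(BRETT_UP) %*% rbind(t(coords), 1))[, 1:3, drop = FALSE]
    down <- t(solve(BRETT_DOWN) %*% rbind(t(coords), 1))[, 1:3, drop = FALSE]
    use_down <- up[, 3] < 0
    out <- up
    out[use_down, ] <- down[use_down, , drop = FALSE]
  }
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}
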