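#' Read and validate a foci table
#'
#' A foci table lists one reported activation coordinate per row, the unit of
#' input for network mapping. Required columns: `study_id`, `contrast_id`,
#' `acupoint`, `x`, `y`, `z`, `space`, `n_subjects`. `space` accepts
#' `"MNI"` or `"Talairach"` (aliases `"TAL"`, `"tal"`, case-insensitive).
#' Studies with fewer than 10 participants are rejected, mirroring the
#' inclusion rule of coordinate-based meta-analysis.
#'
#' @param path Path to a CSV or TSV file (delimiter sniffed from the header).
#' @return A tibble of validated focus records, row order preserved, with
#'   `space` normalised to `"MNI"`/`"Talairach"`.
#' @seealso [convert_foci_to_mni()] to map Talairach rows into MNI space.
#' @export
read_foci <- function(path) {
  if (!file.exists(path)) stop("foci table not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path,
    header = TRUE, sep = sep, stringsAsFactors = FALSE,
    colClasses = "character", quote = "\""
  )
  validate_foci(raw)
}

FOCI_COLUMNS <- c(
  "study_id", "contrast_id", "acupoint", "x", "y", "z", "space", "n_subjects"
)

SPACE_ALIASES <- c(
  mni = "MNI", talairach = "Talairach", tal = "Talairach"
)

#' Validate a foci data frame
#'
#' @param foci A data frame with the columns documented in [read_foci()].
#' @return A validated tibble; errors list the offending row numbers.
#' @export
validate_foci <- function(foci) {
  missing_cols <- setdiff(FOCI_COLUMNS, names(foci))
  if (length(missing_cols) > 0) {
    stop(
      "foci table is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::as_tibble(foci)[FOCI_COLUMNS]
  problems <- character()
  flag <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, paste0(what, " (row ", paste(rows, collapse = ", "), ")"))
    }
  }
  for (col in c("x", "y", "z", "n_subjects")) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    flag(which(!is.finite(vals)), paste0("non-numeric ", col))
    out[[col]] <- vals
  }
  space_norm <- unname(SPACE_ALIASES[tolower(trimws(as.character(out$space)))])
  flag(which(is.na(space_norm)), "unknown coordinate space")
  out$space <- space_norm
  flag(which(is.finite(out$n_subjects) & out$n_subjects < 10),
       "sample size below 10 participants")
  if (length(problems) > 0) {
    stop("invalid foci table: ", paste(problems, collapse = "; "), call. = FALSE)
  }
  out$n_subjects <- as.integer(out$n_subjects)
  out
}

#' Convert all foci to MNI millimetre coordinates
#'
#' MNI rows pass through unchanged; Talairach rows are transformed with
#' [tal_to_mni()] and relabelled. The conversion method used is recorded in
#' the `tal_conversion` attribute of the result.
#'
#' @param foci A validated foci tibble.
#' @param method Talairach conversion method, see [tal_to_mni()].
#' @return The foci tibble with all rows in MNI space.
#' @export
convert_foci_to_mni <- function(foci, method = c("lancaster", "brett")) {
  method <- match.arg(method)
  is_tal <- foci$space == "Talairach"
  if (any(is_tal)) {
    mni <- tal_to_mni(as.matrix(foci[is_tal, c("x", "y", "z")]), method = method)
    foci$x[is_tal] <- mni[, 1]
    foci$y[is_tal] <- mni[, 2]
    foci$z[is_tal] <- mni[, 3]
    foci$space[is_tal] <- "MNI"
  }
  attr(foci, "tal_conversion") <- if (any(is_tal)) method else "none"
  foci
}

#' Scalar volume on a reference grid
#'
#' @param grid An `fcnm_grid`.
#' @param data 3D numeric array matching the grid shape.
#' @param kind One of `"t"`, `"p"`, `"z"`, `"probability"`, `"density"`,
#'   `"gm"`, `"binary"`.
#' @return An `fcnm_map` object.
#' @export
fcnm_map <- function(grid, data, kind = c("z", "t", "p", "probability", "density", "gm", "binary")) {
  kind <- match.arg(kind)
  data <- array(as.numeric(data), dim = dim(data))
  if (!identical(dim(data), grid$dim)) {
    stop("map data shape does not match grid", call. = FALSE)
  }
  if (kind == "probability") {
    rng <- range(data, na.rm = TRUE)
    if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12) {
      stop("probability map values must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(grid = grid, data = data, kind = kind), class = "fcnm_map")
}

#' @export
print.fcnm_map <- function(x, ...) {
  cat(sprintf(
    "<fcnm_map kind=%s> %s voxels, range [%.4g, %.4g]\n",
    x$kind, paste(x$grid$dim, collapse = "x"),
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' 4D resting-state time series for one subject
#'
#' @param grid An `fcnm_grid`.
#' @param data 4D array, three spatial axes then time. At least 3 timepoints.
#' @param subject_id Subject identifier.
#' @return An `fcnm_series` object.
#' @export
fcnm_series <- function(grid, data, subject_id = "subject") {
  stopifnot(length(dim(data)) == 4)
  if (!identical(dim(data)[1:3], grid$dim)) {
    stop("series spatial shape does not match grid", call. = FALSE)
  }
  if (dim(data)[4] < 3) stop("series needs at least 3 timepoints", call. = FALSE)
  structure(
    list(grid = grid, data = data, subject_id = as.character(subject_id)),
    class = "fcnm_series"
  )
}

#' @export
print.fcnm_series <- function(x, ...) {
  cat(sprintf(
    "<fcnm_series %s> %s x %d timepoints\n",
    x$subject_id, paste(x$grid$dim, collapse = "x"), dim(x$data)[4]
  ))
  invisible(x)
}

#' Read a NIfTI volume onto a reference grid
#'
#' 3D files come back as an [fcnm_map()], 4D files as an [fcnm_series()].
#' If `grid` is supplied the file's affine and shape must agree with it;
#' disagreement is an error, never a silent resample.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param grid Optional session `fcnm_grid` to check against.
#' @param kind Map kind for 3D volumes (see [fcnm_map()]).
#' @param subject_id Subject id for 4D volumes.
#' @return An `fcnm_map` or `fcnm_series`.
#' @export
read_volume <- function(path, grid = NULL, kind = "z", subject_id = NULL) {
  img <- RNifti::readNifti(path)
  affine <- unname(structure(RNifti::xform(img), explicitness = NULL))
  dims <- dim(img)
  file_grid <- fcnm_grid(dims[1:3], affine)
  if (!is.null(grid)) {
    stopifnot_same_grid(grid, file_grid, tol = 1e-4)
    file_grid <- grid
  }
  data <- array(as.numeric(img), dim = dims)
  if (length(dims) == 3) {
    fcnm_map(file_grid, data, kind = kind)
  } else if (length(dims) == 4) {
    if (is.null(subject_id)) {
      subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
    }
    fcnm_series(file_grid, data, subject_id = subject_id)
  } else {
    stop("unsupported NIfTI dimensionality: ", length(dims), call. = FALSE)
  }
}

#' Write a map or series to NIfTI-1
#'
#' Data are stored as float32 (the native precision of connectivity maps);
#' the round trip through [read_volume()] preserves float32 payloads
#' bit-exactly.
#'
#' @param x An `fcnm_map` or `fcnm_series`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "fcnm_map") || inherits(x, "fcnm_series"))
  arr <- array(as.numeric(x$data), dim = dim(x$data))
  # pixdim must be seeded before conversion; sform<- preserves it but will
  # not rescale a unit-spacing header
  attr(arr, "pixdim") <- x$grid$voxel_size_mm
  img <- RNifti::asNifti(arr, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(x$grid$affine, code = 4L))
  img <- RNifti::`qform<-`(img, structure(x$grid$affine, code = 4L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
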