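#' Brain parcellation for parcel-wise spatial statistics
#'
#' Integer-labelled regions 1..R (0 = background) on the session grid,
#' emulating the 119-region whole-brain parcellation conventionally used
#' for receptor-map correlation.
#'
#' @param grid Session `fcnm_grid`.
#' @param labels Integer 3D array with contiguous region ids 1..R.
#' @param region_names Optional character vector of length R.
#' @return An `fcnm_parcellation` with `n_regions`.
#' @export
fcnm_parcellation <- function(grid, labels, region_names = NULL) {
  labels <- array(as.integer(labels), dim = dim(labels))
  if (!identical(dim(labels), grid$dim)) {
    stop("parcellation shape does not match grid", call. = FALSE)
  }
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  n_regions <- max(c(ids, 0L))
  if (!identical(ids, seq_len(n_regions))) {
    stop("region ids must be contiguous 1..R", call. = FALSE)
  }
  if (is.null(region_names)) {
    region_names <- sprintf("region_%03d", seq_len(n_regions))
  }
  stopifnot(length(region_names) == n_regions)
  structure(
    list(
      grid = grid, labels = labels,
      n_regions = n_regions, region_names = region_names
    ),
    class = "fcnm_parcellation"
  )
}

#' Per-region means of a scalar map
#'
#' Mean of the map over each region's voxels. On a binary network map this
#' is the per-region coverage fraction. Regions with no voxels on the grid
#' are returned as `NA` and excluded pairwise from downstream correlations.
#'
#' @param map An `fcnm_map`, `fcnm_network`, or `fcnm_seed`.
#' @param parc An `fcnm_parcellation` on the same grid.
#' @return Named numeric vector of length R (names = region names).
#' @export
parcel_means <- function(map, parc) {
  if (inherits(map, "fcnm_network") || inherits(map, "fcnm_seed")) {
    map <- as_binary_map(map)
  }
  stopifnot_same_grid(map$grid, parc$grid)
  lab <- as.integer(parc$labels)
  vals <- as.numeric(map$data)
  keep <- lab > 0L
  sums <- rowsum(vals[keep], lab[keep])
  counts <- rowsum(rep(1, sum(keep)), lab[keep])
  out <- rep(NA_real_, parc$n_regions)
  out[as.integer(rownames(sums))] <- sums / counts
  stats::setNames(out, parc$region_names)
}

rank_avg <- function(x) rank(x, ties.method = "average")

residualize <- function(v, covar_ranks) {
  vc <- v - mean(v)
  cc <- covar_ranks - mean(covar_ranks)
  ss <- sum(cc^2)
  if (ss == 0) return(vc)
  vc - cc * (sum(vc * cc) / ss)
}

#' Partial Spearman correlation controlling one covariate
#'
#' Rank-transforms `x`, `y` and the covariate over jointly non-missing
#' regions (average ranks for ties), residualizes the rank vectors of `x`
#' and `y` on the covariate ranks, and correlates the residuals. With a
#' constant covariate this reduces exactly to the plain Spearman
#' correlation. The Fisher z value uses the same `±(1 - 1e-7)` clipping as
#' the connectivity maps.
#'
#' @param x,y Numeric parcel vectors of equal length (NA = missing region).
#' @param covar Optional covariate parcel vector (e.g. gray-matter
#'   probability); `NULL` for plain Spearman.
#' @return A list with `rho`, `rho_z`, and `n` (regions used).
#' @export
partial_spearman <- function(x, y, covar = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(covar)) covar <- rep(0, length(x))
  stopifnot(length(covar) == length(x))
  ok <- is.finite(x) & is.finite(y) & is.finite(covar)
  if (sum(ok) < 5) {
    stop("need at least 5 jointly non-missing regions", call. = FALSE)
  }
  rx <- rank_avg(x[ok])
  ry <- rank_avg(y[ok])
  rc <- rank_avg(covar[ok])
  xr <- residualize(rx, rc)
  yr <- residualize(ry, rc)
  denom <- sqrt(sum(xr^2) * sum(yr^2))
  if (denom == 0) {
    stop("undefined correlation: constant input after ranking", call. = FALSE)
  }
  rho <- sum(xr * yr) / denom
  list(rho = rho, rho_z = atanh(clip_r(rho)), n = sum(ok))
}

clip_r <- function(r) pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)

#' Exact permutation p-value for a partial Spearman correlation
#'
#' Builds the null by uniformly permuting `y`'s region values while keeping
#' `x` and the covariate fixed to their regions, recomputing the partial
#' Spearman statistic for each draw. Two-sided p with the add-one
#' correction: (1 + #{|rho_null| >= |rho_obs|}) / (n_perm + 1), so the
#' smallest attainable p is 1/(n_perm + 1).
#'
#' @inheritParams partial_spearman
#' @param n_perm Number of permutations (>= 100; default 10000).
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @return A list with `rho`, `rho_z`, `p_perm`, `n`, `n_perm`.
#' @export
permutation_pvalue <- function(x, y, covar = NULL, n_perm = 10000, seed = NULL) {
  stopifnot(n_perm >= 100)
  obs <- partial_spearman(x, y, covar)
  if (is.null(covar)) covar <- rep(0, length(x))
  ok <- is.finite(x) & is.finite(y) & is.finite(covar)
  rx <- rank_avg(x[ok])
  ry <- rank_avg(y[ok])
  rc <- rank_avg(covar[ok])
  xr <- residualize(rx, rc)
  n <- length(ry)
  perm_idx <- with_seed(seed, {
    matrix(
      vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)),
      nrow = n
    )
  })
  # permuting values then ranking equals permuting the ranks
  ym <- matrix(ry[perm_idx], nrow = n)
  cc <- rc - mean(rc)
  ss <- sum(cc^2)
  yc <- sweep(ym, 2, colMeans(ym))
  yres <- if (ss == 0) yc else yc - cc %o% (as.numeric(cc %*% yc) / ss)
  rho_null <- as.numeric(crossprod(yres, xr)) /
    sqrt(colSums(yres^2) * sum(xr^2))
  p <- (1 + sum(abs(rho_null) >= abs(obs$rho))) / (n_perm + 1)
  c(obs, list(p_perm = p, n_perm = n_perm))
}

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(eval.parent(substitute(expr)))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

NT_MAP_NAMES <- c(
  "5HT1a", "5HT1b", "5HT2a", "SERT", "D1", "D2", "DAT", "FDOPA",
  "GABAa", "KappaOp", "MU", "NAT", "CB1", "NMDA", "VAChT", "mGluR5"
)

#' Screen a network against a neurotransmitter map catalogue
#'
#' Correlates the parcellated network with each receptor/transporter
#' density map by partial Spearman correlation (gray-matter covariate),
#' attaches an exact permutation p-value per map, and controls the family
#' with BH-FDR at `fdr_alpha`.
#'
#' Two modes:
#' \describe{
#'   \item{single-map}{`x` is one network or scalar map; one correlation
#'     per catalogue entry with a permutation p (the default for the final
#'     consensus network).}
#'   \item{subject-level}{`x` is a list of per-subject connectivity maps;
#'     per catalogue entry, each subject contributes a Fisher-z rho, tested
#'     against zero with a one-sample t whose null is built by permuting
#'     the receptor map's regions.}
#' }
#'
#' @param x An `fcnm_network` / `fcnm_map`, or a list of `fcnm_map` subject
#'   maps.
#' @param catalogue Region-by-map data frame or matrix: R rows, one column
#'   per neurotransmitter map.
#' @param parc The `fcnm_parcellation` matching `x`'s grid.
#' @param gm Gray-matter covariate: parcel vector of length R, an
#'   `fcnm_map`, or `NULL`.
#' @param n_perm Permutations per map (default 10000).
#' @param fdr_alpha FDR level across the catalogue (default 0.05).
#' @param seed Integer seed; per-map sub-streams are derived from it.
#' @return A tibble (class `fcnm_molecular`) with one row per map:
#'   `map`, `rho`, `rho_z`, `p_perm`, `p_fdr`, `significant`, `n_regions`,
#'   sorted by `p_perm`.
#' @export
molecular_screen <- function(x, catalogue, parc, gm = NULL,
                             n_perm = 10000, fdr_alpha = 0.05, seed = 1L) {
  cat_mat <- as.matrix(catalogue)
  stopifnot(nrow(cat_mat) == parc$n_regions, ncol(cat_mat) >= 1)
  if (inherits(gm, "fcnm_map")) gm <- parcel_means(gm, parc)
  subject_mode <- is.list(x) && !inherits(x, c("fcnm_map", "fcnm_network", "fcnm_seed"))
  if (subject_mode) {
    xp <- vapply(x, function(m) parcel_means(m, parc), numeric(parc$n_regions))
  } else {
    xp <- parcel_means(x, parc)
  }
  map_names <- colnames(cat_mat) %||% paste0("map", seq_len(ncol(cat_mat)))
  rows <- purrr::map_dfr(seq_len(ncol(cat_mat)), function(j) {
    sub_seed <- derive_seed(seed, j)
    y <- cat_mat[, j]
    if (subject_mode) {
      res <- subject_level_association(xp, y, gm, n_perm, sub_seed)
    } else {
      res <- permutation_pvalue(xp, y, gm, n_perm = n_perm, seed = sub_seed)
      res <- res[c("rho", "rho_z", "p_perm", "n")]
    }
    tibble::tibble(
      map = map_names[j],
      rho = res$rho, rho_z = res$rho_z,
      p_perm = res$p_perm, n_regions = res$n
    )
  })
  rows$p_fdr <- stats::p.adjust(rows$p_perm, method = "BH")
  rows$significant <- rows$p_fdr < fdr_alpha
  rows <- dplyr::arrange(rows, .data$p_perm, .data$map)
  class(rows) <- c("fcnm_molecular", class(rows))
  rows
}

# Subject-level association: mean Fisher-z rho across subject maps, one-sample
# t against zero, null by permuting the receptor map once per draw (shared
# across subjects within a draw).
subject_level_association <- function(xp_mat, y, gm, n_perm, seed) {
  rho_z_obs <- apply(xp_mat, 2, function(col) {
    partial_spearman(col, y, gm)$rho_z
  })
  t_obs <- one_sample_t(rho_z_obs)
  n_sub <- ncol(xp_mat)
  t_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yp <- sample(y)
      zb <- apply(xp_mat, 2, function(col) partial_spearman(col, yp, gm)$rho_z)
      one_sample_t(zb)
    }, numeric(1))
  })
  p <- (1 + sum(abs(t_null) >= abs(t_obs))) / (n_perm + 1)
  list(
    rho = mean(tanh(rho_z_obs)), rho_z = mean(rho_z_obs),
    p_perm = p, n = sum(is.finite(y))
  )
}

one_sample_t <- function(v) {
  s <- stats::sd(v)
  if (s == 0) {
    return(sign(mean(v)) * Inf)
  }
  mean(v) / (s / sqrt(length(v)))
}

# Derive a bounded sub-stream seed (keeps within 32-bit integer range).
derive_seed <- function(seed, k) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.double(seed) * 1009 + 97 * as.double(k)) %% 2147483629)
}
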