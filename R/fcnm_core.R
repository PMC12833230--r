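#' Mean time series over a seed mask
#'
#' @param series An `fcnm_series`.
#' @param seed An `fcnm_seed` on the same grid.
#' @return Numeric vector of length T: the unweighted mean of the seed
#'   voxels' series at each timepoint.
#' @export
seed_mean_timeseries <- function(series, seed) {
  stopifnot_same_grid(series$grid, seed$grid)
  nvox <- prod(series$grid$dim)
  tt <- dim(series$data)[4]
  mat <- matrix(series$data, nrow = nvox, ncol = tt)
  colMeans(mat[seed$linear, , drop = FALSE])
}

#' Seed-to-whole-brain connectivity map for one subject
#'
#' Pearson correlation between the seed's mean time series and every voxel
#' inside the brain mask, Fisher z-transformed (`atanh`) to approximate
#' normality for the group test. Correlations are clipped to
#' `±(1 - 1e-7)` before the transform so the map stays finite; voxels whose
#' series has zero variance get z = 0 and are recorded in the
#' `zero_variance` attribute (they are excluded from the multiple-testing
#' family downstream).
#'
#' @param series An `fcnm_series` with at least 3 timepoints.
#' @param seed An `fcnm_seed` on the same grid.
#' @return An `fcnm_map` of kind `"z"`, zero outside the brain mask, with
#'   attributes `subject_id`, `seed_id`, and `zero_variance` (linear indices).
#' @export
subject_fc_map <- function(series, seed) {
  stopifnot_same_grid(series$grid, seed$grid)
  grid <- series$grid
  tt <- dim(series$data)[4]
  if (tt < 3) stop("need at least 3 timepoints", call. = FALSE)
  s <- seed_mean_timeseries(series, seed)
  if (stats::sd(s) == 0) {
    stop("degenerate seed: mean time series is constant", call. = FALSE)
  }
  mask_lin <- which(grid$mask)
  mat <- matrix(series$data, nrow = prod(grid$dim), ncol = tt)[mask_lin, , drop = FALSE]
  r <- fast_pearson(s, mat)
  zero_var <- mask_lin[is.na(r)]
  r[is.na(r)] <- 0
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  z[match(zero_var, mask_lin)] <- 0
  data <- array(0, dim = grid$dim)
  data[mask_lin] <- z
  out <- fcnm_map(grid, data, kind = "z")
  attr(out, "subject_id") <- series$subject_id
  attr(out, "seed_id") <- seed$id
  attr(out, "zero_variance") <- zero_var
  out
}

# Pearson r of vector s against each row of mat (rows = voxels, cols = time).
# Returns NA for zero-variance rows.
fast_pearson <- function(s, mat) {
  tt <- length(s)
  sc <- s - mean(s)
  mc <- mat - rowMeans(mat)
  num <- as.numeric(mc %*% sc)
  den <- sqrt(rowSums(mc^2) * sum(sc^2))
  r <- num / den
  r[den == 0] <- NA_real_
  r
}

#' Voxel-wise one-sample t-test over subject connectivity maps
#'
#' Tests, at each brain-mask voxel, whether the mean Fisher-z connectivity
#' across subjects differs from zero: t = mean / (sd / sqrt(n)), df = n - 1,
#' two-sided p from the t distribution (a one-sided variant is available via
#' `alternative`). Degenerate voxels (zero variance across subjects) get
#' p = 0 when the mean is nonzero and t = 0, p = 1 when the mean is zero;
#' both are flagged.
#'
#' @param maps List of `fcnm_map` objects (kind `"z"`), one per subject, on
#'   a common grid.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return An `fcnm_group`: `t_map`, `p_map`, `df`, `n_subjects`,
#'   `degenerate` (linear indices with zero across-subject variance), and
#'   `zero_variance` (voxels flagged in any subject map).
#' @export
group_onesample <- function(maps, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (length(maps) < 3) stop("need at least 3 subject maps", call. = FALSE)
  grid <- maps[[1]]$grid
  for (m in maps[-1]) stopifnot_same_grid(grid, m$grid)
  mask_lin <- which(grid$mask)
  n <- length(maps)
  vals <- vapply(maps, function(m) m$data[mask_lin], numeric(length(mask_lin)))
  mu <- rowMeans(vals)
  sdv <- sqrt(rowSums((vals - mu)^2) / (n - 1))
  tstat <- mu / (sdv / sqrt(n))
  df <- n - 1L
  p <- if (alternative == "two.sided") {
    2 * stats::pt(-abs(tstat), df)
  } else {
    stats::pt(tstat, df, lower.tail = FALSE)
  }
  degen <- sdv == 0
  tstat[degen & mu == 0] <- 0
  p[degen & mu == 0] <- 1
  p[degen & mu != 0] <- 0
  t_data <- array(0, dim = grid$dim)
  p_data <- array(1, dim = grid$dim)
  t_data[mask_lin] <- tstat
  p_data[mask_lin] <- p
  zero_var <- sort(unique(unlist(lapply(maps, attr, "zero_variance"))))
  structure(
    list(
      t_map = fcnm_map(grid, t_data, kind = "t"),
      p_map = fcnm_map(grid, p_data, kind = "p"),
      df = df, n_subjects = n,
      degenerate = mask_lin[degen],
      zero_variance = zero_var,
      alternative = alternative,
      seed_id = attr(maps[[1]], "seed_id") %||% "network"
    ),
    class = "fcnm_group"
  )
}

#' @export
print.fcnm_group <- function(x, ...) {
  cat(sprintf(
    "<fcnm_group> one-sample t over %d subjects (df = %d, %s)\n",
    x$n_subjects, x$df, x$alternative
  ))
  invisible(x)
}

#' Benjamini-Hochberg selection at a target false discovery rate
#'
#' Step-up rule: with ordered p-values p(1) <= ... <= p(m), reject the k
#' smallest where k = max{ i : p(i) <= i q / m }. Ties at the threshold are
#' all rejected (the rule depends only on values, not order). Implemented
#' through [stats::p.adjust()], whose BH adjustment is equivalent to the
#' step-up search.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q Target FDR in `(0, 1)`.
#' @return Logical vector: `TRUE` where the hypothesis is rejected.
#' @export
fdr_select <- function(p, q) {
  if (length(p) == 0) stop("empty p-value vector", call. = FALSE)
  stopifnot(all(p >= 0 & p <= 1), q > 0, q < 1)
  stats::p.adjust(p, method = "BH") <= q
}

#' Binarize a group result: FDR-significant positive connectivity
#'
#' Keeps voxels that survive BH-FDR at rate `q` and have t > 0; only
#' positive connectivity enters the network, as the interpretation of
#' negative resting-state correlations is contentious. The multiple-testing
#' family is the brain-mask voxels, excluding voxels that were degenerate
#' (zero variance with zero mean) or zero-variance in any subject map.
#'
#' @param group An `fcnm_group`.
#' @param q Voxel-wise FDR threshold (default 0.01).
#' @param positive_only Require t > 0 (default `TRUE`); set `FALSE` to keep
#'   every FDR-significant voxel regardless of sign.
#' @return An `fcnm_network`: voxel set with `linear` indices, the grid, and
#'   metadata. May be empty (a message is emitted).
#' @export
binarize_positive <- function(group, q = 0.01, positive_only = TRUE) {
  grid <- group$t_map$grid
  mask_lin <- which(grid$mask)
  excluded <- union(
    intersect(group$degenerate, which(group$t_map$data == 0)),
    group$zero_variance
  )
  family <- setdiff(mask_lin, excluded)
  if (length(family) == 0) {
    message("binarize_positive: no voxel survives FDR at q = ", q)
    return(new_network(grid, integer(0),
      id = group$seed_id,
      meta = list(q = q, n_subjects = group$n_subjects)
    ))
  }
  p <- group$p_map$data[family]
  keep <- fdr_select(p, q)
  if (positive_only) keep <- keep & group$t_map$data[family] > 0
  linear <- family[keep]
  if (length(linear) == 0) {
    message("binarize_positive: no voxel survives FDR at q = ", q)
  }
  new_network(grid, linear,
    id = group$seed_id,
    meta = list(q = q, n_subjects = group$n_subjects)
  )
}

new_network <- function(grid, linear, id = NULL, meta = list()) {
  structure(
    list(
      grid = grid,
      linear = as.integer(sort(linear)),
      voxels = arrayInd(as.integer(sort(linear)), grid$dim),
      id = id %||% "network",
      meta = meta
    ),
    class = "fcnm_network"
  )
}

#' @export
print.fcnm_network <- function(x, ...) {
  cat(sprintf("<fcnm_network %s> %d voxels\n", x$id, length(x$linear)))
  invisible(x)
}

#' Across-study probability map
#'
#' The voxel-wise fraction of binary per-unit networks that contain each
#' voxel: agreement across studies, in steps of 1/N.
#'
#' @param networks List of `fcnm_network` objects (>= 2) on a common grid.
#' @return An `fcnm_map` of kind `"probability"` with attribute `n_maps`.
#' @export
probability_map <- function(networks) {
  if (length(networks) < 2) stop("need at least 2 binary maps", call. = FALSE)
  grid <- networks[[1]]$grid
  counts <- array(0, dim = grid$dim)
  for (net in networks) {
    stopifnot_same_grid(grid, net$grid)
    counts[net$linear] <- counts[net$linear] + 1
  }
  out <- fcnm_map(grid, counts / length(networks), kind = "probability")
  attr(out, "n_maps") <- length(networks)
  out
}

#' Threshold a probability map into a consensus network
#'
#' Keeps voxels present in at least `threshold` of the per-unit networks
#' (inclusive, so a 60% threshold over 14 studies keeps voxels in 9 or
#' more: 9/14 ~ 0.643 passes, 8/14 ~ 0.571 does not).
#'
#' @param pmap Probability `fcnm_map` from [probability_map()].
#' @param threshold Fraction in `(0, 1]` (default 0.60).
#' @param id Network label (e.g. the acupoint).
#' @return An `fcnm_network`.
#' @export
threshold_probability <- function(pmap, threshold = 0.60, id = "network") {
  stopifnot(threshold > 0, threshold <= 1)
  linear <- which(pmap$data >= threshold - 1e-12)
  new_network(pmap$grid, linear,
    id = id,
    meta = list(
      threshold = threshold,
      n_maps = attr(pmap, "n_maps")
    )
  )
}
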