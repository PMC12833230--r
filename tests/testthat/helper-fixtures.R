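# Shared fixtures and independent oracles for the suite.

# Small all-TRUE grid with the standard negative-x 3 mm affine.
tiny_grid <- function(dim = c(12, 12, 12), voxel_mm = 3, mask = NULL) {
  fcnm_grid(dim, mni_affine(dim, voxel_mm), mask)
}

# Well-formed foci tibble.
make_foci <- function(n = 3, acupoint = "ST36", study = "s1", space = "MNI",
                      xyz = NULL, n_subjects = 20) {
  if (is.null(xyz)) xyz <- matrix(seq_len(3 * n), ncol = 3)
  tibble::tibble(
    study_id = study,
    contrast_id = paste0("c", seq_len(n)),
    acupoint = acupoint,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    space = space,
    n_subjects = n_subjects
  )
}

# Brute-force BH step-up: largest k with p(k) <= k*q/m, reject all p <= p(k).
bh_bruteforce <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0) {
    return(rep(FALSE, m))
  }
  p <= ps[max(ok)]
}

# Independent partial-Spearman oracle: pairwise Spearman correlations fed
# through the textbook first-order partial correlation formula.
partial_spearman_oracle <- function(x, y, covar) {
  rxy <- stats::cor(x, y, method = "spearman")
  rxc <- stats::cor(x, covar, method = "spearman")
  ryc <- stats::cor(y, covar, method = "spearman")
  (rxy - rxc * ryc) / sqrt((1 - rxc^2) * (1 - ryc^2))
}

# Per-voxel Pearson + Fisher z oracle: plain loops over cor().
fc_map_oracle <- function(series, seed) {
  s <- seed_mean_timeseries(series, seed)
  grid <- series$grid
  out <- array(0, dim = grid$dim)
  tt <- dim(series$data)[4]
  flat <- matrix(series$data, nrow = prod(grid$dim), ncol = tt)
  for (v in which(grid$mask)) {
    vs <- flat[v, ]
    if (stats::sd(vs) == 0) next
    r <- stats::cor(s, vs)
    r <- min(max(r, -(1 - 1e-7)), 1 - 1e-7)
    out[v] <- atanh(r)
  }
  out
}

# A small deterministic network on a grid from explicit voxel coordinates.
make_network <- function(grid, ijk, id = "net") {
  lin <- ijk[, 1] + (ijk[, 2] - 1) * grid$dim[1] +
    (ijk[, 3] - 1) * grid$dim[1] * grid$dim[2]
  fcnm:::new_network(grid, lin, id = id)
}
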