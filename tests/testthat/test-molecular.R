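three_region_parc <- function(g) {
  labels <- array(0L, g$dim)
  labels[1:2, 1, 1] <- 1L
  labels[3:5, 1, 1] <- 2L
  labels[1:2, 2, 1] <- 3L
  fcnm_parcellation(g, labels)
}

test_that("parcel means average region voxels and flag absent regions", {
  g <- tiny_grid(c(6, 6, 6))
  labels <- array(0L, g$dim)
  labels[c(1, 2, 3)] <- 1L
  labels[c(10, 11)] <- 2L
  labels[20] <- 3L
  parc <- fcnm_parcellation(g, labels)
  data <- array(0, g$dim)
  data[c(1, 2, 3)] <- c(1, 2, 3)
  data[c(10, 11)] <- c(4, 8)
  pm <- parcel_means(fcnm_map(g, data, kind = "density"), parc)
  expect_equal(unname(pm), c(2, 6, 0))
  # binary network map -> per-region coverage fraction
  net <- fcnm:::new_network(g, c(1L, 2L, 10L))
  cov <- parcel_means(net, parc)
  expect_equal(unname(cov), c(2 / 3, 1 / 2, 0))
})

test_that("regions without voxels come back missing", {
  g <- tiny_grid(c(6, 6, 6))
  labels <- array(0L, g$dim)
  labels[1:4] <- 1L
  labels[5:8] <- 2L
  parc3 <- fcnm_parcellation(g, labels)
  expect_equal(parc3$n_regions, 2)
  # simulate a catalogue with 3 regions against a 2-region grid is a
  # constructor error; missingness instead arises from empty masks
  m <- fcnm_map(g, array(1, g$dim), kind = "density")
  expect_false(anyNA(parcel_means(m, parc3)))
})

test_that("partial Spearman reduces to plain Spearman for a constant covariate", {
  set.seed(31)
  for (i in 1:20) {
    x <- stats::rnorm(30)
    y <- stats::rnorm(30)
    ps <- partial_spearman(x, y, rep(2.5, 30))
    expect_equal(ps$rho, stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
    ps2 <- partial_spearman(x, y, NULL)
    expect_equal(ps2$rho, ps$rho, tolerance = 1e-12)
  }
})

test_that("partial Spearman agrees with the pairwise-correlation oracle", {
  set.seed(32)
  for (i in 1:100) {
    n <- sample(10:120, 1)
    x <- stats::rnorm(n)
    y <- 0.4 * x + stats::rnorm(n)
    covar <- 0.3 * x + stats::rnorm(n)
    got <- partial_spearman(x, y, covar)$rho
    expect_equal(got, partial_spearman_oracle(x, y, covar), tolerance = 1e-12)
  }
})

test_that("partial Spearman is symmetric and monotone-invariant", {
  set.seed(33)
  x <- stats::rgamma(40, 2)
  y <- 0.5 * x + stats::rnorm(40)
  covar <- stats::rnorm(40)
  expect_equal(partial_spearman(x, y, covar)$rho, partial_spearman(y, x, covar)$rho)
  expect_equal(
    partial_spearman(exp(x), y, covar)$rho,
    partial_spearman(x, y, covar)$rho,
    tolerance = 1e-12
  )
  expect_equal(
    partial_spearman(x, log(y - min(y) + 1), covar)$rho,
    partial_spearman(x, y, covar)$rho,
    tolerance = 1e-12
  )
})

test_that("identical x and y give a clipped Fisher z; degenerate input errors", {
  x <- stats::rnorm(20)
  ps <- partial_spearman(x, x, stats::rnorm(20))
  expect_equal(ps$rho, 1, tolerance = 1e-9)
  expect_equal(ps$rho_z, atanh(1 - 1e-7))
  expect_error(partial_spearman(rep(1, 10), stats::rnorm(10), NULL), "constant")
  expect_error(partial_spearman(stats::rnorm(4), stats::rnorm(4), NULL), "at least 5")
})

test_that("missing regions are excluded pairwise", {
  set.seed(35)
  x <- stats::rnorm(30)
  y <- stats::rnorm(30)
  x[c(3, 7)] <- NA
  y[11] <- NA
  ok <- is.finite(x) & is.finite(y)
  got <- partial_spearman(x, y, NULL)
  expect_equal(got$n, sum(ok))
  expect_equal(got$rho, stats::cor(x[ok], y[ok], method = "spearman"), tolerance = 1e-12)
})

test_that("permutation p has the add-one floor and is seed-reproducible", {
  set.seed(36)
  x <- seq_len(40) + stats::rnorm(40, sd = 0.01)
  y <- x # |rho_obs| ~ 1 beats every null draw
  p <- permutation_pvalue(x, y, NULL, n_perm = 199, seed = 7)
  expect_equal(p$p_perm, 1 / 200)
  p2 <- permutation_pvalue(x, y, NULL, n_perm = 199, seed = 7)
  expect_identical(p, p2)
  p3 <- permutation_pvalue(x, y, NULL, n_perm = 199, seed = 8)
  expect_identical(p3$rho, p$rho)
})

test_that("a zero observed correlation yields p near one", {
  # x constant ranks except tiny noise, y orthogonal pattern by symmetry
  set.seed(37)
  n <- 41
  x <- stats::rnorm(n)
  y <- sample(x) # same values, random order: rho ~ 0 on average
  # craft exact zero: use a self-paired antisymmetric pattern
  x0 <- c(-5:-1, 0, 1:5)
  y0 <- c(5:1, 0, 1:5) # even in x: y(-k) = y(k), so Spearman rho is exactly 0
  p <- permutation_pvalue(x0, y0, NULL, n_perm = 499, seed = 3)
  expect_equal(p$rho, 0, tolerance = 1e-12)
  expect_gt(p$p_perm, 0.95)
})

test_that("the permutation stream leaves the caller's RNG untouched", {
  x <- stats::rnorm(20)
  y <- stats::rnorm(20)
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(permutation_pvalue(x, y, NULL, n_perm = 100, seed = 5))
  expect_identical(stats::runif(1), before)
})

test_that("the screen reports one association per catalogue map with BH control", {
  g <- tiny_grid(c(10, 10, 6))
  set.seed(40)
  labels <- array(0L, g$dim)
  labels[] <- sample(1:25, prod(g$dim), replace = TRUE)
  parc <- fcnm_parcellation(g, labels)
  net_lin <- sample(prod(g$dim), 60)
  net <- fcnm:::new_network(g, net_lin, id = "net")
  target <- parcel_means(net, parc)
  nt <- gen_nt_catalogue(parc, target,
    rho_targets = c(FDOPA = 0.9, D1 = 0, D2 = 0, NAT = 0), seed = 11
  )
  scr <- molecular_screen(net, nt$catalogue, parc,
    gm = nt$gm,
    n_perm = 499, fdr_alpha = 0.05, seed = 2
  )
  expect_equal(nrow(scr), 4)
  expect_setequal(scr$map, c("FDOPA", "D1", "D2", "NAT"))
  # BH-adjusted p is monotone in the raw permutation p
  ord <- order(scr$p_perm)
  expect_true(all(diff(scr$p_fdr[ord]) >= -1e-12))
  expect_identical(scr$significant, scr$p_fdr < 0.05)
  expect_true(scr$significant[scr$map == "FDOPA"])
})

test_that("subject-level mode aggregates per-subject correlations", {
  g <- tiny_grid(c(8, 8, 4))
  set.seed(41)
  labels <- array(sample(1:16, prod(g$dim), replace = TRUE), g$dim)
  parc <- fcnm_parcellation(g, labels)
  pattern <- array(stats::rnorm(prod(g$dim)), g$dim)
  subject_maps <- lapply(1:6, function(i) {
    fcnm_map(g, pattern + array(stats::rnorm(prod(g$dim), sd = 0.3), g$dim), kind = "z")
  })
  target <- parcel_means(fcnm_map(g, pattern, kind = "z"), parc)
  nt <- gen_nt_catalogue(parc, target, rho_targets = c(SERT = 0.9, MU = 0), seed = 4)
  scr <- molecular_screen(subject_maps, nt$catalogue, parc,
    gm = nt$gm,
    n_perm = 199, seed = 6
  )
  expect_equal(nrow(scr), 2)
  expect_lt(scr$p_perm[scr$map == "SERT"], scr$p_perm[scr$map == "MU"])
  expect_gt(scr$rho_z[scr$map == "SERT"], 0.5)
})
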