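series_from_matrix <- function(grid, voxel_series) {
  # voxel_series: named list linear-index -> numeric vector; others zero noise
  tt <- length(voxel_series[[1]])
  data <- array(0, dim = c(grid$dim, tt))
  flat <- matrix(data, nrow = prod(grid$dim))
  for (lin in names(voxel_series)) flat[as.integer(lin), ] <- voxel_series[[lin]]
  array(flat, dim = c(grid$dim, tt))
}

test_that("seed mean time series averages exactly the seed voxels", {
  g <- tiny_grid(c(8, 8, 8))
  s1 <- c(1, 2, 3, 4)
  lin <- c(10L, 11L, 12L)
  data <- series_from_matrix(g, stats::setNames(
    list(s1, -s1, c(2, 2, 2, 2)), as.character(lin)
  ))
  series <- fcnm_series(g, data)
  single <- fcnm:::new_seed(g, lin[1], "one")
  expect_equal(seed_mean_timeseries(series, single), s1)
  pair <- fcnm:::new_seed(g, lin[1:2], "pair")
  expect_equal(seed_mean_timeseries(series, pair), c(0, 0, 0, 0))
  triple <- fcnm:::new_seed(g, lin, "triple")
  expect_equal(seed_mean_timeseries(series, triple), (s1 - s1 + 2) / 3)
})

test_that("subject FC map follows the Pearson + clipped atanh contract", {
  g <- tiny_grid(c(8, 8, 8))
  seed_series <- c(1, 2, 3, 4)
  # perfectly correlated, orthogonal (r = 0), and near-collinear voxels
  ortho <- c(1, -1, -1, 1) # orthogonal to the centred seed series
  near <- c(1, 2, 3, 5)
  data <- series_from_matrix(g, stats::setNames(
    list(seed_series, seed_series, ortho, near),
    c("20", "30", "40", "50")
  ))
  fc <- subject_fc_map(fcnm_series(g, data), fcnm:::new_seed(g, 20L, "s"))
  expect_equal(fc$data[30], atanh(1 - 1e-7))
  expect_equal(fc$data[40], 0)
  r_expect <- stats::cor(seed_series, near)
  expect_equal(fc$data[50], atanh(r_expect), tolerance = 1e-12)
  expect_equal(r_expect, 0.9827076, tolerance = 1e-6)
  # zero-variance voxels: z = 0 and flagged
  expect_true(60L %in% attr(fc, "zero_variance"))
  expect_equal(fc$data[60], 0)
})

test_that("a constant seed series is a degenerate-seed error", {
  g <- tiny_grid(c(8, 8, 8))
  data <- series_from_matrix(g, list(`20` = c(5, 5, 5, 5)))
  expect_error(
    subject_fc_map(fcnm_series(g, data), fcnm:::new_seed(g, 20L, "s")),
    "degenerate seed"
  )
})

test_that("FC map equals the independent per-voxel oracle on a random volume", {
  dim <- c(6, 6, 6)
  g <- tiny_grid(dim)
  set.seed(42)
  series <- fcnm_series(g, array(stats::rnorm(prod(dim) * 20), dim = c(dim, 20)))
  seed <- fcnm:::new_seed(g, c(1L, 2L, 40L), "s")
  fc <- subject_fc_map(series, seed)
  expect_lt(max(abs(fc$data - fc_map_oracle(series, seed))), 1e-10)
})

test_that("the one-sample t matches the closed form", {
  g <- tiny_grid(c(6, 6, 6))
  make_map <- function(vals) {
    data <- array(0, dim = g$dim)
    data[c(10, 20, 30)] <- vals
    fcnm_map(g, data, kind = "z")
  }
  # voxel 10: (1, 2, 3); voxel 20: all zero; voxel 30: constant 0.5
  maps <- list(make_map(c(1, 0, 0.5)), make_map(c(2, 0, 0.5)), make_map(c(3, 0, 0.5)))
  grp <- group_onesample(maps)
  expect_equal(grp$df, 2)
  expect_equal(grp$t_map$data[10], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(grp$p_map$data[10], 2 * stats::pt(-2 / (1 / sqrt(3)), 2), tolerance = 1e-12)
  expect_equal(grp$p_map$data[10], 0.0741799, tolerance = 1e-5)
  expect_equal(grp$t_map$data[20], 0)
  expect_equal(grp$p_map$data[20], 1)
  expect_equal(grp$p_map$data[30], 0)
  expect_true(30L %in% grp$degenerate)
  expect_error(group_onesample(maps[1:2]), "at least 3")
})

test_that("BH selection agrees with the worked example and edge rules", {
  expect_equal(
    fdr_select(c(0.001, 0.008, 0.039, 0.041, 0.09), 0.05),
    c(TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  expect_false(any(fdr_select(rep(1, 10), 0.05)))
  expect_true(fdr_select(0.009, 0.01))
  expect_error(fdr_select(numeric(0), 0.05), "empty")
})

test_that("BH selection equals the brute-force max-k search with ties", {
  set.seed(99)
  for (i in 1:1000) {
    m <- sample(1:200, 1)
    p <- stats::runif(m)
    if (m > 3) {
      # force ties, including at potential thresholds
      p[sample(m, 2)] <- p[1]
      p[sample(m, 1)] <- round(p[2], 2)
    }
    q <- stats::runif(1, 0.01, 0.2)
    expect_identical(fdr_select(p, q), bh_bruteforce(p, q))
  }
})

test_that("binarization keeps FDR-surviving positive voxels only", {
  g <- tiny_grid(c(6, 6, 6))
  n <- 10
  set.seed(5)
  maps <- lapply(1:n, function(i) {
    data <- array(stats::rnorm(prod(g$dim), sd = 0.05), dim = g$dim)
    data[10] <- 2 + stats::rnorm(1, sd = 0.1) # strong positive
    data[20] <- -2 + stats::rnorm(1, sd = 0.1) # strong negative
    fcnm_map(g, data, kind = "z")
  })
  grp <- group_onesample(maps)
  net <- binarize_positive(grp, q = 0.01)
  expect_true(10L %in% net$linear)
  expect_false(20L %in% net$linear)
  both <- binarize_positive(grp, q = 0.01, positive_only = FALSE)
  expect_true(all(c(10L, 20L) %in% both$linear))
})

test_that("all-null p-values give an empty network (allowed, logged)", {
  g <- tiny_grid(c(5, 5, 5))
  maps <- lapply(1:4, function(i) {
    data <- array(0, dim = g$dim)
    fcnm_map(g, data, kind = "z")
  })
  grp <- group_onesample(maps)
  expect_message(net <- binarize_positive(grp, q = 0.01), "no voxel survives")
  expect_equal(length(net$linear), 0)
})

test_that("probability map records exact per-voxel fractions", {
  g <- tiny_grid(c(6, 6, 6))
  nets <- lapply(
    list(c(10L, 20L, 40L), c(10L, 20L, 40L), c(10L, 20L, 30L), c(10L)),
    function(lin) fcnm:::new_network(g, lin)
  )
  pm <- probability_map(nets)
  expect_equal(attr(pm, "n_maps"), 4)
  expect_equal(pm$data[10], 1)
  expect_equal(pm$data[20], 0.75)
  expect_equal(pm$data[30], 0.25)
  expect_equal(pm$data[40], 0.5)
  expect_equal(pm$data[50], 0)
  # identical maps -> values in {0, 1}
  pm2 <- probability_map(nets[c(1, 2)])
  expect_true(all(pm2$data %in% c(0, 1)))
  expect_error(probability_map(nets[1]), "at least 2")
})

test_that("probability thresholding is inclusive and nests across levels", {
  g <- tiny_grid(c(6, 6, 6))
  nets <- lapply(
    list(c(10L, 20L, 40L), c(10L, 20L, 40L), c(10L, 20L, 30L), c(10L)),
    function(lin) fcnm:::new_network(g, lin)
  )
  pm <- probability_map(nets)
  at60 <- threshold_probability(pm, 0.60)
  expect_true(20L %in% at60$linear) # 0.75 >= 0.6
  expect_false(30L %in% at60$linear) # 0.25 < 0.6
  expect_false(40L %in% at60$linear) # 0.50 < 0.6
  # nesting across thresholds on random probability maps
  set.seed(14)
  for (i in 1:20) {
    counts <- array(sample(0:10, prod(g$dim), replace = TRUE), dim = g$dim)
    pmap <- fcnm_map(g, counts / 10, kind = "probability")
    attr(pmap, "n_maps") <- 10
    t1 <- stats::runif(1, 0.05, 0.5)
    t2 <- stats::runif(1, t1, 1)
    expect_true(all(
      threshold_probability(pmap, t2)$linear %in% threshold_probability(pmap, t1)$linear
    ))
  }
})

test_that("the minimum surviving study count matches the 60% arithmetic", {
  expect_equal(min_surviving_count(14, 0.60), 9L) # 9/14 ~ 0.643, 8/14 ~ 0.571
  expect_equal(min_surviving_count(4, 0.60), 3L)
  # threshold -> 0+ keeps every nonzero voxel
  expect_equal(min_surviving_count(14, 1e-9), 1L)
})
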