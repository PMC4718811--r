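make_paired_sets <- function(a_vals, b_vals, spacing = c(1, 1, 1)) {
  to_set <- function(vals, g)
    scan_set(lapply(seq_len(dim(vals)[4]), function(i)
      brain_volume(vals[, , , i, drop = TRUE], spacing)),
      sprintf("s%02d", seq_len(dim(vals)[4])), g)
  list(a = to_set(a_vals, "A"), b = to_set(b_vals, "B"))
}

test_that("identical groups give t = 0 and p = 1 everywhere", {
  set.seed(1)
  vals <- array(rnorm(4 * 4 * 2 * 5), c(4, 4, 2, 5))
  sets <- make_paired_sets(vals, vals)
  mask <- brain_mask(array(1, c(4, 4, 2)), c(1, 1, 1))
  sm <- paired_t_map(sets$a, sets$b, mask)
  expect_true(all(sm$t[mask$values != 0] == 0))
  expect_true(all(sm$p[mask$values != 0] == 1))
  expect_equal(sm$df, 4)
})

test_that("fewer than 3 pairs is rejected", {
  set.seed(2)
  vals <- array(rnorm(2 * 2 * 2 * 2), c(2, 2, 2, 2))
  sets <- make_paired_sets(vals, vals + 1)
  mask <- brain_mask(array(1, c(2, 2, 2)), c(1, 1, 1))
  expect_error(paired_t_map(sets$a, sets$b, mask), "at least 3 pairs")
})

test_that("the paired t statistic matches its closed-form expectation", {
  # planted difference d with noise sd s at n pairs: E[t] ~ d / (s / sqrt(n))
  # (up to the small-sample bias of 1/sd); Monte Carlo over 200 cohorts
  d <- 0.8; s <- 1; n <- 12
  dims <- c(4L, 4L, 2L)
  region <- array(FALSE, dims); region[1:2, 1:2, 1] <- TRUE
  mask <- brain_mask(array(1, dims), c(1, 1, 1))
  set.seed(33)
  tbar <- replicate(200, {
    base <- array(rnorm(prod(dims) * n), c(dims, n))
    delta <- array(rnorm(prod(dims) * n, sd = s), c(dims, n))
    delta[region] <- delta[region] # noise everywhere
    b <- base + delta + array(rep(region * d, n), c(dims, n))
    sets <- make_paired_sets(base, b)
    mean(paired_t_map(sets$a, sets$b, mask)$t[region])
  })
  expected <- d / (s / sqrt(n)) # = 2.77
  # small-sample E[1/sd] inflation for n=12 is ~7%; allow 10% band
  expect_gt(mean(tbar), expected * 0.9)
  expect_lt(mean(tbar), expected * 1.2)
})

test_that("welch fallback handles unequal group sizes", {
  set.seed(5)
  a <- array(rnorm(2 * 2 * 2 * 8), c(2, 2, 2, 8))
  b <- array(rnorm(2 * 2 * 2 * 6, mean = 2), c(2, 2, 2, 6))
  sa <- scan_set(lapply(1:8, function(i) brain_volume(a[, , , i], c(1, 1, 1))),
                 sprintf("a%d", 1:8), "A")
  sb <- scan_set(lapply(1:6, function(i) brain_volume(b[, , , i], c(1, 1, 1))),
                 sprintf("b%d", 1:6), "B")
  mask <- brain_mask(array(1, c(2, 2, 2)), c(1, 1, 1))
  expect_error(paired_t_map(sa, sb, mask), "no shared subject IDs")
  sm <- paired_t_map(sa, sb, mask, method = "welch")
  expect_true(all(sm$t[mask$values != 0] > 0))
})

test_that("BH-FDR matches the step-up definition on worked examples", {
  r1 <- bh_fdr(c(0.001, 0.002, 0.003), q = 0.05)
  expect_true(all(r1$reject))
  # step-up: thresholds i*q/m = .0125/.025/.0375/.05; p_(3)=0.04 > .0375,
  # so exactly the two smallest are rejected
  r2 <- bh_fdr(c(0.01, 0.02, 0.04, 0.50), q = 0.05)
  expect_identical(r2$reject, c(TRUE, TRUE, FALSE, FALSE))
  r0 <- bh_fdr(numeric(0))
  expect_length(r0$reject, 0)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  expect_error(bh_fdr(c(0.5, -0.1)), "0, 1")
})

test_that("BH-FDR rejections equal a brute-force step-up oracle", {
  brute_bh <- function(p, q) {
    m <- length(p)
    o <- order(p)
    k <- 0
    for (i in seq_len(m)) if (p[o[i]] <= i * q / m) k <- i
    rej <- rep(FALSE, m)
    if (k > 0) rej[o[seq_len(k)]] <- TRUE
    rej
  }
  set.seed(99)
  for (i in 1:1000) {
    m <- sample(1:50, 1)
    p <- switch(sample(3, 1),
                runif(m),
                rbeta(m, 0.3, 4),       # enriched small p
                round(runif(m), 2))     # ties
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    got <- bh_fdr(p, q)
    expect_identical(got$reject, brute_bh(p, q))
    expect_true(all(got$qvalue >= p - 1e-12))
  }
})

test_that("cluster labelling honours extent and connectivity", {
  dims <- c(10L, 10L, 10L)
  bin <- array(FALSE, dims)
  bin[2:6, 2:6, 2:6] <- TRUE # 125 voxels
  cl <- label_clusters(bin, connectivity = 18, extent = 100)
  expect_equal(nrow(cl$table), 1L)
  expect_equal(cl$table$n_voxels, 125L)

  bin99 <- array(FALSE, dims)
  bin99[2:6, 2:6, 2:5] <- TRUE  # 100 voxels
  bin99[2, 2, 2] <- FALSE       # -> 99
  expect_equal(nrow(label_clusters(bin99, 18, 100)$table), 0L)
  expect_equal(label_clusters(bin99, 18, 99)$table$n_voxels, 99L)

  empty <- array(FALSE, dims)
  expect_equal(nrow(label_clusters(empty, 18, 1)$table), 0L)

  # two diagonal-touching voxels: one cluster at 26, two at 6 and 18
  diag2 <- array(FALSE, c(4, 4, 4))
  diag2[2, 2, 2] <- TRUE; diag2[3, 3, 3] <- TRUE
  expect_equal(nrow(label_clusters(diag2, 26, 1)$table), 1L)
  expect_equal(nrow(label_clusters(diag2, 18, 1)$table), 2L)
  expect_equal(nrow(label_clusters(diag2, 6, 1)$table), 2L)
  # edge-touching voxels: joined at 18, separate at 6
  edge2 <- array(FALSE, c(4, 4, 4))
  edge2[2, 2, 2] <- TRUE; edge2[3, 3, 2] <- TRUE
  expect_equal(nrow(label_clusters(edge2, 18, 1)$table), 1L)
  expect_equal(nrow(label_clusters(edge2, 6, 1)$table), 2L)
  expect_error(label_clusters(edge2, 7, 1), "6, 18 or 26")
})

test_that("cluster sizes are invariant to voxel visiting order", {
  set.seed(12)
  bin <- array(runif(16 * 16 * 8) < 0.3, c(16, 16, 8))
  sizes <- function(b) sort(label_clusters(b, 18, 1)$table$n_voxels)
  ref <- sizes(bin)
  expect_identical(sizes(bin[16:1, , ]), ref)
  expect_identical(sizes(bin[, 16:1, 8:1]), ref)
  expect_identical(sizes(aperm(bin, c(2, 1, 3))), ref)
})

test_that("under a null simulation the FDR procedure stays calibrated", {
  # no planted effect: average realized false-discovery additions must be
  # rare; with BH at q = 0.05 the rejection of >=1 voxel happens in <~ 5%
  # of cohorts plus Monte-Carlo slack
  dims <- c(6L, 6L, 4L)
  mask <- brain_mask(array(1, dims), c(1, 1, 1))
  set.seed(77)
  any_rej <- replicate(200, {
    a <- array(rnorm(prod(dims) * 8), c(dims, 8))
    b <- array(rnorm(prod(dims) * 8), c(dims, 8))
    sets <- make_paired_sets(a, b)
    sm <- paired_t_map(sets$a, sets$b, mask)
    any(bh_fdr(sm$p[mask$values != 0], 0.05)$reject)
  })
  expect_lt(mean(any_rej), 0.09)
})

test_that("significant_clusters separates increases from decreases", {
  dims <- c(12L, 12L, 4L)
  n <- 10
  up <- array(FALSE, dims); up[2:5, 2:5, 1:3] <- TRUE     # 48 voxels
  down <- array(FALSE, dims); down[8:11, 8:11, 2:4] <- TRUE
  set.seed(8)
  base <- array(rnorm(prod(dims) * n, sd = 0.1), c(dims, n))
  b <- base + array(rep(up * 2 - down * 2, n), c(dims, n)) +
    array(rnorm(prod(dims) * n, sd = 0.1), c(dims, n))
  sets <- make_paired_sets(base, b)
  mask <- brain_mask(array(1, dims), c(1, 1, 1))
  sm <- paired_t_map(sets$a, sets$b, mask)
  res <- significant_clusters(sm, q = 0.05, extent = 40, connectivity = 18)
  expect_equal(nrow(res$table), 2L)
  expect_setequal(res$table$direction, c("increase", "decrease"))
  expect_true(all(res$table$n_voxels >= 40))
  # q-values respect the BH guarantee q >= p in-mask
  keep <- mask$values != 0
  expect_true(all(res$q[keep] >= sm$p[keep] - 1e-12))
})
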