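test_that("VOI sphere masks match a brute-force distance enumeration", {
  vol <- toy_volume(dims = c(15L, 15L, 9L), spacing = c(2, 2, 4),
                    origin = c(-14, -14, -16))
  center <- c(3, -4, 2.5) # (ml, dv, ap)
  radius <- 7
  m <- make_voi_mask(center, radius, vol)
  # oracle: loop every voxel centre, mm distance to (x=ml, y=ap, z=dv)
  target <- c(center[1], center[3], center[2])
  oracle <- array(FALSE, dim(vol$values))
  for (i in 1:15) for (j in 1:15) for (k in 1:9) {
    pos <- vol$origin + (c(i, j, k) - 1) * vol$spacing
    oracle[i, j, k] <- sum((pos - target)^2) <= radius^2
  }
  expect_identical(m$values != 0, oracle)
})

test_that("a radius under half the voxel spacing selects one voxel", {
  vol <- toy_volume(dims = c(9L, 9L, 9L), spacing = c(2, 2, 2),
                    origin = c(0, 0, 0))
  m <- make_voi_mask(c(8.4, 8.4, 8.4), radius_mm = 0.9, vol)
  expect_equal(sum(m$values), 1)
  expect_equal(which(m$values != 0), which(array(seq_len(729), dim = c(9, 9, 9)) ==
                                             (5 + 9 * 4 + 81 * 4)))
})

test_that("the default coordinate table yields exactly 8 spherical masks", {
  cfg <- small_grid_config(c(a = 2))
  tmpl <- brain_volume(array(0, cfg$grid_shape), cfg$voxel_spacing_mm,
                       cfg$origin_mm)
  masks <- voi_masks(cfg$voi_table, tmpl, radius_mm = 8)
  expect_length(masks, 8L)
  expect_named(masks, c("Hp_L", "Hp_R", "MedF", "Rsp",
                        "Mot_L", "Mot_R", "SS_L", "SS_R"))
  expect_true(all(vapply(masks, function(m) sum(m$values) > 0, logical(1))))
  # a centre far outside the grid is rejected
  expect_error(make_voi_mask(c(500, 0, 0), 8, tmpl), "outside")
})

test_that("VOI tables round-trip through TSV", {
  tab <- default_voi_table()
  f <- tempfile(fileext = ".tsv")
  write_voi_table(tab, f)
  tab2 <- read_voi_table(f)
  expect_equal(tab2$ml, tab$ml)
  expect_equal(tab2$abbreviation, tab$abbreviation)
  expect_error(read_voi_table({
    f2 <- tempfile(fileext = ".tsv")
    writeLines("a\tb\n1\t2", f2)
    f2
  }), "columns")
})

test_that("VOI mean extraction matches a voxel-by-voxel oracle", {
  cfg <- small_grid_config(c(a = 3), seed = 17)
  coh <- generate_cohort(cfg)
  masks <- voi_masks(cfg$voi_table, coh$scans$a$volumes[[1]], 8)
  vm <- extract_voi_means(coh$scans$a, masks)
  # constant volume: every entry the constant
  const <- scan_set(list(brain_volume(array(4.2, cfg$grid_shape),
                                      cfg$voxel_spacing_mm, cfg$origin_mm)),
                    "c1", "const")
  expect_true(all(abs(extract_voi_means(const, masks) - 4.2) < 1e-12))
  # brute-force masked average
  for (j in c(1, 5)) {
    keep <- masks[[j]]$values != 0
    for (i in 1:3) {
      acc <- 0; cnt <- 0
      vals <- coh$scans$a$volumes[[i]]$values
      for (v in which(keep)) { acc <- acc + vals[v]; cnt <- cnt + 1 }
      expect_equal(vm[i, j], acc / cnt, tolerance = 1e-6)
    }
  }
  expect_identical(rownames(vm), coh$scans$a$subject_ids)
})

test_that("correlation matrices have 28 edges and match a direct formula", {
  vm <- draw_voi_matrix(20, Sigma = 0.01 * voi_correlation_model(0.4),
                        seed = 3)
  cm <- correlation_matrix(vm)
  expect_equal(cm$n_edges, 28)
  expect_true(isSymmetric(cm$r))
  expect_equal(diag(cm$r), rep(1, 8), ignore_attr = TRUE)
  # direct covariance / (sd*sd) oracle per pair
  m <- unclass(vm)
  for (i in 1:7) for (j in (i + 1):8) {
    xi <- m[, i]; xj <- m[, j]
    oracle <- mean((xi - mean(xi)) * (xj - mean(xj))) /
      (sqrt(mean((xi - mean(xi))^2)) * sqrt(mean((xj - mean(xj))^2)))
    expect_equal(cm$r[i, j], oracle, tolerance = 1e-10)
  }
  expect_equal(cm$z[2, 5], atanh(cm$r[2, 5]))
  expect_equal(diag(cm$z), rep(0, 8), ignore_attr = TRUE)
})

test_that("degenerate VOI matrices are rejected informatively", {
  vm <- draw_voi_matrix(3, seed = 1)
  expect_error(correlation_matrix(vm), "at least 4")
  vm2 <- draw_voi_matrix(10, seed = 2)
  vm2[, "Rsp"] <- 1
  expect_error(correlation_matrix(vm2), "Rsp")
  # duplicated column gives r = 1 on that edge (z clamped, not infinite)
  vm3 <- draw_voi_matrix(10, seed = 3)
  vm3[, "Hp_R"] <- vm3[, "Hp_L"]
  cm3 <- suppressWarnings(correlation_matrix(vm3))
  expect_equal(cm3$r["Hp_L", "Hp_R"], 1, tolerance = 1e-12)
  expect_true(is.finite(cm3$z["Hp_L", "Hp_R"]))
})

test_that("fisher z matches its closed form and symmetry", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5))
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  set.seed(4)
  r <- runif(50, -0.99, 0.99)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_equal(z1, atanh(1 - 1e-7))
  expect_error(fisher_z(1.2), "not a correlation")
})

test_that("permutation edge tests are seeded, bounded and validated", {
  base <- 0.01 * voi_correlation_model(0.2)
  a <- draw_voi_matrix(20, base, group = "young", seed = 5)
  b <- draw_voi_matrix(20, base, group = "old", seed = 6)
  expect_error(permutation_edge_test(a, b, n_perm = 50), "at least 100")
  expect_error(permutation_edge_test(a, unclass(b)[, 8:1], n_perm = 100),
               "different VOI columns")
  e1 <- permutation_edge_test(a, b, n_perm = 300, seed = 9)
  e2 <- permutation_edge_test(a, b, n_perm = 300, seed = 9)
  expect_identical(e1$p, e2$p)
  expect_equal(nrow(e1), 28L)
  expect_true(all(e1$p > 0 & e1$p <= 1))
  expect_gte(min(e1$p), 1 / 301)
})

test_that("an overwhelming effect reaches the add-one lower bound", {
  set.seed(7)
  a <- draw_voi_matrix(40, single_edge_covariance(-0.9) + 1e-4 * diag(8),
                       seed = 10)
  b <- draw_voi_matrix(40, single_edge_covariance(0.95) + 1e-4 * diag(8),
                       seed = 11)
  e <- permutation_edge_test(a, b, n_perm = 199, seed = 1)
  i <- which(e$voi_i == "MedF" & e$voi_j == "Rsp" |
               e$voi_i == "Rsp" & e$voi_j == "MedF")
  expect_equal(e$p[i], 1 / 200)
  expect_equal(e$direction[i], "increase")
})

test_that("swapping the groups flips every dz and preserves p-values", {
  S <- 0.01 * voi_correlation_model(0.3)
  a <- draw_voi_matrix(18, S, group = "A", seed = 12)
  b <- draw_voi_matrix(18, 0.01 * voi_correlation_model(0.6), group = "B",
                       seed = 13)
  n_perm <- 2000
  ab <- permutation_edge_test(a, b, n_perm = n_perm, seed = 2)
  ba <- permutation_edge_test(b, a, n_perm = n_perm, seed = 2)
  expect_equal(ba$dz, -ab$dz)
  # two-sided p is label-exchange symmetric up to Monte-Carlo error
  expect_lt(max(abs(ba$p - ab$p)), 3 * sqrt(0.25 / n_perm) + 0.02)
})
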