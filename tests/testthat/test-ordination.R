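test_that("Hellinger transform yields unit sum-of-squares sample vectors", {
  x <- cbind(S1 = c(1, 0, 0), S2 = c(1, 1, 0), S3 = c(2, 1, 1))
  rownames(x) <- paste0("O", 1:3)
  h <- hellinger_transform(x)
  expect_equal(unname(h[, 1]), c(1, 0, 0))
  expect_equal(unname(h[1:2, 2]), rep(1 / sqrt(2), 2))
  expect_equal(unname(colSums(h^2)), rep(1, 3), tolerance = 1e-12)

  y <- matrix(c(1, 1, 2), ncol = 1, dimnames = list(paste0("O", 1:3), "S"))
  expect_equal(unname(hellinger_transform(y)[, 1]),
               c(0.5, 0.5, sqrt(0.5)), tolerance = 1e-6)

  bad <- x; bad[, 3] <- 0
  expect_error(hellinger_transform(bad), "zero-total")
})

test_that("Bray-Curtis follows its definition and agrees with vegan", {
  x <- cbind(S1 = c(1, 0), S2 = c(0, 1))
  rownames(x) <- c("a", "b")
  expect_equal(bray_curtis(x)["S1", "S2"], 1)

  y <- cbind(S1 = c(2, 2, 0), S2 = c(2, 2, 0), S3 = c(1, 1, 2))
  rownames(y) <- paste0("o", 1:3)
  d <- bray_curtis(y)
  expect_equal(d["S1", "S2"], 0)
  expect_equal(d["S1", "S3"], 0.5)

  skip_if_not_installed("vegan")
  set.seed(2)
  z <- matrix(rpois(8 * 30, 10), nrow = 30,
              dimnames = list(paste0("o", 1:30), paste0("s", 1:8)))
  expect_equal(as.matrix(bray_curtis(z)),
               as.matrix(as.matrix(vegan::vegdist(t(z), "bray"))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCoA reproduces Euclidean configurations and reports negatives", {
  set.seed(7)
  pts <- matrix(rnorm(12), 6, 2)
  d <- euclid_d(pts)
  ord <- pcoa(d)
  expect_lt(max(abs(as.matrix(dist(ord$coordinates)) - d)), 1e-8)

  ## collinear points: one meaningful axis
  d3 <- euclid_d(cbind(c(0, 1, 2), 0))
  ord3 <- pcoa(d3)
  pos <- ord3$eigenvalues[ord3$eigenvalues > 1e-12]
  expect_equal(length(pos), 1L)

  ## all-zero distances: degenerate, everything zero
  dz <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  ordz <- pcoa(dz)
  expect_equal(ncol(ordz$coordinates), 0L)
  expect_equal(max(abs(ordz$eigenvalues)), 0, tolerance = 1e-12)

  ## non-Euclidean input: negative eigenvalue mass reported, coordinates
  ## restricted to positive axes
  set.seed(8)
  cts <- matrix(rpois(10 * 8, 5), 10,
                dimnames = list(paste0("o", 1:10), paste0("s", 1:8)))
  db <- bray_curtis(cts)
  ordb <- pcoa(db)
  expect_gte(ordb$negative_eigenvalue_mass, 0)
  expect_equal(sum(ordb$proportion_explained), 1, tolerance = 1e-12)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCoA eigenvalues agree with cmdscale", {
  set.seed(9)
  pts <- matrix(rnorm(20), 10, 2)
  d <- euclid_d(pts)
  ord <- pcoa(d)
  ref <- cmdscale(d, k = 2, eig = TRUE)
  expect_equal(ord$eigenvalues[1:2], ref$eig[1:2], tolerance = 1e-8)
})

test_that("ANOSIM boundary values and the spread of the permutation null", {
  ## perfect separation: all between = 1, all within = 0 -> R = 1
  d <- matrix(1, 6, 6) - diag(6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  grp <- rep(c("a", "b"), each = 3)
  res <- anosim(d, grp, n_perm = 99, seed = 1)
  expect_equal(res$R, 1)

  ## all dissimilarities tie: mid-ranks equalize the means, R = 0
  dt <- matrix(1, 6, 6); diag(dt) <- 0
  dimnames(dt) <- dimnames(d)
  expect_equal(anosim(dt, grp, n_perm = 99, seed = 1)$R, 0)

  ## R stays within [-1, 1] and is centered near 0 under random labels
  set.seed(10)
  rs <- replicate(60, {
    pts <- matrix(rnorm(16), 8, 2)
    dd <- euclid_d(pts)
    anosim(dd, sample(rep(c("a", "b"), each = 4)), n_perm = 49,
           seed = 1)$R
  })
  expect_true(all(rs >= -1 & rs <= 1))
  expect_lt(abs(mean(rs)), 0.1)

  expect_error(anosim(d, c("a", "a", "a", "a", "a", "b"), 99, 1), ">= 2")
})

test_that("ANOSIM matches brute-force enumeration on 6 samples", {
  set.seed(12)
  pts <- matrix(rnorm(12), 6, 2)
  d <- euclid_d(pts)
  grp <- rep(c("a", "b"), each = 3)
  mine <- anosim(d, grp, n_perm = 999, seed = 1)
  oracle <- oracle_anosim_exact(d, grp)
  expect_equal(mine$R, oracle$R, tolerance = 1e-10)
  expect_equal(mine$p_value, oracle$p, tolerance = 1e-10)
  expect_true(isTRUE(mine$exact))
})

test_that("ANOSIM R agrees with vegan", {
  skip_if_not_installed("vegan")
  set.seed(13)
  cts <- matrix(rpois(12 * 25, 15), 25,
                dimnames = list(paste0("o", 1:25), paste0("s", 1:12)))
  d <- bray_curtis(cts)
  grp <- rep(c("a", "b", "c"), each = 4)
  mine <- anosim(d, grp, n_perm = 99, seed = 1)
  ref <- vegan::anosim(as.dist(d), grp, permutations = 0)
  expect_equal(mine$R, unname(ref$statistic), tolerance = 1e-10)
})

test_that("environment standardization centers, scales and validates", {
  meta <- data.frame(sample_id = paste0("s", 1:3),
                     pH = c(1, 2, 3), SOC = c(5, 5, 8))
  z <- standardize_env(meta, c("pH", "SOC"))
  expect_equal(unname(z[, "pH"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)
  ## idempotence
  meta2 <- data.frame(sample_id = meta$sample_id, pH = z[, "pH"])
  expect_equal(unname(standardize_env(meta2, "pH")[, 1]),
               unname(z[, "pH"]), tolerance = 1e-12)
  meta$flat <- 1
  expect_error(standardize_env(meta, "flat"), "zero-variance")
  expect_error(standardize_env(meta, "missing_var"), "absent")
})

test_that("db-RDA conserves inertia, self-fits and flags collinearity", {
  set.seed(14)
  pts <- matrix(rnorm(24), 12, 2)
  d <- euclid_d(pts)
  env <- cbind(v1 = rnorm(12), v2 = rnorm(12))
  rownames(env) <- rownames(d)
  res <- db_rda(d, scale(env), n_perm = 99, seed = 1)
  expect_equal(res$constrained_inertia + res$unconstrained_inertia,
               res$total_inertia, tolerance = 1e-8)
  expect_true(all(res$envfit$r2 >= 0 & res$envfit$r2 <= 1))
  expect_gte(res$model_p, 1 / 100)

  ## a variable equal to the first PCoA axis fits perfectly
  ax1 <- pcoa(d)$coordinates[, 1]
  env2 <- cbind(axis_copy = as.numeric(scale(ax1)), noise = rnorm(12))
  rownames(env2) <- rownames(d)
  res2 <- db_rda(d, env2, n_perm = 99, seed = 1)
  expect_equal(res2$envfit$r2[res2$envfit$variable == "axis_copy"], 1,
               tolerance = 1e-8)

  env3 <- cbind(a = env[, 1], b = 2 * env[, 1])
  rownames(env3) <- rownames(d)
  expect_error(db_rda(d, env3, 99, 1), "collinear")
})

test_that("db-RDA pseudo-F grows with planted group separation", {
  sep_f <- vapply(c(0.5, 1.5, 3), function(sep) {
    set.seed(20)
    pts <- rbind(matrix(rnorm(12), 6, 2),
                 matrix(rnorm(12, mean = sep), 6, 2))
    d <- euclid_d(pts)
    env <- cbind(grp = rep(c(0, 1), each = 6))
    rownames(env) <- rownames(d)
    db_rda(d, scale(env), n_perm = 19, seed = 1)$pseudo_F
  }, numeric(1))
  expect_true(all(diff(sep_f) > 0))
})

test_that("Mantel identities, exhaustive oracle and degenerate input", {
  set.seed(15)
  pts <- matrix(rnorm(10), 5, 2)
  d1 <- euclid_d(pts)
  expect_equal(mantel_test(d1, d1, 99, 1)$r, 1, tolerance = 1e-12)
  ## affine transform of distances: r still 1
  d2 <- 3 * d1 + 0.5; diag(d2) <- 0
  expect_equal(mantel_test(d1, d2, 99, 1)$r, 1, tolerance = 1e-12)

  ## exhaustive 5-sample oracle: r and exact p to 1e-10
  d3 <- euclid_d(matrix(rnorm(10), 5, 2), ids = rownames(d1))
  mine <- mantel_test(d1, d3, n_perm = 999, seed = 1)
  oracle <- oracle_mantel_exact(d1, d3)
  expect_equal(mine$r, oracle$r, tolerance = 1e-10)
  expect_equal(mine$p_value, oracle$p, tolerance = 1e-10)

  ## constant dissimilarities: r reported as 0 with a warning
  dc <- matrix(1, 5, 5); diag(dc) <- 0; dimnames(dc) <- dimnames(d1)
  expect_warning(res <- mantel_test(dc, d1, 99, 1), "degenerate")
  expect_equal(res$r, 0)

  d4 <- euclid_d(matrix(rnorm(8), 4, 2))
  expect_error(mantel_test(d1, d4, 99, 1), "differ")
})

test_that("permutation p-values respect the add-one lower bound", {
  set.seed(16)
  pts <- matrix(rnorm(20), 10, 2)
  d <- euclid_d(pts)
  grp <- rep(c("a", "b"), each = 5)
  an <- anosim(d, grp, n_perm = 49, seed = 2)
  expect_gte(an$p_value, 1 / 50)
  d2 <- euclid_d(matrix(rnorm(20), 10, 2), ids = rownames(d))
  mt <- mantel_test(d, d2, n_perm = 49, seed = 2)
  expect_gte(mt$p_value, 1 / 50)
})
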