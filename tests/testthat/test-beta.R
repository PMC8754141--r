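test_that("Bray-Curtis matches closed forms and flags all-zero samples", {
  m <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(bray_curtis(m)["a", "b"], 1)
  m2 <- matrix(c(2, 2, 1, 3), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(bray_curtis(m2)["a", "b"], 0.25)
  m3 <- rbind(m2, c = c(2, 2))
  expect_equal(bray_curtis(m3)["a", "c"], 0)
  m4 <- rbind(m2, z = c(0, 0))
  expect_error(bray_curtis(m4), "all-zero")
})

test_that("PCoA reconstructs Euclidean distances and handles collinear points", {
  # 3 collinear points: one positive eigenvalue carrying everything
  pts <- matrix(c(0, 1, 3), dimnames = list(c("a", "b", "c"), NULL))
  d <- as.matrix(dist(cbind(pts, 0)))
  ord <- pcoa(d)
  expect_equal(ord$proportion_explained[1], 1)
  expect_equal(ncol(ord$coordinates), 1)

  # full-rank reconstruction of random Euclidean distances
  for (seed in 1:5) {
    X <- withr::with_seed(seed, matrix(rnorm(15), 5, 3))
    rownames(X) <- paste0("s", 1:5)
    d <- as.matrix(dist(X))
    ord <- pcoa(d)
    expect_lt(max(abs(as.matrix(dist(ord$coordinates)) - d)), 1e-8)
  }

  # duplicated samples land on identical coordinates
  Xd <- matrix(c(0, 0, 1, 1, 0, 0, 3, 4), 4, 2, byrow = TRUE,
               dimnames = list(paste0("s", 1:4), NULL))
  orddup <- pcoa(as.matrix(dist(Xd)))
  expect_equal(orddup$coordinates["s1", ], orddup$coordinates["s3", ],
               tolerance = 1e-8)

  # cailliez correction makes a non-Euclidean matrix embeddable
  dne <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dne[upper.tri(dne)] <- c(1, 1, 1, 1, 1, 1.9)
  dne <- dne + t(dne)
  raw <- pcoa(dne)
  expect_lt(min(raw$eigenvalues), -1e-6)
  cor <- pcoa(dne, correction = "cailliez")
  expect_gt(min(cor$eigenvalues), -1e-6)
})

test_that("ANOSIM matches its rank formula, extremes, and the exhaustive null", {
  # all between-pair distances above all within-pair distances: R = 1
  X <- matrix(c(0, 0, 0.1, 0, 0, 0.1, 9, 9, 9.1, 9, 9, 9.1), 6, 2,
              byrow = TRUE, dimnames = list(paste0("s", 1:6), NULL))
  g <- rep(c("A", "B"), each = 3)
  res <- anosim(as.matrix(dist(X)), g, n_perm = 199, seed = 1)
  expect_equal(res$statistic, 1)
  # n = 6 balanced has only 10 distinct partitions: the exact p of a
  # perfect separation is 2/20
  expect_equal(anosim(as.matrix(dist(X)), g, exhaustive = TRUE)$p_value,
               0.1)

  # agrees with vegan on the statistic
  d <- as.matrix(dist(withr::with_seed(3, matrix(rnorm(24), 6, 4))))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  veg <- vegan::anosim(as.dist(d), grouping = factor(g), permutations = 0)
  expect_equal(anosim(d, g, n_perm = 99, seed = 1)$statistic,
               unname(veg$statistic), tolerance = 1e-10)

  # exhaustive p equals a brute-force enumeration over all 20 label
  # assignments
  ex <- anosim(d, g, exhaustive = TRUE)
  expect_equal(ex$n_permutations, 20)
  pos <- combn(6, 3)
  stats <- apply(pos, 2, function(id) {
    gg <- rep("B", 6)
    gg[id] <- "A"
    anosim(d, gg, n_perm = 0, exhaustive = TRUE)$statistic
  })
  expect_equal(ex$p_value, mean(stats >= ex$statistic - 1e-12))

  # structureless data: mean R near 0
  rs <- vapply(1:300, function(s) {
    dd <- as.matrix(dist(withr::with_seed(1000 + s,
                                          matrix(rnorm(40), 10, 4))))
    anosim(dd, rep(c("A", "B"), each = 5), n_perm = 0,
           exhaustive = FALSE, seed = s)$statistic
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)

  expect_error(anosim(d, c("A", rep("B", 5))), "fewer than 2")
})

test_that("Mantel matches closed forms, vegan, and the exhaustive null", {
  X <- withr::with_seed(5, matrix(rnorm(18), 6, 3))
  rownames(X) <- paste0("s", 1:6)
  d1 <- as.matrix(dist(X))
  expect_equal(mantel(d1, 2 * d1, method = "pearson",
                      n_perm = 99, seed = 1)$statistic, 1)

  d2 <- as.matrix(dist(withr::with_seed(6, matrix(rnorm(18), 6, 3))))
  dimnames(d2) <- dimnames(d1)
  veg <- vegan::mantel(as.dist(d1), as.dist(d2), method = "spearman",
                       permutations = 0)
  expect_equal(mantel(d1, d2, n_perm = 99, seed = 2)$statistic,
               unname(veg$statistic), tolerance = 1e-10)

  # exhaustive p over all 720 relabelings equals direct enumeration
  ex <- mantel(d1, d2, exhaustive = TRUE)
  expect_equal(ex$n_permutations, 720)
  v1 <- rank(d1[lower.tri(d1)])
  perms <- seacomm:::all_permutations(6)
  rs <- vapply(perms, function(p) {
    dp <- d2[p, p]
    cor(v1, rank(dp[lower.tri(dp)]))
  }, numeric(1))
  expect_equal(ex$p_value, mean(rs >= ex$statistic - 1e-12))

  dc <- d1
  dc[] <- 1
  diag(dc) <- 0
  expect_error(mantel(d1, dc), "constant")
})

test_that("Procrustes M2 is 0 for congruent configurations and symmetric", {
  A <- withr::with_seed(7, matrix(rnorm(40), 20, 2))
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2)
  B <- 3.2 * A %*% R + matrix(c(5, -2), 20, 2, byrow = TRUE)
  res <- procrustes_protest(A, B, n_perm = 99, seed = 1)
  expect_lt(res$statistic, 1e-12)
  expect_lte(res$p_value, 0.05)

  # symmetric in its arguments
  C <- withr::with_seed(8, matrix(rnorm(40), 20, 2))
  expect_equal(procrustes_protest(A, C, n_perm = 49, seed = 2)$statistic,
               procrustes_protest(C, A, n_perm = 49, seed = 2)$statistic,
               tolerance = 1e-12)

  # agrees with vegan's symmetric procrustes ss
  veg <- vegan::procrustes(A, C, symmetric = TRUE)$ss
  expect_equal(procrustes_protest(A, C, n_perm = 49, seed = 3)$statistic,
               veg, tolerance = 1e-10)

  # independent random configurations: typically not significant
  ps <- vapply(1:40, function(s) {
    B2 <- withr::with_seed(100 + s, matrix(rnorm(40), 20, 2))
    procrustes_protest(A, B2, n_perm = 199, seed = s)$p_value
  }, numeric(1))
  expect_gt(median(ps), 0.05)
})

test_that("rank-sum test matches exact enumeration and handles ties", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1 / 3)

  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # n = m = 5: exact p equals full 252-assignment enumeration
  x <- withr::with_seed(9, rnorm(5))
  y <- withr::with_seed(10, rnorm(5))
  res <- rank_sum_test(x, y)
  pool <- c(x, y)
  rk <- rank(pool)
  u_of <- function(id) sum(rk[id]) - 5 * 6 / 2
  us <- apply(combn(10, 5), 2, u_of)
  u_obs <- u_of(1:5)
  p_exact <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)

  expect_error(rank_sum_test(numeric(0), 1), "nonempty")
})

test_that("Spearman/FDR matrix has BH closed forms and the adjusted >= raw property", {
  x <- withr::with_seed(11, rnorm(30))
  res <- spearman_fdr_matrix(data.frame(x = x, ex = exp(x),
                                        z = withr::with_seed(12, rnorm(30))))
  expect_equal(res$rho["x", "ex"], 1)
  up <- upper.tri(res$p)
  expect_true(all(res$p_adj[up] >= res$p[up] - 1e-12, na.rm = TRUE))

  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))

  expect_warning(
    spearman_fdr_matrix(data.frame(a = rep(1, 10), b = rnorm(10))),
    "constant")
})

test_that("environmental PCA standardizes and yields orthogonal scores", {
  env <- withr::with_seed(13, {
    base <- rnorm(20)
    data.frame(t = base, s = 2 * base, x = rnorm(20))
  })
  # two perfectly correlated variables dominate PC1
  two <- env[c("t", "s")]
  expect_equal(env_pca(two)$proportion_explained[1], 1)

  ord <- env_pca(env)
  Z <- scale(as.matrix(env))
  expect_true(all(abs(colMeans(Z)) < 1e-12))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-12))
  cp <- crossprod(ord$coordinates)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)

  env$const <- 5
  expect_error(env_pca(env), "const")
})
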