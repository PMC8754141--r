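test_that("cophenetic distances are path sums with additive-metric structure", {
  d <- cophenetic_matrix(abc_tree())
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)

  # ultrametric pure-birth trees: all tip-to-root depths equal, and the
  # four-point condition holds on sampled quartets
  tr <- simulate_tree(25, seed = 41)
  depths <- ape::node.depth.edgelength(tr)[seq_len(25)]
  expect_lt(diff(range(depths)), 1e-8)
  d <- cophenetic_matrix(tr)
  quartets <- withr::with_seed(42, replicate(50, sample(25, 4)))
  for (q in seq_len(ncol(quartets))) {
    i <- quartets[1, q]; j <- quartets[2, q]
    k <- quartets[3, q]; l <- quartets[4, q]
    sums <- sort(c(d[i, j] + d[k, l], d[i, k] + d[j, l],
                   d[i, l] + d[j, k]))
    expect_lt(sums[3] - sums[2], 1e-8)
  }
})

test_that("betaMNTD matches the brute-force oracle and its closed forms", {
  tr <- abc_tree()
  coph <- cophenetic_matrix(tr)
  x <- c(A = 2, B = 0, C = 0)
  y <- c(A = 0, B = 3, C = 0)
  expect_equal(beta_mntd(x, y, coph), 2)
  expect_equal(beta_mntd(x, x, coph), 0)
  expect_error(beta_mntd(c(A = 0, B = 0, C = 0), y, coph), "empty")

  # random instances, both weightings, against the double-loop oracle
  for (seed in 1:30) {
    yule <- simulate_tree(8, seed = seed)
    coph <- cophenetic_matrix(yule)
    m <- random_table(4, 8, depth = 25L, seed = seed)
    colnames(m) <- yule$tip.label
    for (w in c(TRUE, FALSE)) {
      for (a in 1:3) for (b in (a + 1):4) {
        expect_identical(
          beta_mntd(m[a, ], m[b, ], coph, weighted = w),
          brute_beta_mntd(m[a, ], m[b, ], coph, weighted = w))
      }
      # the vectorized all-pairs kernel agrees exactly too
      kern <- seacomm:::beta_mntd_pairs_cpp(m * 1.0, coph,
                                            0:(ncol(m) - 1L), w)
      for (a in 1:3) for (b in (a + 1):4)
        expect_identical(kern[a, b],
                         brute_beta_mntd(m[a, ], m[b, ], coph,
                                         weighted = w))
    }
  }
})

test_that("betaNTI is symmetric, reproducible, and flags its degenerate cases", {
  tr <- simulate_tree(30, seed = 51)
  m <- random_table(5, 30, depth = 120L, seed = 52)
  colnames(m) <- tr$tip.label
  a <- beta_nti(m, tr, n_rand = 199, seed = 53)
  b <- beta_nti(m, tr, n_rand = 199, seed = 53)
  expect_identical(a$beta_nti, b$beta_nti)
  expect_equal(a$beta_nti, t(a$beta_nti))

  # identical samples: bMNTD invariant under every shuffle, no selection
  # signal (exact point-mass null -> 0)
  m2 <- rbind(m, dup = m[1, ])
  res <- beta_nti(m2, tr, n_rand = 99, seed = 1)
  expect_equal(res$beta_mntd_obs["S01", "dup"], 0)
  expect_equal(res$beta_nti["S01", "dup"], 0)
})

test_that("RC_bray hits its extremes and contract", {
  m <- random_table(4, 25, depth = 300L, seed = 61)
  # an identical pair with nondegenerate nulls sits below every null
  m2 <- rbind(m, dup = m[1, ])
  res <- rc_bray(m2, n_rand = 99, seed = 62)
  expect_equal(res$rc_bray["S01", "dup"], -1)
  expect_true(all(abs(res$rc_bray) <= 1))
  expect_equal(res$rc_bray, t(res$rc_bray))
  res2 <- rc_bray(m2, n_rand = 99, seed = 62)
  expect_identical(res$rc_bray, res2$rc_bray)

  expect_error(rc_bray(m / 2), "integer")
})

test_that("classification applies the threshold rules with bNTI precedence", {
  mk <- function(b, r) {
    bm <- matrix(c(0, b, b, 0), 2,
                 dimnames = list(c("x", "y"), c("x", "y")))
    rm <- matrix(c(0, r, r, 0), 2,
                 dimnames = list(c("x", "y"), c("x", "y")))
    classify_pairs(bm, rm)$process
  }
  expect_equal(as.character(mk(2.5, 0.99)), "heterogeneous_selection")
  expect_equal(as.character(mk(-2.5, 0.99)), "homogeneous_selection")
  expect_equal(as.character(mk(0, 0)), "drift")
  expect_equal(as.character(mk(-1, 0.97)), "dispersal_limitation")
  expect_equal(as.character(mk(1, -0.97)), "homogenizing_dispersal")

  # NA pairs are excluded with a warning
  bm <- matrix(c(0, NA, NA, 0), 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  rm <- matrix(0, 2, 2, dimnames = dimnames(bm))
  expect_warning(out <- classify_pairs(bm, rm), "excluded")
  expect_equal(nrow(out), 0)
})

test_that("process fractions sum to one per group and split by membership", {
  pairs <- data.frame(
    sample_i = c("a1", "a1", "a2", "b1"),
    sample_j = c("a2", "b1", "b2", "b2"),
    beta_nti = 0, rc_bray = 0,
    process = factor(c("drift", "dispersal_limitation", "drift",
                       "heterogeneous_selection"),
                     levels = seacomm:::.process_levels),
    stringsAsFactors = FALSE)
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  fr <- summarize_fractions(pairs, groups)
  sums <- rowSums(fr[, seacomm:::.process_levels])
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(fr$n_pairs[fr$group == "A"], 1)
  expect_equal(fr$n_pairs[fr$group == "between"], 2)
  expect_equal(fr$drift[fr$group == "A"], 1)

  # random classifications also conserve mass
  rp <- pairs
  rp$process <- factor(
    withr::with_seed(63, sample(seacomm:::.process_levels, 4,
                                replace = TRUE)),
    levels = seacomm:::.process_levels)
  fr2 <- summarize_fractions(rp, groups)
  expect_true(all(abs(rowSums(fr2[, seacomm:::.process_levels]) - 1)
                  < 1e-12))
})

test_that("a heterogeneous-selection scenario is recovered end to end", {
  ds <- scenario_preset("heterogeneous_selection", seed = 71,
                        n_taxa = 120, n_sites_per_region = c(6, 6))
  g <- setNames(ds$meta$region, ds$meta$sample_id)
  asm <- suppressWarnings(
    assembly_processes(ds$counts, ds$tree, groups = g, n_rand = 199,
                       seed = 72))
  between <- asm$fractions[asm$fractions$group == "between", ]
  expect_equal(seacomm:::.process_levels[
    which.max(unlist(between[seacomm:::.process_levels]))],
    "heterogeneous_selection")
})
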