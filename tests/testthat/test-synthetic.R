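test_that("simulate_tree yields labeled, positive-length, reproducible trees", {
  expect_error(simulate_tree(1), "n_taxa")
  tr2 <- simulate_tree(2, seed = 1)
  expect_length(tr2$tip.label, 2)
  expect_equal(tr2$Nnode, 1)

  a <- simulate_tree(100, seed = 5)
  b <- simulate_tree(100, seed = 5)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_true(all(a$edge.length > 0))

  d <- cophenetic_matrix(a)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d[upper.tri(d)] > 0))
})

test_that("Brownian niche optima have the BM variance and covariance structure", {
  tr <- abc_tree()
  expect_equal(unname(simulate_niche_optima(tr, 0, seed = 1)),
               c(0, 0, 0), ignore_attr = TRUE)

  # two-tip tree, root-to-tip length t: tip variance = sigma^2 * t
  two <- ape::read.tree(text = "(A:2,B:2);")
  sims <- vapply(seq_len(2000), function(i)
    simulate_niche_optima(two, bm_sigma = 1.5, seed = i)[["A"]],
    numeric(1))
  expect_lt(abs(var(sims) - 1.5^2 * 2), 0.1 * 1.5^2 * 2)

  # sister tips covary more than distant tips
  tr4 <- ape::read.tree(text = "((A:1,B:1):3,(C:1,D:1):3);")
  reps <- vapply(seq_len(1500), function(i)
    simulate_niche_optima(tr4, bm_sigma = 1, seed = 5000 + i),
    numeric(4))
  cov_sisters <- cov(reps["A", ], reps["B", ])
  cov_distant <- cov(reps["A", ], reps["C", ])
  expect_gt(cov_sisters, cov_distant + 1)  # shared path 3 vs 0

  # labile variant: same marginal variance, no tree structure needed
  lab <- vapply(seq_len(2000), function(i)
    simulate_niche_optima(two, bm_sigma = 1.5, seed = i,
                          phylo_signal = FALSE)[["A"]], numeric(1))
  expect_lt(abs(var(lab) - 1.5^2 * 2), 0.1 * 1.5^2 * 2)
})

test_that("simulate_sites builds the two-region seascape", {
  st <- simulate_sites(c(13, 16), seed = 2)
  expect_equal(nrow(st), 29)
  expect_setequal(unique(st$region), c("WTNP", "CTNP"))

  # env exactly equals longitude when slope 1, no offset, no noise
  st0 <- simulate_sites(c(4, 4), env_slope = 1, region_offsets = c(0, 0),
                        env_noise_sd = 0, seed = 3)
  expect_equal(st0$temperature, st0$longitude, tolerance = 1e-12)

  # monotone env-longitude association at low noise
  st1 <- simulate_sites(c(10, 10), env_slope = 1, env_noise_sd = 0.01,
                        seed = 4)
  expect_gt(cor(st1$temperature, st1$longitude, method = "spearman"), 0.99)

  expect_warning(
    simulate_sites(c(3, 3), lon_ranges = list(c(130, 160), c(150, 180)),
                   seed = 5), "overlap")
})

test_that("communities sum to J, are seed-deterministic, and converge to the metacommunity", {
  tr <- simulate_tree(60, seed = 1)
  opt <- simulate_niche_optima(tr, 1, seed = 2)
  st <- simulate_sites(c(4, 4), seed = 3)
  ds <- simulate_communities(tr, opt, st, community_size = 750L, seed = 4)
  expect_true(all(rowSums(ds$counts) == 750L))
  ds2 <- simulate_communities(tr, opt, st, community_size = 750L, seed = 4)
  expect_identical(ds$counts, ds2$counts)

  # pure drift, growing J: all sites converge to the same gamma, so
  # between-site Bray-Curtis shrinks
  bc_at <- function(J) {
    d <- simulate_communities(tr, opt, st, sigma_sel = Inf,
                              pool_overlap = 1, dispersal_lambda = Inf,
                              mixing = 0, community_size = J, seed = 7)
    mean(lower_vec(bray_curtis(d$counts)))
  }
  bcs <- vapply(c(1e2, 1e4, 1e6), bc_at, numeric(1))
  expect_true(all(diff(bcs) < 0))
  expect_lt(bcs[3], 0.02)
})

test_that("disjoint regional pools give Bray-Curtis 1 across regions", {
  tr <- simulate_tree(40, seed = 1)
  opt <- simulate_niche_optima(tr, 1, seed = 2)
  st <- simulate_sites(c(3, 3), seed = 3)
  ds <- simulate_communities(tr, opt, st, pool_overlap = 0,
                             dispersal_lambda = 1,
                             community_size = 500L, seed = 4)
  bc <- bray_curtis(ds$counts)
  cross <- outer(ds$meta$region, ds$meta$region, "!=")
  expect_true(all(bc[cross] == 1))
})

test_that("strong selection favors taxa whose optima match the site environment", {
  tr <- simulate_tree(80, seed = 1)
  opt <- simulate_niche_optima(tr, 2, seed = 2)
  st <- simulate_sites(c(4, 4), region_offsets = c(0, 6),
                       env_noise_sd = 0.3, seed = 3)
  ds <- simulate_communities(tr, opt, st, sigma_sel = 1,
                             dispersal_lambda = 1,
                             community_size = 20000L, seed = 4)
  for (k in c(1, nrow(ds$counts))) {
    mismatch <- abs(opt[colnames(ds$counts)] - ds$meta$temperature[k])
    expect_lt(cor(ds$counts[k, ], mismatch, method = "spearman"), -0.3)
  }
})

test_that("scenario presets are deterministic and carry their regime", {
  a <- scenario_preset("drift", seed = 1, n_taxa = 40,
                       n_sites_per_region = c(3, 3))
  b <- scenario_preset("drift", seed = 1, n_taxa = 40,
                       n_sites_per_region = c(3, 3))
  expect_identical(a$counts, b$counts)
  expect_identical(a$true_regime, "drift")

  hs <- scenario_preset("heterogeneous_selection", seed = 2, n_taxa = 40,
                        n_sites_per_region = c(4, 4))
  env_diff <- abs(mean(hs$meta$temperature[hs$meta$region == "CTNP"]) -
                  mean(hs$meta$temperature[hs$meta$region == "WTNP"]))
  expect_gt(env_diff, 4 * 0.5)  # offset >= 4 x env noise sd

  expect_error(scenario_preset("nonsense", seed = 1), "unknown preset")
})

test_that("write_dataset emits the four files and they re-read consistently", {
  ds <- scenario_preset("drift", seed = 3, n_taxa = 30,
                        n_sites_per_region = c(3, 3))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_setequal(list.files(dir),
                  c("otu_table.tsv", "tree.nwk", "metadata.tsv",
                    "params.yaml"))
  back <- read_otu_table(file.path(dir, "otu_table.tsv"))
  expect_identical(back[rownames(ds$counts), colnames(ds$counts)],
                   ds$counts)
})
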