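# Shared fixtures, built in code.

# the three-tip reference tree used throughout: ((A:1,B:1):1,C:2);
abc_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

# small deterministic OTU table
small_table <- function() {
  m <- matrix(c(3L, 0L, 1L, 2L), nrow = 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("A", "B")))
  m
}

# random count table with lognormal abundance structure
random_table <- function(n_samples, n_taxa, depth = 200L, seed = 1) {
  withr::with_seed(seed, {
    p <- rlnorm(n_taxa)
    m <- t(vapply(seq_len(n_samples), function(i)
      as.integer(rmultinom(1, depth, p)), integer(n_taxa)))
    dimnames(m) <- list(sprintf("S%02d", seq_len(n_samples)),
                        sprintf("OTU_%03d", seq_len(n_taxa)))
    m
  })
}

# metadata for n stations in two regions
random_meta <- function(n1 = 3, n2 = 3, seed = 1) {
  simulate_sites(n_sites_per_region = c(n1, n2), seed = seed)
}

# brute-force betaMNTD: plain double loop, independent of the package's
# kernel
brute_beta_mntd <- function(x, y, coph, weighted = TRUE) {
  px <- names(x)[x > 0]
  py <- names(y)[y > 0]
  wx <- if (weighted) x[px] / sum(x[px]) else rep(1 / length(px), length(px))
  wy <- if (weighted) y[py] / sum(y[py]) else rep(1 / length(py), length(py))
  s1 <- 0
  for (k in seq_along(px)) {
    best <- Inf
    for (l in seq_along(py)) best <- min(best, coph[px[k], py[l]])
    s1 <- s1 + wx[k] * best
  }
  s2 <- 0
  for (l in seq_along(py)) {
    best <- Inf
    for (k in seq_along(px)) best <- min(best, coph[px[k], py[l]])
    s2 <- s2 + wy[l] * best
  }
  unname(0.5 * (s1 + s2))
}
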