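# Synthetic communities under known assembly regimes.
#
# The generator emulates a two-region ocean-survey design: a Yule
# phylogeny of OTUs, niche optima evolved by Brownian motion, stations in
# two longitude bands with an environmental gradient, and counts drawn
# multinomially from site-specific sampling pools.  Four knobs map onto
# the classical assembly processes: niche breadth (selection), pool
# overlap and a distance kernel (dispersal limitation), a mixing fraction
# (homogenizing dispersal), and community size J (drift as sampling
# noise).

#' Simulate a pure-birth (Yule) phylogeny of OTUs
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed RNG seed.
#' @param birth birth rate of the pure-birth process.
#' @return an [ape::phylo] tree with tips `OTU_00001 ...` and strictly
#'   positive branch lengths.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, birth = 1) {
  if (n_taxa < 2L) stop2("n_taxa must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = birth, death = 0))
  tree$tip.label <- sprintf("OTU_%05d", seq_len(n_taxa))
  # degenerate zero-length branches can arise from rounding; floor them
  tree$edge.length[tree$edge.length <= 0] <- 1e-8
  tree
}

#' Evolve niche optima along a tree by Brownian motion
#'
#' The trait starts at 0 at the root and accumulates independent Gaussian
#' increments with variance `bm_sigma^2 * branch length` along each edge,
#' so a tip's optimum has variance `bm_sigma^2` times its root-to-tip
#' path length and sister tips covary through their shared path.
#'
#' @param tree [ape::phylo] tree with branch lengths.
#' @param bm_sigma Brownian-motion rate (>= 0), environmental units per
#'   square-root branch-length unit.
#' @param seed RNG seed.
#' @param phylo_signal with the default `TRUE`, optima evolve by Brownian
#'   motion and close relatives have similar niches.  `FALSE` draws each
#'   tip's optimum independently with the same marginal variance
#'   (`bm_sigma^2` times its root-to-tip path length), i.e. a
#'   phylogenetically labile trait: the niche structure that
#'   phylogenetic-turnover nulls are blind to.
#' @return named numeric vector of tip optima.
#' @export
simulate_niche_optima <- function(tree, bm_sigma, seed = NULL,
                                  phylo_signal = TRUE) {
  tree <- validate_tree(tree)
  if (bm_sigma < 0) stop2("bm_sigma must be >= 0")
  tree_cw <- stats::reorder(tree, "cladewise")  # parents before children
  n_tip <- length(tree_cw$tip.label)
  depths <- ape::node.depth.edgelength(tree_cw)
  if (!phylo_signal) {
    vals <- with_seed(seed,
      rnorm(n_tip, 0, bm_sigma * sqrt(depths[seq_len(n_tip)])))
    return(setNames(vals, tree_cw$tip.label))
  }
  vals <- numeric(n_tip + tree_cw$Nnode)
  steps <- with_seed(seed,
    rnorm(nrow(tree_cw$edge), 0, bm_sigma * sqrt(tree_cw$edge.length)))
  for (e in seq_len(nrow(tree_cw$edge))) {
    vals[tree_cw$edge[e, 2]] <- vals[tree_cw$edge[e, 1]] + steps[e]
  }
  setNames(vals[seq_len(n_tip)], tree_cw$tip.label)
}

#' Simulate station metadata for a two-region seascape
#'
#' Stations are placed uniformly in each region's longitude interval and
#' a shared tropical latitude band.  Each environmental variable is a
#' linear function of longitude plus a region offset and Gaussian noise.
#'
#' @param n_sites_per_region integer vector, stations per region.
#' @param regions region labels.
#' @param lon_ranges list of c(min, max) longitude intervals per region.
#' @param lat_range latitude band shared by all stations.
#' @param env_slope environmental units per degree longitude.
#' @param region_offsets additive offset per region.
#' @param env_noise_sd station-level Gaussian noise sd.
#' @param env_names names of the environmental variables to generate
#'   (each gets independent noise, same slope and offsets).
#' @param seed RNG seed.
#' @return metadata data.frame (see [read_metadata()]).
#' @export
simulate_sites <- function(n_sites_per_region = c(13L, 16L),
                           regions = c("WTNP", "CTNP"),
                           lon_ranges = list(c(130, 150), c(160, 180)),
                           lat_range = c(8, 18),
                           env_slope = 0,
                           region_offsets = c(0, 0),
                           env_noise_sd = 1,
                           env_names = "temperature",
                           seed = NULL) {
  nr <- length(regions)
  stopifnot(length(n_sites_per_region) == nr, length(lon_ranges) == nr,
            length(region_offsets) == nr)
  for (a in seq_len(nr - 1L)) {
    for (b in (a + 1L):nr) {
      if (lon_ranges[[a]][1] < lon_ranges[[b]][2] &&
          lon_ranges[[b]][1] < lon_ranges[[a]][2])
        warn2("longitude intervals of regions '", regions[a], "' and '",
              regions[b], "' overlap")
    }
  }
  with_seed(seed, {
    rows <- lapply(seq_len(nr), function(r) {
      n <- n_sites_per_region[r]
      lon <- runif(n, lon_ranges[[r]][1], lon_ranges[[r]][2])
      lat <- runif(n, lat_range[1], lat_range[2])
      df <- data.frame(
        sample_id = sprintf("%s_%02d", regions[r], seq_len(n)),
        latitude = lat, longitude = lon, region = regions[r],
        stringsAsFactors = FALSE)
      for (v in env_names) {
        df[[v]] <- env_slope * lon + region_offsets[r] +
          rnorm(n, 0, env_noise_sd)
      }
      df
    })
    validate_metadata(do.call(rbind, rows))
  })
}

#' Simulate OTU communities under a parameterized assembly regime
#'
#' Each region has a lognormal metacommunity abundance vector over its
#' species pool; a fraction `pool_overlap` of taxa is shared between
#' regions (shared taxa get the average of the two regions' lognormal
#' draws, so full overlap means identical pools).  A site's expected
#' relative abundances weight the regional pool by a Gaussian niche
#' kernel around each taxon's optimum (`sigma_sel = Inf` disables
#' selection).  The sampling pool of a site mixes the expected vectors of
#' all sites with weights `exp(-distance / dispersal_lambda)` and, with
#' intensity `mixing`, the global mean.  Realized counts are one
#' multinomial draw of `community_size` individuals per site, so small
#' `community_size` means strong drift.
#'
#' @param tree [ape::phylo] tree whose tips are the taxa.
#' @param optima named tip optima (see [simulate_niche_optima()]).
#' @param sites metadata data.frame from [simulate_sites()].
#' @param sigma_sel niche breadth (env units); `Inf` disables selection.
#' @param pool_overlap fraction of taxa shared between regional pools.
#' @param dispersal_lambda distance-kernel scale in km; `Inf` removes
#'   distance effects.
#' @param mixing homogenizing-dispersal intensity in `[0, 1]`.
#' @param community_size individuals per sample (J).
#' @param sd_log lognormal shape of the metacommunity abundances.
#' @param env_var metadata column used as the selective gradient.
#' @param seed RNG seed.
#' @param regime optional label recorded as the true regime.
#' @return list of class `seacomm_dataset` with `counts`, `tree`, `meta`,
#'   `true_regime`, and `params`.
#' @export
simulate_communities <- function(tree, optima, sites,
                                 sigma_sel = Inf, pool_overlap = 1,
                                 dispersal_lambda = Inf, mixing = 0,
                                 community_size = 1000L, sd_log = 1,
                                 env_var = "temperature", seed = NULL,
                                 regime = NA_character_) {
  tree <- validate_tree(tree)
  sites <- validate_metadata(sites)
  taxa <- tree$tip.label
  if (!all(taxa %in% names(optima)))
    stop2("optima must be named for every tree tip")
  optima <- optima[taxa]
  if (pool_overlap < 0 || pool_overlap > 1) stop2("pool_overlap in [0, 1]")
  if (mixing < 0 || mixing > 1) stop2("mixing in [0, 1]")
  if (community_size < 1) stop2("community_size must be >= 1")
  if (!(sigma_sel > 0)) stop2("sigma_sel must be positive (or Inf)")
  if (!env_var %in% colnames(sites)) stop2("env_var '", env_var,
                                           "' not in site metadata")
  S <- length(taxa)
  regions <- unique(sites$region)
  nr <- length(regions)

  with_seed(seed, {
    # Partition taxa into a shared block plus region-exclusive blocks.
    ord <- sample.int(S)
    n_shared <- round(pool_overlap * S)
    shared <- ord[seq_len(n_shared)]
    rest <- setdiff(ord, shared)
    exclusive <- split(rest, rep_len(seq_len(nr), length(rest)))
    gamma <- matrix(0, S, nr, dimnames = list(taxa, regions))
    draws <- matrix(rlnorm(S * nr, 0, sd_log), S, nr)
    for (r in seq_len(nr)) {
      pool_r <- c(shared, if (length(rest)) exclusive[[min(r, length(exclusive))]])
      gamma[pool_r, r] <- draws[pool_r, r]
    }
    if (n_shared > 0) {
      gamma[shared, ] <- rowMeans(draws[shared, , drop = FALSE])
    }
    gamma <- sweep(gamma, 2, colSums(gamma), "/")

    # Expected relative abundances per site: regional pool x niche kernel.
    n_site <- nrow(sites)
    P <- matrix(0, n_site, S, dimnames = list(sites$sample_id, taxa))
    for (k in seq_len(n_site)) {
      g <- gamma[, match(sites$region[k], regions)]
      w <- if (is.finite(sigma_sel)) {
        g * exp(-(sites[[env_var]][k] - optima)^2 / (2 * sigma_sel^2))
      } else g
      if (sum(w) <= 0)
        stop2("site '", sites$sample_id[k], "' has an all-zero expected ",
              "community; increase sigma_sel relative to the env range")
      P[k, ] <- w / sum(w)
    }

    # Distance-kernel mixing plus global homogenizing component.
    W <- if (is.finite(dispersal_lambda)) {
      exp(-haversine_matrix(sites) / dispersal_lambda)
    } else matrix(1, n_site, n_site)
    local_pool <- sweep(W %*% P, 1, rowSums(W), "/")
    global_pool <- matrix(colMeans(P), n_site, S, byrow = TRUE)
    pool <- (1 - mixing) * local_pool + mixing * global_pool

    counts <- t(vapply(seq_len(n_site), function(k)
      as.integer(rmultinom(1, community_size, pool[k, ])), integer(S)))
    dimnames(counts) <- list(sites$sample_id, taxa)

    structure(list(
      counts = counts, tree = tree, meta = sites,
      true_regime = regime,
      params = list(sigma_sel = sigma_sel, pool_overlap = pool_overlap,
                    dispersal_lambda = dispersal_lambda, mixing = mixing,
                    community_size = community_size, sd_log = sd_log,
                    env_var = env_var, seed = seed)),
      class = "seacomm_dataset")
  })
}

# Documented parameter bundles realizing each assembly regime.
.preset_params <- function(name) {
  switch(name,
    drift = list(
      sigma_sel = Inf, pool_overlap = 1, dispersal_lambda = Inf,
      mixing = 0, community_size = 5000L, bm_sigma = 1,
      env_slope = 0, region_offsets = c(0, 0), env_noise_sd = 0.5),
    heterogeneous_selection = list(
      sigma_sel = 1, pool_overlap = 1, dispersal_lambda = 1,
      mixing = 0, community_size = 100000L, bm_sigma = 2,
      env_slope = 0, region_offsets = c(0, 6), env_noise_sd = 0.5),
    dispersal_limitation = list(
      sigma_sel = Inf, pool_overlap = 0.2, dispersal_lambda = 200,
      mixing = 0, community_size = 100000L, bm_sigma = 1,
      env_slope = 0, region_offsets = c(0, 0), env_noise_sd = 0.5),
    homogenizing_dispersal = list(
      sigma_sel = 1, pool_overlap = 1, dispersal_lambda = 1,
      mixing = 0.95, community_size = 100000L, bm_sigma = 2,
      phylo_signal = FALSE,
      env_slope = 0, region_offsets = c(0, 0), env_noise_sd = 0.5),
    stop2("unknown preset '", name, "'; available: drift, ",
          "heterogeneous_selection, dispersal_limitation, ",
          "homogenizing_dispersal")
  )
}

#' Generate a synthetic dataset under a named assembly regime
#'
#' Fixed parameter bundles realize each of four regimes: `drift` (neutral
#' pools, small communities), `heterogeneous_selection` (narrow niches
#' and a strong between-region environmental offset),
#' `dispersal_limitation` (mostly region-exclusive pools and a short
#' distance kernel), and `homogenizing_dispersal` (intense mixing towards
#' the global mean, with selection acting on a phylogenetically labile
#' trait so that the turnover left after homogenization carries no
#' phylogenetic selection signal).
#'
#' @param name preset name.
#' @param seed master seed; the tree, traits, sites and counts get
#'   deterministic child seeds.
#' @param n_taxa taxa in the metacommunity.
#' @param n_sites_per_region stations per region.
#' @param community_size optional override of the preset's J.
#' @return a `seacomm_dataset` list (see [simulate_communities()]).
#' @export
scenario_preset <- function(name = c("drift", "heterogeneous_selection",
                                     "dispersal_limitation",
                                     "homogenizing_dispersal"),
                            seed = NULL, n_taxa = 300L,
                            n_sites_per_region = c(10L, 10L),
                            community_size = NULL) {
  if (length(name) != 1L || !name %in% c("drift", "heterogeneous_selection",
                                         "dispersal_limitation",
                                         "homogenizing_dispersal"))
    stop2("unknown preset '", paste(name, collapse = ","),
          "'; available: drift, heterogeneous_selection, ",
          "dispersal_limitation, homogenizing_dispersal")
  p <- .preset_params(name)
  if (!is.null(community_size)) p$community_size <- as.integer(community_size)
  seeds <- derive_seeds(seed, 4L, c("tree", "optima", "sites", "counts"))
  tree <- simulate_tree(n_taxa, seed = seeds[["tree"]])
  optima <- simulate_niche_optima(tree, p$bm_sigma, seed = seeds[["optima"]],
                                  phylo_signal = p$phylo_signal %||% TRUE)
  sites <- simulate_sites(n_sites_per_region = n_sites_per_region,
                          env_slope = p$env_slope,
                          region_offsets = p$region_offsets,
                          env_noise_sd = p$env_noise_sd,
                          seed = seeds[["sites"]])
  ds <- simulate_communities(tree, optima, sites,
                             sigma_sel = p$sigma_sel,
                             pool_overlap = p$pool_overlap,
                             dispersal_lambda = p$dispersal_lambda,
                             mixing = p$mixing,
                             community_size = p$community_size,
                             seed = seeds[["counts"]], regime = name)
  ds$params$preset <- name
  ds$params$master_seed <- seed
  ds$params$bm_sigma <- p$bm_sigma
  ds
}

#' Write a synthetic dataset to a directory
#'
#' Writes `otu_table.tsv`, `tree.nwk`, `metadata.tsv`, and `params.yaml`.
#'
#' @param dataset a `seacomm_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "seacomm_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- dataset$params$master_seed %||% dataset$params$seed
  write_otu_table(dataset$counts, file.path(dir, "otu_table.tsv"),
                  seed = seed)
  write_tree(dataset$tree, file.path(dir, "tree.nwk"))
  write_metadata(dataset$meta, file.path(dir, "metadata.tsv"), seed = seed)
  params <- dataset$params
  params$true_regime <- dataset$true_regime
  yaml::write_yaml(params, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' @export
print.seacomm_dataset <- function(x, ...) {
  cat("seacomm synthetic dataset\n")
  cat("  samples:", nrow(x$counts), " taxa:", ncol(x$counts), "\n")
  cat("  regions:", paste(unique(x$meta$region), collapse = ", "), "\n")
  cat("  true regime:", x$true_regime, "\n")
  invisible(x)
}
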