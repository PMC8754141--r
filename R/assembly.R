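# Quantifying community assembly processes from pairwise turnover.
#
# Two-step null-model framework: (1) the beta nearest taxon index (bNTI)
# z-scores the observed between-community phylogenetic turnover (bMNTD)
# against tip-shuffle nulls -- |bNTI| > 2 signals selection, with the
# sign separating heterogeneous (+) from homogeneous (-) selection;
# (2) for the remaining pairs, the Bray-Curtis Raup-Crick metric
# (RC_bray) compares observed compositional turnover with a
# probabilistic assembly null -- RC > 0.95 signals dispersal limitation,
# RC < -0.95 homogenizing dispersal, and the rest is drift.

#' Cophenetic (patristic) distance matrix of a tree
#'
#' @param tree [ape::phylo] tree with branch lengths.
#' @return named square matrix of tip-to-tip path lengths.
#' @export
cophenetic_matrix <- function(tree) {
  tree <- validate_tree(tree)
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}

#' Between-community mean nearest taxon distance (bMNTD) of one pair
#'
#' `0.5 * [ sum_i f_i min_j d_ij + sum_j f_j min_i d_ij ]` over the taxa
#' present in each community, with `f` the relative abundances
#' (`weighted = TRUE`) or uniform weights over present taxa.
#'
#' @param x,y named count vectors over the same taxa.
#' @param coph cophenetic distance matrix covering those taxa.
#' @param weighted abundance-weighted (default) or presence-based.
#' @return bMNTD in branch-length units.
#' @export
beta_mntd <- function(x, y, coph, weighted = TRUE) {
  if (is.null(names(x)) || is.null(names(y)))
    stop2("count vectors must be named by taxon")
  px <- names(x)[x > 0]
  py <- names(y)[y > 0]
  if (!length(px) || !length(py)) stop2("empty sample")
  miss <- setdiff(c(px, py), rownames(coph))
  if (length(miss)) stop2("taxa missing from cophenetic matrix: ",
                          paste(miss, collapse = ", "))
  taxa <- union(names(x), names(y))
  comm <- rbind(x[taxa], y[taxa])
  comm[is.na(comm)] <- 0
  colnames(comm) <- taxa
  beta_mntd_pairs_cpp(comm * 1.0, coph[taxa, taxa],
                      seq_along(taxa) - 1L, weighted)[1, 2]
}

#' Beta nearest taxon index (bNTI) for all sample pairs
#'
#' Each randomization shuffles tip identities on the cophenetic matrix
#' once and recomputes bMNTD for all pairs (one shared shuffle per
#' randomization).  `bNTI = (bMNTD_obs - mean_null) / sd_null`.  When the
#' null is a point mass that the observation hits exactly -- notably two
#' samples with identical taxon support, whose bMNTD is invariant under
#' any tip shuffle -- there is no selection signal and `bNTI` is 0; a
#' point-mass null that the observation misses is undefined (`NA`, with
#' a warning).
#'
#' @param counts samples x OTUs matrix (the OTU set is the taxon pool
#'   the shuffle acts on).
#' @param tree [ape::phylo] tree containing every OTU as a tip.
#' @param n_rand number of randomizations.
#' @param weighted abundance-weighted bMNTD (default, the usual
#'   convention for this framework).
#' @param seed RNG seed.
#' @return list of class `seacomm_bnti`: matrices `beta_mntd_obs`,
#'   `beta_nti`, `null_mean`, `null_sd`, and `n_rand`.
#' @export
beta_nti <- function(counts, tree, n_rand = 999L, weighted = TRUE,
                     seed = NULL) {
  validate_otu_table(counts)
  if (nrow(counts) < 2L) stop2("need at least 2 samples")
  if (any(rowSums(counts) == 0)) stop2("all-zero sample(s) present")
  tree <- validate_tree(tree)
  coph <- cophenetic_matrix(tree)
  missing <- setdiff(colnames(counts), rownames(coph))
  if (length(missing))
    stop2("OTU(s) absent from tree: ", paste(missing, collapse = ", "))
  coph <- coph[colnames(counts), colnames(counts)]
  S <- ncol(counts)
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_rand), function(r) sample.int(S) - 1L, integer(S)))
  })
  res <- beta_mntd_null_cpp(counts * 1.0, coph, perms, weighted)
  sd0 <- res$null_sd <= (abs(res$null_mean) + 1e-12) * 1e-7
  res$null_sd[sd0] <- 0
  z <- (res$obs - res$null_mean) / res$null_sd
  # A point-mass null that the observation hits exactly (e.g. two samples
  # with identical taxon support, where every tip shuffle leaves bMNTD
  # unchanged) carries no selection signal: z -> 0.  A point-mass null the
  # observation misses is genuinely undefined.
  exact <- res$null_sd == 0 &
    abs(res$obs - res$null_mean) <= (abs(res$null_mean) + 1e-12) * 1e-7
  z[exact] <- 0
  z[!is.finite(z)] <- NA_real_
  diag(z) <- NA_real_
  dimnames(res$obs) <- dimnames(z) <- dimnames(res$null_mean) <-
    dimnames(res$null_sd) <- list(rownames(counts), rownames(counts))
  degen <- res$null_sd == 0 & !exact & upper.tri(res$null_sd)
  if (any(degen))
    warn2(sum(degen), " pair(s) with degenerate bNTI null (sd = 0)")
  structure(list(beta_mntd_obs = res$obs, beta_nti = z,
                 null_mean = res$null_mean, null_sd = res$null_sd,
                 n_rand = as.integer(n_rand), weighted = weighted),
            class = "seacomm_bnti")
}

#' Bray-Curtis Raup-Crick metric (RC_bray) for all sample pairs
#'
#' Null communities preserve each sample's richness and total count:
#' species are drawn without replacement with probability proportional
#' to their occupancy across the analysis group, seeded with one
#' individual each, and the remaining individuals are distributed with
#' replacement among the drawn species with probability proportional to
#' their summed relative abundance.  Observed Bray-Curtis is located in
#' the null distribution:
#' `RC = 2 * ((n_less + 0.5 * n_equal) / n_rand - 0.5)` in `[-1, 1]`.
#' Bray-Curtis values are rounded to 1e-9 before tie comparison, since
#' integer counts give rational values that differ only by float noise.
#'
#' @param counts samples x OTUs integer matrix.
#' @param n_rand number of null draws.
#' @param seed RNG seed.
#' @param occupancy,abundance optional named weight overrides (taxon
#'   occupancy and summed relative abundance); by default both are
#'   computed from `counts` itself.  Supplying them lets the weights
#'   come from a wider analysis group than the samples being compared.
#' @return list of class `seacomm_rcbray` with matrices `rc_bray`,
#'   `bray_obs`, and `n_rand`.
#' @export
rc_bray <- function(counts, n_rand = 999L, seed = NULL,
                    occupancy = NULL, abundance = NULL) {
  validate_otu_table(counts)
  if (nrow(counts) < 2L) stop2("need at least 2 samples")
  if (!is_whole(counts)) stop2("RC_bray requires integer counts")
  if (any(rowSums(counts) == 0)) stop2("all-zero sample(s) present")
  n <- nrow(counts)
  taxa <- colnames(counts)
  occ <- if (is.null(occupancy)) colSums(counts > 0) else occupancy[taxa]
  ab <- if (is.null(abundance)) {
    colSums(counts / rowSums(counts))
  } else abundance[taxa]
  if (anyNA(occ) || anyNA(ab))
    stop2("occupancy/abundance weights must cover every OTU")
  pool <- which(occ > 0)
  S_k <- apply(counts, 1, function(x) sum(x > 0))
  N_k <- rowSums(counts)
  if (any(S_k > length(pool)))
    stop2("sample richness exceeds the species pool; impossible null")
  obs <- round(bray_curtis(counts), 9)
  less <- equal <- matrix(0, n, n)
  with_seed(seed, {
    for (r in seq_len(n_rand)) {
      null_tab <- matrix(0, n, length(taxa))
      for (k in seq_len(n)) {
        chosen <- pool[sample.int(length(pool), S_k[k], prob = occ[pool])]
        vec <- numeric(length(taxa))
        vec[chosen] <- 1
        extra <- N_k[k] - S_k[k]
        if (extra > 0) {
          vec[chosen] <- vec[chosen] +
            as.numeric(rmultinom(1, extra, prob = ab[chosen]))
        }
        null_tab[k, ] <- vec
      }
      nb <- round(as.matrix(vegan::vegdist(null_tab, method = "bray")), 9)
      less <- less + (nb < obs)
      equal <- equal + (nb == obs)
    }
  })
  rc <- 2 * ((less + 0.5 * equal) / n_rand - 0.5)
  diag(rc) <- 0
  dimnames(rc) <- list(rownames(counts), rownames(counts))
  structure(list(rc_bray = rc, bray_obs = obs,
                 n_rand = as.integer(n_rand)),
            class = "seacomm_rcbray")
}

#' Classify pairwise turnover into five assembly processes
#'
#' `bNTI > 2` gives heterogeneous selection and `bNTI < -2` homogeneous
#' selection; otherwise `RC_bray > 0.95` gives dispersal limitation,
#' `RC_bray < -0.95` homogenizing dispersal, and the remainder is drift.
#' Thresholds are configurable.  Pairs with an undefined bNTI or RC are
#' excluded with a warning.
#'
#' @param bnti bNTI matrix or `seacomm_bnti` result.
#' @param rc RC_bray matrix or `seacomm_rcbray` result.
#' @param bnti_threshold,rc_threshold classification thresholds.
#' @return data.frame with `sample_i`, `sample_j`, `beta_nti`,
#'   `rc_bray`, `process` (factor with the five process levels).
#' @export
classify_pairs <- function(bnti, rc, bnti_threshold = 2,
                           rc_threshold = 0.95) {
  if (inherits(bnti, "seacomm_bnti")) bnti <- bnti$beta_nti
  if (inherits(rc, "seacomm_rcbray")) rc <- rc$rc_bray
  if (!identical(rownames(bnti), rownames(rc)))
    stop2("bNTI and RC matrices must share identifiers in the same order")
  n <- nrow(bnti)
  pi <- pair_index(n)
  b <- bnti[cbind(pi$i, pi$j)]
  r <- rc[cbind(pi$i, pi$j)]
  ok <- !is.na(b) & !is.na(r)
  if (any(!ok))
    warn2(sum(!ok), " pair(s) with undefined bNTI or RC_bray excluded")
  process <- ifelse(b > bnti_threshold, "heterogeneous_selection",
             ifelse(b < -bnti_threshold, "homogeneous_selection",
             ifelse(r > rc_threshold, "dispersal_limitation",
             ifelse(r < -rc_threshold, "homogenizing_dispersal",
                    "drift"))))
  data.frame(sample_i = rownames(bnti)[pi$i][ok],
             sample_j = rownames(bnti)[pi$j][ok],
             beta_nti = b[ok], rc_bray = r[ok],
             process = factor(process[ok], levels = .process_levels),
             stringsAsFactors = FALSE)
}

#' Per-group fractions of assembly processes
#'
#' For each group, the fraction of within-group pairs assigned to each
#' process; pairs whose members belong to different groups are
#' summarized separately under `between`, and a pooled `all` row covers
#' every pair.
#'
#' @param pairs data.frame from [classify_pairs()].
#' @param groups named vector mapping sample ids to group labels, or
#'   `NULL` to summarize all pairs together.
#' @return data.frame with `group`, `n_pairs`, and one fraction column
#'   per process; fractions in each row sum to 1.
#' @export
summarize_fractions <- function(pairs, groups = NULL) {
  frac_row <- function(label, sub) {
    tab <- table(factor(sub$process, levels = .process_levels))
    out <- data.frame(group = label, n_pairs = nrow(sub),
                      stringsAsFactors = FALSE)
    for (pr in .process_levels) out[[pr]] <- unname(tab[pr]) / nrow(sub)
    out
  }
  rows <- list(frac_row("all", pairs))
  if (!is.null(groups)) {
    gi <- groups[pairs$sample_i]
    gj <- groups[pairs$sample_j]
    if (anyNA(gi) || anyNA(gj))
      stop2("groups must map every sample in `pairs`")
    for (g in sort(unique(groups))) {
      sub <- pairs[gi == g & gj == g, , drop = FALSE]
      if (nrow(sub) == 0L) {
        warn2("group '", g, "' has no within-group pairs; skipped")
        next
      }
      rows[[length(rows) + 1L]] <- frac_row(g, sub)
    }
    cross <- pairs[gi != gj, , drop = FALSE]
    if (nrow(cross))
      rows[[length(rows) + 1L]] <- frac_row("between", cross)
  }
  do.call(rbind, rows)
}

#' Full assembly-process analysis of an aligned dataset
#'
#' Runs [beta_nti()] and [rc_bray()] with deterministic child seeds,
#' classifies every pair and summarizes per-group fractions.
#'
#' @inheritParams beta_nti
#' @param groups named vector mapping sample ids to group labels
#'   (optional).
#' @return list with `bnti`, `rc`, `pairs`, `fractions`.
#' @export
assembly_processes <- function(counts, tree, groups = NULL,
                               n_rand = 999L, weighted = TRUE,
                               seed = NULL) {
  seeds <- derive_seeds(seed, 2L, c("bnti", "rc"))
  bn <- beta_nti(counts, tree, n_rand = n_rand, weighted = weighted,
                 seed = seeds[["bnti"]])
  rcres <- rc_bray(counts, n_rand = n_rand, seed = seeds[["rc"]])
  pairs <- classify_pairs(bn, rcres)
  list(bnti = bn, rc = rcres, pairs = pairs,
       fractions = summarize_fractions(pairs, groups))
}

#' @export
print.seacomm_bnti <- function(x, ...) {
  v <- x$beta_nti[upper.tri(x$beta_nti)]
  cat("bNTI over", length(v), "pairs (", x$n_rand, "randomizations )\n")
  cat("  |bNTI| > 2:", sum(abs(v) > 2, na.rm = TRUE), "pairs\n")
  invisible(x)
}

#' @export
print.seacomm_rcbray <- function(x, ...) {
  v <- x$rc_bray[upper.tri(x$rc_bray)]
  cat("RC_bray over", length(v), "pairs (", x$n_rand, "null draws )\n")
  cat("  |RC| > 0.95:", sum(abs(v) > 0.95, na.rm = TRUE), "pairs\n")
  invisible(x)
}
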