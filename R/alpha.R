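# Rarefaction and per-sample diversity indices: richness, Shannon,
# Faith's PD, and the nearest taxon index (NTI).

#' Rarefy an OTU table to a common depth
#'
#' Each sample is subsampled without replacement to exactly `depth`
#' reads.  Samples with fewer reads than `depth` are dropped with a
#' warning.  All-zero OTU columns are retained by default so that tables
#' rarefied separately stay comparable; set `prune_zero` to drop them.
#'
#' @param counts samples x OTUs integer matrix.
#' @param depth target depth (>= 1).
#' @param seed RNG seed.
#' @param prune_zero drop OTU columns that are zero everywhere after
#'   rarefaction.
#' @return rarefied integer matrix; every retained row sums to `depth`.
#' @export
rarefy_table <- function(counts, depth, seed = NULL, prune_zero = FALSE) {
  validate_otu_table(counts)
  if (length(depth) != 1L || depth < 1) stop2("depth must be >= 1")
  depth <- as.integer(depth)
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!any(keep)) stop2("no sample reaches depth ", depth)
  if (any(!keep))
    warn2("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
          paste(rownames(counts)[!keep], collapse = ", "))
  kept <- counts[keep, , drop = FALSE]
  out <- with_seed(seed, {
    t(apply(kept, 1L, function(x) {
      if (sum(x) == depth) return(as.integer(x))
      # draw read indices without replacement; map back to OTUs via the
      # cumulative count boundaries
      reads <- sample.int(sum(x), depth)
      as.integer(tabulate(findInterval(reads - 1L, cumsum(x)) + 1L,
                          nbins = length(x)))
    }))
  })
  dimnames(out) <- dimnames(kept)
  if (prune_zero) out <- out[, colSums(out) > 0, drop = FALSE]
  out
}

#' Mean rarefaction curves
#'
#' Mean observed richness per sample over `reps` random subsamples at
#' each depth.  Depths exceeding a sample's total are reported as `NA`.
#'
#' @param counts samples x OTUs matrix.
#' @param depths ascending depths.
#' @param reps subsamples per depth.
#' @param seed RNG seed.
#' @return data.frame with `sample_id`, `depth`, `mean_richness`.
#' @export
rarefaction_curve <- function(counts, depths, reps = 10L, seed = NULL) {
  validate_otu_table(counts)
  if (is.unsorted(depths)) stop2("depths must be sorted ascending")
  totals <- rowSums(counts)
  grid <- expand.grid(sample_id = rownames(counts), depth = depths,
                      stringsAsFactors = FALSE)
  with_seed(seed, {
    grid$mean_richness <- mapply(function(sid, d) {
      x <- counts[sid, ]
      if (totals[sid] < d) return(NA_real_)
      mean(vapply(seq_len(reps), function(r) {
        reads <- sample.int(totals[sid], d)
        sum(tabulate(findInterval(reads - 1L, cumsum(x)) + 1L,
                     nbins = length(x)) > 0)
      }, numeric(1)))
    }, grid$sample_id, grid$depth)
    grid
  })
}

#' Observed OTU richness of a count vector
#' @param counts count vector.
#' @return number of OTUs with positive count.
#' @export
richness <- function(counts) sum(counts > 0)

#' Shannon diversity of a count vector
#'
#' `H = -sum(p * log(p, base))` with `0 * log(0) = 0`.  Defaults to bits
#' (base 2), the convention of the classic QIIME alpha-diversity tooling;
#' pass `base = exp(1)` for nats.
#'
#' @param counts count vector with at least one positive entry.
#' @param base logarithm base.
#' @return Shannon index.
#' @export
shannon <- function(counts, base = 2) {
  if (any(counts < 0)) stop2("negative counts")
  tot <- sum(counts)
  if (tot <= 0) stop2("Shannon index undefined for an all-zero sample")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Faith's phylogenetic diversity of one sample
#'
#' Sum of the branch lengths of the union of root-to-tip paths over the
#' present taxa.  By default the connection to the root is included
#' (classic QIIME behaviour); with `include_root = FALSE` only the
#' subtree spanning the present taxa below their MRCA is summed.
#'
#' @param counts named count vector (names are tree tips) or character
#'   vector of present taxa.
#' @param tree [ape::phylo] tree with branch lengths.
#' @param include_root include branches from the spanning subtree up to
#'   the tree root.
#' @return total branch length.
#' @export
faith_pd <- function(counts, tree, include_root = TRUE) {
  tree <- validate_tree(tree)
  present <- if (is.character(counts)) counts else {
    if (is.null(names(counts))) stop2("counts must be named by OTU")
    names(counts)[counts > 0]
  }
  if (length(present) == 0L) return(0)
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop2("present OTU(s) absent from tree: ",
          paste(missing, collapse = ", "))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(n_tip + tree$Nnode)
  edge_len <- numeric(n_tip + tree$Nnode)  # length of edge above node
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_len[tree$edge[, 2]] <- tree$edge.length
  on_path <- logical(n_tip + tree$Nnode)
  for (tip in match(present, tree$tip.label)) {
    node <- tip
    while (node != root && !on_path[node]) {
      on_path[node] <- TRUE
      node <- parent[node]
    }
  }
  total <- sum(edge_len[on_path])
  if (!include_root) {
    # subtract the chain of single-path edges from the root down to the
    # MRCA of the present taxa
    node <- root
    repeat {
      children <- tree$edge[tree$edge[, 1] == node, 2]
      children <- children[on_path[children]]
      if (length(children) != 1L) break
      total <- total - edge_len[children]
      node <- children
    }
  }
  total
}

#' Nearest taxon index (NTI) per sample
#'
#' The mean nearest-taxon distance (MNTD) of each sample is compared with
#' a null built by shuffling tip labels across the full taxon pool; one
#' shuffle per randomization is shared by all samples.  `NTI =
#' -(MNTD_obs - mean_null) / sd_null`, so phylogenetically clustered
#' communities give positive NTI.
#'
#' Samples with fewer than two present taxa, or with a degenerate null
#' (sd 0, e.g. a sample containing every pool taxon), are reported as
#' `NA`.
#'
#' @param counts samples x OTUs matrix (all OTUs are the taxon pool).
#' @param tree [ape::phylo] tree containing every OTU as a tip.
#' @param n_rand number of tip-shuffle randomizations.
#' @param weighted weight MNTD by relative abundance (default `FALSE`,
#'   the presence-based convention for NTI).
#' @param seed RNG seed.
#' @return data.frame with `sample_id`, `mntd_obs`, `null_mean`,
#'   `null_sd`, `nti`, `n_rand`.
#' @export
nti <- function(counts, tree, n_rand = 999L, weighted = FALSE, seed = NULL) {
  validate_otu_table(counts)
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
  res <- mntd_null_cpp(counts * 1.0, coph, perms, weighted)
  # an accumulated-rounding sd of ~1e-9 on a constant null is still a
  # degenerate null
  sd0 <- !is.na(res$null_sd) &
    res$null_sd <= (abs(res$null_mean) + 1e-12) * 1e-7
  res$null_sd[sd0] <- 0
  z <- (res$obs - res$null_mean) / res$null_sd
  z[!is.finite(z)] <- NA_real_
  out <- data.frame(sample_id = rownames(counts),
                    mntd_obs = res$obs,
                    null_mean = res$null_mean,
                    null_sd = res$null_sd,
                    nti = -z,
                    n_rand = as.integer(n_rand),
                    stringsAsFactors = FALSE)
  if (any(res$null_sd == 0, na.rm = TRUE))
    warn2("degenerate null (sd = 0) for sample(s): ",
          paste(out$sample_id[!is.na(res$null_sd) & res$null_sd == 0],
                collapse = ", "))
  out
}

#' Alpha diversity table for an aligned dataset
#'
#' Convenience wrapper computing richness, Shannon, Faith's PD, and NTI
#' per sample.
#'
#' @inheritParams nti
#' @param shannon_base logarithm base for the Shannon index.
#' @return data.frame with one row per sample.
#' @export
alpha_diversity <- function(counts, tree, n_rand = 999L, weighted = FALSE,
                            shannon_base = 2, seed = NULL) {
  validate_otu_table(counts)
  tree <- validate_tree(tree)
  nti_tab <- nti(counts, tree, n_rand = n_rand, weighted = weighted,
                 seed = seed)
  data.frame(
    sample_id = rownames(counts),
    richness = apply(counts, 1, richness),
    shannon = apply(counts, 1, shannon, base = shannon_base),
    pd = apply(counts, 1, faith_pd, tree = tree),
    mntd_obs = nti_tab$mntd_obs,
    nti = nti_tab$nti,
    stringsAsFactors = FALSE, row.names = NULL)
}
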