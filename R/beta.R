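# Beta-diversity structure: Bray-Curtis dissimilarity, principal
# coordinates, and the permutation tests used on community matrices
# (ANOSIM, Mantel, Procrustes/PROTEST), plus rank-sum group comparisons,
# Spearman + FDR correlation matrices, and PCA of standardized
# environmental variables.
#
# All permutation p-values follow the (exceedances + 1) / (n_perm + 1)
# convention and are one-sided for ANOSIM, Mantel and PROTEST.

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`.
#'
#' @param counts samples x OTUs matrix; no all-zero sample.
#' @return named square dissimilarity matrix in `[0, 1]`.
#' @export
bray_curtis <- function(counts) {
  validate_otu_table(counts)
  if (nrow(counts) < 2L) stop2("need at least 2 samples")
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop2("all-zero sample(s): ",
          paste(rownames(counts)[zero], collapse = ", "))
  m <- as.matrix(vegan::vegdist(counts, method = "bray"))
  diag(m) <- 0
  m
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigendecomposition of the Gower-centered `-0.5 * D^2` matrix.
#' Coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues.  Negative eigenvalues are reported as-is and
#' excluded from `proportion_explained`; `correction = "cailliez"`
#' applies the Cailliez constant to make the matrix Euclidean first.
#'
#' @param d distance matrix (matrix or `dist`).
#' @param correction `"none"` or `"cailliez"`.
#' @return list of class `seacomm_ordination`: `coordinates` (samples x
#'   positive axes), `eigenvalues` (all, descending),
#'   `proportion_explained`.
#' @export
pcoa <- function(d, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  m <- as_dist_matrix(d)
  if (correction == "cailliez") {
    m <- cailliez_correct(m)
  }
  n <- nrow(m)
  G <- gower_center(-0.5 * m^2)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("Axis.", seq_along(pos))
  structure(list(
    coordinates = coords,
    eigenvalues = e$values,
    proportion_explained = e$values[pos] / sum(e$values[pos]),
    correction = correction), class = "seacomm_ordination")
}

gower_center <- function(A) {
  rm <- rowMeans(A)
  cm <- colMeans(A)
  A - outer(rm, rep(1, ncol(A))) - outer(rep(1, nrow(A)), cm) + mean(A)
}

# Cailliez constant: smallest c such that d + c (off-diagonal) is
# Euclidean; largest real eigenvalue of the standard 2n x 2n block
# matrix.
cailliez_correct <- function(m) {
  n <- nrow(m)
  d1 <- gower_center(-0.5 * m^2)
  d2 <- gower_center(-0.5 * m)
  B <- rbind(cbind(matrix(0, n, n), 2 * d1),
             cbind(-diag(n), -4 * d2))
  ev <- eigen(B, only.values = TRUE)$values
  cc <- max(Re(ev[abs(Im(ev)) < 1e-8]))
  if (cc > 0) {
    m <- m + cc
    diag(m) <- 0
  }
  m
}

#' Analysis of similarity (ANOSIM)
#'
#' Ranks all pairwise dissimilarities (average ranks on ties) and
#' compares mean between-group and within-group ranks:
#' `R = (mean_between - mean_within) / (N (N - 1) / 4)`.  Significance by
#' permuting group labels, or by exhaustive enumeration of all distinct
#' label arrangements when `exhaustive = TRUE`.
#'
#' @param d dissimilarity matrix (matrix or `dist`).
#' @param groups group labels, one per sample; every group needs >= 2
#'   members.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @param exhaustive enumerate all distinct label arrangements instead of
#'   sampling; p is then the exact fraction of arrangements with
#'   `R >= R_obs`.
#' @return list of class `seacomm_permtest`: `statistic` (R), `p_value`,
#'   `n_permutations`, `statistic_name`.
#' @export
anosim <- function(d, groups, n_perm = 9999L, seed = NULL,
                   exhaustive = FALSE) {
  m <- as_dist_matrix(d, "dissimilarity matrix")
  n <- nrow(m)
  groups <- as.character(groups)
  if (length(groups) != n) stop2("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2L) stop2("need at least 2 groups")
  if (any(sizes < 2L))
    stop2("group(s) with fewer than 2 members: ",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  rk <- rank(lower_vec(m))
  pi <- pair_index(n)
  denom <- n * (n - 1) / 4
  r_stat <- function(g) {
    within <- g[pi$i] == g[pi$j]
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  r_obs <- r_stat(groups)
  if (exhaustive) {
    arrangements <- multiset_permutations(groups)
    null_r <- vapply(arrangements, r_stat, numeric(1))
    p <- mean(null_r >= r_obs - 1e-12)
    n_used <- length(arrangements)
  } else {
    null_r <- with_seed(seed, vapply(seq_len(n_perm), function(k)
      r_stat(sample(groups)), numeric(1)))
    p <- perm_pvalue(sum(null_r >= r_obs - 1e-12), n_perm)
    n_used <- n_perm
  }
  structure(list(statistic = r_obs, p_value = p, n_permutations = n_used,
                 statistic_name = "ANOSIM R", exhaustive = exhaustive),
            class = "seacomm_permtest")
}

#' Mantel test between two distance matrices
#'
#' Correlation over strictly-lower-triangle entries; significance by
#' jointly permuting rows and columns of the second matrix.
#'
#' @param d1,d2 distance matrices over the same samples in the same
#'   order.
#' @param method correlation type; Spearman by default.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param exhaustive enumerate all `n!` relabelings (small n only).
#' @return `seacomm_permtest` list with `statistic` (Mantel r).
#' @export
mantel <- function(d1, d2, method = c("spearman", "pearson"),
                   n_perm = 9999L, seed = NULL, exhaustive = FALSE) {
  method <- match.arg(method)
  m1 <- as_dist_matrix(d1, "first distance matrix")
  m2 <- as_dist_matrix(d2, "second distance matrix")
  if (!identical(rownames(m1), rownames(m2)))
    stop2("the two matrices must share identifiers in the same order")
  n <- nrow(m1)
  v1 <- lower_vec(m1)
  if (method == "spearman") {
    v1 <- rank(v1)
    # rank-transform m2's pairs once; permuting samples permutes pairs,
    # leaving the rank multiset unchanged
    rv2 <- rank(lower_vec(m2))
    m2r <- matrix(0, n, n)
    m2r[lower.tri(m2r)] <- rv2
    m2 <- m2r + t(m2r)
  }
  if (sd(v1) == 0 || sd(lower_vec(m2)) == 0)
    stop2("constant distance triangle; Mantel r undefined")
  r_with <- function(idx) {
    cor(v1, lower_vec(m2[idx, idx, drop = FALSE]))
  }
  r_obs <- cor(v1, lower_vec(m2))
  if (exhaustive) {
    if (factorial(n) > 5e5)
      stop2("exhaustive Mantel needs n! <= 5e5 relabelings")
    perms <- all_permutations(n)
    null_r <- vapply(perms, r_with, numeric(1))
    p <- mean(null_r >= r_obs - 1e-12)
    n_used <- length(perms)
  } else {
    null_r <- with_seed(seed, vapply(seq_len(n_perm), function(k)
      r_with(sample.int(n)), numeric(1)))
    p <- perm_pvalue(sum(null_r >= r_obs - 1e-12), n_perm)
    n_used <- n_perm
  }
  structure(list(statistic = r_obs, p_value = p, n_permutations = n_used,
                 statistic_name = paste0("Mantel r (", method, ")"),
                 method = method), class = "seacomm_permtest")
}

# All permutations of 1..n as a list (n <= 9 in practice).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Symmetric Procrustes comparison of two ordinations (PROTEST)
#'
#' Both configurations are centered and scaled to unit trace, then
#' optimally rotated onto each other; `M2` is the residual sum of
#' squares in `[0, 1]` and is symmetric in its arguments.  Significance
#' comes from row permutations of the second configuration (Monte-Carlo
#' PROTEST, one-sided on the correlation `sqrt(1 - M2)`).
#'
#' @param x,y coordinate matrices over the same samples in the same
#'   order, >= 2 axes each.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return `seacomm_permtest` list with `statistic` (M2) and
#'   `correlation`.
#' @export
procrustes_protest <- function(x, y, n_perm = 999L, seed = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop2("configurations must share samples")
  if (!is.null(rownames(x)) && !is.null(rownames(y)) &&
      !identical(rownames(x), rownames(y)))
    stop2("sample identifiers differ between configurations")
  if (ncol(x) < 2L || ncol(y) < 2L) stop2("need >= 2 axes each")
  prep <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  X <- prep(x)
  Y <- prep(y)
  m2_of <- function(Yp) {
    1 - sum(svd(crossprod(X, Yp))$d)^2
  }
  m2 <- m2_of(Y)
  t_obs <- sqrt(max(0, 1 - m2))
  null_t <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    sqrt(max(0, 1 - m2_of(Y[sample.int(nrow(Y)), , drop = FALSE])))
  }, numeric(1)))
  p <- perm_pvalue(sum(null_t >= t_obs - 1e-12), n_perm)
  structure(list(statistic = m2, correlation = t_obs, p_value = p,
                 n_permutations = n_perm,
                 statistic_name = "Procrustes M2"),
            class = "seacomm_permtest")
}

#' Two-sample rank-sum comparison (Mann-Whitney / Wilcoxon)
#'
#' Two-sided by default with `W` the rank-sum statistic of the first
#' sample; exact enumeration for small tie-free samples, normal
#' approximation with tie and continuity correction otherwise.  The
#' paired signed-rank variant is available with `paired = TRUE`.
#'
#' @param x,y numeric vectors.
#' @param paired use the signed-rank test for paired observations.
#' @return `seacomm_permtest` list with `statistic` (W) and `p_value`.
#' @export
rank_sum_test <- function(x, y, paired = FALSE) {
  if (!length(x) || !length(y)) stop2("both samples must be nonempty")
  exact <- !paired && length(x) <= 20 && length(y) <= 20 &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    wilcox.test(x, y, paired = paired, exact = exact, correct = TRUE))
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_permutations = NA_integer_,
                 statistic_name = if (paired) "Wilcoxon V" else "Wilcoxon W",
                 method = ht$method), class = "seacomm_permtest")
}

#' Pairwise Spearman correlations with BH-FDR adjustment
#'
#' @param variables data.frame or named list of numeric vectors of equal
#'   length.
#' @param alpha significance level used by the `significant` mask.
#' @return list with square matrices `rho`, `p`, `p_adj`, logical
#'   `significant`, and `n` (complete observations per pair).  Constant
#'   variables give `NA` correlations for their pairs, with a warning.
#' @export
spearman_fdr_matrix <- function(variables, alpha = 0.05) {
  df <- as.data.frame(variables)
  vars <- colnames(df)
  k <- length(vars)
  if (k < 2L) stop2("need at least two variables")
  rho <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1
  diag(p) <- 0
  constant <- character(0)
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      ok <- stats::complete.cases(df[[a]], df[[b]])
      nmat[a, b] <- nmat[b, a] <- sum(ok)
      if (sum(ok) < 3L) next
      xa <- df[[a]][ok]
      xb <- df[[b]][ok]
      if (sd(xa) == 0 || sd(xb) == 0) {
        constant <- union(constant,
                          vars[c(a, b)][c(sd(xa) == 0, sd(xb) == 0)])
        next
      }
      ct <- suppressWarnings(cor.test(xa, xb, method = "spearman"))
      rho[a, b] <- rho[b, a] <- unname(ct$estimate)
      p[a, b] <- p[b, a] <- ct$p.value
    }
  }
  if (length(constant))
    warn2("constant variable(s), correlations undefined: ",
          paste(constant, collapse = ", "))
  upper <- upper.tri(p)
  p_adj <- p
  p_adj[upper] <- p.adjust(p[upper], method = "BH")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  list(rho = rho, p = p, p_adj = p_adj,
       significant = !is.na(p_adj) & p_adj < alpha, n = nmat)
}

#' PCA of Z-score standardized environmental variables
#'
#' Columns are centered and scaled to unit variance before the
#' eigendecomposition, i.e. the PCA is on the correlation structure.
#'
#' @param env samples x variables numeric data.frame or matrix; no
#'   constant column.
#' @return `seacomm_ordination` list with `coordinates` (scores),
#'   `eigenvalues`, `proportion_explained`, and `loadings`.
#' @export
env_pca <- function(env) {
  X <- as.matrix(as.data.frame(env))
  if (ncol(X) < 2L) stop2("need at least 2 variables")
  if (nrow(X) < 3L) stop2("need at least 3 samples")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop2("constant column(s): ",
          paste(colnames(X)[sds == 0], collapse = ", "))
  pr <- prcomp(X, center = TRUE, scale. = TRUE)
  eig <- pr$sdev^2
  structure(list(coordinates = pr$x, eigenvalues = eig,
                 proportion_explained = eig / sum(eig),
                 loadings = pr$rotation), class = "seacomm_ordination")
}

#' @export
print.seacomm_permtest <- function(x, ...) {
  cat(x$statistic_name, "=", format(x$statistic, digits = 4),
      " p =", format(x$p_value, digits = 4))
  if (!is.na(x$n_permutations %||% NA))
    cat(" (", x$n_permutations, " permutations)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
print.seacomm_ordination <- function(x, ...) {
  cat("ordination:", nrow(x$coordinates), "samples x",
      ncol(x$coordinates), "axes\n")
  pe <- x$proportion_explained
  cat("  proportion explained (first axes):",
      paste(format(utils::head(pe, 3), digits = 3), collapse = ", "), "\n")
  invisible(x)
}
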