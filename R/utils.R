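# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state; seed = NULL runs unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic child seeds for pipeline stages (kept under 2^31 - 1).
derive_seeds <- function(seed, n, labels = NULL) {
  s <- with_seed(seed, sample.int(2147483646L, n))
  if (!is.null(labels)) names(s) <- labels
  s
}

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)

is_whole <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) <= tol)
}

# A matrix with ids; checks the distance-matrix contract.
validate_dist_matrix <- function(m, what = "distance matrix", tol = 1e-12) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop2(what, " must be a square matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop2(what, " must carry row and column identifiers")
  if (!identical(rownames(m), colnames(m)))
    stop2(what, " row and column identifiers differ")
  if (any(abs(m - t(m)) > tol))
    stop2(what, " is not symmetric (tolerance ", format(tol), ")")
  if (any(abs(diag(m)) > tol))
    stop2(what, " has a non-zero diagonal")
  invisible(m)
}

# Coerce dist or matrix input to a named square matrix.
as_dist_matrix <- function(d, what = "distance matrix") {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d)) stop2(what, " must be a 'dist' object or square matrix")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  }
  validate_dist_matrix(d, what)
  d
}

# Strictly-lower-triangle extraction in column-major pair order.
lower_vec <- function(m) m[lower.tri(m)]

# Pair index vectors (i > j, column-major) matching lower_vec() order.
pair_index <- function(n) {
  j <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  i <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  list(i = i, j = j)
}

# Commented provenance header used by all tab-delimited writers.
provenance_header <- function(seed = NULL, params = NULL) {
  bits <- c(paste0("seacomm ", as.character(utils::packageVersion("seacomm"))))
  if (!is.null(seed)) bits <- c(bits, paste0("seed=", seed))
  if (length(params)) {
    kv <- paste(names(params), unname(vapply(params, function(p)
      paste(format(p, trim = TRUE), collapse = ","), "")), sep = "=")
    bits <- c(bits, kv)
  }
  paste0("# ", paste(bits, collapse = " | "))
}

write_tsv <- function(x, path, seed = NULL, params = NULL, row_label = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(seed = seed, params = params), con)
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- row_label %||% "id"
    x <- df
  }
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Permutation p-value convention: never 0, vegan-style.
perm_pvalue <- function(n_exceed, n_perm) (n_exceed + 1) / (n_perm + 1)

# All distinct arrangements of a label vector (multiset permutations).
# Guarded to small problems; used by the exhaustive modes of anosim/mantel.
multiset_permutations <- function(labels, max_n = 5e5) {
  labels <- as.character(labels)
  n <- length(labels)
  counts <- table(labels)
  total <- factorial(n) / prod(factorial(counts))
  if (total > max_n)
    stop2("exhaustive enumeration would need ", format(total),
          " arrangements; use the permutation mode instead")
  rec <- function(remaining) {
    if (sum(remaining) == 0L) return(list(character(0)))
    out <- list()
    for (lv in names(remaining)) {
      if (remaining[[lv]] == 0L) next
      rem <- remaining
      rem[[lv]] <- rem[[lv]] - 1L
      for (tail in rec(rem)) out[[length(out) + 1L]] <- c(lv, tail)
    }
    out
  }
  counts_vec <- stats::setNames(as.integer(counts), names(counts))
  rec(counts_vec)
}
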