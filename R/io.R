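# Reading, writing and cross-validating the standard inputs: OTU count
# tables, Newick trees, sample metadata, and square distance matrices.
# All tab-delimited writers emit a commented provenance header; all
# readers skip '#' comment lines.

#' Validate an OTU count table
#'
#' An OTU table is an integer matrix with samples as rows and OTUs as
#' columns, carrying unique sample and OTU identifiers as dimnames.
#'
#' @param counts numeric matrix, samples x OTUs.
#' @return The validated matrix, invisibly usable downstream.
#' @export
validate_otu_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop2("OTU table must be a numeric matrix")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop2("OTU table needs at least one sample and one OTU")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop2("OTU table must carry sample (row) and OTU (column) identifiers")
  if (anyDuplicated(rownames(counts)))
    stop2("duplicate sample identifiers: ",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop2("duplicate OTU identifiers: ",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                collapse = ", "))
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop2("missing count at sample '", rownames(counts)[bad[1]],
          "', OTU '", colnames(counts)[bad[2]], "'")
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop2("negative count at sample '", rownames(counts)[bad[1]],
          "', OTU '", colnames(counts)[bad[2]], "'")
  }
  counts
}

#' Read an OTU count table from tab-delimited text
#'
#' The file has one header row and one leading identifier column.  By
#' the common amplicon convention OTUs are rows and samples are columns
#' (`samples_as = "columns"`); the returned matrix is always normalized
#' to samples as rows.
#'
#' @param path file path.
#' @param samples_as `"columns"` (classic OTU-table orientation, default)
#'   or `"rows"`.
#' @return integer matrix, samples x OTUs.
#' @export
read_otu_table <- function(path, samples_as = c("columns", "rows")) {
  samples_as <- match.arg(samples_as)
  raw <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, colClasses = "character",
                    quote = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop2("OTU table needs an id column plus counts")
  ids <- as.character(raw[[1L]])
  m <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
              dimnames = list(ids, colnames(raw)[-1L]))
  for (k in seq_len(ncol(raw) - 1L)) {
    v <- suppressWarnings(as.numeric(raw[[k + 1L]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop2("non-numeric count '", raw[[k + 1L]][bad], "' at row '",
            ids[bad], "', column '", colnames(raw)[k + 1L], "'")
    }
    m[, k] <- v
  }
  if (samples_as == "columns") m <- t(m)
  if (!is_whole(m)) {
    bad <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)[1, ]
    stop2("non-integer count at sample '", rownames(m)[bad[1]],
          "', OTU '", colnames(m)[bad[2]], "'")
  }
  storage.mode(m) <- "integer"
  validate_otu_table(m)
}

#' Write an OTU count table as tab-delimited text
#'
#' @param counts samples x OTUs matrix.
#' @param path output path.
#' @param samples_as orientation of the written file; default writes OTUs
#'   as rows (classic convention).
#' @param seed,params optional provenance recorded in the commented header.
#' @export
write_otu_table <- function(counts, path, samples_as = c("columns", "rows"),
                            seed = NULL, params = NULL) {
  samples_as <- match.arg(samples_as)
  validate_otu_table(counts)
  out <- if (samples_as == "columns") t(counts) else counts
  write_tsv(out, path, seed = seed, params = params,
            row_label = if (samples_as == "columns") "otu_id" else "sample_id")
}

#' Read a rooted phylogenetic tree from a Newick file
#'
#' @param path Newick file.
#' @param missing_lengths `"error"` (default) or `"zero"` to substitute 0
#'   for absent branch lengths.  Phylogenetic diversity metrics are
#'   undefined without branch lengths, so silent substitution is opt-in.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop2("unparseable Newick: ",
                                             conditionMessage(e)))
  if (is.null(tree)) stop2("unparseable Newick file: ", path)
  validate_tree(tree, missing_lengths = missing_lengths)
}

#' Validate a phylogenetic tree for use in this package
#' @param tree an [ape::phylo] object.
#' @inheritParams read_tree
#' @return the (possibly repaired) tree.
#' @export
validate_tree <- function(tree, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  if (!inherits(tree, "phylo")) stop2("not a 'phylo' tree")
  if (length(tree$tip.label) < 2L) stop2("tree needs at least 2 tips")
  if (anyDuplicated(tree$tip.label))
    stop2("duplicate tip labels: ",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                collapse = ", "))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (missing_lengths == "error")
      stop2("tree has missing branch lengths; ",
            "use missing_lengths = \"zero\" to substitute 0")
    if (is.null(tree$edge.length))
      tree$edge.length <- rep(0, nrow(tree$edge))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop2("negative branch lengths")
  tree
}

#' Write a tree as Newick
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-delimited with a header; required columns `sample_id`, `latitude`,
#' `longitude`, `region`.  All remaining numeric columns are treated as
#' environmental variables.
#'
#' @param path file path.
#' @return data.frame with one row per sample and an `env_vars` attribute
#'   naming the detected environmental columns.
#' @export
read_metadata <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, quote = "", stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate a sample metadata table
#' @param df data.frame with `sample_id`, `latitude`, `longitude`, `region`.
#' @return the validated data.frame with an `env_vars` attribute.
#' @export
validate_metadata <- function(df) {
  required <- c("sample_id", "latitude", "longitude", "region")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop2("metadata is missing required column(s): ",
          paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop2("duplicate sample_id in metadata")
  df$latitude <- as.numeric(df$latitude)
  df$longitude <- as.numeric(df$longitude)
  if (anyNA(df$latitude) || any(df$latitude < -90 | df$latitude > 90))
    stop2("latitude must lie in [-90, 90]")
  if (anyNA(df$longitude) || any(df$longitude < -180 | df$longitude > 180))
    stop2("longitude must lie in [-180, 180]")
  df$region <- as.character(df$region)
  extra <- setdiff(colnames(df), required)
  env_vars <- extra[vapply(df[extra], function(col) {
    v <- suppressWarnings(as.numeric(col))
    !all(is.na(v))
  }, logical(1))]
  for (v in env_vars) df[[v]] <- suppressWarnings(as.numeric(df[[v]]))
  attr(df, "env_vars") <- env_vars
  df
}

#' Write sample metadata as tab-delimited text
#' @param meta metadata data.frame.
#' @param path output path.
#' @param seed,params optional provenance for the commented header.
#' @export
write_metadata <- function(meta, path, seed = NULL, params = NULL) {
  write_tsv(meta, path, seed = seed, params = params)
}

#' Read a square distance matrix (ids in first row and first column)
#' @param path file path.
#' @return named square matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, quote = "", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  validate_dist_matrix(m)
  m
}

#' Write a square distance matrix
#' @param m named square matrix.
#' @param path output path.
#' @param seed,params optional provenance for the commented header.
#' @export
write_distance_matrix <- function(m, path, seed = NULL, params = NULL) {
  validate_dist_matrix(m)
  write_tsv(m, path, seed = seed, params = params, row_label = "id")
}

#' Align an OTU table, tree, and metadata to their common samples and OTUs
#'
#' Restricts the table to samples present in the metadata and OTUs present
#' as tree tips, prunes the tree accordingly, and orders everything
#' lexicographically so the result is deterministic and idempotent.
#'
#' @param counts samples x OTUs matrix.
#' @param tree [ape::phylo] tree whose tips name OTUs.
#' @param meta metadata data.frame (see [read_metadata()]).
#' @return list with `counts`, `tree`, `meta`, and a `dropped` report
#'   listing identifiers removed from each input.
#' @export
align_inputs <- function(counts, tree, meta) {
  validate_otu_table(counts)
  tree <- validate_tree(tree)
  meta <- validate_metadata(meta)
  samples <- sort(intersect(rownames(counts), meta$sample_id))
  otus <- sort(intersect(colnames(counts), tree$tip.label))
  if (length(samples) == 0L)
    stop2("no samples shared between OTU table and metadata")
  if (length(otus) == 0L)
    stop2("no OTUs shared between OTU table and tree tips")
  dropped <- list(
    samples = sort(setdiff(rownames(counts), samples)),
    otus = sort(setdiff(colnames(counts), otus)),
    tree_tips = sort(setdiff(tree$tip.label, otus)),
    meta_samples = sort(setdiff(meta$sample_id, samples))
  )
  counts <- counts[samples, otus, drop = FALSE]
  if (length(dropped$tree_tips)) tree <- ape::keep.tip(tree, otus)
  meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  attr(meta, "env_vars") <- attr(validate_metadata(meta), "env_vars")
  list(counts = counts, tree = tree, meta = meta, dropped = dropped)
}
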