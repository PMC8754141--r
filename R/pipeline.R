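# End-to-end orchestration: load or simulate a dataset, rarefy, compute
# alpha and beta diversity, distance decay, and assembly processes, and
# write a deterministic results bundle of tab-delimited files.

#' Build and validate a pipeline configuration
#'
#' Either `preset` (a synthetic scenario) or the three input paths must
#' be supplied.
#'
#' @param table,tree,metadata input file paths (see [read_otu_table()],
#'   [read_tree()], [read_metadata()]).
#' @param preset synthetic scenario name (see [scenario_preset()]).
#' @param n_taxa,n_sites_per_region synthetic sizes (preset mode only).
#' @param depth rarefaction depth; `NULL` rarefies to the smallest
#'   sample total.
#' @param n_rand randomization counts, a named list with any of `nti`,
#'   `bnti`, `rc`, `anosim`, `mantel`, `protest`, `diffslope` (each >=
#'   99).
#' @param group metadata column used for grouping.
#' @param seed master seed (required); each stage gets a deterministic
#'   child seed.
#' @param out_dir output directory for the results bundle.
#' @return validated config list of class `seacomm_config`.
#' @export
pipeline_config <- function(table = NULL, tree = NULL, metadata = NULL,
                            preset = NULL, n_taxa = 300L,
                            n_sites_per_region = c(10L, 10L),
                            depth = NULL, n_rand = list(),
                            group = "region", seed = NULL,
                            out_dir = NULL) {
  if (is.null(seed)) stop2("a master seed is required")
  if (is.null(preset) && (is.null(table) || is.null(tree) ||
                          is.null(metadata)))
    stop2("supply either a preset or table + tree + metadata paths")
  defaults <- list(nti = 999L, bnti = 999L, rc = 999L, anosim = 999L,
                   mantel = 999L, protest = 999L, diffslope = 999L)
  unknown <- setdiff(names(n_rand), names(defaults))
  if (length(unknown)) stop2("unknown n_rand entries: ",
                             paste(unknown, collapse = ", "))
  defaults[names(n_rand)] <- lapply(n_rand, as.integer)
  if (any(unlist(defaults) < 99L))
    stop2("all randomization counts must be >= 99")
  if (!is.null(depth) && depth < 1) stop2("depth must be >= 1")
  structure(list(table = table, tree = tree, metadata = metadata,
                 preset = preset, n_taxa = as.integer(n_taxa),
                 n_sites_per_region = as.integer(n_sites_per_region),
                 depth = depth, n_rand = defaults, group = group,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "seacomm_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop2("[stage ", name, "] ", conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Stages: load-or-simulate, align, rarefy, alpha diversity, beta
#' structure (Bray-Curtis, PCoA, ANOSIM, environment PCA, Mantel),
#' distance decay (overall, per group, slope difference), and assembly
#' processes.  Given the same config and seed the bundle is
#' byte-identical across runs.
#'
#' @param config a `seacomm_config` (see [pipeline_config()]).
#' @return list of class `seacomm_bundle` with every stage's result and
#'   a `provenance` block; when `out_dir` is set, tab-delimited outputs
#'   plus a manifest are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "seacomm_config"))
  seeds <- derive_seeds(config$seed, 8L,
                        c("simulate", "rarefy", "alpha", "anosim",
                          "mantel", "decay", "diffslope", "assembly"))

  dat <- stage("load", {
    if (!is.null(config$preset)) {
      ds <- scenario_preset(config$preset, seed = seeds[["simulate"]],
                            n_taxa = config$n_taxa,
                            n_sites_per_region = config$n_sites_per_region)
      list(counts = ds$counts, tree = ds$tree, meta = ds$meta,
           regime = ds$true_regime)
    } else {
      list(counts = read_otu_table(config$table),
           tree = read_tree(config$tree),
           meta = read_metadata(config$metadata),
           regime = NA_character_)
    }
  })
  al <- stage("align", align_inputs(dat$counts, dat$tree, dat$meta))
  depth <- config$depth %||% min(rowSums(al$counts))
  counts <- stage("rarefy",
                  rarefy_table(al$counts, depth, seed = seeds[["rarefy"]]))
  if (nrow(counts) < nrow(al$counts)) {
    keep <- rownames(counts)
    al$meta <- al$meta[al$meta$sample_id %in% keep, , drop = FALSE]
  }
  groups <- setNames(al$meta$region, al$meta$sample_id)
  if (!is.null(config$group) && config$group != "region")
    groups <- setNames(as.character(al$meta[[config$group]]),
                       al$meta$sample_id)

  alpha <- stage("alpha",
                 alpha_diversity(counts, al$tree,
                                 n_rand = config$n_rand$nti,
                                 seed = seeds[["alpha"]]))

  bc <- stage("beta", bray_curtis(counts))
  ord <- pcoa(bc)
  anosim_res <- anosim(bc, groups[rownames(bc)],
                       n_perm = config$n_rand$anosim,
                       seed = seeds[["anosim"]])
  env_vars <- attr(al$meta, "env_vars")
  env_ord <- if (length(env_vars) >= 2) env_pca(al$meta[env_vars]) else NULL

  geo <- stage("decay", haversine_matrix(al$meta))
  geo <- geo[rownames(bc), rownames(bc)]
  env_dist <- if (length(env_vars)) {
    ed <- as.matrix(dist(scale(as.matrix(al$meta[env_vars]))))
    dimnames(ed) <- list(al$meta$sample_id, al$meta$sample_id)
    ed[rownames(bc), rownames(bc)]
  } else NULL
  mantel_geo <- mantel(bc, geo, n_perm = config$n_rand$mantel,
                       seed = seeds[["mantel"]])
  mantel_env <- if (!is.null(env_dist)) {
    mantel(bc, env_dist, n_perm = config$n_rand$mantel,
           seed = seeds[["mantel"]])
  } else NULL

  decay_all <- fit_distance_decay(bc, geo, n_perm = config$n_rand$mantel,
                                  seed = seeds[["decay"]])
  decay_groups <- list()
  glev <- sort(unique(groups))
  for (g in glev) {
    ids <- names(groups)[groups == g]
    ids <- intersect(rownames(bc), ids)
    if (length(ids) >= 3)
      decay_groups[[g]] <- fit_distance_decay(
        bc[ids, ids], geo[ids, ids], n_perm = config$n_rand$mantel,
        seed = seeds[["decay"]])
  }
  diffslope_res <- if (length(glev) == 2 &&
                       all(glev %in% names(decay_groups))) {
    ids1 <- intersect(rownames(bc), names(groups)[groups == glev[1]])
    ids2 <- intersect(rownames(bc), names(groups)[groups == glev[2]])
    diff_slope_test(
      lower_vec(geo[ids1, ids1]), lower_vec(1 - bc[ids1, ids1]),
      lower_vec(geo[ids2, ids2]), lower_vec(1 - bc[ids2, ids2]),
      n_perm = config$n_rand$diffslope, seed = seeds[["diffslope"]])
  } else NULL

  asm <- stage("assembly",
               assembly_processes(counts, al$tree, groups = groups,
                                  n_rand = config$n_rand$bnti,
                                  seed = seeds[["assembly"]]))

  bundle <- structure(list(
    counts = counts, tree = al$tree, meta = al$meta,
    depth = depth, alpha = alpha, bray_curtis = bc, pcoa = ord,
    anosim = anosim_res, env_pca = env_ord, geo = geo,
    mantel_geo = mantel_geo, mantel_env = mantel_env,
    decay = c(list(all = decay_all), decay_groups),
    diff_slope = diffslope_res, assembly = asm,
    provenance = list(version = as.character(packageVersion("seacomm")),
                      seed = config$seed, stage_seeds = as.list(seeds),
                      depth = depth, n_rand = config$n_rand,
                      preset = config$preset, regime = dat$regime,
                      group = config$group)),
    class = "seacomm_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- bundle$provenance$seed
  files <- character(0)
  put <- function(x, name, ...) {
    path <- file.path(dir, name)
    write_tsv(x, path, seed = seed, ...)
    files <<- c(files, name)
  }
  put(bundle$alpha, "alpha.tsv")
  put(bundle$bray_curtis, "bray_curtis.tsv", row_label = "sample_id")
  coords <- data.frame(sample_id = rownames(bundle$pcoa$coordinates),
                       bundle$pcoa$coordinates, check.names = FALSE)
  put(coords, "pcoa.tsv")
  tests <- data.frame(
    test = c("anosim", "mantel_geo",
             if (!is.null(bundle$mantel_env)) "mantel_env",
             if (!is.null(bundle$diff_slope)) "diff_slope"),
    statistic = c(bundle$anosim$statistic, bundle$mantel_geo$statistic,
                  if (!is.null(bundle$mantel_env))
                    bundle$mantel_env$statistic,
                  if (!is.null(bundle$diff_slope))
                    bundle$diff_slope$statistic),
    p_value = c(bundle$anosim$p_value, bundle$mantel_geo$p_value,
                if (!is.null(bundle$mantel_env))
                  bundle$mantel_env$p_value,
                if (!is.null(bundle$diff_slope))
                  bundle$diff_slope$p_value))
  put(tests, "tests.tsv")
  decay_tab <- do.call(rbind, lapply(names(bundle$decay), function(g) {
    f <- bundle$decay[[g]]
    data.frame(scope = g, slope = f$slope, intercept = f$intercept,
               r2_adj = f$r2_adj, p_value = f$p_value,
               n_pairs = f$n_pairs)
  }))
  put(decay_tab, "decay.tsv")
  put(bundle$assembly$bnti$beta_nti, "bnti.tsv", row_label = "sample_id")
  put(bundle$assembly$rc$rc_bray, "rcbray.tsv", row_label = "sample_id")
  put(bundle$assembly$pairs, "pairs.tsv")
  put(bundle$assembly$fractions, "fractions.tsv")
  prov <- bundle$provenance
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  writeLines(c(provenance_header(seed = seed),
               c(files, "provenance.yaml")),
             file.path(dir, "MANIFEST"))
  invisible(dir)
}

#' Summarize a results bundle
#'
#' Prints (and returns invisibly) a human-readable summary; with
#' `plots = TRUE` also writes a four-panel PDF (alpha boxplots, PCoA,
#' decay lines, process fractions) next to the bundle or to `plot_file`.
#'
#' @param bundle a `seacomm_bundle` from [run_pipeline()].
#' @param plots write the figure panels.
#' @param plot_file PDF path (required when `plots = TRUE`).
#' @return the summary lines, invisibly.
#' @export
report <- function(bundle, plots = FALSE, plot_file = NULL) {
  stopifnot(inherits(bundle, "seacomm_bundle"))
  needed <- c("alpha", "bray_curtis", "pcoa", "anosim", "decay",
              "assembly", "provenance")
  miss <- needed[vapply(needed, function(f) is.null(bundle[[f]]),
                        logical(1))]
  if (length(miss)) stop2("incomplete bundle; missing: ",
                          paste(miss, collapse = ", "))
  fr <- bundle$assembly$fractions
  all_row <- fr[fr$group == "all", , drop = FALSE]
  fr_vals <- unlist(all_row[.process_levels])
  modal <- .process_levels[which.max(fr_vals)]
  lines <- c(
    paste0("seacomm ", bundle$provenance$version, " | seed ",
           bundle$provenance$seed),
    paste0("samples: ", nrow(bundle$counts), "  OTUs: ",
           ncol(bundle$counts), "  rarefaction depth: ", bundle$depth),
    paste0("alpha richness: ", min(bundle$alpha$richness), "-",
           max(bundle$alpha$richness), " (mean ",
           round(mean(bundle$alpha$richness), 1), ")"),
    paste0("ANOSIM R = ", round(bundle$anosim$statistic, 3), ", p = ",
           signif(bundle$anosim$p_value, 3)),
    paste0("distance-decay slope (all) = ",
           signif(bundle$decay$all$slope, 3), " per km, p = ",
           signif(bundle$decay$all$p_value, 3)),
    paste0("modal assembly process: ", modal, " (",
           round(100 * max(fr_vals), 1), "% of pairs)"))
  if (plots) {
    if (is.null(plot_file)) stop2("plot_file required when plots = TRUE")
    plot_bundle(bundle, plot_file)
    lines <- c(lines, paste0("figures: ", plot_file))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

plot_bundle <- function(bundle, path) {
  grDevices::pdf(path, width = 10, height = 8)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  groups <- factor(bundle$meta$region[
    match(bundle$alpha$sample_id, bundle$meta$sample_id)])
  graphics::boxplot(richness ~ groups, data = bundle$alpha,
                    xlab = "", ylab = "richness", main = "Alpha diversity")
  cols <- as.integer(factor(bundle$meta$region[
    match(rownames(bundle$pcoa$coordinates), bundle$meta$sample_id)]))
  graphics::plot(bundle$pcoa$coordinates[, 1:2], col = cols, pch = 19,
                 main = "PCoA (Bray-Curtis)")
  x <- lower_vec(bundle$geo)
  y <- 1 - lower_vec(bundle$bray_curtis)
  graphics::plot(x, y, pch = 20, col = "grey40",
                 xlab = "distance (km)", ylab = "similarity",
                 main = "Distance decay")
  graphics::abline(bundle$decay$all$intercept, bundle$decay$all$slope,
                   col = "red")
  fr <- bundle$assembly$fractions
  all_row <- as.numeric(fr[fr$group == "all", .process_levels])
  graphics::barplot(all_row, names.arg = abbreviate(.process_levels, 8),
                    ylab = "fraction of pairs", las = 2,
                    main = "Assembly processes")
  invisible(path)
}
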