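# Distance-decay of community similarity: great-circle distances, the
# similarity-versus-distance regression with a Mantel-style permutation
# test, and the permutation test for a difference between two decay
# slopes.

#' Great-circle (haversine) distance matrix in kilometres
#'
#' Earth is treated as a sphere of radius 6371.0 km.
#'
#' @param meta metadata data.frame with `latitude`/`longitude` in decimal
#'   degrees (see [read_metadata()]), or a two-column matrix
#'   `(latitude, longitude)`.
#' @param radius_km sphere radius.
#' @return named square distance matrix (km).
#' @export
haversine_matrix <- function(meta, radius_km = 6371.0) {
  if (is.data.frame(meta)) {
    meta <- validate_metadata(meta)
    lat <- meta$latitude
    lon <- meta$longitude
    ids <- meta$sample_id
  } else {
    lat <- meta[, 1]
    lon <- meta[, 2]
    ids <- rownames(meta) %||% paste0("s", seq_along(lat))
  }
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(phi)
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  m <- 2 * radius_km * asin(sqrt(a))
  diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  m
}

ols_slope <- function(x, y) cov(x, y) / var(x)

#' Fit a distance-decay regression
#'
#' Ordinary least squares of community similarity (default
#' `1 - dissimilarity`) on geographic distance over all sample pairs.
#' Because pairs sharing a sample are not independent, the p-value comes
#' from Mantel-style permutations of sample identities (two-sided on the
#' slope), not from the OLS t-test.
#'
#' @param community_d community dissimilarity matrix.
#' @param geo_d geographic distance matrix (km), same ids and order.
#' @param n_perm number of sample-identity permutations.
#' @param seed RNG seed.
#' @param response regress similarity (`1 - dissimilarity`, default) or
#'   the raw dissimilarity on distance; the slope flips sign between the
#'   two.
#' @return list of class `seacomm_decay`: `slope` (per km), `intercept`,
#'   `r2_adj`, `p_value`, `n_pairs`, `response`.
#' @export
fit_distance_decay <- function(community_d, geo_d, n_perm = 999L,
                               seed = NULL,
                               response = c("similarity", "dissimilarity")) {
  response <- match.arg(response)
  cm <- as_dist_matrix(community_d, "community matrix")
  gm <- as_dist_matrix(geo_d, "geographic matrix")
  if (!identical(rownames(cm), rownames(gm)))
    stop2("community and geographic matrices must share identifiers ",
          "in the same order")
  n <- nrow(cm)
  if (n < 3L) stop2("need at least 3 samples")
  ym <- if (response == "similarity") 1 - cm else cm
  x <- lower_vec(gm)
  y <- lower_vec(ym)
  if (var(x) == 0) stop2("all geographic distances identical")
  slope_obs <- ols_slope(x, y)
  intercept <- mean(y) - slope_obs * mean(x)
  np <- length(x)
  rss <- sum((y - intercept - slope_obs * x)^2)
  tss <- sum((y - mean(y))^2)
  r2_adj <- if (tss > 0) {
    1 - (rss / tss) * (np - 1) / (np - 2)
  } else NA_real_
  null_slopes <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n)
    ols_slope(x, lower_vec(ym[idx, idx, drop = FALSE]))
  }, numeric(1)))
  p <- perm_pvalue(sum(abs(null_slopes) >= abs(slope_obs) - 1e-15), n_perm)
  structure(list(slope = slope_obs, intercept = intercept,
                 r2_adj = r2_adj, p_value = p,
                 n_pairs = length(x), n_permutations = n_perm,
                 response = response), class = "seacomm_decay")
}

#' Permutation test for a difference between two regression slopes
#'
#' The statistic is `slope_A - slope_B`.  The null exchanges (x, y)
#' pairs at random between the two sets (preserving set sizes) and
#' recomputes the difference; the p-value is two-sided.  The pooled
#' pair list is put in a canonical order before permuting, so swapping
#' the two inputs flips the sign of the statistic but leaves the
#' p-value unchanged for a given seed (exactly so for equal set sizes).
#'
#' @param dist_a,sim_a distances and similarities of the first set.
#' @param dist_b,sim_b distances and similarities of the second set.
#' @param n_perm number of exchanges.
#' @param seed RNG seed.
#' @return `seacomm_permtest` list with `statistic` (slope difference).
#' @export
diff_slope_test <- function(dist_a, sim_a, dist_b, sim_b,
                            n_perm = 1000L, seed = NULL) {
  if (length(dist_a) != length(sim_a) || length(dist_b) != length(sim_b))
    stop2("distance and similarity vectors must have equal length")
  na <- length(dist_a)
  nb <- length(dist_b)
  if (na < 3L || nb < 3L) stop2("each set needs at least 3 pairs")
  d_obs <- ols_slope(dist_a, sim_a) - ols_slope(dist_b, sim_b)
  px <- c(dist_a, dist_b)
  py <- c(sim_a, sim_b)
  ord <- order(px, py)
  px <- px[ord]
  py <- py[ord]
  null_d <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    take <- sample.int(na + nb, na)
    ols_slope(px[take], py[take]) - ols_slope(px[-take], py[-take])
  }, numeric(1)))
  p <- perm_pvalue(sum(abs(null_d) >= abs(d_obs) - 1e-15), n_perm)
  structure(list(statistic = d_obs, p_value = p, n_permutations = n_perm,
                 statistic_name = "slope difference"),
            class = "seacomm_permtest")
}

#' @export
print.seacomm_decay <- function(x, ...) {
  cat("distance-decay fit (", x$response, " ~ km)\n", sep = "")
  cat("  slope =", format(x$slope, digits = 4),
      " intercept =", format(x$intercept, digits = 4), "\n")
  cat("  adj. R2 =", format(x$r2_adj, digits = 3),
      " p =", format(x$p_value, digits = 4),
      " (", x$n_pairs, "pairs )\n")
  invisible(x)
}
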