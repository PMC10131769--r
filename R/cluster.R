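# Trend clustering: k-means with correlation similarity on country-level
# total volume series. Each series is z-standardized, which makes squared
# Euclidean distance a monotone transform of one minus the Pearson
# correlation (d^2 = 2 (T - 1) (1 - r)), so Lloyd k-means on standardized
# series is k-means under correlation similarity.

zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  if (any(s == 0))
    stop("zero-variance series for: ",
         paste(rownames(m)[s == 0], collapse = ", "))
  (m - mu) / s
}

# k-means++ initial centers (D^2 sampling)
kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((m - m[rep(centers[1], n), , drop = FALSE])^2)
  if (k > 1) for (j in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j] <- sample.int(n, 1, prob = p)
    nd <- rowSums((m - m[rep(centers[j], n), , drop = FALSE])^2)
    d2 <- pmin(d2, nd)
  }
  m[centers, , drop = FALSE]
}

#' Cluster countries by the shape of their total volume series
#'
#' Z-standardizes each country's series, then runs Lloyd k-means with
#' k-means++ seeding, keeping the best of `n_restarts` restarts by
#' within-cluster sum of squares. Deterministic under `(seed, n_restarts)`.
#'
#' @param series numeric matrix `country x month` (rownames = countries).
#' @param k number of clusters, `2 <= ... <= nrow(series)` (k = 1 allowed).
#' @param seed integer seed.
#' @param n_restarts number of seeded restarts.
#' @return object of class `trend_clusters`: `k`, `assignment` (named integer
#'   vector, labels 1..k), `centroids` (k x month matrix of standardized
#'   shapes), `sizes`, `min_cluster_size`, `inertia`, `seed`, `n_restarts`.
#' @export
cluster_series <- function(series, k, seed = 1L, n_restarts = 20L) {
  if (k < 1 || k > nrow(series)) stop("k must be in 1..nrow(series)")
  z <- zscore_rows(series)
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- kmeanspp_init(z, k)
    km <- suppressWarnings(
      stats::kmeans(z, centers = init, iter.max = 100L, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  assignment <- stats::setNames(best$cluster, rownames(series))
  sizes <- tabulate(best$cluster, k)
  structure(list(k = k, assignment = assignment, centroids = best$centers,
                 sizes = sizes, min_cluster_size = min(sizes),
                 inertia = best$tot.withinss, seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts), selection_failed = FALSE),
            class = "trend_clusters")
}

#' @export
print.trend_clusters <- function(x, ...) {
  cat(sprintf("Trend clustering: k = %d, sizes [%s], inertia %.3f\n",
              x$k, paste(x$sizes, collapse = ", "), x$inertia))
  if (isTRUE(x$selection_failed))
    cat("  note: no k satisfied the minimum cluster size; best fallback shown\n")
  invisible(x)
}

#' Select the number of clusters by the minimum-size rule
#'
#' Returns the clustering for the smallest `k` in `[k_min, k_max]` whose
#' smallest cluster has at least `min_size` countries. If no `k` qualifies,
#' the `k` with the largest minimum cluster size is returned with
#' `selection_failed = TRUE`.
#'
#' @param series numeric matrix `country x month`.
#' @param k_min,k_max search range (defaults 2..10).
#' @param min_size minimum admissible cluster size (default 5).
#' @param seed,n_restarts passed to [cluster_series()].
#' @return a `trend_clusters` object.
#' @export
select_k <- function(series, k_min = 2L, k_max = 10L, min_size = 5L,
                     seed = 1L, n_restarts = 20L) {
  if (k_max < k_min) stop("k_max < k_min")
  if (k_min < 2L) stop("k_min must be >= 2")
  k_max <- min(k_max, nrow(series))
  fits <- list()
  for (k in k_min:k_max) {
    fit <- cluster_series(series, k, seed = seed, n_restarts = n_restarts)
    if (fit$min_cluster_size >= min_size) return(fit)
    fits[[length(fits) + 1L]] <- fit
  }
  best <- fits[[which.max(vapply(fits, `[[`, 0, "min_cluster_size"))]]
  best$selection_failed <- TRUE
  best
}
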