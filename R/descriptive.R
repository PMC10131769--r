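# Descriptive correlation analyses: within-country temporal stability of
# theme volumes, cross-country similarity, and correlation with an external
# per-country series.

spearman_pair <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(value = NA_real_, n = n, p_value = NA_real_, defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(value = unname(ct$estimate), n = n,
       p_value = if (n >= 3) ct$p.value else NA_real_, defined = TRUE)
}

#' Temporal stability of theme volumes
#'
#' Per country, the Spearman correlation across themes between the annual
#' volumes of two years, plus the unweighted cross-country average of the
#' coefficients. Countries with incomplete years or fewer than 3 themes
#' observed in both years are excluded with a warning.
#'
#' @param annual data frame from [annual_volume()].
#' @param year_a,year_b the two years to compare.
#' @param fisher_z average coefficients on the Fisher-z scale instead of the
#'   plain mean.
#' @return list with `per_country` (data frame `country, rho, n, p_value`) and
#'   `average`.
#' @export
temporal_stability <- function(annual, year_a, year_b, fisher_z = FALSE) {
  a <- annual[annual$year == year_a & annual$complete, , drop = FALSE]
  b <- annual[annual$year == year_b & annual$complete, , drop = FALSE]
  res <- lapply(split(a, a$country), function(da) {
    db <- b[b$country == da$country[1], , drop = FALSE]
    m <- match(da$theme, db$theme)
    ok <- !is.na(m)
    if (sum(ok) < 3) return(NULL)
    s <- spearman_pair(da$volume[ok], db$volume[m[ok]])
    data.frame(country = da$country[1], rho = s$value, n = s$n,
               p_value = s$p_value, stringsAsFactors = FALSE)
  })
  dropped <- names(res)[vapply(res, is.null, logical(1))]
  excluded <- union(dropped, setdiff(unique(annual$country), a$country))
  if (length(excluded))
    warning("countries excluded (incomplete years or <3 themes): ",
            paste(excluded, collapse = ", "))
  per <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(per) <- NULL
  rho <- per$rho[!is.na(per$rho)]
  avg <- if (fisher_z) tanh(mean(atanh(pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12))))
         else mean(rho)
  list(per_country = per, average = avg)
}

#' Cross-country similarity of theme volumes
#'
#' Pairwise Spearman correlation (across themes) between the annual volume
#' vectors of every pair of countries in one year, with the average over the
#' strictly-upper-triangle entries. Countries with a zero-variance theme
#' vector are excluded with a warning.
#'
#' @param annual data frame from [annual_volume()].
#' @param year year to compare.
#' @return list with `matrix` (symmetric, unit diagonal), `average`, and
#'   `excluded`.
#' @export
cross_country_similarity <- function(annual, year) {
  a <- annual[annual$year == year & annual$complete, , drop = FALSE]
  if (nrow(a) == 0L) stop("year not present (or no complete country-years): ", year)
  themes <- sort(unique(a$theme))
  countries <- sort(unique(a$country))
  v <- matrix(NA_real_, length(countries), length(themes),
              dimnames = list(countries, themes))
  v[cbind(match(a$country, countries), match(a$theme, themes))] <- a$volume
  variances <- apply(v, 1, stats::sd, na.rm = TRUE)
  keep <- !is.na(variances) & variances > 0
  if (any(!keep))
    warning("countries with zero-variance theme vector excluded: ",
            paste(countries[!keep], collapse = ", "))
  v <- v[keep, , drop = FALSE]
  cc <- stats::cor(t(v), method = "spearman", use = "pairwise.complete.obs")
  diag(cc) <- 1
  ut <- cc[upper.tri(cc)]
  list(matrix = cc, average = mean(ut, na.rm = TRUE),
       excluded = countries[!keep])
}

#' Pearson correlation with an external per-country series
#'
#' Used e.g. to relate the leading theme's volume to externally reported
#' anxiety incidence. The p-value is two-sided from the t transform with
#' n - 2 degrees of freedom.
#'
#' @param series_a,series_b paired numeric vectors (same countries, same
#'   order).
#' @return list `value, n, p_value, method, defined`.
#' @export
external_correlation <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) stop("series lengths differ")
  ok <- is.finite(series_a) & is.finite(series_b)
  x <- series_a[ok]; y <- series_b[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(value = NA_real_, n = length(x), p_value = NA_real_,
                method = "pearson", defined = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(value = unname(ct$estimate), n = length(x), p_value = ct$p.value,
       method = "pearson", defined = TRUE)
}
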