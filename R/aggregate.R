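# Panel aggregation: annual volumes, domain totals, top themes, and total
# monthly volume series.

#' Annual theme volumes
#'
#' Sums monthly volumes within each calendar year. Years with missing months
#' (absent from the panel or `NA`) are flagged incomplete rather than imputed;
#' analyses that need complete series refuse flagged country-years.
#'
#' @param panel a `volume_panel`.
#' @param fun aggregator: `"sum"` (annual volume, the default) or `"mean"`
#'   (average monthly volume).
#' @return data frame `country, theme, year, volume, n_months, complete`.
#' @export
annual_volume <- function(panel, fun = c("sum", "mean")) {
  stopifnot(inherits(panel, "volume_panel"))
  fun <- match.arg(fun)
  agg <- if (fun == "sum") function(x) sum(x, na.rm = TRUE)
         else function(x) mean(x, na.rm = TRUE)
  d <- as.data.frame(panel)
  months_per_year <- table(factor(panel$months$year))
  res <- stats::aggregate(cbind(volume = d$volume) ~ country + theme + year, d,
                          agg, na.action = stats::na.pass)
  nm <- stats::aggregate(cbind(n = !is.na(d$volume)) ~ country + theme + year,
                         d, sum)
  res$n_months <- nm$n[match(paste(res$country, res$theme, res$year),
                             paste(nm$country, nm$theme, nm$year))]
  res$complete <- res$n_months == 12L &
    as.integer(months_per_year[as.character(res$year)]) == 12L
  res$volume[res$n_months == 0L] <- NA_real_
  res <- res[order(res$country, res$theme, res$year), ]
  rownames(res) <- NULL
  res
}

#' Domain volumes and the leading domain per country
#'
#' Sums volumes over the themes of each domain within a period and reports the
#' highest-volume domain per country. Ties are broken in the fixed order
#' personal > familial > societal and flagged.
#'
#' @param panel a `volume_panel`.
#' @param catalogue data frame `theme, domain` covering every panel theme.
#' @param years integer vector of years to include (default: all panel years).
#' @return list with `totals` (data frame `country, domain, volume`) and
#'   `leading` (data frame `country, domain, tie`).
#' @export
domain_volume <- function(panel, catalogue, years = unique(panel$months$year)) {
  stopifnot(inherits(panel, "volume_panel"))
  missing_themes <- setdiff(panel$themes, catalogue$theme)
  if (length(missing_themes))
    stop("themes missing from catalogue: ", paste(missing_themes, collapse = ", "))
  d <- as.data.frame(panel)
  d <- d[d$year %in% years, , drop = FALSE]
  d$domain <- catalogue$domain[match(d$theme, catalogue$theme)]
  dom_order <- c("personal", "familial", "societal")
  totals <- stats::aggregate(volume ~ country + domain, d, sum)
  grid <- expand.grid(country = panel$countries, domain = dom_order,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$volume <- totals$volume[match(paste(grid$country, grid$domain),
                                     paste(totals$country, totals$domain))]
  grid$volume[is.na(grid$volume)] <- 0
  leading <- do.call(rbind, lapply(split(grid, grid$country), function(g) {
    g <- g[match(dom_order, g$domain), ]
    best <- which.max(g$volume)  # first max wins: personal > familial > societal
    data.frame(country = g$country[1], domain = dom_order[best],
               tie = sum(g$volume == g$volume[best]) > 1,
               stringsAsFactors = FALSE)
  }))
  rownames(leading) <- NULL
  list(totals = grid[order(grid$country, match(grid$domain, dom_order)), ],
       leading = leading)
}

#' Most searched themes for a country-year
#'
#' @param panel a `volume_panel`.
#' @param country,year the country-year to rank.
#' @param m number of themes to return; ties broken lexicographically.
#' @return character vector of `m` themes, volume-descending.
#' @export
top_themes <- function(panel, country, year, m) {
  stopifnot(inherits(panel, "volume_panel"))
  if (m > length(panel$themes))
    stop(sprintf("m = %d exceeds the %d themes", m, length(panel$themes)))
  ci <- match(country, panel$countries)
  if (is.na(ci)) stop("unknown country: ", country)
  sel <- panel$months$year == year
  if (!any(sel)) stop("year not in panel: ", year)
  ann <- apply(panel$volume[ci, , sel, drop = FALSE], 2, sum)
  o <- order(-ann, panel$themes)
  panel$themes[o][seq_len(m)]
}

#' Total monthly volume per country
#'
#' Sums volumes over all themes, giving the country-level series that trend
#' clustering consumes.
#'
#' @param panel a `volume_panel`.
#' @return numeric matrix `country x month` with month keys as column names.
#' @export
total_volume_series <- function(panel) {
  stopifnot(inherits(panel, "volume_panel"))
  if (length(panel$countries) == 0L) stop("empty panel")
  m <- apply(panel$volume, c(1, 3), sum)
  dimnames(m) <- list(panel$countries, month_key(panel$months))
  m
}
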