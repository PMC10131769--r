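# Volume panel container: country x theme x month array of nonnegative search
# volumes, the unit every downstream analysis consumes.

#' Construct a volume panel
#'
#' A `volume_panel` holds a 3-way array of nonnegative search volumes indexed
#' by country, theme and calendar month. Missing observations are `NA`
#' (never silently zero-filled).
#'
#' @param volume numeric array `country x theme x month`, entries `>= 0` or `NA`.
#' @param countries character vector of country identifiers (rows of `volume`).
#' @param themes character vector of theme identifiers.
#' @param months data frame with integer columns `year` and `month` (1-based),
#'   strictly increasing in calendar order.
#' @return An object of class `volume_panel` with elements `volume`,
#'   `countries`, `themes`, `months`.
#' @examples
#' p <- volume_panel(array(1, c(2, 3, 4)), c("A", "B"), c("t1", "t2", "t3"),
#'                   month_seq(2019, 1, 2019, 4))
#' dim(p$volume)
#' @export
volume_panel <- function(volume, countries, themes, months) {
  volume <- as.array(volume)
  if (length(dim(volume)) != 3L)
    stop("`volume` must be a 3-way array (country x theme x month)")
  countries <- as.character(countries)
  themes <- as.character(themes)
  months <- validate_months(months)
  if (dim(volume)[1] != length(countries) ||
      dim(volume)[2] != length(themes) ||
      dim(volume)[3] != nrow(months))
    stop("array dimensions do not match countries/themes/months")
  if (any(volume < 0, na.rm = TRUE))
    stop("volumes must be nonnegative")
  dimnames(volume) <- list(countries, themes, month_key(months))
  structure(list(volume = volume, countries = countries, themes = themes,
                 months = months),
            class = "volume_panel")
}

#' Monthly calendar sequence
#'
#' @param year_from,month_from,year_to,month_to inclusive 1-based bounds.
#' @return data frame with columns `year`, `month`, one row per month.
#' @export
month_seq <- function(year_from, month_from, year_to, month_to) {
  a <- year_from * 12L + (month_from - 1L)
  b <- year_to * 12L + (month_to - 1L)
  if (b < a) stop("month range is empty")
  idx <- a:b
  data.frame(year = idx %/% 12L, month = idx %% 12L + 1L)
}

month_key <- function(months) sprintf("%04d-%02d", months$year, months$month)

validate_months <- function(months) {
  months <- as.data.frame(months)
  if (!all(c("year", "month") %in% names(months)))
    stop("`months` needs `year` and `month` columns")
  if (nrow(months) == 0L) stop("`months` is empty")
  if (any(months$month < 1L | months$month > 12L))
    stop("months must be 1..12")
  idx <- months$year * 12L + months$month
  if (any(diff(idx) <= 0)) stop("months must be strictly increasing")
  months[c("year", "month")]
}

#' @export
print.volume_panel <- function(x, ...) {
  cat(sprintf("Volume panel: %d countries x %d themes x %d months (%s .. %s)\n",
              length(x$countries), length(x$themes), nrow(x$months),
              month_key(x$months)[1], month_key(x$months)[nrow(x$months)]))
  if (anyNA(x$volume))
    cat(sprintf("  %d missing cells flagged NA\n", sum(is.na(x$volume))))
  invisible(x)
}

#' @export
as.data.frame.volume_panel <- function(x, ...) {
  g <- expand.grid(country = x$countries, theme = x$themes,
                   mi = seq_len(nrow(x$months)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(country = g$country, theme = g$theme,
             year = x$months$year[g$mi], month = x$months$month[g$mi],
             volume = as.vector(x$volume),
             stringsAsFactors = FALSE)
}

#' Read / write a volume panel as long-format CSV
#'
#' Columns: `country, theme, year, month, volume`. Cells absent from the file
#' become `NA` in the array.
#'
#' @param path CSV file path.
#' @rdname panel_io
#' @export
read_volume_panel <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "theme", "year", "month", "volume")
  if (!all(need %in% names(d))) stop("panel CSV must have columns: ",
                                     paste(need, collapse = ", "))
  countries <- sort(unique(d$country))
  themes <- sort(unique(d$theme))
  mk <- sprintf("%04d-%02d", d$year, d$month)
  umk <- sort(unique(mk))
  months <- data.frame(year = as.integer(substr(umk, 1, 4)),
                       month = as.integer(substr(umk, 6, 7)))
  vol <- array(NA_real_, c(length(countries), length(themes), length(umk)))
  vol[cbind(match(d$country, countries), match(d$theme, themes),
            match(mk, umk))] <- d$volume
  volume_panel(vol, countries, themes, months)
}

#' @param panel a `volume_panel`.
#' @rdname panel_io
#' @export
write_volume_panel <- function(panel, path) {
  d <- as.data.frame(panel)
  d <- d[!is.na(d$volume), ]
  write_csv_stable(d, path)
}

# Deterministic CSV writer: fixed column order, no row names, 15 significant
# digits so identical inputs give byte-identical files.
write_csv_stable <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1)) & !vapply(d, is.integer, logical(1))
  d[num] <- lapply(d[num], function(x) sprintf("%.15g", x))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
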