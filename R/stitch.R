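# Anchor stitching: recover a common volume scale from windows that were each
# independently normalized to 0-100 (the trends-service convention), by
# chaining ratios of an anchor series shared between consecutive windows.

#' Normalize a volume table into overlapping 0-100 windows
#'
#' Splits the month range into windows, each scaled so that its maximum value
#' is 100, mimicking how a trends service returns data. Useful to exercise
#' and validate [stitch_windows()] round trips.
#'
#' @param truth data frame `term, year, month, volume` on a single true scale.
#' @param window_months window length in months.
#' @param overlap number of months shared by consecutive windows (>= 1).
#' @return list of data frames `term, year, month, value`, each max-100.
#' @export
make_normalized_windows <- function(truth, window_months, overlap = 1L) {
  if (overlap < 1L || window_months <= overlap)
    stop("need 1 <= overlap < window_months")
  key <- truth$year * 12L + truth$month
  uk <- sort(unique(key))
  starts <- seq(1L, length(uk), by = window_months - overlap)
  starts <- starts[starts <= length(uk) - overlap |
                   starts == 1L]
  windows <- list()
  for (s in starts) {
    idx <- uk[s:min(s + window_months - 1L, length(uk))]
    w <- truth[key %in% idx, , drop = FALSE]
    if (nrow(w) == 0L) next
    w$value <- w$volume * 100 / max(w$volume)
    w$volume <- NULL
    windows[[length(windows) + 1L]] <- w[order(w$term, w$year, w$month), ]
    if (max(w$year * 12L + w$month) >= max(uk)) break
  }
  windows
}

#' Stitch normalized windows onto a common scale
#'
#' Consecutive windows must overlap in time and share at least one anchor term
#' with strictly positive values in the overlap. Window `i+1` is rescaled by
#' the ratio of the anchor's values in the overlapping months (geometric mean
#' over overlap months, identical for consistent data), chained so that the
#' first window's scale is the reference. Values for months present in
#' several windows are averaged after rescaling.
#'
#' @param windows ordered list of data frames `term, year, month, value`,
#'   each scaled to max 100.
#' @param anchors optional character vector of terms eligible as anchors;
#'   defaults to every term.
#' @return data frame `term, year, month, volume` on the first window's scale.
#' @export
stitch_windows <- function(windows, anchors = NULL) {
  if (length(windows) == 0L) stop("no windows supplied")
  for (w in windows)
    if (!all(c("term", "year", "month", "value") %in% names(w)))
      stop("each window needs columns term, year, month, value")
  scale <- rep(1, length(windows))
  for (i in seq_along(windows)[-1]) {
    a <- windows[[i - 1]]; b <- windows[[i]]
    akey <- paste(a$term, a$year, a$month)
    bkey <- paste(b$term, b$year, b$month)
    shared <- intersect(akey, bkey)
    if (!is.null(anchors)) {
      tms <- vapply(strsplit(shared, " "), `[`, "", 1)
      shared <- shared[tms %in% anchors]
    }
    va <- a$value[match(shared, akey)]
    vb <- b$value[match(shared, bkey)]
    ok <- va > 0 & vb > 0
    if (length(shared) == 0L || !any(ok))
      stop(sprintf("windows %d and %d share no positive anchor observation",
                   i - 1L, i))
    ratio <- exp(mean(log(va[ok] / vb[ok])))
    scale[i] <- scale[i - 1] * ratio
  }
  long <- do.call(rbind, lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    data.frame(term = w$term, year = w$year, month = w$month,
               volume = w$value * scale[i], stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(volume ~ term + year + month, long, mean)
  agg <- agg[order(agg$term, agg$year, agg$month), ]
  rownames(agg) <- NULL
  agg
}
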