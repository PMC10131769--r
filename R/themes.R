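# Theme identification from query logs: context-keyword counting, correlation
# scoring, top-k selection, topic mapping, and inter-annotator agreement.

#' The anxiety context-keyword lexicon
#'
#' The default lexicon holds the ten anxiety-signalling phrases used to mark a
#' query as an in-context mention of a candidate term.
#'
#' @param keywords character vector of context phrases; must be nonempty and
#'   unique after case-folding.
#' @return character vector of class `anxiety_lexicon`.
#' @examples
#' anxiety_lexicon()
#' @export
anxiety_lexicon <- function(keywords = c("anxious about", "worried about",
                                         "nervous", "dread", "panic",
                                         "bothered by", "concerned",
                                         "distressed", "frightened",
                                         "tormented")) {
  keywords <- as.character(keywords)
  if (length(keywords) == 0L) stop("lexicon must be nonempty")
  folded <- tolower(trimws(keywords))
  if (anyDuplicated(folded)) stop("lexicon entries must be unique after case-folding")
  structure(keywords, class = "anxiety_lexicon")
}

normalize_text <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Count in-context and out-of-context term mentions
#'
#' For each (term, country, month): `n_without_context` is the number of
#' queries whose text contains the term; `n_with_context` is the number that
#' additionally contain at least one lexicon keyword. Matching is case-folded
#' substring matching after whitespace normalization.
#'
#' @param raw_queries data frame with columns `query_text`, `country`, `year`,
#'   `month`.
#' @param lexicon an [anxiety_lexicon()].
#' @param terms nonempty character vector of candidate terms.
#' @return data frame `term, country, year, month, n_with_context,
#'   n_without_context` covering every term x observed (country, month) cell.
#' @export
count_context_mentions <- function(raw_queries, lexicon = anxiety_lexicon(), terms) {
  if (length(terms) == 0L) stop("`terms` must be nonempty")
  terms <- as.character(terms)
  if (any(!nzchar(trimws(terms)))) stop("empty term string in `terms`")
  need <- c("query_text", "country", "year", "month")
  if (!all(need %in% names(raw_queries)))
    stop("raw_queries needs columns: ", paste(need, collapse = ", "))

  cells <- unique(raw_queries[c("country", "year", "month")])
  if (nrow(raw_queries) == 0L)
    cells <- data.frame(country = "all", year = NA_integer_, month = NA_integer_)
  grid <- merge(data.frame(term = terms, stringsAsFactors = FALSE), cells)
  grid$n_with_context <- 0L
  grid$n_without_context <- 0L
  if (nrow(raw_queries) == 0L)
    return(grid[order(grid$term), , drop = FALSE])

  txt <- normalize_text(raw_queries$query_text)
  kw <- normalize_text(unclass(lexicon))
  has_kw <- Reduce(`|`, lapply(kw, function(k) grepl(k, txt, fixed = TRUE)))
  cell_id <- interaction(raw_queries$country, raw_queries$year,
                         raw_queries$month, drop = FALSE)
  grid_id <- interaction(grid$country, grid$year, grid$month, drop = FALSE)
  for (tm in terms) {
    hit <- grepl(normalize_text(tm), txt, fixed = TRUE)
    if (!any(hit)) next
    wo <- tapply(hit, cell_id, sum)
    wi <- tapply(hit & has_kw, cell_id, sum)
    rows <- grid$term == tm
    m <- match(as.character(grid_id[rows]), names(wo))
    grid$n_without_context[rows] <- ifelse(is.na(m), 0L, as.integer(wo[m]))
    grid$n_with_context[rows] <- ifelse(is.na(m), 0L, as.integer(wi[m]))
  }
  grid <- grid[order(grid$term, grid$country, grid$year, grid$month), ]
  rownames(grid) <- NULL
  grid
}

#' Score terms by context correlation
#'
#' Pools counts over countries by month, then computes for each term the
#' Spearman rank correlation between the monthly with-context and
#' without-context series, and the context fraction (total with-context
#' mentions over total without-context mentions). The correlation is flagged
#' undefined when either series has zero variance; the fraction is flagged
#' undefined when the denominator is zero.
#'
#' @param counts data frame as produced by [count_context_mentions()] or
#'   [generate_query_log()].
#' @return data frame `term, context_correlation, context_fraction,
#'   correlation_defined, fraction_defined, n_months`, one row per term.
#' @export
score_terms <- function(counts) {
  need <- c("term", "year", "month", "n_with_context", "n_without_context")
  if (!all(need %in% names(counts)))
    stop("counts needs columns: ", paste(need, collapse = ", "))
  res <- lapply(split(counts, counts$term), function(d) {
    key <- d$year * 12L + d$month
    wi <- tapply(d$n_with_context, key, sum)
    wo <- tapply(d$n_without_context, key, sum)
    o <- order(as.integer(names(wi)))
    wi <- as.numeric(wi[o]); wo <- as.numeric(wo[o])
    defined <- length(wi) >= 2 && stats::sd(wi) > 0 && stats::sd(wo) > 0
    rho <- if (defined) stats::cor(wi, wo, method = "spearman") else NA_real_
    fdef <- sum(wo) > 0
    data.frame(term = d$term[1],
               context_correlation = rho,
               context_fraction = if (fdef) sum(wi) / sum(wo) else NA_real_,
               correlation_defined = defined, fraction_defined = fdef,
               n_months = length(wi), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select the top-k terms by context correlation
#'
#' Terms with undefined correlation are excluded before selection. Ties are
#' broken by higher context fraction, then lexicographic term order, so the
#' result is deterministic.
#'
#' @param scores data frame from [score_terms()].
#' @param k number of terms to keep.
#' @return character vector of `k` terms, correlation-descending.
#' @export
select_top_terms <- function(scores, k) {
  eligible <- scores[scores$correlation_defined, , drop = FALSE]
  if (k > nrow(eligible))
    stop(sprintf("k = %d exceeds the %d terms with defined correlation",
                 k, nrow(eligible)))
  frac <- ifelse(is.na(eligible$context_fraction), -Inf, eligible$context_fraction)
  o <- order(-eligible$context_correlation, -frac, eligible$term)
  eligible$term[o][seq_len(k)]
}

#' Partition selected terms by a topic lookup
#'
#' Emulates mapping search terms to language-independent trend topics via a
#' user-supplied lookup table (no live service is queried).
#'
#' @param selected character vector of terms, in selection order.
#' @param gtt_lookup named character vector or list mapping term to topic id;
#'   terms absent from it are unmapped.
#' @return list with `mapped` (data frame `term, topic` preserving selection
#'   order) and `unmapped` (character vector).
#' @export
map_to_gtt <- function(selected, gtt_lookup) {
  gtt_lookup <- unlist(gtt_lookup)
  hit <- selected %in% names(gtt_lookup)
  list(mapped = data.frame(term = selected[hit],
                           topic = unname(gtt_lookup[selected[hit]]),
                           stringsAsFactors = FALSE),
       unmapped = selected[!hit])
}

#' Cohen's kappa for two annotators
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with `p_e` computed
#' from each annotator's marginal label frequencies. Undefined (flagged) when
#' the expected agreement is 1, i.e. both annotators use a single identical
#' label throughout.
#'
#' @param pairs data frame with columns `label_a`, `label_b` (one row per
#'   annotated item).
#' @return list with `kappa`, `p_observed`, `p_expected`, `defined`, `n`.
#' @export
cohen_kappa <- function(pairs) {
  if (!all(c("label_a", "label_b") %in% names(pairs)))
    stop("pairs needs columns label_a, label_b")
  n <- nrow(pairs)
  if (n == 0L) stop("no annotation pairs")
  a <- as.character(pairs$label_a); b <- as.character(pairs$label_b)
  cats <- union(a, b)
  pa <- table(factor(a, cats)) / n
  pb <- table(factor(b, cats)) / n
  p_o <- mean(a == b)
  p_e <- sum(pa * pb)
  defined <- p_e < 1
  list(kappa = if (defined) (p_o - p_e) / (1 - p_e) else NA_real_,
       p_observed = p_o, p_expected = unname(p_e), defined = defined, n = n)
}
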