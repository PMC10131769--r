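# Rank-based association of volumes, cluster membership, and effect labels
# with country-level attributes.

attribute_columns <- function(attrs) setdiff(names(attrs), "country")

#' Theme-attribute Spearman correlations
#'
#' Pools country-year annual volume observations per theme against the
#' (year-constant) country attribute and computes the Spearman correlation
#' for every theme x attribute pair, with Bonferroni adjustment across all
#' pairs. Attributes constant across countries are flagged undefined.
#'
#' @param annual data frame from [annual_volume()].
#' @param attrs country attribute table (column `country` plus numeric
#'   attribute columns).
#' @param attributes attribute columns to use (default: all).
#' @return data frame `theme, attribute, rho, n, p_value, p_adjusted,
#'   defined`.
#' @export
volume_attribute_correlation <- function(annual, attrs,
                                         attributes = attribute_columns(attrs)) {
  a <- annual[annual$complete, , drop = FALSE]
  res <- list()
  for (th in sort(unique(a$theme))) {
    d <- a[a$theme == th, , drop = FALSE]
    for (at in attributes) {
      av <- attrs[[at]][match(d$country, attrs$country)]
      ok <- is.finite(d$volume) & is.finite(av)
      if (sum(ok) < 3 || length(unique(d$country[ok])) < 3) next
      defined <- stats::sd(av[ok]) > 0 && stats::sd(d$volume[ok]) > 0
      s <- if (defined) spearman_pair(d$volume[ok], av[ok])
           else list(value = NA_real_, n = sum(ok), p_value = NA_real_)
      res[[length(res) + 1L]] <-
        data.frame(theme = th, attribute = at, rho = s$value, n = s$n,
                   p_value = s$p_value, defined = defined,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$p_adjusted <- pmin(1, out$p_value * sum(!is.na(out$p_value)))
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank test across effect groups
#'
#' Tie-corrected H statistic with a chi-square p-value on `groups - 1`
#' degrees of freedom (via [stats::kruskal.test]). Flagged when fewer than 5
#' observations support the chi-square approximation.
#'
#' @param values numeric per-country values.
#' @param groups per-country group labels (>= 2 nonempty groups).
#' @return list `statistic, df, p_value, group_sizes, approx_ok, method`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(as.character(groups[ok]))
  if (nlevels(groups) < 2) stop("need at least 2 nonempty groups")
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, group_sizes = as.integer(table(groups)),
       group_labels = levels(groups), approx_ok = length(values) >= 5,
       method = "kruskal_wallis")
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z tests on the pooled ranks for each pair of groups, with the
#' usual tie correction and Bonferroni adjustment over pairs. Intended as the
#' follow-up to a rejecting omnibus [kruskal_wallis()] test; the omnibus
#' gatekeeping result is recorded in the output.
#'
#' @param values,groups as in [kruskal_wallis()].
#' @param alpha omnibus significance level used for the gatekeeping record.
#' @return data frame `group_a, group_b, z, p_value, p_adjusted` with
#'   attribute `omnibus` (the Kruskal-Wallis result) and `gatekeeper_passed`.
#' @export
pairwise_posthoc <- function(values, groups, alpha = 0.05) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(as.character(groups[ok]))
  if (nlevels(groups) < 2) stop("need at least 2 nonempty groups")
  omnibus <- kruskal_wallis(values, groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_corr
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(pr) {
    ra <- r[groups == pr[1]]; rb <- r[groups == pr[2]]
    v <- base_var * (1 / length(ra) + 1 / length(rb))
    z <- if (v > 0) (mean(ra) - mean(rb)) / sqrt(v) else 0
    data.frame(group_a = pr[1], group_b = pr[2], z = z,
               p_value = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  attr(out, "omnibus") <- omnibus
  attr(out, "gatekeeper_passed") <- omnibus$p_value < alpha
  out
}

#' Two-sample rank-sum test of an attribute between cluster groups
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test of a country attribute
#' between the countries of one cluster group and the rest, e.g. constant
#' total-volume countries versus all others. The direction is reported as the
#' rank-biserial correlation (positive when the first group tends higher).
#'
#' @param membership per-country labels with exactly two distinct values, or
#'   a logical vector (`TRUE` = first group).
#' @param attrs country attribute table.
#' @param attribute_name attribute column to test.
#' @param countries country identifiers aligned with `membership` (default:
#'   `attrs$country` order).
#' @return list `statistic, p_value, direction, group_sizes, groups, method`.
#' @export
cluster_attribute_test <- function(membership, attrs, attribute_name,
                                   countries = attrs$country) {
  if (!attribute_name %in% names(attrs)) stop("unknown attribute: ", attribute_name)
  if (is.logical(membership))
    membership <- ifelse(membership, "in_group", "rest")
  membership <- as.character(membership)
  lv <- sort(unique(membership))
  if (length(lv) != 2) stop("membership must define exactly 2 groups")
  v <- attrs[[attribute_name]][match(countries, attrs$country)]
  va <- v[membership == lv[1]]; vb <- v[membership == lv[2]]
  va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
  if (length(va) == 0 || length(vb) == 0)
    stop("attribute all-missing in one group")
  wt <- suppressWarnings(stats::wilcox.test(va, vb, alternative = "two.sided"))
  u <- unname(wt$statistic)  # Mann-Whitney U of group a over group b
  rank_biserial <- 2 * u / (length(va) * length(vb)) - 1
  list(statistic = u, p_value = wt$p.value, direction = rank_biserial,
       group_sizes = c(length(va), length(vb)), groups = lv,
       method = "rank_sum")
}
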