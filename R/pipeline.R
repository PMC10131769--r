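# End-to-end orchestration: run the stages in dependency order from a config
# (list or YAML file), write every intermediate artifact as CSV, and return a
# machine-readable report. All randomness flows from named seeds in the
# config, so identical config + seed reproduces byte-identical outputs.

#' Default pipeline configuration
#'
#' @param seed master seed; stage seeds default to it.
#' @param alpha significance level for effect classification and gatekeeping.
#' @param m_top number of top themes in the effect model.
#' @param k_min,k_max,min_size cluster-count selection rule.
#' @param n_terms_selected size of the term short-list.
#' @param stability_years the two years compared for temporal stability;
#'   analyses of the pre-pandemic period deliberately stop at 2019 so the
#'   2020 shock does not distort them.
#' @param similarity_year year for the cross-country similarity matrix.
#' @param stages named logical list toggling `identify`, `describe`,
#'   `cluster`, `effects`, `associate`.
#' @param simulate generator settings: lists of arguments for
#'   [panel_config()], [query_log_config()], and
#'   [generate_country_attributes()].
#' @param inputs optional named paths (`panel`, `catalogue`, `attributes`,
#'   `query_log`) read instead of simulating; any path given disables the
#'   corresponding generator.
#' @return a classed `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, alpha = 0.05, m_top = 3L,
                            k_min = 2L, k_max = 10L, min_size = 5L,
                            n_terms_selected = 10L,
                            stability_years = c(2004L, 2019L),
                            similarity_year = 2019L,
                            stages = list(identify = TRUE, describe = TRUE,
                                          cluster = TRUE, effects = TRUE,
                                          associate = TRUE),
                            simulate = list(panel = list(),
                                            query_log = list(),
                                            attributes = list()),
                            inputs = list()) {
  structure(list(seed = as.integer(seed), alpha = alpha, m_top = m_top,
                 k_min = k_min, k_max = k_max, min_size = min_size,
                 n_terms_selected = n_terms_selected,
                 stability_years = stability_years,
                 similarity_year = similarity_year,
                 stages = utils::modifyList(
                   list(identify = TRUE, describe = TRUE, cluster = TRUE,
                        effects = TRUE, associate = TRUE), stages),
                 simulate = simulate, inputs = inputs),
            class = "pipeline_config")
}

read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the surveillance pipeline
#'
#' Executes the enabled stages in dependency order: theme identification from
#' the query log, panel aggregation, descriptive correlations, trend
#' clustering, effect-model classification, and attribute associations.
#' Inputs are read from `config$inputs` paths when given, otherwise generated
#' by the synthetic module under the config seed.
#'
#' @param config a [pipeline_config()], a list of its arguments, or the path
#'   to a YAML file of them.
#' @param output_dir directory for CSV artifacts and the JSON report;
#'   nothing is written when `NULL`.
#' @return a classed `pipeline_report` list with one summary per enabled
#'   stage, the config echo, and the package version.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  if (!is.null(output_dir) && !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  emit <- function(d, name) if (!is.null(output_dir))
    write_csv_stable(d, file.path(output_dir, name))

  report <- list(config = unclass(config),
                 version = as.character(utils::packageVersion("anxitrends")))

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$inputs$panel)) {
    panel <- read_volume_panel(config$inputs$panel)
    catalogue <- if (!is.null(config$inputs$catalogue))
      utils::read.csv(config$inputs$catalogue, stringsAsFactors = FALSE)
    else generate_theme_catalogue(panel$themes, config$seed)
    truth <- NULL
  } else {
    pc <- do.call(panel_config,
                  utils::modifyList(list(seed = config$seed), config$simulate$panel))
    panel <- generate_volume_panel(pc)
    catalogue <- panel$catalogue
    truth <- panel$truth
  }
  attrs <- if (!is.null(config$inputs$attributes))
    utils::read.csv(config$inputs$attributes, stringsAsFactors = FALSE)
  else NULL

  emit(as.data.frame(panel), "panel.csv")
  emit(catalogue, "catalogue.csv")
  if (!is.null(truth) && !is.null(output_dir))
    write_ground_truth(truth, file.path(output_dir, "panel_truth.json"))

  # --- identify -----------------------------------------------------------
  if (isTRUE(config$stages$identify)) {
    qlog <- if (!is.null(config$inputs$query_log))
      utils::read.csv(config$inputs$query_log, stringsAsFactors = FALSE)
    else {
      qc <- do.call(query_log_config,
                    utils::modifyList(list(seed = config$seed),
                                      config$simulate$query_log))
      generate_query_log(qc)
    }
    scores <- score_terms(qlog)
    k <- min(config$n_terms_selected, sum(scores$correlation_defined))
    selected <- select_top_terms(scores, k)
    emit(qlog, "query_log.csv"); emit(scores, "term_scores.csv")
    emit(data.frame(rank = seq_along(selected), term = selected), "selected_terms.csv")
    report$identify <- list(n_terms = nrow(scores), k = k, selected = selected)
    if (!is.null(attr(qlog, "truth")))
      report$identify$recovered <-
        length(intersect(selected, attr(qlog, "truth")$related_terms))
  }

  # --- panel aggregation --------------------------------------------------
  annual <- annual_volume(panel)
  emit(annual, "annual_volume.csv")

  # --- describe -----------------------------------------------------------
  if (isTRUE(config$stages$describe)) {
    st <- suppressWarnings(temporal_stability(annual, config$stability_years[1],
                                              config$stability_years[2]))
    cs <- suppressWarnings(cross_country_similarity(annual, config$similarity_year))
    dv <- domain_volume(panel, catalogue)
    emit(st$per_country, "temporal_stability.csv")
    emit(as.data.frame(as.table(cs$matrix),
                       stringsAsFactors = FALSE) |>
           stats::setNames(c("country_a", "country_b", "rho")),
         "similarity_matrix.csv")
    emit(dv$leading, "leading_domain.csv")
    report$describe <- list(stability_average = st$average,
                            similarity_average = cs$average,
                            leading_domain_counts =
                              as.list(table(dv$leading$domain)))
  }

  # --- cluster ------------------------------------------------------------
  if (isTRUE(config$stages$cluster)) {
    series <- total_volume_series(panel)
    cl <- select_k(series, config$k_min, config$k_max, config$min_size,
                   seed = config$seed)
    emit(data.frame(country = names(cl$assignment), cluster = cl$assignment),
         "clusters.csv")
    emit(data.frame(cluster = rep(seq_len(cl$k), each = ncol(cl$centroids)),
                    month = rep(colnames(series), cl$k),
                    value = as.vector(t(cl$centroids))),
         "cluster_centroids.csv")
    report$cluster <- list(k = cl$k, sizes = cl$sizes, inertia = cl$inertia,
                           selection_failed = cl$selection_failed,
                           seed = cl$seed, n_restarts = cl$n_restarts)
  }

  # --- effects ------------------------------------------------------------
  if (isTRUE(config$stages$effects)) {
    ep <- build_effect_panel(panel, config$m_top)
    fit <- fit_interaction_model(ep)
    effect_labels <- cls <- classify_effects(fit, alpha = config$alpha)
    emit(ep, "effect_panel.csv"); emit(cls, "effect_classification.csv")
    report$effects <- list(
      label_counts = as.list(table(factor(cls$label,
        c("compensatory", "noncompensatory", "none")))),
      n = fit$n, df = fit$df_residual)
    if (!is.null(truth)) {
      planted <- c(`-1` = "compensatory", `0` = "none",
                   `1` = "noncompensatory")[as.character(truth$interaction_sign)]
      report$effects$recovery_accuracy <-
        mean(cls$label[match(truth$country, cls$country)] == planted)
    }
  }

  # --- associate ----------------------------------------------------------
  if (isTRUE(config$stages$associate)) {
    if (is.null(attrs)) {
      labels <- if (!is.null(report$effects) && !is.null(truth))
        c(`-1` = "compensatory", `0` = "none",
          `1` = "noncompensatory")[as.character(truth$interaction_sign)]
      else rep("none", length(panel$countries))
      aa <- utils::modifyList(list(n_countries = length(panel$countries),
                                   effect_labels = unname(labels),
                                   seed = config$seed),
                              config$simulate$attributes)
      attrs <- do.call(generate_country_attributes, aa)
      attrs$country <- panel$countries
    }
    emit(attrs, "country_attributes.csv")
    vac <- volume_attribute_correlation(annual, attrs)
    emit(vac, "volume_attribute_correlations.csv")
    report$associate <- list(
      n_pairs = nrow(vac),
      n_significant_adjusted = sum(vac$p_adjusted < config$alpha, na.rm = TRUE))
    if (!is.null(report$effects)) {
      labels <- effect_labels
      kw <- kruskal_wallis(
        attrs$mental_disorder_prevalence[match(labels$country, attrs$country)],
        labels$label)
      report$associate$prevalence_kruskal <- kw[c("statistic", "df", "p_value")]
      if (length(unique(labels$label)) >= 2) {
        ph <- pairwise_posthoc(
          attrs$mental_disorder_prevalence[match(labels$country, attrs$country)],
          labels$label, alpha = config$alpha)
        emit(ph, "prevalence_posthoc.csv")
      }
    }
  }

  if (!is.null(output_dir))
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Anxiety-surveillance pipeline report\n")
  if (!is.null(x$identify))
    cat(sprintf("  identify: %d terms scored, %d selected\n",
                x$identify$n_terms, x$identify$k))
  if (!is.null(x$describe))
    cat(sprintf("  describe: stability avg %.3f, similarity avg %.3f\n",
                x$describe$stability_average, x$describe$similarity_average))
  if (!is.null(x$cluster))
    cat(sprintf("  cluster: k = %d, sizes [%s]\n", x$cluster$k,
                paste(x$cluster$sizes, collapse = ", ")))
  if (!is.null(x$effects))
    cat(sprintf("  effects: %s compensatory, %s noncompensatory, %s none\n",
                x$effects$label_counts$compensatory,
                x$effects$label_counts$noncompensatory,
                x$effects$label_counts$none))
  invisible(x)
}

# ---------------------------------------------------------------------------

default_schemas <- function() list(
  panel = list(columns = c("country", "theme", "year", "month", "volume"),
               numeric = c("year", "month", "volume"),
               nonnegative = "volume"),
  catalogue = list(columns = c("theme", "domain", "timeframe"),
                   levels = list(domain = c("personal", "familial", "societal"),
                                 timeframe = c("short-term", "long-term")),
                   unique = "theme"),
  attributes = list(columns = c("country", "mental_disorder_prevalence"),
                    unique = "country"),
  query_log = list(columns = c("term", "country", "year", "month",
                               "n_with_context", "n_without_context"),
                   numeric = c("n_with_context", "n_without_context"),
                   nonnegative = c("n_with_context", "n_without_context")))

#' Validate input CSV files against their schemas
#'
#' Header-keyed parsing: column order is irrelevant, but required columns,
#' types, value domains and uniqueness are checked, and every violation is
#' reported with its row number.
#'
#' @param paths named character vector/list of file paths; names must match
#'   schema names.
#' @param schemas named list of schema descriptions (default:
#'   panel/catalogue/attributes/query_log).
#' @return data frame `file, row, message` (zero rows when all inputs are
#'   clean).
#' @export
validate_inputs <- function(paths, schemas = default_schemas()) {
  issues <- list()
  note <- function(f, row, msg) issues[[length(issues) + 1L]] <<-
    data.frame(file = f, row = row, message = msg, stringsAsFactors = FALSE)
  for (nm in names(paths)) {
    path <- paths[[nm]]
    sc <- schemas[[nm]]
    if (is.null(sc)) { note(nm, NA_integer_, "no schema for this input"); next }
    if (!file.exists(path)) stop("unreadable file: ", path)
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(sc$columns, names(d))
    if (length(miss)) {
      note(nm, NA_integer_, paste("missing columns:", paste(miss, collapse = ", ")))
      next
    }
    for (col in sc$numeric %||% character())
      if (!is.numeric(d[[col]]))
        note(nm, NA_integer_, paste("non-numeric column:", col))
    for (col in sc$nonnegative %||% character())
      if (is.numeric(d[[col]]))
        for (r in which(!is.na(d[[col]]) & d[[col]] < 0))
          note(nm, r, paste("negative value in", col))
    for (col in names(sc$levels %||% list()))
      for (r in which(!d[[col]] %in% sc$levels[[col]]))
        note(nm, r, paste("invalid", col, "value:", d[[col]][r]))
    for (col in sc$unique %||% character())
      for (r in which(duplicated(d[[col]])))
        note(nm, r, paste("duplicate", col, "value:", d[[col]][r]))
  }
  if (length(issues) == 0L)
    return(data.frame(file = character(), row = integer(),
                      message = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
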