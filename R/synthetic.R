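# Synthetic data generators. These emulate the statistical structure the
# analyses assume -- trend-shaped country clusters, planted compensatory /
# noncompensatory coupling between the top-3 and remaining themes, geographic
# correlation blocks, year-to-year rank persistence, and a pandemic-like level
# shock -- so every downstream stage can be exercised and validated without
# access to proprietary query logs. Ground truth is always attached.

#' Configuration for the synthetic volume panel
#'
#' Defaults reproduce the study conditions: 50 countries, 37 themes, monthly
#' 2004-01..2020-12, trend classes split 22 declining-then-flat / 9 constant /
#' 19 increasing, interaction signs split 13 negative / 17 positive / 20 zero,
#' and a societal-theme shock from 2020-03.
#'
#' @param n_countries,n_themes positive integers.
#' @param months data frame of `year`, `month` rows (strictly increasing).
#' @param trend_class character vector, one of `"declining_then_flat"`,
#'   `"constant"`, `"increasing"` per country. Recycled from the default
#'   22/9/19 split when `NULL`.
#' @param interaction_sign integer vector in `{-1, 0, 1}` per country
#'   (compensatory / none / noncompensatory). Default 13/17/20 split.
#' @param shock_start `c(year, month)` for the multiplicative level shift on
#'   societal-domain themes, or `NULL` for no shock.
#' @param shock_size multiplicative factor applied from `shock_start` onward.
#' @param geo_blocks integer vector assigning each country to a block.
#' @param rho_block within-block share of the country-theme baseline variance,
#'   in `[0, 1]`.
#' @param persistence AR(1) coefficient of the year-level log-mean deviations,
#'   in `[0, 1]`; higher values raise the Spearman rank stability between
#'   distant years.
#' @param year_sd standard deviation of the stationary year-level deviation.
#' @param noise_dispersion log-scale s.d. of the multiplicative monthly
#'   lognormal noise. `0` switches off all stochastic components of the time
#'   dimension, leaving the exact deterministic mean paths.
#' @param coupling strength of the planted interaction (relative response of
#'   the remaining themes to the top-3 oscillation).
#' @param osc_amplitude relative amplitude of the deterministic 12-month
#'   oscillation planted on the top-3 themes of coupled countries.
#' @param trend_drop,trend_rise total log change of the declining / increasing
#'   trend shapes.
#' @param country_scale_sd log-scale s.d. of the overall per-country volume
#'   level. Nonzero values make residual scale differ across countries
#'   (realistic, but at odds with the pooled homoskedastic error assumption
#'   of the interaction model); set 0 for scale-homogeneous panels.
#' @param seed integer seed; identical configs give identical panels.
#' @return A classed `panel_config` list.
#' @export
panel_config <- function(n_countries = 50, n_themes = 37,
                         months = month_seq(2004, 1, 2020, 12),
                         trend_class = NULL, interaction_sign = NULL,
                         shock_start = c(2020, 3), shock_size = 3,
                         geo_blocks = NULL, rho_block = 0.5,
                         persistence = 0.9, year_sd = 0.25,
                         noise_dispersion = 0.15,
                         coupling = 0.8, osc_amplitude = 0.6,
                         trend_drop = 0.7, trend_rise = 0.7,
                         country_scale_sd = 0.5, seed = 1L) {
  if (n_countries < 1 || n_themes < 1) stop("need at least one country and one theme")
  months <- validate_months(months)
  if (is.null(trend_class)) {
    split <- round(n_countries * c(22, 9, 19) / 50)
    split[2] <- n_countries - split[1] - split[3]
    trend_class <- rep(c("declining_then_flat", "constant", "increasing"), split)
  }
  trend_class <- rep_len(trend_class, n_countries)
  bad <- setdiff(trend_class, c("declining_then_flat", "constant", "increasing"))
  if (length(bad)) stop("unknown trend class: ", paste(bad, collapse = ", "))
  if (is.null(interaction_sign)) {
    split <- round(n_countries * c(13, 17, 20) / 50)
    split[3] <- n_countries - split[1] - split[2]
    interaction_sign <- rep(c(-1L, 1L, 0L), split)
  }
  interaction_sign <- rep_len(as.integer(interaction_sign), n_countries)
  if (!all(interaction_sign %in% c(-1L, 0L, 1L)))
    stop("interaction signs must be -1, 0 or +1")
  if (is.null(geo_blocks))
    geo_blocks <- rep(seq_len(max(1L, n_countries %/% 10L)),
                      length.out = n_countries)
  geo_blocks <- rep_len(as.integer(geo_blocks), n_countries)
  if (rho_block < 0 || rho_block > 1) stop("rho_block must be in [0, 1]")
  if (persistence < 0 || persistence > 1) stop("persistence must be in [0, 1]")
  if (noise_dispersion < 0) stop("noise_dispersion must be nonnegative")
  if (!is.null(shock_start) && length(shock_start) != 2L)
    stop("shock_start must be c(year, month) or NULL")
  structure(list(n_countries = n_countries, n_themes = n_themes,
                 months = months, trend_class = trend_class,
                 interaction_sign = interaction_sign,
                 shock_start = shock_start, shock_size = shock_size,
                 geo_blocks = geo_blocks, rho_block = rho_block,
                 persistence = persistence, year_sd = year_sd,
                 noise_dispersion = noise_dispersion, coupling = coupling,
                 osc_amplitude = osc_amplitude, trend_drop = trend_drop,
                 trend_rise = trend_rise, country_scale_sd = country_scale_sd,
                 seed = as.integer(seed)),
            class = "panel_config")
}

#' Generate a synthetic theme catalogue
#'
#' Assigns each theme a domain (personal / familial / societal) and timeframe
#' (short-term / long-term). Personal and long-term labels dominate, matching
#' the composition observed for real anxiety themes.
#'
#' @param themes character vector of theme identifiers.
#' @param seed integer seed.
#' @return data frame `theme, domain, timeframe`.
#' @export
generate_theme_catalogue <- function(themes, seed = 1L) {
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  data.frame(
    theme = themes,
    domain = sample(c("personal", "familial", "societal"), length(themes),
                    replace = TRUE, prob = c(0.5, 0.25, 0.25)),
    timeframe = sample(c("short-term", "long-term"), length(themes),
                       replace = TRUE, prob = c(0.4, 0.6)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic volume panel with planted structure
#'
#' Volumes are lognormal around deterministic mean paths. Each country carries
#' one trend shape (declining-then-flat / constant / increasing on the
#' log scale); country-theme baselines share a geographic block component with
#' within-block variance share `rho_block`; year-level deviations follow an
#' AR(1) with coefficient `persistence`; countries with a nonzero planted
#' interaction sign receive a deterministic 12-month oscillation on their
#' three most popular themes, and the remaining themes respond with relative
#' strength `coupling` and the planted sign; societal-domain themes are
#' multiplied by `shock_size` from `shock_start` onward.
#'
#' @param config a [panel_config()].
#' @param catalogue optional theme catalogue; generated from the config seed
#'   when `NULL`.
#' @return A `volume_panel` with an extra `truth` element (trend class,
#'   interaction sign, geo block per country; the designated top themes;
#'   shocked themes) and the catalogue attached.
#' @export
generate_volume_panel <- function(config, catalogue = NULL) {
  stopifnot(inherits(config, "panel_config"))
  nc <- config$n_countries; nt <- config$n_themes
  months <- config$months; nm <- nrow(months)
  countries <- sprintf("C%02d", seq_len(nc))
  themes <- sprintf("theme%02d", seq_len(nt))
  if (is.null(catalogue)) catalogue <- generate_theme_catalogue(themes, config$seed)
  if (!all(themes %in% catalogue$theme)) stop("catalogue does not cover all themes")

  rs <- local_rng(config$seed)
  on.exit(restore_rng(rs))

  deterministic <- config$noise_dispersion == 0

  # cross-sectional baselines (log scale); variance components sized so that
  # the default year-to-year rank stability and cross-country similarity sit
  # in the regimes real query panels show
  popularity <- stats::rnorm(nt, mean = 3, sd = 0.44)
  top_idx <- order(popularity, decreasing = TRUE)[seq_len(min(3L, nt))]
  popularity[top_idx] <- max(popularity) + c(2.6, 2.4, 2.2)[seq_along(top_idx)]
  tau <- 0.44
  block_eff <- matrix(stats::rnorm(max(config$geo_blocks) * nt), ncol = nt)
  indiv_eff <- matrix(stats::rnorm(nc * nt), ncol = nt)
  country_scale <- stats::rnorm(nc, 0, config$country_scale_sd)
  base <- sqrt(config$rho_block) * tau * block_eff[config$geo_blocks, , drop = FALSE] +
    sqrt(1 - config$rho_block) * tau * indiv_eff
  # the designated top themes have deterministic baselines: with a fixed
  # popularity margin this pins the realized yearly top-3 to the designated
  # set, so the planted coupling is identified from the intended X
  base[, top_idx] <- 0
  base <- sweep(base, 2, popularity, `+`)
  base <- base + country_scale

  # year-level AR(1) deviations (stochastic; off in zero-noise mode)
  years <- sort(unique(months$year)); ny <- length(years)
  ysd <- if (deterministic) 0 else config$year_sd
  dev <- array(0, c(nc, nt, ny))
  dev[, , 1] <- stats::rnorm(nc * nt, 0, ysd)
  if (ny > 1) for (y in 2:ny)
    dev[, , y] <- config$persistence * dev[, , y - 1] +
      sqrt(1 - config$persistence^2) * stats::rnorm(nc * nt, 0, ysd)
  # the top themes carry no year-level persistence: their stochastic variation
  # is purely monthly, which keeps the per-country slope test of the effect
  # model calibrated when no coupling is planted
  dev[, top_idx, ] <- 0

  # deterministic trend multiplier per country x month (log scale)
  t01 <- (seq_len(nm) - 1) / max(1, nm - 1)
  pivot_i <- match(TRUE, months$year >= 2014)
  if (is.na(pivot_i)) pivot_i <- ceiling(nm * 0.6)
  pivot <- t01[pivot_i]
  shape <- function(cls) switch(cls,
    constant = rep(0, nm),
    declining_then_flat = -config$trend_drop * pmin(t01, pivot) / max(pivot, 1e-9),
    increasing = config$trend_rise * pmax(0, t01 - pivot) / max(1 - pivot, 1e-9))
  trend <- t(vapply(config$trend_class, shape, numeric(nm)))

  # shock on societal themes; the designated top themes are never shocked so
  # the level shift cannot masquerade as an interaction effect
  shocked <- setdiff(catalogue$theme[catalogue$domain == "societal"],
                     themes[top_idx])
  shock_on <- rep(FALSE, nm)
  if (!is.null(config$shock_start))
    shock_on <- months$year * 12L + months$month >=
      config$shock_start[1] * 12L + config$shock_start[2]

  # planted interaction: oscillation on top themes, coupled response on rest
  osc <- 1 + config$osc_amplitude * sin(2 * pi * seq_len(nm) / 12)

  vol <- array(0, c(nc, nt, nm))
  is_shocked <- themes %in% shocked
  # the broad theme base carries the country trend; the top themes stay
  # trend-free so the planted oscillation is the only deterministic X-Y link
  trend_mask <- as.numeric(!(seq_len(nt) %in% top_idx))
  for (ci in seq_len(nc)) {
    mu <- exp(outer(base[ci, ], rep(1, nm)) +
              dev[ci, , match(months$year, years)] +
              trend_mask * matrix(trend[ci, ], nt, nm, byrow = TRUE))
    if (any(is_shocked) && any(shock_on))
      mu[is_shocked, shock_on] <- mu[is_shocked, shock_on] * config$shock_size
    s <- config$interaction_sign[ci]
    if (s != 0L) {
      mu[top_idx, ] <- mu[top_idx, ] * rep(osc, each = length(top_idx))
      rest <- setdiff(seq_len(nt), top_idx)
      mu[rest, ] <- mu[rest, ] *
        rep(pmax(0, 1 + s * config$coupling * (osc - 1)), each = length(rest))
    }
    if (deterministic) vol[ci, , ] <- mu
    else vol[ci, , ] <- mu * exp(stats::rnorm(nt * nm, 0, config$noise_dispersion) -
                                 config$noise_dispersion^2 / 2)
  }

  panel <- volume_panel(vol, countries, themes, months)
  panel$truth <- list(
    country = countries,
    trend_class = config$trend_class,
    interaction_sign = config$interaction_sign,
    geo_block = config$geo_blocks,
    top_themes = themes[top_idx],
    shocked_themes = intersect(themes, shocked))
  panel$catalogue <- catalogue[match(themes, catalogue$theme), ]
  panel
}

#' Configuration for the synthetic query log
#'
#' @param n_terms number of candidate terms.
#' @param n_related number of terms planted as anxiety-related.
#' @param months data frame of `year`, `month` (default the 12 months of 2020,
#'   the scoring window used for real query logs).
#' @param related_context_correlation,unrelated_context_correlation target
#'   correlation between the monthly with-context and without-context latent
#'   rates for related / unrelated terms, in `[-1, 1]`.
#' @param base_rate mean monthly without-context count (> 0).
#' @param context_rate mean with-context count as a fraction of `base_rate`.
#' @param rate_sd log-scale s.d. of the monthly latent rate variation.
#' @param poisson_noise draw Poisson counts around the rates (`TRUE`, the
#'   default) or return the deterministic real-valued rates (`FALSE`).
#' @param seed integer seed.
#' @return A classed `query_log_config` list.
#' @export
query_log_config <- function(n_terms = 50, n_related = 10,
                             months = month_seq(2020, 1, 2020, 12),
                             related_context_correlation = 0.95,
                             unrelated_context_correlation = 0,
                             base_rate = 1000, context_rate = 0.05,
                             rate_sd = 0.5, poisson_noise = TRUE, seed = 1L) {
  if (n_related < 0 || n_related > n_terms)
    stop("n_related must be between 0 and n_terms")
  if (abs(related_context_correlation) > 1 || abs(unrelated_context_correlation) > 1)
    stop("context correlations must be in [-1, 1]")
  if (base_rate <= 0) stop("base_rate must be positive")
  structure(list(n_terms = n_terms, n_related = n_related,
                 months = validate_months(months),
                 related_context_correlation = related_context_correlation,
                 unrelated_context_correlation = unrelated_context_correlation,
                 base_rate = base_rate, context_rate = context_rate,
                 rate_sd = rate_sd, poisson_noise = poisson_noise,
                 seed = as.integer(seed)),
            class = "query_log_config")
}

#' Generate synthetic query-context counts
#'
#' For each term and month, a latent log-rate drives the without-context
#' count; the with-context count follows a latent rate correlated with it at
#' the term's target correlation (high for planted related terms, low
#' otherwise). Counts are Poisson around the rates unless `poisson_noise` is
#' off, in which case the exact rates are returned (and for a target
#' correlation of 1 the with-context series is an exact positive multiple of
#' the without-context series).
#'
#' @param config a [query_log_config()].
#' @return data frame `term, language, country, year, month, n_with_context,
#'   n_without_context` with attribute `truth`: the planted related-term set.
#' @export
generate_query_log <- function(config) {
  stopifnot(inherits(config, "query_log_config"))
  rs <- local_rng(config$seed)
  on.exit(restore_rng(rs))
  nm <- nrow(config$months)
  terms <- sprintf("term%03d", seq_len(config$n_terms))
  related <- terms[seq_len(config$n_related)]
  out <- vector("list", config$n_terms)
  for (ti in seq_len(config$n_terms)) {
    r <- if (terms[ti] %in% related) config$related_context_correlation
         else config$unrelated_context_correlation
    u <- stats::rnorm(nm); v <- stats::rnorm(nm)
    w <- r * u + sqrt(1 - r^2) * v
    s <- config$rate_sd
    rate_wo <- config$base_rate * exp(s * u - s^2 / 2)
    rate_wi <- config$base_rate * config$context_rate * exp(s * w - s^2 / 2)
    if (config$poisson_noise) {
      n_wo <- stats::rpois(nm, rate_wo); n_wi <- stats::rpois(nm, rate_wi)
    } else {
      n_wo <- rate_wo; n_wi <- rate_wi
    }
    out[[ti]] <- data.frame(term = terms[ti], language = "en", country = "C01",
                            year = config$months$year, month = config$months$month,
                            n_with_context = n_wi, n_without_context = n_wo,
                            stringsAsFactors = FALSE)
  }
  log <- do.call(rbind, out)
  rownames(log) <- NULL
  attr(log, "truth") <- list(related_terms = related)
  log
}

#' Generate synthetic country attributes
#'
#' Draws the full attribute table (economy, demography, politics, religion,
#' prevalence of mental disorders, and the six Hofstede cultural dimensions)
#' from plausible marginal distributions. The mental-disorder prevalence of
#' countries labelled `"none"` is shifted upward by `prevalence_shift`,
#' planting the association between absent interaction effects and higher
#' prevalence.
#'
#' @param n_countries number of countries (rows).
#' @param effect_labels character vector per country in
#'   `{"compensatory", "noncompensatory", "none"}`.
#' @param prevalence_shift mean shift (percentage points) added to the
#'   prevalence of the `"none"` group.
#' @param seed integer seed.
#' @return data frame with one row per country and attribute `truth`
#'   (the labels used).
#' @export
generate_country_attributes <- function(n_countries,
                                        effect_labels = rep("none", n_countries),
                                        prevalence_shift = 3, seed = 1L) {
  if (length(effect_labels) != n_countries)
    stop("effect_labels must cover all countries")
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  n <- n_countries
  attrs <- data.frame(
    country = sprintf("C%02d", seq_len(n)),
    gdp = exp(stats::rnorm(n, 9, 1)),
    life_expectancy = clip(stats::rnorm(n, 72, 5), 50, 90),
    median_age = clip(stats::rnorm(n, 30, 7), 15, 50),
    urban_percent = clip(stats::rnorm(n, 60, 18), 10, 100),
    sex_ratio = clip(stats::rnorm(n, 100, 3), 85, 115),
    mental_disorder_prevalence =
      clip(stats::rnorm(n, 12, 2) + ifelse(effect_labels == "none",
                                           prevalence_shift, 0), 1, 40),
    freedom_score = clip(stats::rnorm(n, 60, 25), 0, 100),
    religiosity = clip(stats::rnorm(n, 60, 25), 0, 100),
    fragile_states_index = clip(stats::rnorm(n, 70, 25), 0, 120),
    power_distance = clip(stats::rnorm(n, 60, 20), 0, 100),
    individualism = clip(stats::rnorm(n, 45, 22), 0, 100),
    masculinity = clip(stats::rnorm(n, 50, 18), 0, 100),
    uncertainty_avoidance = clip(stats::rnorm(n, 60, 20), 0, 100),
    long_term_orientation = clip(stats::rnorm(n, 45, 22), 0, 100),
    indulgence = clip(stats::rnorm(n, 48, 20), 0, 100),
    stringsAsFactors = FALSE)
  attr(attrs, "truth") <- list(effect_labels = effect_labels)
  attrs
}

#' Write ground-truth sidecar as JSON
#'
#' @param truth a list of planted ground-truth components (as attached by the
#'   generators).
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Seed hygiene: generators use an isolated RNG state so that callers' RNG
# streams are untouched and identical seeds give identical output.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_rng <- function(old) {
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
}
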