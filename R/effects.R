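# Compensatory / noncompensatory effect analysis. A cross-country monthly
# OLS model regresses the summed volume of the less-searched themes (Y) on
# the summed volume of the top-3 themes (X), with country and year indicators
# and per-country X interactions:
#
#   Y = b0 + b1 X + b2 C + b3 Year + b4 X*C + e
#
# A country whose total slope (b1 plus its interaction deviation) is
# significantly negative shows a compensatory effect -- rising volume of the
# dominant anxiety themes comes at the expense of the rest; significantly
# positive is noncompensatory; otherwise no effect.

#' Build the effect panel
#'
#' For every country-year, the `m_top` most searched themes of that year
#' define `x` (their summed monthly volume) for the year's months; `y` is the
#' summed volume of all remaining themes. By construction `x + y` equals the
#' total monthly volume. Top-theme membership is recomputed every year, so
#' `x`'s composition may change at year boundaries.
#'
#' @param panel a `volume_panel`.
#' @param m_top number of top themes (default 3).
#' @return data frame `country, year, month, x, y, total` with one row per
#'   country-month.
#' @export
build_effect_panel <- function(panel, m_top = 3L) {
  stopifnot(inherits(panel, "volume_panel"))
  if (length(panel$themes) < m_top + 1L)
    stop(sprintf("need at least %d themes, have %d", m_top + 1L,
                 length(panel$themes)))
  months <- panel$months
  rows <- vector("list", length(panel$countries))
  for (ci in seq_along(panel$countries)) {
    co <- panel$countries[ci]
    x <- numeric(nrow(months)); tot <- numeric(nrow(months))
    for (yr in unique(months$year)) {
      sel <- months$year == yr
      top <- top_themes(panel, co, yr, m_top)
      ti <- match(top, panel$themes)
      sub <- panel$volume[ci, , sel, drop = FALSE]
      x[sel] <- apply(sub[1, ti, , drop = FALSE], 3, sum)
      tot[sel] <- apply(sub, 3, sum)
    }
    rows[[ci]] <- data.frame(country = co, year = months$year,
                             month = months$month, x = x, y = tot - x,
                             total = tot, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the cross-country interaction model
#'
#' Ordinary least squares of `y` on an intercept, `x`, country indicators,
#' year indicators and per-country `x` interactions (first country and year
#' absorbed as reference levels). Homoskedastic standard errors; the
#' coefficient covariance is `sigma^2 (D'D)^-1`.
#'
#' @param ep effect panel from [build_effect_panel()].
#' @return object of class `effect_fit`: the underlying `lm` in `$lm`,
#'   `countries`, `reference_country`, `n`, `df_residual`, `sigma2`.
#' @export
fit_interaction_model <- function(ep) {
  need <- c("country", "year", "month", "x", "y")
  if (!all(need %in% names(ep)))
    stop("effect panel needs columns: ", paste(need, collapse = ", "))
  d <- data.frame(y = ep$y, x = ep$x,
                  country = factor(ep$country),
                  year = factor(ep$year))
  terms <- c("x",
             if (nlevels(d$country) > 1) "country",
             if (nlevels(d$year) > 1) "year",
             if (nlevels(d$country) > 1) "x:country")
  fml <- stats::reformulate(terms, response = "y")
  fit <- stats::lm(fml, data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(lm = fit, countries = levels(d$country),
                 reference_country = levels(d$country)[1],
                 n = nrow(d), df_residual = fit$df.residual,
                 sigma2 = sum(stats::residuals(fit)^2) / fit$df.residual),
            class = "effect_fit")
}

#' @export
print.effect_fit <- function(x, ...) {
  cat(sprintf("Cross-country interaction model: %d countries, n = %d, df = %d\n",
              length(x$countries), x$n, x$df_residual))
  cat(sprintf("  reference country: %s; residual variance %.4g\n",
              x$reference_country, x$sigma2))
  invisible(x)
}

#' @export
coef.effect_fit <- function(object, ...) stats::coef(object$lm)

#' @export
residuals.effect_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
predict.effect_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$lm, ...))
  nd <- data.frame(x = newdata$x,
                   country = factor(newdata$country, levels = object$countries),
                   year = factor(newdata$year,
                                 levels = levels(object$lm$model$year)))
  stats::predict(object$lm, newdata = nd, ...)
}

#' @export
summary.effect_fit <- function(object, alpha = 0.05, ...) {
  cls <- classify_effects(object, alpha = alpha)
  structure(list(fit = object, classification = cls, alpha = alpha),
            class = "summary.effect_fit")
}

#' @export
print.summary.effect_fit <- function(x, ...) {
  print(x$fit)
  tab <- table(factor(x$classification$label,
                      c("compensatory", "noncompensatory", "none")))
  cat(sprintf("  effects at alpha = %g: %d compensatory, %d noncompensatory, %d none\n",
              x$alpha, tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Per-country total slopes and effect labels
#'
#' For each country, the total slope of `y` on `x` (the reference country's
#' `b1`, or `b1` plus the country's interaction deviation) with its standard
#' error from the coefficient covariance, a two-sided t-test against zero,
#' and the effect label: compensatory (slope < 0, p < alpha),
#' noncompensatory (slope > 0, p < alpha), none otherwise.
#'
#' @param fit an `effect_fit`.
#' @param alpha significance level in (0, 1).
#' @param p_adjust optional multiple-testing correction across countries
#'   (`"none"`, the default, or any [stats::p.adjust] method).
#' @param vcov_type `"const"` for classical homoskedastic standard errors
#'   (the default, matching the plain OLS model) or `"HC1"` for
#'   heteroskedasticity-robust ones.
#' @return data frame `country, slope, se, t, p_value, label`.
#' @export
classify_effects <- function(fit, alpha = 0.05, p_adjust = "none",
                             vcov_type = c("const", "HC1")) {
  stopifnot(inherits(fit, "effect_fit"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  vcov_type <- match.arg(vcov_type)
  b <- stats::coef(fit$lm)
  V <- if (vcov_type == "const") stats::vcov(fit$lm)
       else sandwich::vcovHC(fit$lm, type = "HC1")
  res <- lapply(fit$countries, function(co) {
    if (co == fit$reference_country) {
      slope <- b["x"]; v <- V["x", "x"]
    } else {
      ic <- paste0("x:country", co)
      slope <- b["x"] + b[ic]
      v <- V["x", "x"] + V[ic, ic] + 2 * V["x", ic]
    }
    se <- sqrt(v)
    tstat <- slope / se
    p <- 2 * stats::pt(-abs(tstat), fit$df_residual)
    data.frame(country = co, slope = unname(slope), se = unname(se),
               t = unname(tstat), p_value = unname(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$label <- ifelse(out$p_value < alpha,
                      ifelse(out$slope < 0, "compensatory", "noncompensatory"),
                      "none")
  rownames(out) <- NULL
  out
}

#' Plot per-country effect slopes
#'
#' Total slope with a (1 - alpha) confidence interval per country, coloured by
#' effect label.
#'
#' @param x an `effect_fit`.
#' @param alpha significance level for the classification and intervals.
#' @param ... further arguments passed to [graphics::plot].
#' @export
plot.effect_fit <- function(x, alpha = 0.05, ...) {
  cls <- classify_effects(x, alpha = alpha)
  o <- order(cls$slope)
  cls <- cls[o, ]
  q <- stats::qt(1 - alpha / 2, x$df_residual)
  col <- c(compensatory = "forestgreen", noncompensatory = "firebrick",
           none = "steelblue")[cls$label]
  graphics::plot(cls$slope, seq_len(nrow(cls)), pch = 19, col = col,
                 xlab = "total slope of Y on X", ylab = "country (ordered)",
                 xlim = range(cls$slope - q * cls$se, cls$slope + q * cls$se),
                 ...)
  graphics::segments(cls$slope - q * cls$se, seq_len(nrow(cls)),
                     cls$slope + q * cls$se, seq_len(nrow(cls)), col = col)
  graphics::abline(v = 0, lty = 2)
  invisible(cls)
}
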