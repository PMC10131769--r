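test_that("effect panel complements the top themes and conserves total volume", {
  months <- month_seq(2019, 1, 2020, 12)
  set.seed(4)
  vol <- array(exp(rnorm(2 * 5 * 24, 2, 0.3)), c(2, 5, 24))
  vol[, 1:3, ] <- vol[, 1:3, ] + 50          # clear top-3
  p <- volume_panel(vol, c("A", "B"), paste0("t", 1:5), months)
  ep <- build_effect_panel(p, 3)
  expect_equal(ep$x + ep$y, ep$total, tolerance = 1e-12)
  for (co in c("A", "B")) for (yr in 2019:2020) {
    sel <- ep$country == co & ep$year == yr
    top <- top_themes(p, co, yr, 3)
    hand_x <- apply(p$volume[match(co, p$countries), match(top, p$themes),
                             p$months$year == yr], 2, sum)
    expect_equal(ep$x[sel], unname(hand_x))
  }
  # with 4 themes, y is exactly the excluded theme's series
  p4 <- volume_panel(vol[, 1:4, ], c("A", "B"), paste0("t", 1:4), months)
  ep4 <- build_effect_panel(p4, 3)
  for (co in c("A", "B")) for (yr in 2019:2020) {
    sel <- ep4$country == co & ep4$year == yr
    excl <- setdiff(paste0("t", 1:4), top_themes(p4, co, yr, 3))
    expect_equal(ep4$y[sel],
                 unname(p4$volume[match(co, p4$countries),
                                  match(excl, p4$themes),
                                  p4$months$year == yr]))
  }
  expect_error(build_effect_panel(p4, 4), "at least 5 themes")
})

test_that("noiseless coefficients are recovered to numerical precision", {
  set.seed(1)
  countries <- c("A", "B", "C"); years <- 2019:2020
  ep <- expand.grid(month = 1:12, year = years, country = countries,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ep$x <- runif(nrow(ep), 10, 20)
  b0 <- 5; b1 <- 2; b2 <- c(B = 3, C = -1); b3 <- c(`2020` = 1.5)
  b4 <- c(B = -0.5, C = 0.8)
  ep$y <- b0 + b1 * ep$x +
    ifelse(ep$country == "B", b2["B"], ifelse(ep$country == "C", b2["C"], 0)) +
    ifelse(ep$year == 2020, b3, 0) +
    ep$x * ifelse(ep$country == "B", b4["B"],
                  ifelse(ep$country == "C", b4["C"], 0))
  fit <- fit_interaction_model(ep)
  cf <- coef(fit)
  expect_equal(unname(cf["(Intercept)"]), b0, tolerance = 1e-8)
  expect_equal(unname(cf["x"]), b1, tolerance = 1e-8)
  expect_equal(unname(cf["countryB"]), unname(b2["B"]), tolerance = 1e-8)
  expect_equal(unname(cf["year2020"]), unname(b3), tolerance = 1e-8)
  expect_equal(unname(cf["x:countryB"]), unname(b4["B"]), tolerance = 1e-8)
  expect_equal(unname(cf["x:countryC"]), unname(b4["C"]), tolerance = 1e-8)
  cls <- suppressWarnings(classify_effects(fit))  # zero-residual fit
  expect_equal(cls$slope[cls$country == "A"], b1, tolerance = 1e-8)
  expect_equal(cls$slope[cls$country == "B"], unname(b1 + b4["B"]), tolerance = 1e-8)
})

test_that("the interaction fit equals the normal-equations oracle", {
  set.seed(2)
  nc <- 4; ny <- 3
  ep <- expand.grid(month = 1:12, year = 2004 + seq_len(ny) - 1,
                    country = paste0("C", 1:nc),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ep$x <- exp(rnorm(nrow(ep), 2, 0.5))
  ep$y <- 10 + 0.5 * ep$x + rnorm(nrow(ep), 0, 2)
  fit <- fit_interaction_model(ep)
  X <- stats::model.matrix(~ x + country + year + x:country,
                           transform(ep, country = factor(country),
                                     year = factor(year)))
  o <- oracle_ols(X, ep$y)
  expect_equal(unname(coef(fit)), unname(o$beta), tolerance = 1e-8)
  expect_equal(fit$sigma2, o$sigma2, tolerance = 1e-8)
  sm <- summary(fit$lm)$coefficients
  expect_equal(unname(sm[, 2]), unname(o$se), tolerance = 1e-8)
  expect_equal(unname(sm[, 4]), unname(o$p), tolerance = 1e-8)
})

test_that("a single country-year reduces to simple regression", {
  set.seed(3)
  ep <- data.frame(country = "A", year = 2020, month = 1:12,
                   x = runif(12, 5, 15))
  ep$y <- 3 + 0.7 * ep$x + rnorm(12, 0, 0.5)
  fit <- fit_interaction_model(ep)
  slope_hand <- sum((ep$x - mean(ep$x)) * (ep$y - mean(ep$y))) /
    sum((ep$x - mean(ep$x))^2)
  expect_equal(unname(coef(fit)["x"]), slope_hand, tolerance = 1e-10)
  cls <- classify_effects(fit)
  expect_equal(cls$slope, slope_hand, tolerance = 1e-10)
})

test_that("rank-deficient designs fail with the collinear columns named", {
  ep <- expand.grid(month = 1:12, year = 2019:2020, country = c("A", "B"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ep$x <- ifelse(ep$country == "A", 4, 9)   # x constant within country
  ep$y <- rnorm(nrow(ep))
  expect_error(fit_interaction_model(ep), "collinear")
})

test_that("classification follows slope sign and significance", {
  p <- generate_volume_panel(panel_config(seed = 21))
  fit <- fit_interaction_model(build_effect_panel(p))
  cls <- classify_effects(fit, alpha = 0.05)
  expect_true(all(cls$label[cls$p_value < 0.05 & cls$slope < 0] == "compensatory"))
  expect_true(all(cls$label[cls$p_value < 0.05 & cls$slope > 0] == "noncompensatory"))
  expect_true(all(cls$label[cls$p_value >= 0.05] == "none"))
  # vanishing alpha labels everything none when no coupling is planted
  p0 <- generate_volume_panel(panel_config(n_countries = 8, n_themes = 8,
                                           interaction_sign = rep(0L, 8),
                                           shock_start = NULL, seed = 22))
  fit0 <- fit_interaction_model(build_effect_panel(p0))
  expect_true(all(classify_effects(fit0, alpha = 1e-15)$label == "none"))
  expect_error(classify_effects(fit, alpha = 0), "alpha")
  expect_error(classify_effects(fit, alpha = 1), "alpha")
})

test_that("flipping every planted sign swaps the two effect labels", {
  signs <- rep(c(-1L, 1L, 0L), c(4, 4, 4))
  cfg <- function(s) panel_config(n_countries = 12, n_themes = 10,
                                  interaction_sign = s, shock_start = NULL,
                                  noise_dispersion = 0.05, seed = 17)
  cls_a <- classify_effects(fit_interaction_model(build_effect_panel(
    generate_volume_panel(cfg(signs)))))
  cls_b <- classify_effects(fit_interaction_model(build_effect_panel(
    generate_volume_panel(cfg(-signs)))))
  swap <- c(compensatory = "noncompensatory", noncompensatory = "compensatory",
            none = "none")
  signed <- signs != 0
  expect_equal(unname(swap[cls_a$label[signed]]), cls_b$label[signed])
})

test_that("labels are invariant to a global positive rescaling of volumes", {
  p <- generate_volume_panel(panel_config(n_countries = 10, n_themes = 8, seed = 6))
  ep <- build_effect_panel(p)
  cls <- classify_effects(fit_interaction_model(ep))
  ep2 <- transform(ep, x = 7.3 * x, y = 7.3 * y, total = 7.3 * total)
  cls2 <- classify_effects(fit_interaction_model(ep2))
  expect_equal(cls$label, cls2$label)
  expect_equal(cls$p_value, cls2$p_value, tolerance = 1e-9)
})

test_that("fit object methods behave like a regression fit", {
  p <- generate_volume_panel(panel_config(n_countries = 5, n_themes = 6, seed = 2))
  ep <- build_effect_panel(p)
  fit <- fit_interaction_model(ep)
  expect_s3_class(fit, "effect_fit")
  expect_equal(length(residuals(fit)), nrow(ep))
  expect_equal(unname(predict(fit) + residuals(fit)), ep$y, tolerance = 1e-9)
  expect_output(print(fit), "interaction model")
  sm <- summary(fit)
  expect_output(print(sm), "compensatory")
  nd <- ep[1:3, c("x", "country", "year")]
  expect_equal(unname(predict(fit, nd)), unname(predict(fit)[1:3]), tolerance = 1e-9)
})
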