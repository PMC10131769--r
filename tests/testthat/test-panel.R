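hand_panel <- function(vol, countries, themes, months) {
  volume_panel(array(vol, c(length(countries), length(themes), nrow(months))),
               countries, themes, months)
}

test_that("volume panels round-trip through long CSV losslessly", {
  p <- generate_volume_panel(panel_config(n_countries = 3, n_themes = 4,
                                          months = month_seq(2019, 1, 2019, 12),
                                          seed = 2))
  tmp <- tempfile(fileext = ".csv")
  write_volume_panel(p, tmp)
  p2 <- read_volume_panel(tmp)
  expect_equal(p2$volume, p$volume, tolerance = 1e-12)
  expect_equal(p2$months, p$months)
})

test_that("a single window is returned unchanged by stitching", {
  w <- data.frame(term = c("a", "a", "b", "b"), year = 2020,
                  month = c(1, 2, 1, 2), value = c(100, 50, 30, 20))
  out <- stitch_windows(list(w))
  expect_equal(out$volume[order(out$term, out$month)],
               w$value[order(w$term, w$month)])
})

test_that("a known anchor ratio rescales the second window", {
  w1 <- data.frame(term = "a", year = 2020, month = 1:3, value = c(80, 90, 100))
  w2 <- data.frame(term = "a", year = 2020, month = 3:5, value = c(50, 40, 30))
  out <- stitch_windows(list(w1, w2))
  expect_equal(out$volume[out$month == 5], 30 * 2)  # anchor 100 vs 50 -> x2
  expect_equal(out$volume[out$month == 3], 100)
})

test_that("window round trip recovers planted truth up to one global constant", {
  set.seed(4)
  months <- month_seq(2004, 1, 2006, 12)
  truth <- expand.grid(term = c("anchor", "b", "c"), mi = seq_len(nrow(months)),
                       stringsAsFactors = FALSE)
  truth$year <- months$year[truth$mi]; truth$month <- months$month[truth$mi]
  truth$volume <- exp(rnorm(nrow(truth), 3, 0.7))
  truth$mi <- NULL
  windows <- make_normalized_windows(truth, window_months = 10, overlap = 2)
  expect_gt(length(windows), 2)
  expect_equal(vapply(windows, function(w) max(w$value), 0),
               rep(100, length(windows)), tolerance = 1e-12)
  out <- stitch_windows(windows)
  m <- merge(out, truth, by = c("term", "year", "month"))
  ratio <- m$volume.x / m$volume.y
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})

test_that("stitching is reference-invariant up to a global constant", {
  set.seed(5)
  months <- month_seq(2010, 1, 2011, 12)
  truth <- expand.grid(term = c("a", "b"), mi = seq_len(nrow(months)),
                       stringsAsFactors = FALSE)
  truth$year <- months$year[truth$mi]; truth$month <- months$month[truth$mi]
  truth$volume <- exp(rnorm(nrow(truth), 2, 0.5)); truth$mi <- NULL
  ws <- make_normalized_windows(truth, 8, 2)
  a <- stitch_windows(ws)
  b <- stitch_windows(rev(ws))  # same chain walked from the other end
  m <- merge(a, b, by = c("term", "year", "month"))
  ratio <- m$volume.x / m$volume.y
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})

test_that("stitching fails loudly without a positive shared anchor", {
  w1 <- data.frame(term = "a", year = 2020, month = 1:2, value = c(100, 50))
  w2 <- data.frame(term = "a", year = 2020, month = 4:5, value = c(100, 50))
  expect_error(stitch_windows(list(w1, w2)), "windows 1 and 2")
  w3 <- data.frame(term = "b", year = 2020, month = 2:3, value = c(100, 50))
  expect_error(stitch_windows(list(w1, w3)), "anchor")
})

test_that("annual volumes sum months and flag partial years", {
  months <- month_seq(2019, 1, 2019, 12)
  p <- hand_panel(rep(2, 12), "A", "t", months)
  ann <- annual_volume(p)
  expect_equal(ann$volume, 24)
  expect_true(ann$complete)
  p2 <- hand_panel(1:12, "A", "t", months)
  expect_equal(annual_volume(p2)$volume, 78)
  # NA month -> incomplete, not imputed
  v <- array(1, c(1, 1, 12)); v[1, 1, 5] <- NA
  p3 <- volume_panel(v, "A", "t", months)
  ann3 <- annual_volume(p3)
  expect_false(ann3$complete)
  expect_equal(ann3$n_months, 11)
  # partial calendar coverage is flagged even without NAs
  p4 <- hand_panel(rep(1, 6), "A", "t", month_seq(2019, 1, 2019, 6))
  expect_false(annual_volume(p4)$complete)
})

test_that("annual volume is additive over theme subsets", {
  p <- generate_volume_panel(panel_config(n_countries = 2, n_themes = 6,
                                          months = month_seq(2018, 1, 2019, 12),
                                          seed = 9))
  whole <- annual_volume(p)
  split1 <- p; split1$volume <- p$volume[, 1:3, , drop = FALSE]
  split1$themes <- p$themes[1:3]
  split2 <- p; split2$volume <- p$volume[, 4:6, , drop = FALSE]
  split2$themes <- p$themes[4:6]
  part <- rbind(annual_volume(volume_panel(split1$volume, p$countries,
                                           split1$themes, p$months)),
                annual_volume(volume_panel(split2$volume, p$countries,
                                           split2$themes, p$months)))
  tot <- tapply(part$volume, paste(part$country, part$year), sum)
  whole_tot <- tapply(whole$volume, paste(whole$country, whole$year), sum)
  expect_equal(as.numeric(tot[names(whole_tot)]), as.numeric(whole_tot))
})

test_that("domain volumes honour the catalogue and the tie rule", {
  months <- month_seq(2020, 1, 2020, 12)
  cat6 <- data.frame(theme = paste0("t", 1:6),
                     domain = rep(c("personal", "familial", "societal"), each = 2),
                     timeframe = "long-term")
  p <- volume_panel(aperm(array(rep(c(5, 2, 2, 2, 3, 3), 12), c(6, 12, 1)),
                          c(3, 1, 2)), "A", paste0("t", 1:6), months)
  dv <- domain_volume(p, cat6)
  tot <- dv$totals
  expect_equal(tot$volume[tot$domain == "personal"], (5 + 2) * 12)
  expect_equal(tot$volume[tot$domain == "familial"], (2 + 2) * 12)
  expect_equal(tot$volume[tot$domain == "societal"], (3 + 3) * 12)
  expect_equal(sum(tot$volume), sum(p$volume))
  # equal totals across domains -> personal wins with tie flag
  expect_equal(dv$leading$domain, "personal")
  expect_false(dv$leading$tie)
  vol_eq <- aperm(array(rep(c(3, 3, 3, 3, 3, 3), 12), c(6, 12, 1)), c(3, 1, 2))
  p_eq <- volume_panel(vol_eq, "A", paste0("t", 1:6), months)
  dv_eq <- domain_volume(p_eq, cat6)
  expect_equal(dv_eq$leading$domain, "personal")
  expect_true(dv_eq$leading$tie)
  # single-domain catalogue
  cat_p <- data.frame(theme = paste0("t", 1:6), domain = "personal",
                      timeframe = "short-term")
  dvp <- domain_volume(p, cat_p)
  expect_equal(dvp$totals$volume[dvp$totals$domain != "personal"], c(0, 0))
  expect_error(domain_volume(p, cat6[-1, ]), "t1")
})

test_that("top themes rank annual volumes with deterministic ties", {
  months <- month_seq(2020, 1, 2020, 12)
  vol <- aperm(array(rep(c(5, 9, 1), 12), c(3, 12, 1)), c(3, 1, 2))
  p <- volume_panel(vol, "A", c("a", "b", "c"), months)
  expect_equal(top_themes(p, "A", 2020, 2), c("b", "a"))
  expect_equal(top_themes(p, "A", 2020, 3), c("b", "a", "c"))
  expect_error(top_themes(p, "A", 2020, 4), "exceeds")
  vol_eq <- array(1, c(1, 3, 12))
  p_eq <- volume_panel(vol_eq, "A", c("c", "a", "b"), months)
  expect_equal(top_themes(p_eq, "A", 2020, 1), "a")
})

test_that("total volume series sums themes elementwise", {
  months <- month_seq(2020, 1, 2020, 3)
  vol <- array(c(1, 2, 3, 4, 5, 6), c(1, 2, 3))
  p <- volume_panel(vol, "A", c("t1", "t2"), months)
  expect_equal(unname(total_volume_series(p)[1, ]), c(1 + 2, 3 + 4, 5 + 6))
  single <- volume_panel(vol[, 1, , drop = FALSE], "A", "t1", months)
  expect_equal(unname(total_volume_series(single)[1, ]), c(1, 3, 5))
  zero <- volume_panel(array(0, c(2, 2, 3)), c("A", "B"), c("t1", "t2"), months)
  expect_true(all(total_volume_series(zero) == 0))
})
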