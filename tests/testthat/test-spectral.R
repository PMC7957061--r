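make_trace <- function(x, fs = 1e5) {
  tibble::tibble(time_ms = (seq_along(x) - 1) / fs * 1000, ca_nM = x)
}

test_that("band power: sentinels, variance scaling, leakage and Parseval", {
  fs <- 1e5
  n <- 3000
  # constant trace: zero band power, reported as missing
  flat <- band_power_db(make_trace(rep(5, n)), window_ms = c(12, 21))
  expect_true(is.na(flat$power_db))
  expect_equal(flat$power_linear, 0)
  withr::with_seed(11, x <- rnorm(n))
  tr <- make_trace(x)
  # doubling the amplitude adds exactly 10 log10(4) ~ 6.02 dB
  p1 <- band_power_db(tr, window_ms = c(12, 21))
  tr2 <- tr
  tr2$ca_nM <- 2 * tr2$ca_nM
  p2 <- band_power_db(tr2, window_ms = c(12, 21))
  expect_equal(p2$power_db - p1$power_db, 10 * log10(4), tolerance = 1e-9)
  # a 300 Hz unit sinusoid over the 9 ms window keeps >= 95% of its power
  # in the 100-500 Hz band despite rectangular-window leakage (phase taken
  # at the window start; an arbitrary phase shifts a few percent more into
  # the sidelobes)
  tt <- seq(0, 30e-3, by = 1 / fs)
  sine <- make_trace(sin(2 * pi * 300 * (tt - 12e-3)))
  pb <- band_power_db(sine, window_ms = c(12, 21))
  ptot <- band_power_db(sine, band_hz = c(0, fs / 2), window_ms = c(12, 21))
  expect_gte(pb$power_linear / ptot$power_linear, 0.95)
  sine2 <- make_trace(sin(2 * pi * 300 * tt))
  pb2 <- band_power_db(sine2, window_ms = c(12, 21))
  ptot2 <- band_power_db(sine2, band_hz = c(0, fs / 2), window_ms = c(12, 21))
  expect_gte(pb2$power_linear / ptot2$power_linear, 0.90)
  # window resolution metadata: 900 samples -> ~111 Hz
  expect_equal(pb$n, 900)
  expect_equal(pb$freq_resolution_hz, fs / 900)
  # Parseval: total one-sided power equals the biased segment variance
  seg <- x[1201:2100]
  expect_equal(ptot$power_linear * 0 + band_power_db(tr, band_hz = c(0, fs / 2),
                                                     window_ms = c(12, 21))$power_linear,
               mean((seg - mean(seg))^2), tolerance = 1e-9)
  # widening the band never loses power
  p_narrow <- band_power_db(tr, band_hz = c(200, 400), window_ms = c(12, 21))
  p_wide <- band_power_db(tr, band_hz = c(100, 500), window_ms = c(12, 21))
  expect_gte(p_wide$power_linear, p_narrow$power_linear)
  # guard rails
  expect_error(band_power_db(make_trace(x[1:100]), window_ms = c(12, 21)),
               "window")
  expect_error(band_power_db(tr, band_hz = c(100, 6e4), window_ms = c(12, 21)),
               "Nyquist")
})

test_that("power-vs-SVR regression matches the normal-equation oracle", {
  # hand-computed via solve(t(X) X) t(X) y on this 5-point set
  pts <- tibble::tibble(svr = c(5, 10, 15, 25, 35),
                        power_db = c(-30, -27, -25.5, -20, -16))
  fit <- power_vs_svr_regression(pts)
  g <- glance(fit)
  expect_equal(g$slope, 0.4663793, tolerance = 1e-6)
  expect_equal(g$intercept, -32.09483, tolerance = 1e-6)
  expect_equal(g$r.squared, 0.9949185, tolerance = 1e-6)
  expect_equal(g$n, 5L)
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "svr"))
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  # exactly collinear points: R^2 = 1 (lm warns about the perfect fit)
  col <- tibble::tibble(svr = 1:6, power_db = 2 * (1:6) - 40)
  expect_equal(suppressWarnings(glance(power_vs_svr_regression(col))$r.squared), 1)
  # slope-zero data: confidence interval covers zero
  withr::with_seed(13, {
    null <- tibble::tibble(svr = runif(40, 3, 35), power_db = rnorm(40, -25, 2))
    gn <- glance(power_vs_svr_regression(null))
    expect_lt(abs(gn$slope), 2.1 * gn$slope.se)
    expect_lt(gn$r.squared, 0.2)
  })
  expect_error(power_vs_svr_regression(pts[1:2, ]), "at least 3")
  expect_error(power_vs_svr_regression(
    tibble::tibble(svr = rep(5, 5), power_db = rnorm(5))), "Degenerate")
})

test_that("one-way ANOVA equals its classical constructions", {
  # identical groups: F = 0, p = 1
  a <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3)))
  expect_equal(a$statistic, 0)
  expect_equal(a$p.value, 1)
  # two groups: F is the squared pooled-variance t statistic
  withr::with_seed(19, {
    x <- rnorm(12)
    y <- rnorm(10, 0.8)
    a2 <- one_way_anova(list(x = x, y = y))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(a2$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(a2$p.value, tt$p.value, tolerance = 1e-9)
    # three groups against a brute-force sum-of-squares oracle
    g <- list(a = rnorm(8, 0), b = rnorm(9, 0.5), c = rnorm(7, 1))
    a3 <- one_way_anova(g)
    gm <- mean(unlist(g))
    ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
    ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
    f_oracle <- (ssb / 2) / (ssw / (24 - 3))
    expect_equal(a3$statistic, f_oracle, tolerance = 1e-9)
    expect_equal(a3$p.value, pf(f_oracle, 2, 21, lower.tail = FALSE),
                 tolerance = 1e-12)
    # permutation agreement on a small two-group sample
    x2 <- rnorm(8)
    y2 <- rnorm(8, 1.0)
    pobs <- one_way_anova(list(x2, y2))
    pool <- c(x2, y2)
    fstat <- function(idx) {
      one_way_anova(list(pool[idx], pool[-idx]))$statistic
    }
    perm <- replicate(1e4, fstat(sample.int(16, 8)))
    p_perm <- mean(perm >= pobs$statistic)
    expect_lt(abs(p_perm - pobs$p.value), 0.02)
  })
  expect_error(one_way_anova(list(c(1, 2), numeric(0))), "Empty group")
  expect_error(one_way_anova(list(c(1, 2))), "two groups")
  expect_error(one_way_anova(list(c(1, 2), 3)), "at least two observations")
})

test_that("SVR binning reports exact group summaries and flags empty bins", {
  df <- tibble::tibble(svr = c(2, 4, 6, 22, 24, 26), power_db = c(1, 2, 3, 7, 8, 9))
  # all points in one bin: bin mean equals the global mean
  one <- group_powers_by_svr(df, c(0, 100))
  expect_equal(one$mean_db[1], mean(df$power_db))
  expect_equal(one$sem_db[1], sd(df$power_db) / sqrt(6))
  # brute-force group-by with an empty middle bin
  g3 <- group_powers_by_svr(df, c(0, 10, 20, 30))
  expect_equal(g3$n, c(3L, 0L, 3L))
  expect_equal(g3$mean_db, c(2, NA, 8))
  expect_equal(g3$sem_db[3], sd(c(7, 8, 9)) / sqrt(3))
  expect_equal(g3$svr_lo, c(0, 10, 20))
  expect_error(group_powers_by_svr(df, c(10, 10)), "increasing")
})
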