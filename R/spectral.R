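#' Band power of a concentration trace, in dB
#'
#' The analysis window (default 12-21 ms) is extracted, mean-subtracted and
#' turned into a single-segment rectangular-window periodogram (one-sided
#' density, `|X_k|^2 * 2 / (fs N)` scaling, so the density summed over bins
#' times the bin width equals the segment variance). Power is the sum of
#' density times bin width over bins whose centre frequency falls inside the
#' band, and is reported as `10 log10` relative to 1 (unit of the trace)^2.
#' With a 9 ms window the frequency resolution is ~111 Hz; this is inherent
#' to a short-window estimate and is carried in the result.
#'
#' @param trace numeric vector, or a tibble with `time_ms` and a value column
#'   (e.g. the `$trace` of a `calf_sim`).
#' @param sampling_rate_hz sampling rate; inferred from `time_ms` if given a
#'   tibble.
#' @param band_hz frequency band, Hz (default 100-500).
#' @param window_ms analysis window, ms (default 12-21), interpreted as
#'   `[lo, hi)`; must lie inside the trace.
#' @param value column to analyse when `trace` is a tibble.
#' @return one-row tibble (class `calf_bandpower`): `power_db` (`NA` for a
#'   constant segment, whose band power is zero), `power_linear`, `band_lo_hz`,
#'   `band_hi_hz`, `window_lo_ms`, `window_hi_ms`, `sampling_rate_hz`,
#'   `freq_resolution_hz`, `n`.
#' @export
band_power_db <- function(trace, sampling_rate_hz = NULL,
                          band_hz = c(100, 500), window_ms = c(12, 21),
                          value = "ca_nM") {
  if (is.data.frame(trace)) {
    if (is.null(sampling_rate_hz)) {
      dt_ms <- diff(trace$time_ms[1:2])
      sampling_rate_hz <- 1000 / dt_ms
    }
    keep <- trace$time_ms >= window_ms[1] & trace$time_ms < window_ms[2]
    if (!any(keep)) abort("Analysis window lies outside the trace.")
    x <- trace[[value]][keep]
  } else {
    if (is.null(sampling_rate_hz)) abort("`sampling_rate_hz` is required for a bare vector.")
    i0 <- floor(window_ms[1] * sampling_rate_hz / 1000) + 1
    i1 <- ceiling(window_ms[2] * sampling_rate_hz / 1000)
    if (i0 < 1 || i1 > length(trace) || i1 <= i0) {
      abort("Analysis window lies outside the trace.")
    }
    x <- trace[i0:min(i1, length(trace))]
  }
  if (band_hz[2] > sampling_rate_hz / 2) {
    abort("Band extends above the Nyquist frequency.")
  }
  n <- length(x)
  x <- x - mean(x)
  out <- tibble(power_db = NA_real_, power_linear = 0,
                band_lo_hz = band_hz[1], band_hi_hz = band_hz[2],
                window_lo_ms = window_ms[1], window_hi_ms = window_ms[2],
                sampling_rate_hz = sampling_rate_hz,
                freq_resolution_hz = sampling_rate_hz / n, n = n)
  class(out) <- c("calf_bandpower", class(out))
  if (all(x == 0)) return(out)
  xk <- fft(x)
  kmax <- floor(n / 2)
  k <- seq_len(kmax)                      # positive-frequency bins
  dens <- (Mod(xk[k + 1])^2) * 2 / (sampling_rate_hz * n)
  if (n %% 2 == 0) dens[kmax] <- dens[kmax] / 2  # Nyquist bin is not doubled
  freq <- k * sampling_rate_hz / n
  df <- sampling_rate_hz / n
  in_band <- freq >= band_hz[1] & freq <= band_hz[2]
  p <- sum(dens[in_band]) * df
  out$power_linear <- p
  out$power_db <- if (p > 0) 10 * log10(p) else NA_real_
  out
}

# full one-sided PSD of a mean-removed segment (internal; Parseval-consistent
# with band_power_db)
psd_one_sided <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  xk <- fft(x)
  kmax <- floor(n / 2)
  k <- seq_len(kmax)
  dens <- (Mod(xk[k + 1])^2) * 2 / (fs * n)
  if (n %% 2 == 0) dens[kmax] <- dens[kmax] / 2
  tibble(freq_hz = k * fs / n, density = dens, df_hz = fs / n)
}

#' Ordinary least-squares regression of band power on astrocytic SVR
#'
#' @param points data frame with columns `svr` (or `svr_um_inv`) and
#'   `power_db`; rows with missing power are dropped.
#' @return a `calf_regression` wrapping the [stats::lm()] fit; supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
power_vs_svr_regression <- function(points) {
  df <- as_tibble(points)
  if (!"svr" %in% names(df) && "svr_um_inv" %in% names(df)) {
    df$svr <- df$svr_um_inv
  }
  stopifnot(all(c("svr", "power_db") %in% names(df)))
  df <- df[is.finite(df$svr) & is.finite(df$power_db), ]
  if (nrow(df) < 3) abort("Need at least 3 finite points for the regression.")
  if (sd(df$svr) == 0) abort("Degenerate design: all SVR values are equal.")
  fit <- lm(power_db ~ svr, data = df)
  structure(list(fit = fit, data = df), class = "calf_regression")
}

#' @export
print.calf_regression <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<calf_regression> power_db ~ svr: slope %.3f dB/um^-1, R^2 = %.3f, n = %d, p = %.3g\n",
              g$slope, g$r.squared, g$n, g$p.value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.calf_regression <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.calf_regression <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble(r.squared = s$r.squared,
         slope = co["svr", 1], intercept = co["(Intercept)", 1],
         slope.se = co["svr", 2],
         statistic = co["svr", 3], p.value = co["svr", 4],
         n = nrow(x$data))
}

#' Classical one-way analysis of variance
#'
#' Between-group over within-group mean squares, with the p value from the F
#' distribution (equal-variance classical ANOVA, computed by
#' [stats::oneway.test()] with `var.equal = TRUE`).
#'
#' @param groups a list of numeric samples, or a data frame with `value` and
#'   `group` columns.
#' @param value,group column names when a data frame is given.
#' @return one-row tibble: `statistic` (F), `p.value`, `df_between`,
#'   `df_within`, `n_groups`.
#' @export
one_way_anova <- function(groups, value = "value", group = "group") {
  if (is.data.frame(groups)) {
    df <- tibble(value = groups[[value]], group = as.factor(groups[[group]]))
  } else {
    if (any(vapply(groups, length, integer(1)) == 0L)) {
      abort("Empty group supplied to the ANOVA.")
    }
    nm <- names(groups) %||% paste0("g", seq_along(groups))
    df <- tibble(value = unlist(groups),
                 group = factor(rep(nm, vapply(groups, length, integer(1)))))
  }
  if (nlevels(df$group) < 2) abort("Need at least two groups.")
  if (any(table(df$group) < 2)) abort("Every group needs at least two observations.")
  ft <- oneway.test(value ~ group, data = df, var.equal = TRUE)
  f <- unname(ft$statistic)
  tibble(statistic = f,
         p.value = unname(ft$p.value),
         df_between = unname(ft$parameter[1]),
         df_within = unname(ft$parameter[2]),
         n_groups = nlevels(df$group))
}

#' Bin band powers by astrocytic SVR
#'
#' @param results data frame with `svr` (or `svr_um_inv`) and `power_db`.
#' @param bin_edges strictly increasing numeric bin edges.
#' @return tibble with one row per bin (empty bins reported with `NA`
#'   summaries): `bin`, `svr_lo`, `svr_hi`, `n`, `mean_db`, `sem_db`.
#' @export
group_powers_by_svr <- function(results, bin_edges) {
  if (any(diff(bin_edges) <= 0)) abort("`bin_edges` must be strictly increasing.")
  df <- as_tibble(results)
  if (!"svr" %in% names(df) && "svr_um_inv" %in% names(df)) df$svr <- df$svr_um_inv
  df$bin <- cut(df$svr, bin_edges, include.lowest = TRUE)
  lv <- levels(df$bin)
  df |>
    dplyr::filter(!is.na(.data$bin), is.finite(.data$power_db)) |>
    dplyr::group_by(bin = factor(.data$bin, levels = lv)) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_db = mean(.data$power_db),
                     sem_db = sd(.data$power_db) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    tidyr::complete(bin = factor(lv, levels = lv),
                    fill = list(n = 0L)) |>
    dplyr::mutate(svr_lo = bin_edges[as.integer(.data$bin)],
                  svr_hi = bin_edges[as.integer(.data$bin) + 1L]) |>
    dplyr::relocate("bin", "svr_lo", "svr_hi")
}

#' Band powers for every run in a condition grid
#'
#' @param grid result of [run_condition_grid()].
#' @param svr optional tibble `synapse_id` -> `svr_um_inv` to join in (e.g. a
#'   [make_population()] manifest).
#' @param ... passed to [band_power_db()].
#' @return the grid with `power_db` and band metadata columns (and `svr` when
#'   provided), `result` dropped.
#' @export
grid_band_powers <- function(grid, svr = NULL, ...) {
  bp <- purrr::map(grid$result, function(r) band_power_db(r$trace, ...))
  out <- dplyr::bind_cols(dplyr::select(grid, -"result"),
                          dplyr::bind_rows(lapply(bp, as.data.frame)))
  if (!is.null(svr)) {
    out <- dplyr::left_join(out,
                            dplyr::select(svr, "synapse_id", "svr_um_inv"),
                            by = "synapse_id")
    out$svr <- out$svr_um_inv
  }
  out
}
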