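#' Assemble the cross-study meta-dataset
#'
#' Applies the grouping and exclusion rules used to build the latitudinal
#' comparison: rows sharing a `region_id` (replicate populations within a
#' region, e.g. regional groupings of nearby populations) are averaged into
#' one data point per region; records whose allocation `measure` is `"RE"`
#' rather than `"annRA"` are excluded from the annRA response (their annRA is
#' set to `NA`, since RE is not comparable to annRA) and dropped entirely
#' when they carry no phenology either; `peak_month` entries are converted to
#' approximate Julian days where `peak_jd` is absent. The same `region_id`
#' supplied by two different sources is rejected as a duplicate.
#'
#' The operation is idempotent: assembling an assembled table returns it
#' unchanged.
#'
#' @param records Data frame with columns `region_id`, `latitude_degN`,
#'   `sst_mean_C`, `annRA`, `peak_month`, `peak_jd`, `source` and optionally
#'   `measure` (defaults to `"annRA"` where an annRA value is present).
#' @param wrap_policy Passed to [month_to_julian_day()].
#' @return Tibble with one row per region: `region_id`, `latitude_degN`,
#'   `sst_mean_C`, `annRA`, `peak_jd`, `n_populations`, `source`; attribute
#'   `exclusions` logs dropped or masked records.
#' @export
assemble_meta_table <- function(records,
                                wrap_policy = c("autumn-negative", "none")) {
  wrap_policy <- match.arg(wrap_policy)
  records <- tibble::as_tibble(records)
  need <- c("region_id", "latitude_degN", "annRA")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"sst_mean_C" %in% names(records)) records$sst_mean_C <- NA_real_
  if (!"peak_month" %in% names(records)) records$peak_month <- NA_integer_
  if (!"peak_jd" %in% names(records)) records$peak_jd <- NA_real_
  if (!"source" %in% names(records)) records$source <- NA_character_
  if (!"measure" %in% names(records)) {
    records$measure <- ifelse(is.na(records$annRA), NA_character_, "annRA")
  }
  if ("n_populations" %in% names(records)) {
    np <- records$n_populations
  } else {
    np <- rep(1L, nrow(records))
  }
  records$n_populations <- ifelse(is.na(np), 1L, as.integer(np))

  exclusions <- character()
  re_only <- !is.na(records$measure) & records$measure == "RE"
  if (any(re_only)) {
    exclusions <- c(exclusions, sprintf(
      "%s: measure is RE, not annRA; excluded from the annRA response",
      records$region_id[re_only]))
    records$annRA[re_only] <- NA_real_
  }
  jd <- records$peak_jd
  use_month <- is.na(jd) & !is.na(records$peak_month)
  jd[use_month] <- month_to_julian_day(records$peak_month[use_month], wrap_policy)
  records$peak_jd <- as.numeric(jd)

  no_response <- is.na(records$annRA) & is.na(records$peak_jd)
  if (any(no_response)) {
    exclusions <- c(exclusions, sprintf(
      "%s: no usable response (neither annRA nor reproduction peak); dropped",
      records$region_id[no_response]))
    records <- records[!no_response, , drop = FALSE]
  }

  grouped <- dplyr::summarise(
    dplyr::group_by(records, .data$region_id),
    latitude_degN = mean(.data$latitude_degN),
    sst_mean_C = mean(.data$sst_mean_C),
    annRA = if (all(is.na(.data$annRA))) NA_real_ else
      mean(.data$annRA, na.rm = TRUE),
    peak_jd = if (all(is.na(.data$peak_jd))) NA_real_ else
      mean(.data$peak_jd, na.rm = TRUE),
    n_populations = sum(.data$n_populations),
    n_sources = length(unique(.data$source[!is.na(.data$source)])),
    source = paste(unique(.data$source[!is.na(.data$source)]), collapse = ";"),
    .groups = "drop")
  dup <- grouped$n_sources > 1
  if (any(dup)) {
    stop("duplicate region(s) from different sources: ",
         paste(grouped$region_id[dup], collapse = ", "), call. = FALSE)
  }
  grouped$n_sources <- NULL
  structure(grouped, exclusions = exclusions)
}

#' Simple linear regression with the reporting conventions of the analysis
#'
#' Ordinary least squares of `y` on `x` with a two-sided t-test on the slope,
#' the adjusted R-squared `1 - (1 - R2)(n - 1)/(n - 2)`, and a Shapiro-Wilk
#' test on the residuals as the normality diagnostic. Results are reported
#' alongside the conventional alpha = 0.05 and the conservative alpha = 0.01
#' without enforcing either.
#'
#' @param x Predictor values (not constant).
#' @param y Response values, same length, n >= 3.
#' @return An `asco_ols`: `slope`, `intercept`, `r_squared`, `adj_r_squared`,
#'   `p_value`, `n`, `shapiro_p`, plus the `lm` fit.
#' @export
#' @examples
#' f <- ols_fit(1:5, 2 * (1:5) + 1)
#' c(f$slope, f$intercept, f$r_squared)  # 2 1 1
ols_fit <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete (x, y) pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("predictor is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  r2 <- sm$r.squared
  shapiro_p <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                        error = function(e) NA_real_)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
         p_value = sm$coefficients["x", "Pr(>|t|)"],
         n = n,
         shapiro_p = shapiro_p,
         fit = fit),
    class = "asco_ols")
}

#' @export
print.asco_ols <- function(x, ...) {
  cat(sprintf("<asco_ols> y = %.4g %+.4g x;  adj R2 = %.2f, p = %.3g, n = %d\n",
              x$intercept, x$slope, x$adj_r_squared, x$p_value, x$n))
  invisible(x)
}

#' Pearson correlation between two candidate predictors
#'
#' Collinearity screen for the meta-regression: strongly correlated
#' predictors (latitude and SST) are tested in separate univariate
#' regressions rather than one multivariate model.
#'
#' @param x1,x2 Numeric vectors, n >= 3, neither constant.
#' @return Pearson product-moment correlation in \[-1, 1\].
#' @export
collinearity <- function(x1, x2) {
  ok <- stats::complete.cases(x1, x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  if (length(x1) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  stats::cor(x1, x2)
}

#' The four headline meta-regressions
#'
#' Separate univariate OLS fits of annual reproductive allocation and of
#' reproduction-peak Julian day on latitude and on mean SST, each using the
#' rows where both variables are available. Regressions with fewer than 3
#' usable points are reported as unavailable with the reason rather than
#' fitted.
#'
#' @param table Assembled meta table ([assemble_meta_table()]) with columns
#'   `latitude_degN`, `sst_mean_C`, `annRA`, `peak_jd`.
#' @return Named list (`annRA_latitude`, `annRA_sst`, `jd_latitude`,
#'   `jd_sst`) of [ols_fit()] results; an unavailable regression is an
#'   `asco_ols_unavailable` stub carrying the `reason`.
#' @export
run_headline_regressions <- function(table) {
  table <- tibble::as_tibble(table)
  need <- c("latitude_degN", "sst_mean_C", "annRA", "peak_jd")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  spec <- list(
    annRA_latitude = c("latitude_degN", "annRA"),
    annRA_sst = c("sst_mean_C", "annRA"),
    jd_latitude = c("latitude_degN", "peak_jd"),
    jd_sst = c("sst_mean_C", "peak_jd"))
  lapply(spec, function(v) {
    x <- table[[v[1]]]; y <- table[[v[2]]]
    n_ok <- sum(stats::complete.cases(x, y))
    if (n_ok < 3) {
      return(structure(
        list(reason = sprintf("only %d usable points for %s ~ %s",
                              n_ok, v[2], v[1])),
        class = "asco_ols_unavailable"))
    }
    ols_fit(x, y)
  })
}
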