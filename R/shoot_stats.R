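#' Receptacle counts per segment age, long format
#'
#' Extracts the primary-axis count-age table used by the count model. Most
#' shoots are not older than 12 years, so segments beyond `max_age` are
#' excluded (the number dropped is attached as attribute `n_excluded` and
#' reported via message).
#'
#' @param dataset An [site_dataset()].
#' @param max_age Oldest age retained (default 12).
#' @return Tibble (`shoot_id`, `age_years`, `receptacle_count`), one row per
#'   shoot x age.
#' @export
counts_by_age <- function(dataset, max_age = 12L) {
  stopifnot(inherits(dataset, "asco_site_dataset"))
  rows <- lapply(dataset$shoots, function(s) {
    tibble::tibble(shoot_id = s$shoot_id,
                   age_years = s$segments$age_years,
                   receptacle_count = s$segments$receptacle_count)
  })
  tab <- dplyr::bind_rows(rows)
  drop <- tab$age_years > max_age
  if (any(drop)) {
    message(sum(drop), " segment(s) older than ", max_age, " years excluded")
  }
  out <- tab[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Quadratic negative-binomial count-age model
#'
#' Fits the receptacle-formation model: counts are negative binomial with a
#' log link and a concave quadratic age trend,
#' log lambda = beta0 + beta1 age + beta2 age^2. `method = "pooled-NB"`
#' ignores the shoot grouping; `method = "NB-with-shoot-intercepts"` adds a
#' shoot-level random intercept, the hierarchical structure of repeated
#' measures along each primary axis (random slopes are deliberately not
#' fitted: they are fragile at typical within-site sample sizes of 10-14
#' shoots, and the scientific question is the sign and location of the
#' quadratic peak).
#'
#' The fitted peak age is -beta1 / (2 beta2) when beta2 < 0. All-zero counts
#' give a degenerate fit flagged via `converged = FALSE`; other fitting
#' failures are caught and flagged, returning partial results where possible.
#'
#' @param table Count-age table from [counts_by_age()] (columns `shoot_id`,
#'   `age_years`, `receptacle_count`).
#' @param method Fitting strategy, see above.
#' @return An `asco_count_fit`: list with `beta` (length 3), `dispersion_k`,
#'   `shoot_intercept_var` (mixed fit only), `argmax_age`, `converged`,
#'   `reason`, `method`, `n_obs`.
#' @export
fit_count_age <- function(table,
                          method = c("pooled-NB", "NB-with-shoot-intercepts")) {
  method <- match.arg(method)
  table <- tibble::as_tibble(table)
  stopifnot(all(c("shoot_id", "age_years", "receptacle_count") %in% names(table)))
  if (length(unique(table$age_years)) < 3) {
    stop("need at least 3 distinct segment ages", call. = FALSE)
  }
  if (length(unique(table$shoot_id)) < 2) {
    stop("need at least 2 shoots", call. = FALSE)
  }
  out <- structure(
    list(beta = c(beta0 = NA_real_, beta1 = NA_real_, beta2 = NA_real_),
         dispersion_k = NA_real_, shoot_intercept_var = NA_real_,
         argmax_age = NA_real_, converged = FALSE, reason = NULL,
         method = method, n_obs = nrow(table)),
    class = "asco_count_fit")
  if (all(table$receptacle_count == 0)) {
    out$reason <- "degenerate: all counts are zero"
    return(out)
  }
  if (method == "pooled-NB") {
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(
        receptacle_count ~ age_years + I(age_years^2), data = table)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      out$reason <- conditionMessage(fit)
      return(out)
    }
    out$beta[] <- unname(stats::coef(fit))
    out$dispersion_k <- fit$theta
    out$converged <- isTRUE(fit$converged) || is.null(fit$converged)
  } else {
    fit <- tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(
        receptacle_count ~ age_years + I(age_years^2) + (1 | shoot_id),
        family = glmmTMB::nbinom2, data = table)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      out$reason <- conditionMessage(fit)
      return(out)
    }
    out$beta[] <- unname(glmmTMB::fixef(fit)$cond)
    out$dispersion_k <- stats::sigma(fit)
    vc <- glmmTMB::VarCorr(fit)$cond$shoot_id
    out$shoot_intercept_var <- as.numeric(vc[1, 1])
    out$converged <- is.finite(fit$fit$objective) &&
      isTRUE(fit$sdr$pdHess %||% TRUE)
  }
  if (!is.na(out$beta[3]) && out$beta[3] < 0) {
    out$argmax_age <- -out$beta[2] / (2 * out$beta[3])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.asco_count_fit <- function(x, ...) {
  cat(sprintf("<asco_count_fit> %s, n=%d obs\n", x$method, x$n_obs))
  if (!x$converged) {
    cat("  NOT converged:", x$reason %||% "see fit", "\n")
  }
  cat(sprintf("  log lambda = %.3f %+.3f age %+.4f age^2   (k = %.3g)\n",
              x$beta[1], x$beta[2], x$beta[3], x$dispersion_k))
  if (!is.na(x$argmax_age)) cat(sprintf("  peak age: %.2f yr\n", x$argmax_age))
  invisible(x)
}

#' Linear receptacle size-age model
#'
#' Ordinary least squares of mean receptacle dry mass per segment age on age,
#' with a two-sided t-test on the slope. Operates on site-level means per
#' age (receptacles are pooled per age before weighing, so there is one
#' observation per age and no repeated-measures structure).
#'
#' @param mean_sizes Data frame with columns `age_years` and
#'   `mean_receptacle_mass` (g DW); at least 3 ages.
#' @return An `asco_size_fit`: `intercept` (g DW), `slope` (g DW yr^-1),
#'   `r_squared`, `p_value`, `n`, and the underlying `lm` fit.
#' @export
fit_size_age <- function(mean_sizes) {
  mean_sizes <- tibble::as_tibble(mean_sizes)
  stopifnot(all(c("age_years", "mean_receptacle_mass") %in% names(mean_sizes)))
  mean_sizes <- mean_sizes[stats::complete.cases(mean_sizes), ]
  if (nrow(mean_sizes) < 3) {
    stop("need at least 3 segment ages with pooled receptacle masses", call. = FALSE)
  }
  fit <- stats::lm(mean_receptacle_mass ~ age_years, data = mean_sizes)
  sm <- summary(fit)
  structure(
    list(intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients["age_years", "Pr(>|t|)"],
         n = nrow(mean_sizes),
         fit = fit),
    class = "asco_size_fit")
}

#' @export
print.asco_size_fit <- function(x, ...) {
  cat(sprintf("<asco_size_fit> RS = %.4g %+.4g SA;  R2 = %.2f, p = %.3g, n = %d\n",
              x$intercept, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Segment age by which half the receptacles are produced
#'
#' Counting from the apical tip (age 0) towards the origin, the smallest
#' segment age at which the cumulative receptacle count reaches at least 50%
#' of the shoot (or site) total. Ties resolve to the first age reaching the
#' threshold (>=). Invariant to rescaling all counts by a common positive
#' factor.
#'
#' @param counts Non-negative receptacle counts.
#' @param ages Segment ages matching `counts`; defaults to
#'   `0:(length(counts)-1)`.
#' @return The half-production age (integer-valued element of `ages`).
#' @export
#' @examples
#' cumulative_half_age(c(0, 2, 4, 6, 4, 2))  # 3
cumulative_half_age <- function(counts, ages = seq_along(counts) - 1) {
  stopifnot(length(counts) == length(ages), all(counts >= 0))
  o <- order(ages)
  counts <- counts[o]; ages <- ages[o]
  total <- sum(counts)
  if (total <= 0) stop("all counts are zero: half-production age undefined", call. = FALSE)
  ages[which(cumsum(counts) >= total / 2)[1]]
}
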