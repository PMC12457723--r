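#' Number of apical tips per shoot
#'
#' Annual tip production can be bracketed by the count of second-youngest
#' bladders (b1, an underestimate: tips formed this season are missed) and
#' the count of youngest bladders (b0, an overestimate: not all current tips
#' complete a segment). The working estimate is their arithmetic mean, which
#' may be half-integer.
#'
#' @param b0,b1 Whole-shoot bladder counts (integers >= 1).
#' @param method `"mean"` (default), `"b0"` or `"b1"`.
#' @return Tip count (numeric).
#' @export
#' @examples
#' tip_count(12, 8)  # 10
#' tip_count(7, 4)   # 5.5
tip_count <- function(b0, b1, method = c("mean", "b0", "b1")) {
  method <- match.arg(method)
  if (any(b0 < 1) || any(b1 < 1)) {
    stop("bladder counts must be >= 1", call. = FALSE)
  }
  switch(method,
         mean = (b0 + b1) / 2,
         b0 = as.numeric(b0),
         b1 = as.numeric(b1))
}

#' Annual vegetative growth of a shoot (annV)
#'
#' annV = mean S1 dry mass x number of tips: the newest fully formed annual
#' segment is the unit of apical growth, replicated over every growing tip of
#' the shoot.
#'
#' @param mean_s1_mass Mean dry mass of segment S1 (g DW, > 0); by convention
#'   a site-level mean over the sampled apical segments.
#' @param n_tips Tips per shoot (>= 1), typically from [tip_count()].
#' @return annV in g DW yr^-1.
#' @export
annual_vegetative_growth <- function(mean_s1_mass, n_tips) {
  if (any(mean_s1_mass <= 0)) stop("mean_s1_mass must be > 0", call. = FALSE)
  if (any(n_tips < 1)) stop("n_tips must be >= 1", call. = FALSE)
  mean_s1_mass * n_tips
}

#' Shoot vegetative biomass turnover rate
#'
#' The fraction of standing vegetative shoot biomass renewed annually:
#' annV / V.
#'
#' @param annV Annual vegetative growth (g DW yr^-1, > 0).
#' @param V Whole-shoot vegetative dry mass, receptacles excluded (g DW, > 0).
#' @return Turnover rate, yr^-1.
#' @export
turnover_rate <- function(annV, V) {
  if (any(annV <= 0)) stop("annV must be > 0", call. = FALSE)
  if (any(V <= 0)) stop("V must be > 0", call. = FALSE)
  annV / V
}

#' Reproductive effort (RE)
#'
#' R / V: annual reproductive biomass relative to standing vegetative shoot
#' biomass. Used descriptively, for comparability with older literature.
#'
#' @param R Annual reproductive (receptacle) dry mass, g DW (>= 0).
#' @param V Vegetative dry mass, g DW (> 0).
#' @return Dimensionless ratio >= 0.
#' @export
reproductive_effort <- function(R, V) {
  if (any(R < 0)) stop("R must be >= 0", call. = FALSE)
  if (any(V <= 0)) stop("V must be > 0", call. = FALSE)
  R / V
}

#' Annual reproductive allocation (annRA)
#'
#' annRA = R / (R + annV): the fraction of a shoot's annual production
#' invested in reproduction. Unlike RE it excludes older vegetative biomass,
#' so it compares more reliably across individuals and species.
#'
#' @param R Annual reproductive dry mass, g DW (>= 0).
#' @param annV Annual vegetative growth, g DW yr^-1 (>= 0; not both zero).
#' @return Fraction in \[0, 1\].
#' @export
annual_reproductive_allocation <- function(R, annV) {
  if (any(R < 0) || any(annV < 0)) {
    stop("R and annV must be non-negative", call. = FALSE)
  }
  if (any(R + annV == 0)) {
    stop("annRA is undefined when R and annV are both zero", call. = FALSE)
  }
  R / (R + annV)
}

#' Convert dry mass to carbon
#'
#' @param mass Dry mass, g DW (>= 0).
#' @param c_fraction Carbon content as a fraction of dry weight, in \[0, 1\].
#' @return g C.
#' @export
to_carbon <- function(mass, c_fraction) {
  if (any(mass < 0)) stop("mass must be >= 0", call. = FALSE)
  if (any(is.na(c_fraction)) || any(c_fraction < 0) || any(c_fraction > 1)) {
    stop("c_fraction must lie in [0, 1]", call. = FALSE)
  }
  mass * c_fraction
}

#' Annual reproductive allocation in carbon units
#'
#' annRA computed after converting both terms to carbon:
#' (R c_rep) / (R c_rep + annV c_veg). Receptacle tissue is typically poorer
#' in carbon than vegetative tissue, so the C-unit allocation lies below the
#' dry-mass allocation.
#'
#' @inheritParams annual_reproductive_allocation
#' @param c_rep,c_veg Carbon fractions of reproductive and vegetative dry
#'   mass, in \[0, 1\].
#' @return Fraction in \[0, 1\].
#' @export
carbon_allocation <- function(R, annV, c_rep, c_veg) {
  num <- to_carbon(R, c_rep)
  den <- num + to_carbon(annV, c_veg)
  if (any(den == 0)) {
    stop("carbon allocation undefined: zero total carbon production", call. = FALSE)
  }
  num / den
}

#' Per-shoot allocation statistics
#'
#' Composes the allocation equations for one shoot: tips, annV, turnover,
#' RE, annRA and C-unit annRA. The algebraic identity
#' annRA = RE / (RE + turnover) holds to machine precision. Broken shoots get
#' `NA` for the tip-count based quantities (annV, turnover, annRA) but keep
#' RE, which only needs measured R and V.
#'
#' @param x An [shoot()] object.
#' @param mean_s1_mass Mean S1 dry mass (g DW), normally the site-level mean.
#' @param c_rep,c_veg Carbon fractions; `NA` propagates to `annRA_C`.
#' @param tip_method Passed to [tip_count()].
#' @return One-row tibble: `shoot_id`, `broken`, `n_tips`, `annV`, `turnover`,
#'   `RE`, `annRA`, `annRA_C`.
#' @export
shoot_allocation <- function(x, mean_s1_mass,
                             c_rep = NA_real_, c_veg = NA_real_,
                             tip_method = c("mean", "b0", "b1")) {
  stopifnot(inherits(x, "asco_shoot"))
  tip_method <- match.arg(tip_method)
  RE <- reproductive_effort(x$reproductive_mass, x$vegetative_mass)
  if (x$broken) {
    return(tibble::tibble(
      shoot_id = x$shoot_id, broken = TRUE, n_tips = NA_real_,
      annV = NA_real_, turnover = NA_real_, RE = RE,
      annRA = NA_real_, annRA_C = NA_real_))
  }
  n <- tip_count(x$b0_count, x$b1_count, method = tip_method)
  annV <- annual_vegetative_growth(mean_s1_mass, n)
  tibble::tibble(
    shoot_id = x$shoot_id,
    broken = FALSE,
    n_tips = n,
    annV = annV,
    turnover = turnover_rate(annV, x$vegetative_mass),
    RE = RE,
    annRA = annual_reproductive_allocation(x$reproductive_mass, annV),
    annRA_C = if (is.na(c_rep) || is.na(c_veg)) NA_real_ else
      carbon_allocation(x$reproductive_mass, annV, c_rep, c_veg)
  )
}

#' Allocation statistics for every shoot of a site
#'
#' @param dataset An [site_dataset()].
#' @param mean_s1_mass Site mean S1 dry mass; default is the mean of the
#'   age-1 primary-axis segment masses over unbroken shoots, mirroring the
#'   site-level apical sampling design.
#' @param tip_method Passed to [tip_count()].
#' @return Tibble with one row per shoot (see [shoot_allocation()]).
#' @export
site_allocation <- function(dataset, mean_s1_mass = NULL,
                            tip_method = c("mean", "b0", "b1")) {
  stopifnot(inherits(dataset, "asco_site_dataset"))
  tip_method <- match.arg(tip_method)
  if (is.null(mean_s1_mass)) mean_s1_mass <- mean_s1_mass(dataset)
  site <- dataset$site
  dplyr::bind_rows(lapply(dataset$shoots, shoot_allocation,
                          mean_s1_mass = mean_s1_mass,
                          c_rep = site$c_fraction_reproductive,
                          c_veg = site$c_fraction_vegetative,
                          tip_method = tip_method))
}

#' Site mean S1 dry mass
#'
#' @param dataset An [site_dataset()].
#' @return Mean dry mass (g DW) of the age-1 segment across unbroken shoots.
#' @export
mean_s1_mass <- function(dataset) {
  stopifnot(inherits(dataset, "asco_site_dataset"))
  s1 <- vapply(dataset$shoots, function(s) {
    if (s$broken) return(NA_real_)
    m <- s$segments$segment_dry_mass[s$segments$age_years == 1L]
    if (length(m)) m[[1]] else NA_real_
  }, numeric(1))
  mean(s1, na.rm = TRUE)
}

#' Site-level summary of allocation metrics
#'
#' Mean and standard error (sd/sqrt(n)) of annV, turnover, RE, annRA and
#' C-unit annRA across shoots; the reporting convention of the field. With a
#' single usable shoot the SE is flagged `NA`.
#'
#' @param dataset An [site_dataset()], or a per-shoot allocation tibble from
#'   [site_allocation()].
#' @param ... Passed to [site_allocation()] when `dataset` is a site dataset.
#' @return An `asco_site_summary`: tibble (`metric`, `mean`, `se`, `n`) plus
#'   `n_shoots` and the per-shoot table as attributes.
#' @export
site_summary <- function(dataset, ...) {
  alloc <- if (inherits(dataset, "asco_site_dataset")) {
    site_allocation(dataset, ...)
  } else {
    tibble::as_tibble(dataset)
  }
  metrics <- c("annV", "turnover", "RE", "annRA", "annRA_C")
  rows <- lapply(metrics, function(m) {
    v <- alloc[[m]]
    v <- v[!is.na(v)]
    n <- length(v)
    tibble::tibble(
      metric = m,
      mean = if (n) mean(v) else NA_real_,
      se = if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_,
      n = n)
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            class = c("asco_site_summary", class(out)),
            n_shoots = nrow(alloc),
            allocation = alloc)
}

#' @export
print.asco_site_summary <- function(x, ...) {
  cat(sprintf("<asco_site_summary> %d shoots\n", attr(x, "n_shoots")))
  NextMethod()
  invisible(x)
}

#' Areal carbon production
#'
#' Upscales shoot-level allocation to the population: standing biomass
#' (g DW m^-2) times the fraction renewed (turnover) gives vegetative
#' production, times the reproductive fraction (RE) gives reproductive
#' production, each converted to carbon with its tissue C fraction. Shed
#' receptacles export the reproductive term to the surroundings.
#'
#' SEs are propagated by computing the per-shoot areal values (shoot RE and
#' turnover x site-mean biomass x C fraction) and taking mean and SE across
#' shoots, consistent with shoot-level replication.
#'
#' @param site An [site_record()] with `standing_biomass` and both C
#'   fractions set.
#' @param allocation Per-shoot allocation tibble ([site_allocation()]) or an
#'   [site_summary()] object (its per-shoot table is used).
#' @return An `asco_areal_production`: tibble (`component`, `mean`, `se`) in
#'   g C m^-2 yr^-1 for `vegetative`, `reproductive`, `total`.
#' @export
areal_production <- function(site, allocation) {
  stopifnot(inherits(site, "asco_site"))
  if (inherits(allocation, "asco_site_summary")) {
    allocation <- attr(allocation, "allocation")
  }
  if (is.na(site$standing_biomass)) {
    stop("standing biomass missing for site '", site$site_id,
         "': areal production cannot be estimated", call. = FALSE)
  }
  if (is.na(site$c_fraction_vegetative) || is.na(site$c_fraction_reproductive)) {
    stop("carbon fractions missing for site '", site$site_id, "'", call. = FALSE)
  }
  B <- site$standing_biomass
  rep_i <- to_carbon(B * allocation$RE, site$c_fraction_reproductive)
  veg_i <- to_carbon(B * allocation$turnover, site$c_fraction_vegetative)
  tot_i <- rep_i + veg_i
  mse <- function(v) {
    v <- v[!is.na(v)]
    c(mean(v), if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }
  m <- rbind(vegetative = mse(veg_i), reproductive = mse(rep_i), total = mse(tot_i))
  out <- tibble::tibble(component = rownames(m),
                        mean = unname(m[, 1]), se = unname(m[, 2]))
  structure(out, class = c("asco_areal_production", class(out)))
}

#' @export
print.asco_areal_production <- function(x, ...) {
  cat("<asco_areal_production> g C m-2 yr-1\n")
  NextMethod()
  invisible(x)
}
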