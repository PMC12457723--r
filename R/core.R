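#' Construct a site record
#'
#' A site record carries the covariates needed to interpret a shoot
#' population: position, long-term mean sea surface temperature, standing
#' biomass of the population per unit area, and the carbon fractions of
#' vegetative and reproductive dry mass used for C-unit conversion.
#'
#' @param site_id Character identifier.
#' @param latitude Degrees North, in \[-90, 90\].
#' @param sst_mean Long-term (2000--2020 convention) mean sea surface
#'   temperature, degrees C. May be `NA`.
#' @param standing_biomass Standing biomass, g DW m^-2 (>= 0), or `NA` when
#'   not measured.
#' @param standing_biomass_se Standard error of `standing_biomass` (g DW m^-2).
#' @param c_fraction_vegetative,c_fraction_reproductive Carbon content as a
#'   fraction of dry weight, in \[0, 1\].
#' @return An object of class `asco_site`.
#' @export
#' @examples
#' site_record("demo", latitude = 64.23, standing_biomass = 6860,
#'             c_fraction_vegetative = 0.42, c_fraction_reproductive = 0.29)
site_record <- function(site_id,
                        latitude,
                        sst_mean = NA_real_,
                        standing_biomass = NA_real_,
                        standing_biomass_se = NA_real_,
                        c_fraction_vegetative = NA_real_,
                        c_fraction_reproductive = NA_real_) {
  stopifnot(is.character(site_id), length(site_id) == 1L, nzchar(site_id))
  if (!is.na(latitude) && (latitude < -90 || latitude > 90)) {
    stop("latitude must lie in [-90, 90]", call. = FALSE)
  }
  for (f in c(c_fraction_vegetative, c_fraction_reproductive)) {
    if (!is.na(f) && (f < 0 || f > 1)) {
      stop("carbon fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.na(standing_biomass) && standing_biomass < 0) {
    stop("standing_biomass must be >= 0", call. = FALSE)
  }
  structure(
    list(
      site_id = site_id,
      latitude = as.numeric(latitude),
      sst_mean = as.numeric(sst_mean),
      standing_biomass = as.numeric(standing_biomass),
      standing_biomass_se = as.numeric(standing_biomass_se),
      c_fraction_vegetative = as.numeric(c_fraction_vegetative),
      c_fraction_reproductive = as.numeric(c_fraction_reproductive)
    ),
    class = "asco_site"
  )
}

#' @export
print.asco_site <- function(x, ...) {
  cat(sprintf("<asco_site> %s  lat %.2f N  SST %s C  biomass %s g DW m-2\n",
              x$site_id, x$latitude,
              format(x$sst_mean), format(x$standing_biomass)))
  invisible(x)
}

#' Construct a shoot
#'
#' A shoot is the longest unbroken primary axis of an individual (plus its
#' laterals), fractioned into annual segments read off the bladder sequence.
#' Age 0 is the current-season, incompletely formed apical segment; age 1
#' ("S1") is the newest fully formed segment. `b0_count` and `b1_count` are
#' whole-shoot counts of the youngest and second-youngest bladders; because
#' tips divide dichotomously, `b0_count >= b1_count` unless the shoot is
#' flagged broken.
#'
#' @param shoot_id,site_id Character identifiers.
#' @param segments Data frame with columns `age_years` (contiguous integers
#'   starting at 0, primary axis), `segment_dry_mass` (g DW, > 0) and
#'   `receptacle_count` (integer >= 0, primary-axis count per segment).
#' @param b0_count,b1_count Whole-shoot bladder counts (integers >= 1).
#' @param vegetative_mass Whole-shoot vegetative dry mass V (g DW, > 0),
#'   receptacles excluded.
#' @param reproductive_mass Whole-shoot receptacle dry mass R (g DW, >= 0).
#' @param broken Logical; broken shoots are excluded from tip-count based
#'   growth estimates downstream.
#' @param receptacles Optional data frame with per-age receptacle summaries
#'   (`age_years`, `total_count`, `mean_mass`), whole shoot. Used for pooling.
#' @return An object of class `asco_shoot`.
#' @seealso [validate_shoot()]
#' @export
shoot <- function(shoot_id, site_id, segments, b0_count, b1_count,
                  vegetative_mass, reproductive_mass,
                  broken = FALSE, receptacles = NULL) {
  segments <- tibble::as_tibble(segments)
  obj <- structure(
    list(
      shoot_id = as.character(shoot_id),
      site_id = as.character(site_id),
      segments = segments,
      b0_count = as.integer(b0_count),
      b1_count = as.integer(b1_count),
      vegetative_mass = as.numeric(vegetative_mass),
      reproductive_mass = as.numeric(reproductive_mass),
      broken = isTRUE(broken),
      receptacles = if (is.null(receptacles)) NULL else tibble::as_tibble(receptacles)
    ),
    class = "asco_shoot"
  )
  obj
}

#' @export
print.asco_shoot <- function(x, ...) {
  cat(sprintf(
    "<asco_shoot> %s (site %s): %d segments (ages %s-%s), b0=%d b1=%d, V=%.3g g, R=%.3g g%s\n",
    x$shoot_id, x$site_id, nrow(x$segments),
    min(x$segments$age_years), max(x$segments$age_years),
    x$b0_count, x$b1_count, x$vegetative_mass, x$reproductive_mass,
    if (x$broken) " [broken]" else ""))
  invisible(x)
}

#' Validate a shoot against its structural invariants
#'
#' Validation reports rather than throws: every violated invariant yields one
#' row naming the offending field and the rule. An empty result means the
#' shoot is well formed.
#'
#' Rules checked: contiguous unique segment ages starting at 0; strictly
#' positive segment masses; non-negative integer receptacle counts; bladder
#' counts >= 1; `b0 >= b1` unless `broken`; vegetative mass at least the sum
#' of primary-axis segment masses; non-negative reproductive mass.
#'
#' @param x An [shoot()] object.
#' @return A tibble with columns `field` and `rule`; zero rows iff valid.
#' @export
#' @examples
#' s <- shoot("s1", "demo",
#'            data.frame(age_years = 0:2, segment_dry_mass = c(.02, .05, .06),
#'                       receptacle_count = c(0L, 2L, 5L)),
#'            b0_count = 4, b1_count = 3,
#'            vegetative_mass = 0.5, reproductive_mass = 0.1)
#' validate_shoot(s)  # zero rows
validate_shoot <- function(x) {
  v <- list()
  bad <- function(field, rule) tibble::tibble(field = field, rule = rule)

  seg <- x$segments
  need <- c("age_years", "segment_dry_mass", "receptacle_count")
  miss <- setdiff(need, names(seg))
  if (length(miss)) {
    v[[length(v) + 1L]] <- bad("segments", paste("missing columns:", paste(miss, collapse = ", ")))
    return(dplyr::bind_rows(v))
  }
  ages <- seg$age_years
  if (anyDuplicated(ages)) {
    v[[length(v) + 1L]] <- bad("segments$age_years", "duplicated ages")
  }
  if (!setequal(ages, seq(0L, max(ages))) || min(ages) != 0L) {
    v[[length(v) + 1L]] <- bad("segments$age_years", "non-contiguous ages (expected 0..A)")
  }
  if (any(seg$segment_dry_mass <= 0, na.rm = TRUE) || anyNA(seg$segment_dry_mass)) {
    v[[length(v) + 1L]] <- bad("segments$segment_dry_mass", "masses must be strictly positive")
  }
  rc <- seg$receptacle_count
  if (anyNA(rc) || any(rc < 0) || any(rc != round(rc))) {
    v[[length(v) + 1L]] <- bad("segments$receptacle_count", "counts must be non-negative integers")
  }
  if (is.na(x$b0_count) || x$b0_count < 1L) {
    v[[length(v) + 1L]] <- bad("b0_count", "must be an integer >= 1")
  }
  if (is.na(x$b1_count) || x$b1_count < 1L) {
    v[[length(v) + 1L]] <- bad("b1_count", "must be an integer >= 1")
  }
  if (!x$broken && !is.na(x$b0_count) && !is.na(x$b1_count) && x$b0_count < x$b1_count) {
    v[[length(v) + 1L]] <- bad("b0_count", "b0 < b1 on an unbroken shoot (dichotomous branching)")
  }
  if (is.na(x$vegetative_mass) || x$vegetative_mass <= 0) {
    v[[length(v) + 1L]] <- bad("vegetative_mass", "must be > 0")
  } else if (!anyNA(seg$segment_dry_mass) &&
             x$vegetative_mass < sum(seg$segment_dry_mass) - 1e-9) {
    v[[length(v) + 1L]] <- bad("vegetative_mass",
                               "smaller than the sum of primary-axis segment masses")
  }
  if (is.na(x$reproductive_mass) || x$reproductive_mass < 0) {
    v[[length(v) + 1L]] <- bad("reproductive_mass", "must be >= 0")
  }
  if (length(v) == 0L) {
    return(tibble::tibble(field = character(), rule = character()))
  }
  dplyr::bind_rows(v)
}

#' Bundle a site record with its sampled shoots
#'
#' @param site An [site_record()].
#' @param shoots List of [shoot()] objects, all referencing `site$site_id`.
#' @param receptacle_pools Optional tibble (`age_years`,
#'   `mean_receptacle_mass`, `n_pooled`): mean receptacle dry mass per segment
#'   age after pooling receptacles from all shoots, the canonical granularity
#'   for receptacle size.
#' @return An object of class `asco_site_dataset`.
#' @export
site_dataset <- function(site, shoots, receptacle_pools = NULL) {
  stopifnot(inherits(site, "asco_site"), length(shoots) >= 1L)
  ok <- vapply(shoots, function(s) inherits(s, "asco_shoot"), logical(1))
  if (!all(ok)) stop("all elements of `shoots` must be asco_shoot objects", call. = FALSE)
  ref <- vapply(shoots, function(s) s$site_id, character(1))
  if (!all(ref == site$site_id)) {
    stop("all shoots must reference site_id '", site$site_id, "'", call. = FALSE)
  }
  names(shoots) <- vapply(shoots, function(s) s$shoot_id, character(1))
  structure(
    list(site = site, shoots = shoots,
         receptacle_pools = if (is.null(receptacle_pools)) NULL else tibble::as_tibble(receptacle_pools)),
    class = "asco_site_dataset"
  )
}

#' @export
print.asco_site_dataset <- function(x, ...) {
  cat(sprintf("<asco_site_dataset> site %s: %d shoots\n",
              x$site$site_id, length(x$shoots)))
  invisible(x)
}
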