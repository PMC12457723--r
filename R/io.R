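# Frozen CSV schemas. Every file starts with a "# units:" comment line; all
# masses are g DW unless the column name says otherwise.
.schemas <- list(
  sites = c("site_id", "latitude_degN", "sst_mean_C", "standing_biomass_gDW_m2",
            "biomass_se", "c_frac_veg", "c_frac_rep"),
  shoots = c("shoot_id", "site_id", "b0_count", "b1_count", "V_gDW", "R_gDW",
             "broken"),
  segments = c("shoot_id", "age_years", "segment_gDW", "receptacle_count"),
  receptacle_pools = c("site_id", "age_years", "mean_receptacle_gDW", "n_pooled"),
  meta_records = c("region_id", "latitude_degN", "sst_mean_C", "annRA",
                   "peak_month", "peak_jd", "measure", "source"))

.units_line <- list(
  sites = "# units: latitude degN; SST degC; standing biomass g DW m-2; C fractions of DW",
  shoots = "# units: V and R in g DW; counts are whole-shoot bladder counts",
  segments = "# units: segment mass g DW; receptacle_count per primary-axis segment",
  receptacle_pools = "# units: mean receptacle mass g DW, pooled across shoots per age",
  meta_records = "# units: latitude degN; SST degC; annRA fraction; peak_jd approximate Julian day")

.read_schema_csv <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  miss <- setdiff(.schemas[[what]], names(df))
  if (length(miss)) {
    stop(sprintf("%s: schema mismatch in %s: missing column(s) %s",
                 what, path, paste(sprintf("'%s'", miss), collapse = ", ")),
         call. = FALSE)
  }
  df
}

.write_schema_csv <- function(df, path, what) {
  readr::write_lines(.units_line[[what]], path)
  readr::write_csv(df[.schemas[[what]]], path, append = TRUE, col_names = TRUE)
}

#' Read site datasets from the CSV schemas
#'
#' Expects `sites.csv`, `shoots.csv` and `segments.csv` (and optionally
#' `receptacle_pools.csv`) in `dir`, with the frozen column sets documented
#' in the package. A schema mismatch is an error naming the offending
#' column; structural problems in individual shoots are surfaced as a
#' warning listing every [validate_shoot()] violation (the data are still
#' returned, with the violation table attached as attribute `violations`).
#' UTF-8 BOMs and CRLF line endings are tolerated.
#'
#' @param dir Directory containing the CSV files.
#' @return Named list of [site_dataset()] objects, one per site.
#' @export
read_site_data <- function(dir) {
  sites <- .read_schema_csv(file.path(dir, "sites.csv"), "sites")
  shoots_df <- .read_schema_csv(file.path(dir, "shoots.csv"), "shoots")
  segments_df <- .read_schema_csv(file.path(dir, "segments.csv"), "segments")
  pools_path <- file.path(dir, "receptacle_pools.csv")
  pools_df <- if (file.exists(pools_path)) {
    .read_schema_csv(pools_path, "receptacle_pools")
  } else NULL

  datasets <- lapply(seq_len(nrow(sites)), function(i) {
    srow <- sites[i, ]
    site <- site_record(
      site_id = srow$site_id,
      latitude = srow$latitude_degN,
      sst_mean = srow$sst_mean_C,
      standing_biomass = srow$standing_biomass_gDW_m2,
      standing_biomass_se = srow$biomass_se,
      c_fraction_vegetative = srow$c_frac_veg,
      c_fraction_reproductive = srow$c_frac_rep)
    sh_rows <- shoots_df[shoots_df$site_id == srow$site_id, ]
    if (nrow(sh_rows) == 0) {
      stop("site '", srow$site_id, "' has no shoots in shoots.csv", call. = FALSE)
    }
    shoots <- lapply(seq_len(nrow(sh_rows)), function(j) {
      r <- sh_rows[j, ]
      seg <- segments_df[segments_df$shoot_id == r$shoot_id, ]
      shoot(shoot_id = r$shoot_id, site_id = r$site_id,
            segments = tibble::tibble(
              age_years = as.integer(seg$age_years),
              segment_dry_mass = seg$segment_gDW,
              receptacle_count = as.integer(seg$receptacle_count)),
            b0_count = r$b0_count, b1_count = r$b1_count,
            vegetative_mass = r$V_gDW, reproductive_mass = r$R_gDW,
            broken = isTRUE(as.logical(r$broken)))
    })
    pools <- if (!is.null(pools_df)) {
      p <- pools_df[pools_df$site_id == srow$site_id, ]
      tibble::tibble(age_years = as.integer(p$age_years),
                     mean_receptacle_mass = p$mean_receptacle_gDW,
                     n_pooled = as.integer(p$n_pooled))
    } else NULL
    site_dataset(site, shoots, receptacle_pools = pools)
  })
  names(datasets) <- sites$site_id

  viol <- dplyr::bind_rows(lapply(datasets, function(d) {
    dplyr::bind_rows(lapply(d$shoots, function(s) {
      v <- validate_shoot(s)
      if (nrow(v)) v$shoot_id <- s$shoot_id
      v
    }))
  }))
  if (nrow(viol)) {
    warning("shoot validation reported ", nrow(viol), " violation(s); ",
            "see attr(, 'violations')", call. = FALSE)
    attr(datasets, "violations") <- viol
  }
  datasets
}

#' Write site datasets to the CSV schemas
#'
#' Inverse of [read_site_data()]: writes `sites.csv`, `shoots.csv`,
#' `segments.csv` and `receptacle_pools.csv` under `dir`, each with a units
#' header comment. Numeric values round-trip exactly.
#'
#' @param datasets A single [site_dataset()] or a list of them.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_site_data <- function(datasets, dir) {
  if (inherits(datasets, "asco_site_dataset")) datasets <- list(datasets)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sites <- dplyr::bind_rows(lapply(datasets, function(d) {
    s <- d$site
    tibble::tibble(site_id = s$site_id, latitude_degN = s$latitude,
                   sst_mean_C = s$sst_mean,
                   standing_biomass_gDW_m2 = s$standing_biomass,
                   biomass_se = s$standing_biomass_se,
                   c_frac_veg = s$c_fraction_vegetative,
                   c_frac_rep = s$c_fraction_reproductive)
  }))
  shoots_df <- dplyr::bind_rows(lapply(datasets, function(d) {
    dplyr::bind_rows(lapply(d$shoots, function(s) {
      tibble::tibble(shoot_id = s$shoot_id, site_id = s$site_id,
                     b0_count = s$b0_count, b1_count = s$b1_count,
                     V_gDW = s$vegetative_mass, R_gDW = s$reproductive_mass,
                     broken = s$broken)
    }))
  }))
  segments_df <- dplyr::bind_rows(lapply(datasets, function(d) {
    dplyr::bind_rows(lapply(d$shoots, function(s) {
      tibble::tibble(shoot_id = s$shoot_id,
                     age_years = s$segments$age_years,
                     segment_gDW = s$segments$segment_dry_mass,
                     receptacle_count = s$segments$receptacle_count)
    }))
  }))
  pools_df <- dplyr::bind_rows(lapply(datasets, function(d) {
    if (is.null(d$receptacle_pools)) return(NULL)
    tibble::tibble(site_id = d$site$site_id,
                   age_years = d$receptacle_pools$age_years,
                   mean_receptacle_gDW = d$receptacle_pools$mean_receptacle_mass,
                   n_pooled = d$receptacle_pools$n_pooled)
  }))
  .write_schema_csv(sites, file.path(dir, "sites.csv"), "sites")
  .write_schema_csv(shoots_df, file.path(dir, "shoots.csv"), "shoots")
  .write_schema_csv(segments_df, file.path(dir, "segments.csv"), "segments")
  if (nrow(pools_df)) {
    .write_schema_csv(pools_df, file.path(dir, "receptacle_pools.csv"),
                      "receptacle_pools")
  }
  invisible(dir)
}

#' Read a meta-record table
#'
#' Reads the `meta_records.csv` schema (`region_id`, `latitude_degN`,
#' `sst_mean_C`, `annRA`, `peak_month`, `peak_jd`, `measure`, `source`).
#' The package ships two example tables under `extdata/`: the canonical
#' printed literature compilation (`meta_records.csv`, one row per region)
#' and a variant with the Nova Scotia populations split into three regional
#' groups (`meta_records_ns3_synthetic.csv`; the regional means are
#' synthetic, as the originals were published only as a single mean).
#'
#' @param path CSV file path.
#' @return Tibble in the meta-record schema.
#' @export
#' @examples
#' tab <- read_meta_records(asco_example("meta_records.csv"))
#' nrow(assemble_meta_table(tab))
read_meta_records <- function(path) {
  .read_schema_csv(path, "meta_records")
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata/`; with no argument,
#'   lists the available files.
#' @return Full path (or character vector of file names).
#' @export
asco_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "ascoalloc")))
  }
  path <- system.file("extdata", file, package = "ascoalloc")
  if (!nzchar(path)) stop("no packaged example file '", file, "'", call. = FALSE)
  path
}
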