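# Site time-series container, delimited-file IO, the plant-functional-type
# catalogue, and MODIS-style quality-flag gap filling.

DRIVER_COLS <- c("date", "t_avg", "t_max", "t_min", "rh", "precip",
                 "par", "cloud_frac", "le", "h")
FLUX_COLS <- c("nee_day", "nee_night", "gpp_obs")

#' Construct a site series
#'
#' A `site_series` bundles one eddy-covariance site: an ordered daily table
#' of meteorological drivers and fluxes, plus optional 8-day NDVI and LAI
#' series carrying quality flags.
#'
#' @param site_id short site token, e.g. `"CA-Man"`.
#' @param pft plant-functional-type label. Cropland and wetland labels are
#'   remapped to `"C3 herbaceous"` (the model cannot represent them).
#' @param records data.frame with columns `date` (Date), `t_avg`, `t_max`,
#'   `t_min` (degC), `rh` (%), `precip` (mm/day), `par` (mol quanta/m2/day),
#'   `cloud_frac` (0-1), `le`, `h` (W/m2), and optionally `nee_day`,
#'   `nee_night` (g C/m2 per period, negative = uptake) and `gpp_obs`
#'   (g C/m2/day).
#' @param lai,ndvi optional data.frames with columns `date`, `value`, `qc`
#'   (`qc == 0` means reliable; anything else is fillable).
#' @param latitude site latitude in degrees (needed for the day/night split).
#' @return an object of class `site_series`.
#' @export
site_series <- function(site_id, pft, records, lai = NULL, ndvi = NULL,
                        latitude = NA_real_) {
  stopifnot(is.character(site_id), length(site_id) == 1L)
  records <- validate_records(records, drop_invalid = FALSE)
  for (s in c("lai", "ndvi")) {
    fl <- get(s)
    if (!is.null(fl)) {
      if (!all(c("date", "value", "qc") %in% names(fl)))
        stop(sprintf("%s series needs columns date, value, qc", s))
      if (nrow(fl) && (min(fl$date) < min(records$date) ||
                       max(fl$date) > max(records$date)))
        stop(sprintf("%s timestamps fall outside the daily record span", s))
    }
  }
  structure(list(site_id = site_id, pft = normalize_pft(pft),
                 latitude = latitude, records = records,
                 lai = lai, ndvi = ndvi),
            class = "site_series")
}

#' @export
print.site_series <- function(x, ...) {
  cat(sprintf("<site_series> %s  pft: %s  lat: %s\n", x$site_id, x$pft,
              format(x$latitude)))
  cat(sprintf("  %d daily records, %s to %s\n", nrow(x$records),
              min(x$records$date), max(x$records$date)))
  cat(sprintf("  lai: %s  ndvi: %s  gpp_obs: %s\n",
              if (is.null(x$lai)) "none" else paste0(nrow(x$lai), " pts"),
              if (is.null(x$ndvi)) "none" else paste0(nrow(x$ndvi), " pts"),
              if (all(is.na(x$records$gpp_obs))) "absent" else "present"))
  invisible(x)
}

# Row-level invariants of the daily record; returns the cleaned frame with a
# "n_rejected" attribute when drop_invalid = TRUE, errors otherwise.
validate_records <- function(records, drop_invalid = TRUE) {
  miss <- setdiff(DRIVER_COLS, names(records))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (!nrow(records)) stop("empty site file: no daily records")
  records$date <- as.Date(records$date)
  for (cc in FLUX_COLS) if (!cc %in% names(records)) records[[cc]] <- NA_real_
  records <- records[c(DRIVER_COLS, FLUX_COLS)]
  if (anyDuplicated(records$date)) stop("duplicate dates in daily records")
  records <- records[order(records$date), , drop = FALSE]
  ok <- with(records,
             t_min <= t_avg & t_avg <= t_max &
               par >= 0 & precip >= 0 &
               cloud_frac >= 0 & cloud_frac <= 1 &
               rh >= 0 & rh <= 100)
  ok[is.na(ok)] <- FALSE
  if (!drop_invalid && !all(ok))
    stop(sum(!ok), " daily record(s) violate field invariants")
  if (any(!ok))
    message(sum(!ok), " daily record(s) rejected (invariant violations)")
  out <- records[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(!ok)
  out
}

#' Remap non-simulable vegetation labels
#'
#' Cropland and wetland classes are replaced by C3 grassland; every other
#' label passes through unchanged.
#' @param pft character label.
#' @return character label.
#' @export
normalize_pft <- function(pft) {
  sub <- c("Cropland" = "C3 herbaceous", "CRO" = "C3 herbaceous",
           "Wetland" = "C3 herbaceous", "WET" = "C3 herbaceous")
  ifelse(pft %in% names(sub), unname(sub[pft]), pft)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE,
                                   trim = TRUE)
  }, character(1))
  out
}

#' Write a site series to delimited text
#'
#' One tab-separated file of daily records, preceded by `#`-comment header
#' lines carrying site metadata. When the series holds LAI/NDVI they are
#' written to sidecar files `<stem>-lai.tsv` / `<stem>-ndvi.tsv` that
#' [read_site_series()] picks up automatically. Serialization is
#' deterministic: writing the result of a read reproduces the bytes.
#'
#' @param x a `site_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_site_series <- function(x, path) {
  stopifnot(inherits(x, "site_series"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# gppval site file",
               paste0("# site_id: ", x$site_id),
               paste0("# pft: ", x$pft),
               paste0("# latitude: ", fmt_num(x$latitude))), con)
  rec <- x$records
  rec$date <- format(rec$date)
  for (cc in setdiff(names(rec), "date")) rec[[cc]] <- fmt_num(rec[[cc]])
  utils::write.table(rec, con, sep = "\t", quote = FALSE, row.names = FALSE)
  stem <- sub("\\.[[:alnum:]]+$", "", path)
  for (s in c("lai", "ndvi")) {
    fl <- x[[s]]
    side <- paste0(stem, "-", s, ".tsv")
    if (!is.null(fl)) {
      fl$date <- format(fl$date)
      fl$value <- fmt_num(fl$value)
      utils::write.table(fl, side, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else if (file.exists(side)) {
      unlink(side)
    }
  }
  invisible(path)
}

#' Read a site series from delimited text
#'
#' Reads a file written in the [write_site_series()] dialect (tab-separated,
#' ISO-8601 dates, `#` metadata header). Rows violating the daily-record
#' invariants (`t_min <= t_avg <= t_max`, nonnegative PAR and precipitation,
#' `cloud_frac` in `[0,1]`, `rh` in `[0,100]`) are dropped with a message
#' giving the count, which is also available as `attr(x$records,
#' "n_rejected")`.
#'
#' @param path input file path.
#' @param pft_label optional override of the PFT recorded in the file.
#' @param latitude optional override of the latitude recorded in the file.
#' @return a [site_series()].
#' @export
read_site_series <- function(path, pft_label = NULL, latitude = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key, default = NA_character_) {
    hit <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, ": "), "", hit[1]) else default
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2L) stop("empty site file: no daily records")
  rec <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  rec <- validate_records(rec)
  n_rej <- attr(rec, "n_rejected")
  lat <- latitude %||% suppressWarnings(as.numeric(meta("latitude")))
  stem <- sub("\\.[[:alnum:]]+$", "", path)
  side <- function(s) {
    f <- paste0(stem, "-", s, ".tsv")
    if (!file.exists(f)) return(NULL)
    fl <- utils::read.delim(f, stringsAsFactors = FALSE)
    fl$date <- as.Date(fl$date)
    fl
  }
  out <- site_series(site_id = meta("site_id", basename(stem)),
                     pft = pft_label %||% meta("pft"),
                     records = rec, lai = side("lai"), ndvi = side("ndvi"),
                     latitude = lat)
  attr(out$records, "n_rejected") <- n_rej
  out
}

#' Load the plant-functional-type catalogue
#'
#' The builtin catalogue holds the nine PFTs of the photosynthesis scheme
#' with their default maximum carboxylation rate Vcmax25 and the uniform
#' inversion bounds, all converted from the tabulated 1e-6 scale to
#' mol CO2 m-2 s-1.
#'
#' @param path optional path to a catalogue file with columns `name`,
#'   `vcmax_umol`, `vcmax_lo_umol`, `vcmax_hi_umol`, `pathway`; the packaged
#'   default is used when `NULL`.
#' @return data.frame with columns `name`, `vcmax_default`, `vcmax_lo`,
#'   `vcmax_hi` (mol CO2 m-2 s-1) and `pathway` (`"C3"` or `"C4"`).
#' @export
load_pft_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pft_catalog.tsv",
                                package = "gppval", mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(raw$name))
    stop("catalogue error: duplicate PFT name(s)")
  out <- data.frame(name = raw$name,
                    vcmax_default = raw$vcmax_umol * 1e-6,
                    vcmax_lo = raw$vcmax_lo_umol * 1e-6,
                    vcmax_hi = raw$vcmax_hi_umol * 1e-6,
                    pathway = raw$pathway,
                    stringsAsFactors = FALSE)
  if (nrow(out) != 9L) stop("catalogue error: expected exactly nine PFTs")
  with(out, stopifnot(all(vcmax_lo < vcmax_default),
                      all(vcmax_default < vcmax_hi),
                      all(pathway %in% c("C3", "C4"))))
  out
}

pft_entry <- function(pft, catalog = NULL) {
  catalog <- catalog %||% load_pft_catalog()
  pft <- normalize_pft(pft)
  i <- match(pft, catalog$name)
  if (is.na(i)) stop("unknown PFT label: ", pft)
  catalog[i, , drop = FALSE]
}

#' Fill flagged values in an 8-day series
#'
#' Linear interpolation in time across runs of unreliable values, mirroring
#' the temporal fill applied to quality-flagged satellite NDVI/LAI pixels:
#' each flagged value is replaced by the straight line between its nearest
#' reliable neighbours; flagged values before the first (after the last)
#' reliable point take that nearest reliable value. Reliable values are
#' never modified, so the operation is idempotent.
#'
#' @param x data.frame with columns `date`, `value`, `qc` (`qc == 0`
#'   reliable), or a numeric vector paired with `reliable`.
#' @param reliable logical vector (used only for the vector interface).
#' @return object of the same shape with flagged values replaced and `qc`
#'   reset to 0.
#' @export
fill_temporal_gaps <- function(x, reliable = NULL) {
  if (is.data.frame(x)) {
    rel <- x$qc == 0
    x$value <- fill_temporal_gaps(x$value, rel)
    x$qc <- 0L
    return(x)
  }
  stopifnot(length(reliable) == length(x))
  if (sum(reliable) < 2L)
    stop("unusable series: fewer than two reliable values")
  if (all(reliable)) return(x)
  t <- seq_along(x)
  out <- x
  out[!reliable] <- stats::approx(t[reliable], x[reliable],
                                  xout = t[!reliable], rule = 2)$y
  out
}

# Daily interpolation of an (already gap-filled) 8-day series onto the dates
# of a record table; constant extension beyond the sampled span.
interp_to_daily <- function(flagged, dates) {
  if (is.null(flagged)) stop("series has no NDVI/LAI to interpolate")
  if (any(flagged$qc != 0)) flagged <- fill_temporal_gaps(flagged)
  stats::approx(as.numeric(flagged$date), flagged$value,
                xout = as.numeric(dates), rule = 2)$y
}
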