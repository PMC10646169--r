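#' @keywords internal
provenance_header <- function(seed = NULL, extra = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("songscape")),
                  error = function(e) "dev")
  h <- sprintf("# songscape %s | written %s", ver,
               format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %s", seed))
  if (!is.null(extra)) h <- c(h, paste0("# ", extra))
  h
}

write_csv_prov <- function(df, path, seed = NULL, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, extra), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

require_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
  invisible(df)
}

#' Read point-count detection records
#'
#' One row per independent detection. Required columns: `grid_id`, `year`,
#' `species`, `distance_m`, `minute`, `observer_experienced`. Optional
#' `flyover` and `migrant` flags support the standard data filters:
#' detections of unidentified species, fly-overs, possible migrants, and
#' rows with missing fields are dropped (each filter can be switched off).
#'
#' @param path CSV file (lines starting with `#` are provenance comments).
#' @param species Optional species label to subset to.
#' @param drop_unknown,drop_flyovers,drop_migrants,drop_incomplete Filter
#'   switches (all `TRUE` by default).
#' @param quiet Suppress the per-filter count log.
#' @return Data frame of typed detection records.
#' @export
read_detections <- function(path, species = NULL,
                            drop_unknown = TRUE, drop_flyovers = TRUE,
                            drop_migrants = TRUE, drop_incomplete = TRUE,
                            quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  require_columns(d, c("grid_id", "year", "species", "distance_m", "minute",
                       "observer_experienced"), "detections CSV")
  n0 <- nrow(d)
  log1 <- function(label, kept) {
    if (!quiet) message(sprintf("detections: %s -> %d rows kept", label, kept))
  }
  if (!is.null(species)) d <- d[d$species == species, , drop = FALSE]
  if (drop_unknown) {
    d <- d[tolower(d$species) != "unknown", , drop = FALSE]
    log1("drop unknown species", nrow(d))
  }
  if (drop_flyovers && "flyover" %in% names(d)) {
    d <- d[!(d$flyover %in% c(1, TRUE)), , drop = FALSE]
    log1("drop fly-overs", nrow(d))
  }
  if (drop_migrants && "migrant" %in% names(d)) {
    d <- d[!(d$migrant %in% c(1, TRUE)), , drop = FALSE]
    log1("drop possible migrants", nrow(d))
  }
  if (drop_incomplete) {
    core <- d[, c("grid_id", "year", "distance_m", "minute")]
    d <- d[stats::complete.cases(core), , drop = FALSE]
    log1("drop incomplete rows", nrow(d))
  }
  if (!quiet)
    message(sprintf("detections: read %d rows, kept %d", n0, nrow(d)))
  d$year <- as.integer(d$year)
  d$minute <- as.integer(d$minute)
  d$distance_m <- as.numeric(d$distance_m)
  d$observer_experienced <- as.integer(d$observer_experienced)
  d
}

#' Read the survey panel
#'
#' One row per survey (grid-year). Required columns: `grid_id`, `year`,
#' `n_points` (1-16), `ordinal_date`, `mean_min_since_sunrise`, `bcr_id`,
#' `easting`, `northing`. Optional: `observer_experienced` (derived from a
#' survey's detections, default 0, when absent) and `minutes` (count length;
#' defaults to 5 in 2008-2009 and 6 afterwards).
#'
#' @param path CSV file.
#' @param detections Optional detection records used to back-fill the
#'   observer-experience flag.
#' @return Data frame of typed survey rows.
#' @export
read_surveys <- function(path, detections = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  s <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  require_columns(s, c("grid_id", "year", "n_points", "ordinal_date",
                       "mean_min_since_sunrise", "bcr_id", "easting",
                       "northing"), "surveys CSV")
  s$year <- as.integer(s$year)
  s$n_points <- as.integer(s$n_points)
  if (any(s$n_points < 1 | s$n_points > 16))
    stop("n_points must lie in 1..16")
  if (!"minutes" %in% names(s))
    s$minutes <- ifelse(s$year <= 2009, 5L, 6L)
  if (!"observer_experienced" %in% names(s)) {
    s$observer_experienced <- 0L
    if (!is.null(detections) && nrow(detections)) {
      key <- paste(s$grid_id, s$year)
      agg <- stats::aggregate(observer_experienced ~ grid_id + year,
                              detections, function(v) round(mean(v)))
      m <- match(key, paste(agg$grid_id, agg$year))
      s$observer_experienced[!is.na(m)] <-
        as.integer(agg$observer_experienced[m[!is.na(m)]])
    }
  }
  s
}

#' Grid-inclusion filter
#'
#' Keeps grids surveyed in at least `min_years` distinct years and in at
#' least `min_frac` of the calendar years between their first and last
#' survey (inclusive). A grid surveyed in 2010, 2012 and 2014 spans five
#' years but was surveyed in three (60%), so it is excluded at the default
#' 67%.
#'
#' @param surveys Survey panel data frame.
#' @param min_years Minimum distinct survey years (default 3).
#' @param min_frac Minimum surveyed fraction of the span (default 0.67).
#' @param quiet Suppress the count log.
#' @return The filtered panel.
#' @export
filter_grid_inclusion <- function(surveys, min_years = 3, min_frac = 0.67,
                                  quiet = FALSE) {
  spl <- split(surveys$year, surveys$grid_id)
  ok <- vapply(spl, function(y) {
    y <- unique(y)
    span <- diff(range(y)) + 1
    length(y) >= min_years && length(y) / span >= min_frac
  }, TRUE)
  keep <- names(spl)[ok]
  out <- surveys[as.character(surveys$grid_id) %in% keep, , drop = FALSE]
  if (!quiet)
    message(sprintf("grid inclusion: kept %d of %d grids (%d of %d surveys)",
                    length(keep), length(spl), nrow(out), nrow(surveys)))
  out
}

#' Write detection records / survey panel
#'
#' CSV writers with a provenance comment header (package version, time,
#' optional seed), readable back via [read_detections] / [read_surveys].
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(df, path, seed = NULL) {
  write_csv_prov(df, path, seed = seed)
}
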