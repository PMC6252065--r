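#' Default column mapping for detection tables
#'
#' Maps the canonical field names used by the package to the column names in
#' an input CSV. Override individual entries to read other dialects, or
#' supply a mapping from a YAML config (see \code{\link{read_config}}).
#'
#' @return named character vector: canonical name -> file column name.
#' @export
default_schema <- function() {
  c(species = "species", site_id = "site_id", camera_id = "camera_id",
    timestamp = "timestamp", latitude = "latitude", longitude = "longitude",
    group_size = "group_size")
}

parse_timestamps <- function(x) {
  # ISO-8601 preferred; "DD/MM/YYYY HH:MM" dialect accepted
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}[ T]\\d{2}:\\d{2}(:\\d{2})?$", x)
  dmy <- grepl("^\\d{2}/\\d{2}/\\d{4} \\d{2}:\\d{2}(:\\d{2})?$", x)
  out[iso] <- as.POSIXct(sub("T", " ", x[iso]), tz = "UTC")
  out[dmy] <- as.POSIXct(x[dmy], format = "%d/%m/%Y %H:%M", tz = "UTC")
  out
}

validate_detections <- function(df) {
  msgs <- character(0)
  bad_row <- function(rows, what)
    sprintf("row %d: %s", rows, what)
  if (anyNA(df$timestamp))
    msgs <- c(msgs, bad_row(which(is.na(df$timestamp)), "unparseable timestamp"))
  bad_lat <- which(!is.na(df$latitude) & (df$latitude < -90 | df$latitude > 90))
  if (length(bad_lat))
    msgs <- c(msgs, bad_row(bad_lat, sprintf("latitude %g outside [-90, 90]",
                                             df$latitude[bad_lat])))
  bad_lon <- which(!is.na(df$longitude) & (df$longitude < -180 | df$longitude > 180))
  if (length(bad_lon))
    msgs <- c(msgs, bad_row(bad_lon, sprintf("longitude %g outside [-180, 180]",
                                             df$longitude[bad_lon])))
  bad_gs <- which(!is.na(df$group_size) & df$group_size < 1)
  if (length(bad_gs))
    msgs <- c(msgs, bad_row(bad_gs, "group_size < 1"))
  msgs
}

#' Read a camera-trap detection table
#'
#' Reads a CSV of detection records, applies a column mapping, parses
#' timestamps (ISO-8601 or \code{DD/MM/YYYY HH:MM}), validates coordinate and
#' group-size bounds, and sorts by (species, camera, timestamp). A multi-animal
#' image is one record (\code{group_size} carries the count). Images of the
#' same species at the same camera in the same minute are collapsed to a
#' single record (burst captures).
#'
#' Malformed rows are collected and reported together with their row numbers;
#' any malformed row is an error.
#'
#' @param path CSV file with header.
#' @param schema named character vector mapping canonical names to file
#'   columns (see \code{\link{default_schema}}); \code{group_size} is optional
#'   in the file and defaults to 1.
#' @return data.frame of detection records sorted by (species, camera_id,
#'   timestamp), with \code{timestamp} as POSIXct local civil time.
#' @export
read_detections <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- setdiff(names(default_schema()), "group_size")
  missing_cols <- required[!schema[required] %in% names(raw)]
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(schema[missing_cols], collapse = ", "))
  df <- data.frame(
    species = as.character(raw[[schema[["species"]]]]),
    site_id = as.character(raw[[schema[["site_id"]]]]),
    camera_id = as.character(raw[[schema[["camera_id"]]]]),
    timestamp = parse_timestamps(as.character(raw[[schema[["timestamp"]]]])),
    latitude = as.numeric(raw[[schema[["latitude"]]]]),
    longitude = as.numeric(raw[[schema[["longitude"]]]]),
    stringsAsFactors = FALSE
  )
  gs_col <- schema[["group_size"]]
  df$group_size <- if (!is.na(gs_col) && gs_col %in% names(raw))
    as.integer(raw[[gs_col]]) else 1L
  msgs <- validate_detections(df)
  if (length(msgs))
    stop("invalid detection rows:\n", paste(msgs, collapse = "\n"))
  # collapse same species/camera/minute duplicates (bursts)
  minute <- trunc(as.numeric(df$timestamp) / 60)
  dup <- duplicated(data.frame(df$species, df$camera_id, minute))
  df <- df[!dup, , drop = FALSE]
  df <- df[order(df$species, df$camera_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a detection table
#'
#' Inverse of \code{\link{read_detections}}: writes the canonical CSV dialect
#' (ISO-8601 minute-resolution timestamps) that \code{read_detections} reads
#' back losslessly.
#'
#' @param records detection data.frame.
#' @param path output CSV path.
#' @export
write_detections <- function(records, path) {
  out <- records[, c("species", "site_id", "camera_id", "timestamp",
                     "latitude", "longitude", "group_size")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a site table
#'
#' @param path CSV with columns \code{site_id, latitude, longitude,
#'   utc_offset}.
#' @return data.frame of sites.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "latitude", "longitude", "utc_offset")
  if (!all(need %in% names(df)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  stopifnot(all(df$latitude >= -90 & df$latitude <= 90),
            all(df$longitude >= -180 & df$longitude <= 180))
  df$site_id <- as.character(df$site_id)
  df
}

#' Enforce detection independence
#'
#' Greedy forward scan per (species, camera): the first record is retained and
#' a subsequent record is retained iff it falls at least \code{interval} after
#' the most recently retained record of that species at that camera. This
#' guarantees that consecutive retained same-species records at a camera are
#' separated by at least the independence interval (1 h by default).
#'
#' @param records detection data.frame (sorted or not; sorted internally).
#' @param interval independence interval in hours (default 1).
#' @return an \code{event_stream}: the retained records with attributes
#'   \code{independence_interval} (hours) and \code{n_removed}.
#' @export
filter_independent <- function(records, interval = 1) {
  if (length(interval) != 1 || is.na(interval) || interval < 0)
    stop("interval must be a single non-negative number of hours")
  records <- records[order(records$species, records$camera_id,
                           records$timestamp), , drop = FALSE]
  t_sec <- as.numeric(records$timestamp)
  grp <- paste(records$species, records$camera_id, sep = "\r")
  keep <- logical(nrow(records))
  for (idx in split(seq_len(nrow(records)), grp)) {
    last <- -Inf
    for (i in idx) {
      if (t_sec[i] - last >= interval * 3600) {
        keep[i] <- TRUE
        last <- t_sec[i]
      }
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "independence_interval") <- interval
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- c("event_stream", "data.frame")
  out
}

#' @export
print.event_stream <- function(x, ...) {
  cat("<event_stream> ", nrow(x), " independent events (interval ",
      attr(x, "independence_interval"), " h, ", attr(x, "n_removed"),
      " removed)\n", sep = "")
  NextMethod()
}

#' Per-species raw vs independent event counts
#'
#' @param raw,independent detection data.frames before/after
#'   \code{\link{filter_independent}}.
#' @return data.frame with columns \code{species}, \code{n_raw},
#'   \code{n_independent}.
#' @export
independence_summary <- function(raw, independent) {
  a <- table(raw$species)
  b <- table(factor(independent$species, levels = names(a)))
  data.frame(species = names(a), n_raw = as.integer(a),
             n_independent = as.integer(b), row.names = NULL)
}

#' Restrict a pair analysis to co-occurrence locations
#'
#' Keeps only records (of the two named species) from locations where both
#' species were detected at least once, per the co-occurrence restriction for
#' predator--prey comparisons. The location unit defaults to the broad study
#' site (\code{site_id}).
#'
#' @param records detection data.frame.
#' @param species_a,species_b species labels present in \code{records}.
#' @param location_key \code{"site_id"} or \code{"camera_id"}.
#' @return records of the two species at shared locations, with attribute
#'   \code{locations} (the retained location set). Empty (with a warning) when
#'   no location is shared.
#' @export
restrict_to_cooccurrence <- function(records, species_a, species_b,
                                     location_key = c("site_id", "camera_id")) {
  location_key <- match.arg(location_key)
  present <- unique(records$species)
  for (sp in c(species_a, species_b))
    if (!sp %in% present) stop("unknown species label: ", sp)
  loc_a <- unique(records[[location_key]][records$species == species_a])
  loc_b <- unique(records[[location_key]][records$species == species_b])
  shared <- intersect(loc_a, loc_b)
  out <- records[records$species %in% c(species_a, species_b) &
                   records[[location_key]] %in% shared, , drop = FALSE]
  rownames(out) <- NULL
  if (length(shared) == 0)
    warning("no shared locations for ", species_a, " and ", species_b)
  attr(out, "locations") <- shared
  out
}
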