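#' Read and validate a raw BLE sighting file
#'
#' The file must be comma-separated UTF-8 with header exactly
#' `device_a,device_b,timestamp,rssi`. Every row is validated: the two
#' IDs must differ and be non-empty, the timestamp must parse as ISO-8601
#' and the RSSI must be a finite number. Malformed rows are never silently
#' dropped -- they are returned in a rejects table with their file row
#' number and a reason, and `nrow(read) = nrow(kept) + nrow(rejects)`.
#'
#' @param path Path to the sightings CSV.
#' @param roster Optional roster tibble (from [read_roster()] or
#'   [simulate_home()]); when supplied, each sighting is classified as
#'   `kind = "dyad"` (second device is a rostered wearable) or
#'   `"location"` (second device is a location marker).
#' @return A list of class `"sighting_set"` with `sightings` (validated
#'   tibble: `device_a, device_b, timestamp` (POSIXct UTC), `rssi, kind`)
#'   and `rejects` (tibble `row, reason`).
#' @export
read_sightings <- function(path, roster = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  need <- c("device_a", "device_b", "timestamp", "rssi")
  if (!identical(names(raw), need)) {
    stop("sightings file must have header exactly 'device_a,device_b,timestamp,rssi'",
         call. = FALSE)
  }
  n <- nrow(raw)
  if (n == 0L) {
    return(structure(list(sightings = empty_sightings(),
                          rejects = tibble::tibble(row = integer(),
                                                   reason = character())),
                     class = "sighting_set"))
  }
  ts <- suppressWarnings(lubridate::ymd_hms(raw$timestamp, tz = "UTC",
                                            quiet = TRUE))
  rssi <- suppressWarnings(as.numeric(raw$rssi))
  reason <- rep(NA_character_, n)
  bad_id <- is.na(raw$device_a) | is.na(raw$device_b) |
    raw$device_a == "" | raw$device_b == ""
  reason[bad_id] <- "missing device id"
  same <- !bad_id & raw$device_a == raw$device_b
  reason[same] <- "device_a equals device_b"
  bad_ts <- is.na(reason) & is.na(ts)
  reason[bad_ts] <- "unparseable timestamp"
  bad_rssi <- is.na(reason) & (is.na(rssi) | !is.finite(rssi))
  reason[bad_rssi] <- "unparseable or non-finite rssi"
  keep <- is.na(reason)

  sightings <- tibble::tibble(device_a = raw$device_a[keep],
                              device_b = raw$device_b[keep],
                              timestamp = ts[keep],
                              rssi = rssi[keep],
                              kind = NA_character_)
  if (!is.null(roster)) {
    sightings$kind <- ifelse(sightings$device_b %in% roster$device_id,
                             "dyad", "location")
  }
  structure(list(sightings = sightings,
                 rejects = tibble::tibble(row = which(!keep),
                                          reason = reason[!keep])),
            class = "sighting_set")
}

#' Read a device roster (`device_id,role,home,unit`)
#'
#' Roles are restricted to `resident`, `staff` and `agency`. Duplicate
#' device IDs and unknown role strings are hard errors that name the
#' offending rows.
#'
#' @param path Path to the roster CSV.
#' @return Roster tibble `device_id, role, home, unit`.
#' @export
read_roster <- function(path) {
  r <- readr::read_csv(path, col_types = readr::cols(
    device_id = readr::col_character(), role = readr::col_character(),
    home = readr::col_character(), unit = readr::col_integer()),
    progress = FALSE)
  need <- c("device_id", "role", "home", "unit")
  if (!all(need %in% names(r))) {
    stop("roster file must have columns device_id,role,home,unit", call. = FALSE)
  }
  dup <- r$device_id[duplicated(r$device_id)]
  if (length(dup)) {
    stop("duplicate device ids in roster: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- !r$role %in% c("resident", "staff", "agency")
  if (any(bad)) {
    stop("unknown role(s) in roster: ",
         paste(sprintf("%s (row %d, role '%s')", r$device_id[bad],
                       which(bad), r$role[bad]), collapse = "; "),
         call. = FALSE)
  }
  r[, need]
}

#' Keep only sightings that indicate physical proximity
#'
#' Applies the RSSI proximity rule of the analysis configuration to dyad
#' sightings; location-marker sightings are always kept. Under the
#' default `stronger_than_threshold` rule a sighting is proximate when
#' `rssi >= rssi_threshold` (the deployment convention: a signal stronger than
#' -75 dBm means the devices were within about 1.5 m). The mirrored
#' `weaker_than_threshold` rule keeps `rssi < rssi_threshold`. Output is
#' a subset of the input with order preserved, and the filter is
#' idempotent.
#'
#' @param records Sightings tibble (with `kind` column; `NA` kind is
#'   treated as a dyad sighting).
#' @param config An [analysis_config()].
#' @return Filtered sightings tibble.
#' @export
filter_proximate <- function(records, config) {
  if (nrow(records) == 0L) return(records)
  is_loc <- !is.na(records$kind) & records$kind == "location"
  ok <- if (config$rssi_keep_rule == "stronger_than_threshold") {
    records$rssi >= config$rssi_threshold
  } else {
    records$rssi < config$rssi_threshold
  }
  records[is_loc | ok, ]
}

#' Canonical (undirected) form of a device pair
#'
#' Contact data here are undirected: a sighting of B by A is the same
#' dyad as a sighting of A by B. The canonical form orders the two IDs
#' lexicographically, so `canonical_dyad(a, b)` equals
#' `canonical_dyad(b, a)`.
#'
#' @param a,b Device ID character vectors (elementwise `a != b`).
#' @return A list with `a` (smaller ID) and `b` (larger ID).
#' @examples
#' canonical_dyad("S01", "R07")  # list(a = "R07", b = "S01")
#' @export
canonical_dyad <- function(a, b) {
  if (any(a == b)) stop("a dyad must consist of two distinct devices",
                        call. = FALSE)
  list(a = pmin(a, b), b = pmax(a, b))
}
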