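#' Configuration for the synthetic care-home simulator
#'
#' Builds the parameter set that [simulate_home()] uses to generate a
#' ground-truthed stream of BLE proximity sightings. Defaults describe a
#' small nursing home of around thirty people (12 residents, 19 permanent
#' staff) with a single 08:00--20:00 day shift, handover peaks at the
#' start, middle and end of the shift, and a busier 10:00--15:00 core day
#' -- the temporal structure typical of UK residential care.
#'
#' @param n_residents,n_staff,n_agency Number of residents, permanent
#'   staff and agency (temporary) staff wearing devices. Agency staff are
#'   modelled as staff with sparse, irregular presence (see
#'   `agency_presence_prob`).
#' @param home_name Label attached to every simulated person (the "home").
#' @param locations Character vector of location-marker labels installed
#'   in the home. Markers appear in the sighting stream as the second
#'   device of `kind = "location"` rows.
#' @param n_units Number of planted subcommunities (care units). Residents
#'   and permanent staff are assigned to units round-robin when
#'   `unit_assignment` is `NULL`; agency staff float and belong to none.
#' @param unit_assignment Optional named integer vector `device_id -> unit`
#'   covering every resident and permanent staff member exactly once.
#' @param shift_windows List of `c("HH:MM", "HH:MM")` clock-time windows
#'   during which staff (and agency staff, on days they attend) are
#'   present. Default one 08:00--20:00 day shift.
#' @param resident_day `c("HH:MM", "HH:MM")` waking-day window during
#'   which residents are available for contact.
#' @param rate_matrix Named numeric vector of expected interaction
#'   episodes per dyad per hour of joint presence, keyed by
#'   alphabetically-ordered role pair (`"resident-staff"`, etc.).
#' @param handover_boost Multiplicative factor applied to staff-staff
#'   episode rates inside short handover windows at the start, middle and
#'   end of each shift.
#' @param handover_len_min Length (minutes) of each handover window.
#' @param midday_boost Multiplicative factor applied to staff-resident and
#'   staff-staff rates in the 10:00--15:00 core of the home day.
#' @param duration_model Named list of `c(median_min, sdlog)` log-normal
#'   episode-duration parameters per role pair (median in minutes).
#' @param within_unit_bias Multiplier (>= 1) on the episode rate of dyads
#'   sharing a planted unit.
#' @param agency_presence_prob Probability an agency staff member attends
#'   on any given day.
#' @param ping_interval_s Seconds between successive scans while a contact
#'   is ongoing (exact cadence; first ping at episode start).
#' @param ping_miss_prob Probability each scheduled scan is not recorded.
#' @param rssi_model List with `rssi_at_1m` (dBm at 1 metre), `exponent`
#'   (path-loss exponent) and `noise_sd` (dBm) for the log-distance RSSI
#'   model. The default (-66 dBm, 4, 3 dB) places the -75 dBm proximity
#'   threshold at about 1.7 m, so within-contact distances (<= 1.5 m) pass
#'   the filter and far pings (>= 3 m) do not.
#' @param decoy_rate Expected far-distance (3--8 m) decoy pings per dyad
#'   per hour of joint presence; 0 (default) disables decoys.
#' @param sim_days Number of simulated days.
#' @param start_date Date of the first simulated day (clock is simulated
#'   local time with no daylight-saving transitions; timestamps are
#'   emitted as ISO-8601 with a +0000 offset).
#' @param min_separation_s Minimum enforced gap (seconds) between
#'   successive true episodes of the same dyad, so that distinct true
#'   episodes remain distinct after sessionization.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#'
#' @return A list of class `"home_config"`.
#' @seealso [simulate_home()], [analysis_config()]
#' @export
home_config <- function(n_residents = 12,
                        n_staff = 19,
                        n_agency = 0,
                        home_name = "home-1",
                        locations = c("lounge", "dining-room", "bedroom-wing",
                                      "staff-room", "smoking-shelter", "corridor"),
                        n_units = 2,
                        unit_assignment = NULL,
                        shift_windows = list(c("08:00", "20:00")),
                        resident_day = c("07:00", "22:00"),
                        rate_matrix = c("agency-agency"     = 0.005,
                                        "agency-resident"   = 0.01,
                                        "agency-staff"      = 0.02,
                                        "resident-resident" = 0.02,
                                        "resident-staff"    = 0.05,
                                        "staff-staff"       = 0.08),
                        handover_boost = 3,
                        handover_len_min = 30,
                        midday_boost = 1.5,
                        duration_model = list(
                          "agency-agency"     = c(median_min = 9,  sdlog = 0.9),
                          "agency-resident"   = c(median_min = 8,  sdlog = 0.8),
                          "agency-staff"      = c(median_min = 9,  sdlog = 0.9),
                          "resident-resident" = c(median_min = 10, sdlog = 0.7),
                          "resident-staff"    = c(median_min = 8,  sdlog = 0.8),
                          "staff-staff"       = c(median_min = 9,  sdlog = 0.9)),
                        within_unit_bias = 3,
                        agency_presence_prob = 0.3,
                        ping_interval_s = 20,
                        ping_miss_prob = 0.1,
                        rssi_model = list(rssi_at_1m = -66, exponent = 4,
                                          noise_sd = 3),
                        decoy_rate = 0,
                        sim_days = 14,
                        start_date = "2021-11-29",
                        min_separation_s = 180,
                        seed = 1L) {
  cfg <- list(
    n_residents = as.integer(n_residents), n_staff = as.integer(n_staff),
    n_agency = as.integer(n_agency), home_name = home_name,
    locations = locations, n_units = as.integer(n_units),
    unit_assignment = unit_assignment, shift_windows = shift_windows,
    resident_day = resident_day, rate_matrix = rate_matrix,
    handover_boost = handover_boost, handover_len_min = handover_len_min,
    midday_boost = midday_boost, duration_model = duration_model,
    within_unit_bias = within_unit_bias,
    agency_presence_prob = agency_presence_prob,
    ping_interval_s = ping_interval_s, ping_miss_prob = ping_miss_prob,
    rssi_model = rssi_model, decoy_rate = decoy_rate,
    sim_days = as.integer(sim_days), start_date = start_date,
    min_separation_s = min_separation_s, seed = as.integer(seed))
  class(cfg) <- "home_config"
  validate_home_config(cfg)
}

validate_home_config <- function(cfg) {
  stopifnot(inherits(cfg, "home_config"))
  counts <- c(cfg$n_residents, cfg$n_staff, cfg$n_agency, cfg$n_units)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("population and unit counts must be non-negative", call. = FALSE)
  }
  if (any(cfg$rate_matrix < 0)) stop("rate_matrix entries must be >= 0", call. = FALSE)
  if (cfg$ping_miss_prob < 0 || cfg$ping_miss_prob >= 1) {
    stop("ping_miss_prob must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$within_unit_bias < 1) stop("within_unit_bias must be >= 1", call. = FALSE)
  if (cfg$sim_days <= 0) stop("sim_days must be positive", call. = FALSE)
  pairs <- c("agency-agency", "agency-resident", "agency-staff",
             "resident-resident", "resident-staff", "staff-staff")
  if (!all(pairs %in% names(cfg$rate_matrix))) {
    stop("rate_matrix must name all six role pairs", call. = FALSE)
  }
  if (!all(pairs %in% names(cfg$duration_model))) {
    stop("duration_model must name all six role pairs", call. = FALSE)
  }
  if (!is.null(cfg$unit_assignment)) {
    ids <- roster_ids(cfg)
    core <- ids[ids$role != "agency", , drop = FALSE]
    nm <- names(cfg$unit_assignment)
    if (is.null(nm) || !setequal(nm, core$device_id) || anyDuplicated(nm)) {
      stop("unit_assignment must cover every resident and staff device exactly once",
           call. = FALSE)
    }
  }
  cfg
}

#' Analysis parameters for the contact pipeline
#'
#' Thresholds and rules used by the ingest, sessionization and reporting
#' stages.
#'
#' @param rssi_threshold Proximity threshold in dBm; the deployment
#'   convention is that a signal stronger than -75 dBm indicates two
#'   devices within about 1.5 metres.
#' @param rssi_keep_rule `"stronger_than_threshold"` (default: keep dyad
#'   sightings with `rssi >= rssi_threshold`, i.e. closer than the
#'   threshold distance) or `"weaker_than_threshold"` (keep
#'   `rssi < rssi_threshold`). The rule is configurable because deployed
#'   hardware sometimes reports RSSI on a device-specific scale.
#' @param max_gap_s Maximum gap in seconds between successive sightings of
#'   a dyad for them to be merged into one interaction episode; a gap
#'   strictly greater than this starts a new episode.
#' @param long_interaction_min Duration threshold (minutes) above which an
#'   episode counts as a "long" interaction (default 2 minutes).
#' @param long_rule `"strict"` (duration strictly greater than the
#'   threshold, the default) or `"inclusive"` (greater or equal).
#' @param hour_bin_h Bin width in hours for temporal summaries.
#' @param report_tz IANA time zone in which clock-time reports (hour of
#'   day, shift windows) are rendered. Timestamps are held in UTC
#'   internally.
#'
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(rssi_threshold = -75,
                            rssi_keep_rule = c("stronger_than_threshold",
                                               "weaker_than_threshold"),
                            max_gap_s = 60,
                            long_interaction_min = 2,
                            long_rule = c("strict", "inclusive"),
                            hour_bin_h = 1,
                            report_tz = "Europe/London") {
  rssi_keep_rule <- match.arg(rssi_keep_rule)
  long_rule <- match.arg(long_rule)
  if (max_gap_s <= 0) stop("max_gap_s must be positive", call. = FALSE)
  if (long_interaction_min <= 0) {
    stop("long_interaction_min must be positive", call. = FALSE)
  }
  if (hour_bin_h <= 0) stop("hour_bin_h must be positive", call. = FALSE)
  structure(list(rssi_threshold = rssi_threshold,
                 rssi_keep_rule = rssi_keep_rule,
                 max_gap_s = max_gap_s,
                 long_interaction_min = long_interaction_min,
                 long_rule = long_rule,
                 hour_bin_h = hour_bin_h,
                 report_tz = report_tz),
            class = "analysis_config")
}

# device IDs + roles implied by a home_config, before any simulation
roster_ids <- function(cfg) {
  ids <- c(sprintf("R%03d", seq_len(cfg$n_residents)),
           sprintf("S%03d", seq_len(cfg$n_staff)),
           sprintf("A%03d", seq_len(cfg$n_agency)))
  roles <- c(rep("resident", cfg$n_residents),
             rep("staff", cfg$n_staff),
             rep("agency", cfg$n_agency))
  tibble::tibble(device_id = ids, role = roles)
}
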