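#' Read a receiver registry
#'
#' Canonical CSV: columns `receiver_id`, `lat`, `lon` and optionally
#' `is_island_site` (logical; marks offshore island receivers used by the
#' offshore routing rule). Missing `is_island_site` defaults to `FALSE`.
#'
#' @param path Path to a CSV file.
#' @return `data.frame` with one row per receiver.
#' @export
read_receivers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("receiver_id", "lat", "lon")
  if (!all(need %in% names(df))) {
    stop("receiver registry must have columns: ", paste(need, collapse = ", "))
  }
  df$receiver_id <- as.character(df$receiver_id)
  if (anyDuplicated(df$receiver_id)) stop("duplicate receiver_id in registry")
  check_coords(df$lat, df$lon)
  if (is.null(df$is_island_site)) df$is_island_site <- FALSE
  df$is_island_site <- as.logical(df$is_island_site)
  df[c("receiver_id", "lat", "lon", "is_island_site")]
}

#' Read a tag deployment table
#'
#' Canonical CSV: columns `tag_id`, `species`, `season` (`spring` or
#' `autumn`), `release_ts_utc` (ISO-8601 UTC or epoch seconds), `lat`,
#' `lon`, `fat_score` (visual fat score, ordinal 0-8, quarter steps
#' allowed). One deployment per tag.
#'
#' @param path Path to a CSV file.
#' @return `data.frame` with `release_t` as POSIXct UTC.
#' @export
read_deployments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tag_id", "species", "season", "release_ts_utc", "lat", "lon", "fat_score")
  if (!all(need %in% names(df))) {
    stop("deployment table must have columns: ", paste(need, collapse = ", "))
  }
  df$tag_id <- as.character(df$tag_id)
  if (anyDuplicated(df$tag_id)) stop("more than one deployment per tag_id")
  if (!all(df$season %in% c("spring", "autumn"))) stop("season must be 'spring' or 'autumn'")
  check_coords(df$lat, df$lon)
  if (any(df$fat_score < 0 | df$fat_score > 8, na.rm = TRUE)) stop("fat_score outside 0-8")
  df$release_t <- parse_ts(df$release_ts_utc, "deployment table")
  df[c("tag_id", "species", "season", "release_t", "lat", "lon", "fat_score")]
}

#' Read a detection table
#'
#' Canonical CSV: columns `tag_id`, `ts_utc`, `receiver_id`, optionally
#' `fp_score` (estimated probability the detection is a false positive) and
#' `source` (`network` or `recapture`; default `network`). Timestamps may
#' be ISO-8601 (`2018-03-20T12:00:00Z`, `T` or space, optional trailing
#' `Z`) or epoch seconds; both parse to the same instant. Receiver ids are
#' validated against the registry; output is sorted by tag then time.
#'
#' @param path Path to a CSV file.
#' @param receivers Receiver registry from [read_receivers()].
#' @return `data.frame` with columns `tag_id`, `t` (POSIXct UTC),
#'   `receiver_id`, `fp_score`, `source`.
#' @export
read_detections <- function(path, receivers) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tag_id", "ts_utc", "receiver_id")
  if (!all(need %in% names(df))) {
    stop("detection table must have columns: ", paste(need, collapse = ", "))
  }
  df$tag_id <- as.character(df$tag_id)
  df$receiver_id <- as.character(df$receiver_id)
  unknown <- setdiff(unique(df$receiver_id), receivers$receiver_id)
  if (length(unknown)) {
    stop("detection table references unknown receiver id(s): ",
         paste(unknown, collapse = ", "))
  }
  df$t <- parse_ts(df$ts_utc, "detection table")
  if (is.null(df$fp_score)) df$fp_score <- NA_real_
  df$fp_score <- as.numeric(df$fp_score)
  if (any(df$fp_score < 0 | df$fp_score > 1, na.rm = TRUE)) stop("fp_score outside [0, 1]")
  if (is.null(df$source)) df$source <- "network"
  df$source[is.na(df$source) | df$source == ""] <- "network"
  if (!all(df$source %in% c("network", "recapture"))) {
    stop("source must be 'network' or 'recapture'")
  }
  out <- df[order(df$tag_id, df$t, df$receiver_id),
            c("tag_id", "t", "receiver_id", "fp_score", "source")]
  rownames(out) <- NULL
  out
}

#' Write a detection table in the canonical dialect
#'
#' Comma-separated, UTF-8, ISO-8601 UTC timestamps; round-trips through
#' [read_detections()] bit-identically.
#'
#' @param detections Detection `data.frame` as returned by [read_detections()].
#' @param path Output path.
#' @export
write_detections <- function(detections, path) {
  out <- data.frame(
    tag_id = detections$tag_id,
    ts_utc = format(detections$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    receiver_id = detections$receiver_id,
    fp_score = detections$fp_score,
    source = detections$source
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# parse ISO-8601 (T or space separator, optional Z) or epoch seconds;
# errors name the offending rows
parse_ts <- function(x, what) {
  x <- trimws(as.character(x))
  t <- rep(as.POSIXct(NA), length(x))
  iso <- gsub("T", " ", sub("Z$", "", x))
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M")) {
    parsed <- as.POSIXct(strptime(iso[is.na(t)], fmt, tz = "UTC"))
    t[is.na(t)][!is.na(parsed)] <- parsed[!is.na(parsed)]
  }
  num <- suppressWarnings(as.numeric(x))
  epoch <- is.na(t) & !is.na(num)
  t[epoch] <- as.POSIXct(num[epoch], origin = "1970-01-01", tz = "UTC")
  if (anyNA(t)) {
    stop("unparseable timestamp(s) in ", what, " at row(s): ",
         paste(utils::head(which(is.na(t)), 10), collapse = ", "))
  }
  attr(t, "tzone") <- "UTC"
  t
}

#' Drop probable false-positive detections
#'
#' Removes detections whose false-positive probability score is at or above
#' the threshold. Detections without a score and recaptures at the
#' deployment site are always retained. Idempotent; output is a subset of
#' the input.
#'
#' @param detections Detection `data.frame`.
#' @param cfg A [filter_config()].
#' @return Filtered detection `data.frame`.
#' @export
filter_false_positives <- function(detections, cfg = filter_config()) {
  drop <- !is.na(detections$fp_score) &
    detections$fp_score >= cfg$fp_threshold &
    detections$source != "recapture"
  out <- detections[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
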