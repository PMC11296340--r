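#' Construct a recording-session object
#'
#' A session is one recording day: denoised fluorescence traces and deconvolved
#' transients (cells x bins at the analysis sample rate, 5 Hz by default), a
#' trial table with context and treatment labels, optional behavior streams,
#' and metadata. Time is 0-based with half-open bin intervals
#' `[start_bin, end_bin)` throughout.
#'
#' @param traces cells x bins numeric matrix of denoised fluorescence (a.u.).
#' @param transients cells x bins non-negative matrix of deconvolved
#'   transients; same shape as `traces`.
#' @param cell_ids integer/character vector of global cell identifiers, one
#'   per row of `traces`.
#' @param trial_table data.frame with columns `start_bin`, `end_bin`,
#'   `context_id` (one of "C1", "C2", "novel"), `treatment` (one of "none",
#'   "VEH", "C21"), and reward-well center coordinates `well1_x`, `well1_y`,
#'   `well2_x`, `well2_y` (pixels).
#' @param behavior optional list with `head_xy` (bins x 2 pixel matrix),
#'   `speed` (pixels/s), `digging`, `sniffing` (logical vectors); all streams
#'   of length `ncol(traces)`.
#' @param meta list; recognized entries: `day` (integer), `kind`
#'   ("training" or "probe"), `mouse`, `sample_rate` (Hz, default 5).
#' @return an object of class `ca_session`.
#' @seealso [write_session()], [read_session()]
#' @export
ca_session <- function(traces, transients, cell_ids, trial_table,
                       behavior = NULL, meta = list()) {
  meta$sample_rate <- meta$sample_rate %||% 5
  meta$kind <- meta$kind %||% "training"
  meta$day <- meta$day %||% 1L
  meta$mouse <- meta$mouse %||% "m1"
  s <- structure(
    list(traces = traces, transients = transients, cell_ids = cell_ids,
         trial_table = trial_table, behavior = behavior, meta = meta),
    class = "ca_session")
  validate_session(s)
  s
}

#' Validate a session object
#'
#' Checks the structural invariants of a session bundle; on failure raises an
#' error naming the offending field.
#'
#' @param s a `ca_session`.
#' @return `s`, invisibly.
#' @export
validate_session <- function(s) {
  if (!is.matrix(s$traces) || !is.numeric(s$traces))
    stop_field("traces", "must be a numeric matrix")
  if (is.null(s$transients))
    stop_field("transients", "missing deconvolved transients array")
  if (!is.matrix(s$transients) ||
      !identical(dim(s$transients), dim(s$traces)))
    stop_field("transients", "must share the shape of traces")
  if (any(s$transients < 0))
    stop_field("transients", "deconvolved transients must be non-negative")
  if (length(s$cell_ids) != nrow(s$traces))
    stop_field("cell_ids", "one id per trace row required")
  if (anyDuplicated(s$cell_ids))
    stop_field("cell_ids", "ids must be unique")
  tt <- s$trial_table
  need <- c("start_bin", "end_bin", "context_id", "treatment",
            "well1_x", "well1_y", "well2_x", "well2_y")
  if (!is.data.frame(tt) || !all(need %in% names(tt)))
    stop_field("trial_table",
               paste("required columns:", paste(need, collapse = ", ")))
  nb <- ncol(s$traces)
  if (any(tt$start_bin >= tt$end_bin))
    stop_field("trial_table", "start_bin must be < end_bin")
  if (any(tt$start_bin < 0) || any(tt$end_bin > nb))
    stop_field("trial_table", "trial windows must lie within [0, bins)")
  if (!all(tt$context_id %in% c("C1", "C2", "novel")))
    stop_field("trial_table", "context_id must be C1, C2 or novel")
  if (!all(tt$treatment %in% c("none", "VEH", "C21")))
    stop_field("trial_table", "treatment must be none, VEH or C21")
  if (!is.null(s$behavior)) {
    b <- s$behavior
    if (!is.matrix(b$head_xy) || nrow(b$head_xy) != nb || ncol(b$head_xy) != 2)
      stop_field("behavior", "head_xy must be bins x 2")
    for (f in c("speed", "digging", "sniffing"))
      if (length(b[[f]]) != nb)
        stop_field("behavior", sprintf("stream '%s' must have length bins", f))
  }
  invisible(s)
}

#' @export
print.ca_session <- function(x, ...) {
  cat(sprintf("<ca_session> mouse %s, day %d (%s): %d cells x %d bins @ %g Hz, %d trials\n",
              x$meta$mouse, x$meta$day, x$meta$kind, nrow(x$traces),
              ncol(x$traces), x$meta$sample_rate, nrow(x$trial_table)))
  ctx <- table(x$trial_table$context_id)
  cat("  contexts:", paste(sprintf("%s=%d", names(ctx), ctx), collapse = ", "),
      if (is.null(x$behavior)) "(no behavior)" else "(behavior attached)", "\n")
  invisible(x)
}

n_bins <- function(s) ncol(s$traces)

SCHEMA_VERSION <- "1.0"

#' Write a session bundle to disk
#'
#' The bundle is a directory holding plain-text arrays (`traces.csv`,
#' `transients.csv`, optional `behavior.csv`) plus a `session.json` file with
#' the trial table, metadata and a schema version stamp. Floating-point values
#' are written with shortest-round-trip precision, so `read_session()`
#' recovers every field exactly.
#'
#' @param s a `ca_session`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  validate_session(s)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tr <- data.table::as.data.table(s$traces)
  data.table::fwrite(cbind(data.table::data.table(cell_id = s$cell_ids), tr),
                     file.path(path, "traces.csv"))
  ts <- data.table::as.data.table(s$transients)
  data.table::fwrite(cbind(data.table::data.table(cell_id = s$cell_ids), ts),
                     file.path(path, "transients.csv"))
  if (!is.null(s$behavior)) {
    b <- s$behavior
    data.table::fwrite(data.table::data.table(
      x = b$head_xy[, 1], y = b$head_xy[, 2], speed = b$speed,
      digging = b$digging, sniffing = b$sniffing),
      file.path(path, "behavior.csv"))
  }
  meta <- list(schema_version = SCHEMA_VERSION, meta = s$meta,
               trial_table = s$trial_table,
               has_behavior = !is.null(s$behavior))
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Inverse of [write_session()]; validates the bundle and raises a structured
#' error naming any missing or inconsistent field.
#'
#' @param path bundle directory.
#' @return a `ca_session`.
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop_field("path", paste("no such bundle:", path))
  jf <- file.path(path, "session.json")
  if (!file.exists(jf)) stop_field("session.json", "missing metadata file")
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  read_mat <- function(name) {
    f <- file.path(path, paste0(name, ".csv"))
    if (!file.exists(f)) stop_field(name, "missing array file")
    dt <- data.table::fread(f)
    m <- as.matrix(dt[, -1])
    dimnames(m) <- NULL
    list(ids = dt[[1]], m = m)
  }
  tr <- read_mat("traces")
  ts <- read_mat("transients")
  if (!identical(tr$ids, ts$ids))
    stop_field("transients", "cell ids disagree with traces")
  behavior <- NULL
  if (isTRUE(meta$has_behavior)) {
    bf <- file.path(path, "behavior.csv")
    if (!file.exists(bf)) stop_field("behavior", "missing behavior file")
    b <- data.table::fread(bf)
    behavior <- list(head_xy = cbind(b$x, b$y), speed = b$speed,
                     digging = as.logical(b$digging),
                     sniffing = as.logical(b$sniffing))
  }
  tt <- as.data.frame(meta$trial_table, stringsAsFactors = FALSE)
  ca_session(tr$m, ts$m, tr$ids, tt, behavior = behavior, meta = meta$meta)
}

#' Build a registration map between two sets of cell identifiers
#'
#' Cross-session registration pairs cell identities between a session X and a
#' session Y. The map must be injective on both sides. When both sessions
#' carry global cell ids (as the synthetic generator guarantees), the exact
#' map is the identity on the shared ids.
#'
#' @param pairs data.frame with columns `id_x`, `id_y`.
#' @return an object of class `registration_map`.
#' @export
registration_map <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("id_x", "id_y") %in% names(pairs)))
  if (anyDuplicated(pairs$id_x) || anyDuplicated(pairs$id_y))
    stop_field("pairs", "registration must be injective on both sides")
  structure(list(pairs = pairs), class = "registration_map")
}

#' Registration between two sessions via shared global ids
#'
#' @param sx,sy `ca_session` objects whose `cell_ids` are drawn from one
#'   global id space.
#' @return a `registration_map` over the intersection of the two id sets.
#' @export
register_by_id <- function(sx, sy) {
  shared <- intersect(sx$cell_ids, sy$cell_ids)
  registration_map(data.frame(id_x = shared, id_y = shared))
}

#' @export
print.registration_map <- function(x, ...) {
  cat(sprintf("<registration_map> %d registered cell pairs\n", nrow(x$pairs)))
  invisible(x)
}
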