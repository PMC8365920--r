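# Trajectory logs: the tabular record of an episode at one row per control
# step, written/read as plain CSV with a small comment header carrying the
# schema version, seed and config hash.  This is the interchange format
# between the live environment, the fixture generator and the offline
# scorer.

.traj_schema <- "gaitenv-trajectory-1"

#' Trajectory column names
#'
#' The documented column order of a trajectory log: time (s); pelvis
#' ground-plane position `pel_x`/`pel_lat`, height and pitch; pelvis
#' ground-plane velocity `v_x`/`v_lat`; six joint angles and speeds (rad,
#' rad/s; right hip/knee/ankle then left); per-foot contact flags (0/1);
#' one activation column per muscle (`act_<NAME>_<SIDE>`, in canonical
#' order); and the current target's location, index and required dwell.
#'
#' @param planar Use the 18-muscle sagittal-plane activation set instead of
#'   the full 22.
#' @return Character vector of column names.
#' @export
trajectory_columns <- function(planar = FALSE) {
  mus <- muscle_order(planar = planar)
  c("time", "pel_x", "pel_lat", "pel_height", "pel_pitch", "v_x", "v_lat",
    "hip_r", "knee_r", "ankle_r", "hip_l", "knee_l", "ankle_l",
    "dhip_r", "dknee_r", "dankle_r", "dhip_l", "dknee_l", "dankle_l",
    "contact_r", "contact_l",
    paste0("act_", mus),
    "tgt_x", "tgt_lat", "tgt_index", "tgt_dwell")
}

activation_columns <- function(df) {
  grep("^act_", names(df), value = TRUE)
}

#' Write a trajectory log to CSV
#'
#' Plain CSV with fixed decimal precision (12 significant digits) and
#' comment header lines (`# key: value`) recording the schema version, seed
#' and configuration hash, so every run is reproducible from the log alone.
#'
#' @param log Trajectory data frame (see [trajectory_columns()]).
#' @param path Output file.
#' @param seed Seed recorded in the header (may be `NA`).
#' @param config_hash Configuration hash recorded in the header.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(log, path, seed = NA, config_hash = "") {
  validate_trajectory(log)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# schema: ", .traj_schema),
               paste0("# seed: ", seed),
               paste0("# config_hash: ", config_hash)), con)
  fmt <- as.data.frame(lapply(log, function(col) {
    if (is.numeric(col)) formatC(col, digits = 12, format = "g") else col
  }), check.names = FALSE)
  utils::write.csv(fmt, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory log from CSV
#'
#' Validates the schema header and the column set; the header metadata is
#' attached as attributes `seed` and `config_hash`.
#'
#' @param path CSV file written by [write_trajectory()].
#' @return A tibble, one row per control step.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such trajectory file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty input: ", path, call. = FALSE)
  hdr <- readLines(path, n = 3)
  meta <- list()
  for (h in hdr[startsWith(hdr, "# ")]) {
    kv <- strsplit(sub("^# ", "", h), ": ", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- if (length(kv) > 1) kv[2] else ""
  }
  if (!identical(meta$schema, .traj_schema)) {
    stop("not a ", .traj_schema, " file: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  validate_trajectory(df)
  attr(df, "seed") <- meta$seed
  attr(df, "config_hash") <- meta$config_hash
  df
}

validate_trajectory <- function(df) {
  if (nrow(df) == 0) stop("empty trajectory (no rows)", call. = FALSE)
  base_cols <- setdiff(trajectory_columns(), paste0("act_", muscle_order()))
  missing <- setdiff(base_cols, names(df))
  if (length(missing) > 0) {
    stop("trajectory missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  nact <- length(activation_columns(df))
  if (!nact %in% c(18L, 22L)) {
    stop("expected 22 (or 18 sagittal-plane) activation columns, found ",
         nact, call. = FALSE)
  }
  dt <- diff(df$time)
  if (nrow(df) > 1 && (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6)) {
    stop("non-monotone or unevenly spaced time column", call. = FALSE)
  }
  invisible(df)
}

#' Hash a configuration
#'
#' Order-stable structural hash of a configuration list, recorded in
#' trajectory headers for reproducibility.
#'
#' @param config Any serialisable list.
#' @return Character scalar.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  # small polynomial rolling hash over the serialised text; stable across
  # sessions and platforms
  h <- 17
  for (b in utils::head(as.integer(charToRaw(as.character(s))), 1e5)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}
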