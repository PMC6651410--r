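#' Write a trial recording to a bundled container
#'
#' The container is a directory of plain per-stream CSV files (header row:
#' time plus channel names, time in seconds) and a JSON manifest, mirroring
#' the stream groups segments / grf / imu / events / meta.
#'
#' @param trial a `trial_recording`.
#' @param path directory to create (must not exist unless `overwrite`).
#' @param overwrite replace an existing container.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, overwrite = FALSE) {
  stopifnot(inherits(trial, "trial_recording"))
  if (dir.exists(path)) {
    if (!overwrite) fail("container %s already exists", path)
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  segs <- trial$segment_coms
  wide <- data.frame(time = trial$t_mocap)
  for (i in seq_len(dim(segs)[3])) {
    nm <- dimnames(segs)[[3]][i]
    for (j in 1:3)
      wide[[paste(nm, c("x", "y", "z")[j], sep = "_")]] <- segs[, j, i]
  }
  write.csv(wide, file.path(path, "segments.csv"), row.names = FALSE)
  g <- trial$grf
  write.csv(data.frame(time = g$t, fz1 = g$fz1,
                       cop1_x = g$cop1[, 1], cop1_y = g$cop1[, 2],
                       fz2 = g$fz2, cop2_x = g$cop2[, 1],
                       cop2_y = g$cop2[, 2]),
            file.path(path, "grf.csv"), row.names = FALSE)
  write.csv(trial$imu, file.path(path, "imu.csv"), row.names = FALSE)
  write.csv(as.data.frame(trial$events), file.path(path, "events.csv"),
            row.names = FALSE)
  meta <- trial$meta
  meta$noise <- unclass(meta$noise)
  sj <- unclass(meta$subject)
  # named atomic vectors must become lists to survive JSON as objects
  sj$speed_scalars <- as.list(sj$speed_scalars)
  sj$trunk_amp_deg <- as.list(sj$trunk_amp_deg)
  meta$subject <- sj
  jsonlite::write_json(
    list(subject_id = trial$subject_id, speed_class = trial$speed_class,
         mocap_rate = trial$mocap_rate, force_rate = trial$force_rate,
         imu_rate = trial$imu_rate, meta = meta),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial recording from a bundled container
#'
#' @param path directory written by [write_trial()].
#' @return a `trial_recording`.
#' @export
read_trial <- function(path) {
  if (!dir.exists(path)) fail("no container at %s", path)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  wide <- read.csv(file.path(path, "segments.csv"))
  n <- nrow(wide)
  seg_names <- unique(sub("_[xyz]$", "", names(wide)[-1]))
  segs <- array(0, dim = c(n, 3, length(seg_names)),
                dimnames = list(NULL, c("x", "y", "z"), seg_names))
  for (i in seq_along(seg_names)) for (j in 1:3)
    segs[, j, i] <- wide[[paste(seg_names[i], c("x", "y", "z")[j], sep = "_")]]
  gd <- read.csv(file.path(path, "grf.csv"))
  ev <- read.csv(file.path(path, "events.csv"))
  m <- meta$meta
  m$noise <- do.call(noise_spec, m$noise[c("accel_sigma", "gyro_sigma",
                                           "mag_sigma", "drift_rate", "seed")])
  sj <- m$subject
  m$subject <- subject_params(sj$subject_id, sj$height_cm, sj$mass_kg,
                              sj$leg_length_m, sj$preferred_cadence,
                              unlist(sj$speed_scalars), sj$com_height_m,
                              sj$step_length_m, sj$step_width_m,
                              sj$sway_amp_m, sj$vert_amp_m,
                              unlist(sj$trunk_amp_deg), sj$seed)
  trial <- structure(list(
    subject_id = meta$subject_id, speed_class = meta$speed_class,
    mocap_rate = meta$mocap_rate, force_rate = meta$force_rate,
    imu_rate = meta$imu_rate,
    t_mocap = wide$time, segment_coms = segs,
    grf = list(t = gd$time, fz1 = gd$fz1, fz2 = gd$fz2,
               cop1 = cbind(x = gd$cop1_x, y = gd$cop1_y),
               cop2 = cbind(x = gd$cop2_x, y = gd$cop2_y)),
    imu = read.csv(file.path(path, "imu.csv")),
    events = structure(ev, class = c("gait_events", "data.frame")),
    meta = m), class = "trial_recording")
  validate_trial_recording(trial)
  trial
}

#' Write per-cycle inclination angles as CSV
#'
#' Long format: one row per normalized frame with columns frame,
#' sagittal_deg, frontal_deg, subject, trial, speed.
#'
#' @param ia_list list of `ia_series` (each with provenance attributes).
#' @param file output CSV path.
#' @return the written data.frame, invisibly.
#' @export
write_ia_csv <- function(ia_list, file) {
  rows <- do.call(rbind, lapply(ia_list, function(ia) {
    pv <- attr(ia, "provenance")
    data.frame(frame = seq_len(nrow(ia)), sagittal_deg = ia$sagittal,
               frontal_deg = ia$frontal,
               subject = pv$subject %||% NA, trial = pv$trial %||% NA,
               speed = pv$speed %||% NA)
  }))
  write.csv(rows, file, row.names = FALSE)
  invisible(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
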