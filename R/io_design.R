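# Data containers, readers/writers, channel/ROI layout and experiment design.

#' Experiment design for one dyad
#'
#' Describes one dyad's session: the two participants and the ordered,
#' non-overlapping condition blocks (BB = back-to-back rest, FM = free
#' movement, IS = intentional synchrony), each with a start time and duration
#' in seconds of session time.
#'
#' @param dyad_id Character scalar.
#' @param participant_ids Character vector of length 2.
#' @param blocks Data frame with columns `condition` (one of `"BB"`, `"FM"`,
#'   `"IS"`), `start_s` and `duration_s` (seconds). Blocks must be ordered in
#'   time and non-overlapping, with positive durations.
#' @param group `"real"` for a measured dyad, `"pseudo"` for a permutation
#'   pairing.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(dyad_id, participant_ids, blocks, group = "real") {
  stopifnot(is.character(dyad_id), length(dyad_id) == 1)
  if (length(participant_ids) != 2)
    stop("an experiment design requires exactly 2 participants")
  req <- c("condition", "start_s", "duration_s")
  if (!all(req %in% names(blocks)))
    stop("blocks must have columns condition, start_s, duration_s")
  blocks$condition <- as.character(blocks$condition)
  bad <- setdiff(blocks$condition, CONDITION_LEVELS)
  if (length(bad))
    stop("unknown condition label: ", paste(bad, collapse = ", "))
  if (any(blocks$duration_s <= 0)) stop("block duration_s must be > 0")
  if (is.unsorted(blocks$start_s, strictly = TRUE))
    stop("condition blocks must be ordered in time")
  ends <- blocks$start_s + blocks$duration_s
  if (nrow(blocks) > 1 && any(blocks$start_s[-1] < ends[-nrow(blocks)]))
    stop("condition blocks overlap")
  group <- match.arg(group, c("real", "pseudo"))
  structure(
    list(dyad_id = dyad_id,
         participant_ids = as.character(participant_ids),
         blocks = blocks[, req],
         group = group),
    class = "experiment_design")
}

#' Default three-condition design
#'
#' Convenience constructor: the three task conditions in a given order,
#' back-to-back blocks of equal duration (default 120 s).
#'
#' @param dyad_id,participant_ids See [experiment_design()].
#' @param conditions Order of the condition labels.
#' @param duration_s Block duration in seconds.
#' @param gap_s Gap between consecutive blocks, seconds.
#' @return An `experiment_design`.
#' @export
default_design <- function(dyad_id, participant_ids,
                           conditions = c("BB", "FM", "IS"),
                           duration_s = 120, gap_s = 0) {
  n <- length(conditions)
  experiment_design(
    dyad_id, participant_ids,
    data.frame(condition = conditions,
               start_s = (seq_len(n) - 1) * (duration_s + gap_s),
               duration_s = duration_s))
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design: dyad", x$dyad_id,
      sprintf("(%s)", x$group), "\n")
  cat("Participants:", paste(x$participant_ids, collapse = ", "), "\n")
  print(x$blocks)
  invisible(x)
}

#' 3D hand-motion trace for one participant and condition block
#'
#' Positions are in device length units with the convention that x runs along
#' the inter-participant axis (forward/backward), y right/left, z up/down.
#' Timestamps are block-relative: `(0:(n-1))/fs`.
#'
#' @param participant_id Character scalar.
#' @param condition Condition label (`"BB"`, `"FM"`, `"IS"`).
#' @param pos Numeric matrix, n x 3 (columns x, y, z).
#' @param fs Sampling rate, Hz (default 50).
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(participant_id, condition, pos, fs = 50) {
  stopifnot(fs > 0)
  pos <- as.matrix(pos)
  if (ncol(pos) != 3) stop("pos must have 3 columns (x, y, z)")
  if (!all(is.finite(pos))) stop("pos must be finite")
  condition <- match.arg(condition, CONDITION_LEVELS)
  structure(
    list(participant_id = as.character(participant_id),
         condition = condition, fs = fs,
         t = (seq_len(nrow(pos)) - 1) / fs,
         pos = unname(pos)),
    class = "motion_trace")
}

#' Read dyadic motion data and slice it into condition blocks
#'
#' Reads a CSV with columns `time, participant, condition, x, y, z` (time in
#' seconds of session time) and returns one [motion_trace()] per participant
#' and design block. Sampling must already be uniform: gaps beyond tolerance
#' raise an error rather than being resampled.
#'
#' @param path CSV file path.
#' @param design An [experiment_design()].
#' @param tol Relative tolerance on sampling-interval uniformity.
#' @return List of `motion_trace` objects (participant-major, block order).
#' @export
read_motion <- function(path, design, tol = 1e-6) {
  stopifnot(inherits(design, "experiment_design"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time", "participant", "condition", "x", "y", "z")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$condition), CONDITION_LEVELS)
  if (length(bad))
    stop("unknown condition label: ", paste(bad, collapse = ", "))
  out <- list()
  for (p in design$participant_ids) {
    for (b in seq_len(nrow(design$blocks))) {
      cond <- design$blocks$condition[b]
      t0 <- design$blocks$start_s[b]
      t1 <- t0 + design$blocks$duration_s[b]
      rows <- df[df$participant == p & df$time >= t0 & df$time < t1, ]
      if (nrow(rows) == 0)
        stop("empty block: participant ", p, ", condition ", cond)
      if (any(rows$condition != cond))
        stop("condition label mismatch inside block ", cond)
      rows <- rows[order(rows$time), ]
      dt <- diff(rows$time)
      if (nrow(rows) >= 3) {
        dt0 <- stats::median(dt)
        if (any(abs(dt - dt0) > tol * dt0 + 1e-12))
          stop("non-uniform sampling in block ", cond,
               " for participant ", p)
      }
      fs <- 1 / stats::median(dt)
      out[[length(out) + 1]] <- motion_trace(
        p, cond, as.matrix(rows[, c("x", "y", "z")]), fs = round(fs, 6))
    }
  }
  out
}

#' Write motion traces to the canonical CSV format
#'
#' Inverse of [read_motion()]: block-relative timestamps are shifted to the
#' session times given by `design`.
#'
#' @param traces List of [motion_trace()] objects.
#' @param path Output CSV path.
#' @param design The [experiment_design()] supplying block start times.
#' @return `path`, invisibly.
#' @export
write_motion <- function(traces, path, design) {
  starts <- stats::setNames(design$blocks$start_s, design$blocks$condition)
  rows <- lapply(traces, function(tr) {
    data.frame(time = tr$t + starts[[tr$condition]],
               participant = tr$participant_id,
               condition = tr$condition,
               x = tr$pos[, 1], y = tr$pos[, 2], z = tr$pos[, 3])
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$participant, df$time), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Optode channel layout with ROI assignment
#'
#' @param df Data frame with columns `channel`, `source_x`, `source_y`,
#'   `source_z`, `detector_x`, `detector_y`, `detector_z` (cm) and optionally
#'   `roi` (one of `"L.IFG"`, `"R.IFG"`, `"dmPFC"`, `"none"`). Midpoints and
#'   source-detector separations are derived.
#' @return An object of class `channel_layout` (a data frame).
#' @export
channel_layout <- function(df) {
  req <- c("channel", "source_x", "source_y", "source_z",
           "detector_x", "detector_y", "detector_z")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("layout missing columns: ", paste(miss, collapse = ", "))
  df$channel <- as.character(df$channel)
  if (anyDuplicated(df$channel)) stop("duplicate channel ids in layout")
  if (is.null(df$roi)) df$roi <- "none"
  bad <- setdiff(unique(df$roi), c(hypersync_constants$roi_levels, "none"))
  if (length(bad)) stop("unknown ROI label: ", paste(bad, collapse = ", "))
  df$mid_x <- (df$source_x + df$detector_x) / 2
  df$mid_y <- (df$source_y + df$detector_y) / 2
  df$mid_z <- (df$source_z + df$detector_z) / 2
  df$separation_cm <- sqrt((df$source_x - df$detector_x)^2 +
                           (df$source_y - df$detector_y)^2 +
                           (df$source_z - df$detector_z)^2)
  if (any(df$separation_cm <= 0)) stop("optode separation must be > 0")
  structure(df, class = c("channel_layout", "data.frame"))
}

#' Read a channel layout CSV
#' @param path CSV with the [channel_layout()] columns.
#' @return A `channel_layout`.
#' @export
read_layout <- function(path) {
  channel_layout(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Assign channels to regions of interest
#'
#' Sets the `roi` field of a layout from an explicit channel-to-ROI map.
#' Channels absent from the map get `roi = "none"` and are excluded from all
#' downstream coupling computations. The ROI vocabulary is closed:
#' `L.IFG`, `R.IFG`, `dmPFC`.
#'
#' @param layout A [channel_layout()].
#' @param roi_map Named character vector, `channel id -> ROI label`.
#' @return The layout with `roi` set.
#' @export
assign_rois <- function(layout, roi_map) {
  stopifnot(inherits(layout, "channel_layout"))
  bad <- setdiff(unique(unname(roi_map)), hypersync_constants$roi_levels)
  if (length(bad)) stop("unknown ROI label: ", paste(bad, collapse = ", "))
  unknown <- setdiff(names(roi_map), layout$channel)
  if (length(unknown))
    stop("channel not in layout: ", paste(unknown, collapse = ", "))
  layout$roi <- "none"
  layout$roi[match(names(roi_map), layout$channel)] <- unname(roi_map)
  layout
}

#' Raw two-wavelength fNIRS intensities for one participant
#'
#' @param participant_id Character scalar.
#' @param intensity Numeric array, channels x wavelengths x time, strictly
#'   positive detector units.
#' @param channel_ids Character vector of channel ids (rows of `intensity`).
#' @param fs Sampling rate, Hz (default 10).
#' @param wavelengths Wavelengths in nm (default 760, 850).
#' @return An object of class `raw_nirs`.
#' @export
raw_nirs <- function(participant_id, intensity, channel_ids,
                     fs = 10, wavelengths = c(760, 850)) {
  stopifnot(fs > 0, length(dim(intensity)) == 3)
  if (dim(intensity)[2] != length(wavelengths))
    stop("both wavelengths must be present for every channel")
  if (dim(intensity)[1] != length(channel_ids))
    stop("channel_ids must match intensity rows")
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("intensities must be strictly positive")
  structure(
    list(participant_id = as.character(participant_id),
         fs = fs, wavelengths = wavelengths,
         channel_ids = as.character(channel_ids),
         intensity = unname(intensity)),
    class = "raw_nirs")
}

#' Write raw fNIRS intensities to the tabular fallback format
#'
#' Long CSV with columns `time, channel, wavelength, intensity`.
#'
#' @param nirs A [raw_nirs()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nirs_csv <- function(nirs, path) {
  d <- dim(nirs$intensity)
  tt <- (seq_len(d[3]) - 1) / nirs$fs
  df <- expand.grid(time = tt, channel = nirs$channel_ids,
                    wavelength = nirs$wavelengths,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$intensity <- as.vector(aperm(nirs$intensity, c(3, 1, 2)))
  df <- df[order(df$channel, df$wavelength, df$time), ]
  df <- cbind(participant = nirs$participant_id, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_nirs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time", "channel", "wavelength", "intensity")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  chans <- unique(df$channel)
  wls <- sort(unique(df$wavelength))
  if (length(wls) != 2) stop("missing wavelength: expected 2, got ", length(wls))
  tt <- sort(unique(df$time))
  fs <- 1 / stats::median(diff(tt))
  arr <- array(NA_real_, c(length(chans), 2, length(tt)))
  for (ci in seq_along(chans)) for (wi in 1:2) {
    rows <- df[df$channel == chans[ci] & df$wavelength == wls[wi], ]
    rows <- rows[order(rows$time), ]
    if (nrow(rows) != length(tt)) stop("missing wavelength data for channel ", chans[ci])
    arr[ci, wi, ] <- rows$intensity
  }
  pid <- if ("participant" %in% names(df)) as.character(df$participant[1]) else "unknown"
  raw_nirs(pid, arr, as.character(chans), fs = round(fs, 6), wavelengths = wls)
}

#' Read an fNIRS recording (SNIRF or tabular CSV)
#'
#' Dispatches on the file extension: `.snirf` files are read through the
#' HDF5 SNIRF layout (requires the `rhdf5` package), anything else through
#' the documented CSV fallback (`time, channel, wavelength, intensity`).
#'
#' @param path File path.
#' @param layout Optional [channel_layout()]; channels without a layout entry
#'   get `roi = "none"`.
#' @return List with elements `nirs` (a [raw_nirs()]) and `layout`.
#' @export
read_nirs <- function(path, layout = NULL) {
  nirs <- if (grepl("\\.snirf$", path, ignore.case = TRUE)) {
    read_snirf(path)
  } else {
    read_nirs_csv(path)
  }
  list(nirs = nirs, layout = layout)
}

#' Write a raw fNIRS recording as a minimal SNIRF (HDF5) file
#'
#' Writes the continuous-wave SNIRF groups (`/nirs/data1` time series and
#' measurement list, `/nirs/probe` wavelengths). Requires `rhdf5`.
#'
#' @param nirs A [raw_nirs()].
#' @param path Output path (`.snirf`).
#' @return `path`, invisibly.
#' @export
write_snirf <- function(nirs, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("SNIRF support requires the rhdf5 package; use write_nirs_csv()")
  if (file.exists(path)) unlink(path)
  d <- dim(nirs$intensity)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/data1")
  rhdf5::h5createGroup(path, "nirs/probe")
  # measurement columns: channel-major, wavelength within channel
  nmeas <- d[1] * d[2]
  mat <- matrix(NA_real_, nrow = d[3], ncol = nmeas)
  k <- 0
  for (ci in seq_len(d[1])) for (wi in seq_len(d[2])) {
    k <- k + 1
    mat[, k] <- nirs$intensity[ci, wi, ]
  }
  rhdf5::h5write(mat, path, "nirs/data1/dataTimeSeries")
  rhdf5::h5write((seq_len(d[3]) - 1) / nirs$fs, path, "nirs/data1/time")
  rhdf5::h5write(nirs$wavelengths, path, "nirs/probe/wavelengths")
  rhdf5::h5write(nirs$channel_ids, path, "nirs/probe/channelLabels")
  rhdf5::h5write(nirs$participant_id, path, "nirs/metaDataTags.SubjectID")
  k <- 0
  for (ci in seq_len(d[1])) for (wi in seq_len(d[2])) {
    k <- k + 1
    g <- sprintf("nirs/data1/measurementList%d", k)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(ci, path, file.path(g, "sourceIndex"))
    rhdf5::h5write(ci, path, file.path(g, "detectorIndex"))
    rhdf5::h5write(wi, path, file.path(g, "wavelengthIndex"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

read_snirf <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("SNIRF support requires the rhdf5 package")
  on.exit(rhdf5::h5closeAll())
  mat <- rhdf5::h5read(path, "nirs/data1/dataTimeSeries")
  tt <- as.vector(rhdf5::h5read(path, "nirs/data1/time"))
  wls <- as.vector(rhdf5::h5read(path, "nirs/probe/wavelengths"))
  chans <- as.character(rhdf5::h5read(path, "nirs/probe/channelLabels"))
  pid <- tryCatch(as.character(rhdf5::h5read(path, "nirs/metaDataTags.SubjectID")),
                  error = function(e) "unknown")
  nmeas <- ncol(mat)
  nw <- length(wls)
  nch <- nmeas / nw
  arr <- array(NA_real_, c(nch, nw, nrow(mat)))
  k <- 0
  for (ci in seq_len(nch)) for (wi in seq_len(nw)) {
    k <- k + 1
    # wavelength index recorded per measurement; writer uses channel-major order
    widx <- as.integer(rhdf5::h5read(
      path, sprintf("nirs/data1/measurementList%d/wavelengthIndex", k)))
    arr[ci, widx, ] <- mat[, k]
  }
  fs <- 1 / stats::median(diff(tt))
  raw_nirs(pid, arr, chans, fs = round(fs, 6), wavelengths = wls)
}
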