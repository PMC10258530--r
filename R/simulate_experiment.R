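# End-to-end synthetic dataset generation in the on-disk interchange formats,
# plus a record-level simulator for the statistical stage.

#' Illustrative prefrontal channel layout
#'
#' A 23-channel layout over the prefrontal cortex with channels assigned to
#' the three regions of interest (left/right inferior frontal gyrus,
#' dorsomedial prefrontal cortex). Geometry is schematic (cm on a flattened
#' scalp patch, 3.5 cm source-detector separation); the ROI assignment is a
#' default vocabulary carrier, not a reconstruction of any particular cap.
#'
#' @param n_per_roi Channels per ROI (default 6; the remaining channels are
#'   unassigned, `roi = "none"`).
#' @return A [channel_layout()].
#' @export
example_layout <- function(n_per_roi = 6) {
  n <- 23
  centers <- list("L.IFG" = c(-7, 4, 0), "R.IFG" = c(7, 4, 0),
                  "dmPFC" = c(0, 8, 3))
  rois <- rep("none", n)
  pos <- matrix(NA_real_, n, 3)
  k <- 0
  for (r in names(centers)) {
    for (i in seq_len(n_per_roi)) {
      k <- k + 1
      ang <- 2 * pi * (i - 1) / n_per_roi
      pos[k, ] <- centers[[r]] + 1.8 * c(cos(ang), sin(ang), 0.2 * cos(ang))
      rois[k] <- r
    }
  }
  if (k < n) for (i in (k + 1):n) {
    pos[i, ] <- c(-10 + 20 * (i - k) / (n - k), -2, 0)
  }
  df <- data.frame(channel = sprintf("ch%02d", seq_len(n)),
                   source_x = pos[, 1] - 1.75, source_y = pos[, 2],
                   source_z = pos[, 3],
                   detector_x = pos[, 1] + 1.75, detector_y = pos[, 2],
                   detector_z = pos[, 3],
                   roi = rois)
  channel_layout(df)
}

#' Write a layout CSV
#' @param layout A [channel_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(
    as.data.frame(layout)[, c("channel", "source_x", "source_y", "source_z",
                              "detector_x", "detector_y", "detector_z",
                              "roi")],
    path, row.names = FALSE)
  invisible(path)
}

#' Write / read an experiment design CSV
#'
#' One row per condition block: `dyad_id, participant_1, participant_2,
#' group, condition, start_s, duration_s`.
#'
#' @param design An [experiment_design()].
#' @param path CSV path.
#' @return `path` (write) or an `experiment_design` (read).
#' @export
write_design <- function(design, path) {
  df <- cbind(dyad_id = design$dyad_id,
              participant_1 = design$participant_ids[1],
              participant_2 = design$participant_ids[2],
              group = design$group, design$blocks)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  experiment_design(df$dyad_id[1],
                    c(df$participant_1[1], df$participant_2[1]),
                    df[, c("condition", "start_s", "duration_s")],
                    group = df$group[1])
}

# Look up a named parameter with a default for absent cells.
named_get <- function(x, key, default = 0) {
  if (is.null(names(x))) return(unname(x[1]))
  if (key %in% names(x)) unname(x[[key]]) else default
}

# Deterministic sub-seed derivation (kept below 2^31).
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Homologous-channel coupling plan
#'
#' Pairs each ROI-assigned channel with its homologue on the other
#' participant at the given per-ROI shared-signal weight.
#'
#' @param layout A [channel_layout()].
#' @param rho_by_roi Named numeric vector, ROI -> rho; unnamed scalar
#'   applies to all ROIs.
#' @return Data frame `channel_a`, `channel_b`, `rho`.
#' @export
homologous_pair_plan <- function(layout, rho_by_roi) {
  sel <- layout$roi != "none"
  rho <- if (is.null(names(rho_by_roi)))
    rep(rho_by_roi[1], sum(sel)) else unname(rho_by_roi[layout$roi[sel]])
  data.frame(channel_a = layout$channel[sel],
             channel_b = layout$channel[sel],
             rho = rho, stringsAsFactors = FALSE)
}

#' Simulate and write a complete dyadic experiment
#'
#' Generates `n_dyads` dyads with the three task conditions. Motion coupling
#' and fNIRS shared-signal weight vary by condition: the back-to-back
#' baseline gets zero motion coupling and the baseline rho, free movement
#' and intentional synchrony get their configured values (defaults: motion
#' coupling 0 / 0.1 / 0.9 and rho 0.05 / 0.3 / 0.5 for BB / FM / IS).
#' Writes, under `out_dir`: one motion CSV and one design CSV per dyad, one
#' fNIRS file per participant, and the layout CSV. Deterministic given
#' `seed`.
#'
#' @param n_dyads Number of dyads (>= 2; pseudo-dyad construction needs at
#'   least two).
#' @param out_dir Output directory (created if missing).
#' @param motion_kappa Named per-condition motion coupling.
#' @param nirs_rho Named per-condition shared-signal weight.
#' @param lag_ms Motion lag of participant B behind A, ms.
#' @param duration_s Block duration, seconds.
#' @param motion_fs,nirs_fs Sampling rates, Hz.
#' @param layout Channel layout (default [example_layout()]).
#' @param nirs_format `"csv"` or `"snirf"`.
#' @param seed Integer master seed.
#' @param quiet_nirs If TRUE, simulate fNIRS without physiological noise,
#'   scalp signal or artifacts (for recovery tests).
#' @return List: `designs`, `motion_files`, `nirs_files`, `layout_file`,
#'   `layout`.
#' @export
simulate_experiment <- function(n_dyads, out_dir,
                                motion_kappa = c(BB = 0, FM = 0.1, IS = 0.9),
                                nirs_rho = c(BB = 0.05, FM = 0.3, IS = 0.5),
                                lag_ms = 0, duration_s = 120,
                                motion_fs = 50, nirs_fs = 10,
                                layout = example_layout(),
                                nirs_format = c("csv", "snirf"),
                                seed = 1, quiet_nirs = FALSE) {
  if (n_dyads < 2)
    stop("n_dyads must be >= 2 (pseudo-dyad construction impossible)")
  nirs_format <- match.arg(nirs_format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layout_file <- file.path(out_dir, "layout.csv")
  write_layout(layout, layout_file)
  conditions <- c("BB", "FM", "IS")
  designs <- list()
  motion_files <- character(0)
  nirs_files <- character(0)
  ctr <- 0
  for (d in seq_len(n_dyads)) {
    dyad_id <- sprintf("dyad%02d", d)
    pids <- sprintf("%s_p%d", dyad_id, 1:2)
    design <- default_design(dyad_id, pids, conditions, duration_s)
    designs[[dyad_id]] <- design
    # motion: one trace pair per condition
    traces <- list()
    for (cond in conditions) {
      ctr <- ctr + 1
      cfg <- motion_sim_config(fs = motion_fs, duration_s = duration_s,
                               coupling = motion_kappa[[cond]],
                               lag_ms = lag_ms,
                               seed = sub_seed(seed, ctr))
      traces <- c(traces, simulate_dyad_motion(cfg, cond, ids = pids))
    }
    mf <- file.path(out_dir, sprintf("motion_%s.csv", dyad_id))
    write_motion(traces, mf, design)
    motion_files <- c(motion_files, mf)
    write_design(design, file.path(out_dir, sprintf("design_%s.csv", dyad_id)))
    # fNIRS: per-condition blocks concatenated into one session recording
    blocksA <- blocksB <- list()
    for (cond in conditions) {
      ctr <- ctr + 1
      cfg <- if (quiet_nirs) {
        nirs_sim_config(fs = nirs_fs, duration_s = duration_s,
                        cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                        global_amp = 0, spike_rate = 0,
                        seed = sub_seed(seed, ctr))
      } else {
        nirs_sim_config(fs = nirs_fs, duration_s = duration_s,
                        seed = sub_seed(seed, ctr))
      }
      plan <- homologous_pair_plan(layout, nirs_rho[[cond]])
      pair <- simulate_dyad_nirs(cfg, layout, plan, ids = pids)
      blocksA[[cond]] <- pair[[1]]
      blocksB[[cond]] <- pair[[2]]
    }
    concat <- function(blocks, pid) {
      arr <- do.call(function(...) abind3(...), lapply(blocks, `[[`, "intensity"))
      raw_nirs(pid, arr, blocks[[1]]$channel_ids, fs = nirs_fs)
    }
    for (m in 1:2) {
      blk <- if (m == 1) blocksA else blocksB
      nirs <- concat(blk, pids[m])
      nf <- file.path(out_dir, sprintf("nirs_%s.%s", pids[m],
                                       if (nirs_format == "snirf") "snirf" else "csv"))
      if (nirs_format == "snirf") write_snirf(nirs, nf)
      else write_nirs_csv(nirs, nf)
      nirs_files <- c(nirs_files, nf)
    }
  }
  list(designs = designs, motion_files = motion_files,
       nirs_files = nirs_files, layout_file = layout_file, layout = layout)
}

# Concatenate channels x wavelengths x time arrays along time.
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  nt <- sum(vapply(arrs, function(a) dim(a)[3], numeric(1)))
  out <- array(NA_real_, c(d[1], d[2], nt))
  at <- 0
  for (a in arrs) {
    out[, , at + seq_len(dim(a)[3])] <- a
    at <- at + dim(a)[3]
  }
  out
}

#' Simulate coupling/synchrony records for the statistical stage
#'
#' Generates the merged record table the mixed models consume directly,
#' from a known generative model: per-dyad random intercepts, cell-specific
#' coupling means, and a configurable linear effect of coupling on the
#' behavioral response in chosen cells.
#'
#' @param n_dyads Number of dyads.
#' @param conditions,roi_pairs Cell factors.
#' @param slope Named numeric: `"condition:roi_pair"` -> slope of
#'   `total_sync` on `wtc_z` in that cell (others 0). An unnamed scalar
#'   applies everywhere.
#' @param group_shift Named numeric per condition: amount added to real
#'   (not pseudo) dyads' `wtc_z` (default 0).
#' @param sd_dyad Random-intercept SD of the response.
#' @param sd_resid Residual SD of the response.
#' @param sd_wtc SD of the coupling values around 0.
#' @param seed Integer seed.
#' @return Data frame: `dyad_id`, `group`, `condition`, `roi_pair`,
#'   `wtc_z`, `total_sync`.
#' @export
simulate_coupling_records <- function(n_dyads = 30,
                                      conditions = c("BB", "FM", "IS"),
                                      roi_pairs = c("L.IFG-L.IFG",
                                                    "R.IFG-R.IFG",
                                                    "dmPFC-dmPFC"),
                                      slope = 0, group_shift = 0,
                                      sd_dyad = 0.05, sd_resid = 0.05,
                                      sd_wtc = 0.3, seed = 1) {
  withr::with_seed(as.integer(seed), {
    cells <- expand.grid(condition = conditions, roi_pair = roi_pairs,
                         stringsAsFactors = FALSE)
    rows <- list()
    for (g in c("real", "pseudo")) {
      for (d in seq_len(n_dyads)) {
        dyad <- sprintf("%s%02d", if (g == "real") "dyad" else "pseudo", d)
        u <- stats::rnorm(1, 0, sd_dyad)
        for (i in seq_len(nrow(cells))) {
          cond <- cells$condition[i]
          rp <- cells$roi_pair[i]
          shift <- if (g == "real") named_get(group_shift, cond) else 0
          w <- stats::rnorm(1, 0, sd_wtc) + shift
          b <- named_get(slope, paste(cond, rp, sep = ":"))
          y <- 0.3 + b * w + u + stats::rnorm(1, 0, sd_resid)
          rows[[length(rows) + 1]] <- data.frame(
            dyad_id = dyad, group = g, condition = cond, roi_pair = rp,
            wtc_z = w, total_sync = y, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
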