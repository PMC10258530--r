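# Aggregation of channel-pair WTC into between- and within-brain ROI-pair
# coupling records.

roi_pair_label <- function(r1, r2) {
  lv <- hypersync_constants$roi_levels
  o <- order(match(c(r1, r2), lv))
  paste(c(r1, r2)[o], collapse = "-")
}

ok_roi_channels <- function(hemo, layout) {
  roi <- layout$roi[match(hemo$channel_ids, layout$channel)]
  roi[is.na(roi)] <- "none"
  data.frame(index = seq_along(hemo$channel_ids),
             channel = hemo$channel_ids, roi = roi,
             ok = unname(hemo$qc) == "ok",
             stringsAsFactors = FALSE)
}

# Cache the CWT of every usable channel once; channel pairs then only pay
# for the smoothing passes.
cwt_cache <- function(hemo, rows, flo, fhi, dj) {
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    x <- hemo$hbo[rows$index[i], ]
    out[[i]] <- cwt_morlet(x, hemo$fs, flo = flo, fhi = fhi, dj = dj)
  }
  names(out) <- rows$channel
  out
}

#' ROI-pair coupling records from wavelet coherence
#'
#' Computes WTC + band-averaged Fisher-z coupling for every quality-passing
#' channel pair spanning an ROI pair, and averages the z values over channel
#' pairs into one record per (unit, ROI pair, condition). Between-brain
#' scope pairs channels of the two participants across all ROI
#' combinations (including homologous pairs); within-brain scope pairs
#' channels of distinct ROIs of a single participant (a channel is never
#' paired with itself). WTC is computed on the full recording; cells are
#' assigned to condition blocks by time before averaging, so block edges
#' lose nothing extra to the cone of influence.
#'
#' @param hemoA `hemo_series` of participant A.
#' @param hemoB `hemo_series` of participant B (between scope) or `NULL`
#'   (within scope).
#' @param layout A [channel_layout()] with ROI assignments.
#' @param design The [experiment_design()] (condition block times).
#' @param scope `"between"` or `"within"`.
#' @param unit_id Identifier written on the records (dyad id for between,
#'   participant id for within). Defaults from design / hemo.
#' @param group `"real"` or `"pseudo"`.
#' @param flo,fhi,dj CWT grid (see [cwt_morlet()]).
#' @param band_hz Coherence band for [band_average()].
#' @return Data frame of coupling records: `scope`, `unit_id`, `roi_pair`,
#'   `condition`, `group`, `wtc_z`, `n_channel_pairs`,
#'   `effective_band_floor_hz`.
#' @export
roi_pair_coupling <- function(hemoA, hemoB = NULL, layout, design,
                              scope = c("between", "within"),
                              unit_id = NULL, group = "real",
                              flo = 0.01, fhi = 0.5, dj = 1 / 12,
                              band_hz = hypersync_constants$band_hz) {
  scope <- match.arg(scope)
  stopifnot(inherits(design, "experiment_design"))
  rowsA <- ok_roi_channels(hemoA, layout)
  rowsA <- rowsA[rowsA$ok & rowsA$roi != "none", , drop = FALSE]
  if (scope == "between") {
    stopifnot(inherits(hemoB, "hemo_series"))
    rowsB <- ok_roi_channels(hemoB, layout)
    rowsB <- rowsB[rowsB$ok & rowsB$roi != "none", , drop = FALSE]
    unit_id <- unit_id %||% design$dyad_id
  } else {
    rowsB <- rowsA
    hemoB <- hemoA
    unit_id <- unit_id %||% hemoA$participant_id
  }
  if (nrow(rowsA) == 0 || nrow(rowsB) == 0) {
    warning("no quality-passing ROI channels; no records produced")
    return(empty_coupling_records())
  }
  cacheA <- cwt_cache(hemoA, rowsA, flo, fhi, dj)
  cacheB <- if (scope == "between") cwt_cache(hemoB, rowsB, flo, fhi, dj)
            else cacheA
  lv <- hypersync_constants$roi_levels
  roisA <- intersect(lv, unique(rowsA$roi))
  roisB <- intersect(lv, unique(rowsB$roi))
  pairs <- list()
  for (ra in roisA) for (rb in roisB) {
    if (scope == "within" && ra == rb) next
    lbl <- roi_pair_label(ra, rb)
    if (!is.null(pairs[[lbl]]) || (scope == "within" &&
        !is.null(pairs[[roi_pair_label(rb, ra)]]))) next
    pairs[[lbl]] <- c(ra, rb)
  }
  blocks <- design$blocks
  recs <- list()
  for (lbl in names(pairs)) {
    ra <- pairs[[lbl]][1]
    rb <- pairs[[lbl]][2]
    # channel pairs spanning the ROI pair; between scope includes both
    # orientations (A's ra with B's rb, and A's rb with B's ra)
    cp <- expand.grid(a = rowsA$channel[rowsA$roi == ra],
                      b = rowsB$channel[rowsB$roi == rb],
                      stringsAsFactors = FALSE)
    if (ra != rb) {
      cp2 <- expand.grid(a = rowsA$channel[rowsA$roi == rb],
                         b = rowsB$channel[rowsB$roi == ra],
                         stringsAsFactors = FALSE)
      cp <- rbind(cp, cp2)
    }
    if (scope == "within") {
      cp <- cp[cp$a != cp$b, , drop = FALSE]
      # unordered channel pairs: keep one orientation
      key <- apply(cp, 1, function(r) paste(sort(r), collapse = "|"))
      cp <- cp[!duplicated(key), , drop = FALSE]
    }
    if (nrow(cp) == 0) next
    zmat <- matrix(NA_real_, nrow(cp), nrow(blocks))
    floors <- rep(NA_real_, nrow(blocks))
    for (pi in seq_len(nrow(cp))) {
      res <- wtc_from_cwt(cacheA[[cp$a[pi]]], cacheB[[cp$b[pi]]])
      for (bi in seq_len(nrow(blocks))) {
        tr <- c(blocks$start_s[bi],
                blocks$start_s[bi] + blocks$duration_s[bi])
        ba <- band_average(res, band_hz[1], band_hz[2], time_range = tr)
        zmat[pi, bi] <- ba$band_mean_z
        floors[bi] <- ba$effective_band_floor_hz
      }
    }
    for (bi in seq_len(nrow(blocks))) {
      recs[[length(recs) + 1]] <- data.frame(
        scope = scope, unit_id = unit_id, roi_pair = lbl,
        condition = blocks$condition[bi], group = group,
        wtc_z = mean(zmat[, bi]), n_channel_pairs = nrow(cp),
        effective_band_floor_hz = floors[bi],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) return(empty_coupling_records())
  do.call(rbind, recs)
}

empty_coupling_records <- function() {
  data.frame(scope = character(0), unit_id = character(0),
             roi_pair = character(0), condition = character(0),
             group = character(0), wtc_z = numeric(0),
             n_channel_pairs = integer(0),
             effective_band_floor_hz = numeric(0))
}

#' Pseudo-dyad coupling records
#'
#' Applies the same derangement pairing scheme as [pseudo_pairings()] to the
#' preprocessed fNIRS series: each pseudo dyad couples participant 1 of one
#' real dyad with participant 2 of a different real dyad, condition-matched,
#' between-brain scope only.
#'
#' @param hemo_by_dyad Named list (by dyad id); each element a list of the
#'   two participants' `hemo_series` (in participant order).
#' @param layout,design See [roi_pair_coupling()]. The same design (block
#'   structure) must apply to all dyads.
#' @param seed Integer seed for the pairing permutation.
#' @param ... Passed to [roi_pair_coupling()].
#' @return Data frame of coupling records with `group = "pseudo"`.
#' @export
pseudo_coupling <- function(hemo_by_dyad, layout, design, seed = 1, ...) {
  ids <- names(hemo_by_dyad)
  if (length(ids) < 2) stop("pseudo coupling requires >= 2 dyads")
  plan <- pseudo_pairings(ids, seed)
  out <- lapply(seq_len(nrow(plan)), function(i) {
    hA <- hemo_by_dyad[[plan$dyad_a[i]]][[1]]
    hB <- hemo_by_dyad[[plan$dyad_b[i]]][[2]]
    pd <- design
    pd$dyad_id <- plan$pseudo_id[i]
    pd$group <- "pseudo"
    roi_pair_coupling(hA, hB, layout, pd, scope = "between",
                      unit_id = plan$pseudo_id[i], group = "pseudo", ...)
  })
  do.call(rbind, out)
}
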