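# ---- tracefit: cycle segmentation from the histone signal ------------------
#
# Two-stage procedure: (1) detect the sudden anaphase fluorescence drops,
# which delimit cycles; (2) between consecutive drops, fit the continuous
# plateau-ramp-plateau model by exhaustive breakpoint search on the frame
# grid, then convert breakpoints into G1/S/G2M/anaphase durations using the
# fixed anaphase-end-to-cytokinesis offset (5.6 min).

#' Detect anaphase fluorescence drops in a trace
#'
#' A drop is flagged at frame i when the fluorescence falls, within at most
#' two frames, by more than `drop_frac` of the local 3-frame running median.
#' Consecutive flagged frames are merged into one event whose end is the
#' local fluorescence minimum reached by the decline; events closer than
#' `min_cycle_frames` frames are merged, keeping the larger drop.
#'
#' @param trace data.frame with columns `t_min` and `fluo_au` (one cell).
#' @param drop_frac Minimum fractional decrease (default 0.25).
#' @param min_cycle_frames Minimum frames between distinct events (default 10).
#' @return data.frame with one row per event: `onset_frame`, `end_frame`
#'   (0-based), `onset_t`, `end_t` (minutes), `drop_au`. Zero rows if the
#'   cell never divided.
#' @export
detect_anaphase_drops <- function(trace, drop_frac = 0.25, min_cycle_frames = 10) {
  if (is.null(trace) || nrow(trace) == 0) stop("empty trace")
  if (nrow(trace) < 10) stop("trace must have at least 10 frames")
  f <- trace$fluo_au
  n <- length(f)
  med3 <- f
  if (n >= 3) med3[2:(n - 1)] <- vapply(2:(n - 1), function(i) stats::median(f[(i - 1):(i + 1)]), 0)

  cand <- logical(n)
  for (k in 1:2) {
    i <- seq_len(n - k)
    cand[i] <- cand[i] | (f[i] - f[i + k]) > drop_frac * med3[i]
  }
  idx <- which(cand)
  if (!length(idx)) return(data.frame(onset_frame = integer(0), end_frame = integer(0),
                                      onset_t = numeric(0), end_t = numeric(0),
                                      drop_au = numeric(0)))
  # merge runs of flagged frames (gap <= 2 frames)
  grp <- cumsum(c(1L, diff(idx) > 2L))
  ev <- lapply(split(idx, grp), function(ii) {
    onset <- ii[1]
    # the 2-frame lookahead can fire one frame before the decline actually
    # starts; advance the onset to the last frame not yet significantly
    # below its successor (2% of the local median)
    thresh <- 0.02 * med3[onset]
    while (onset < ii[length(ii)] && onset < n - 1 &&
           f[onset + 1] > f[onset] - thresh) onset <- onset + 1L
    # walk down the decline; stop when the per-frame decrease is no longer
    # significant, so noise on the post-drop plateau does not extend the event
    j <- onset
    while (j < n && f[j + 1] < f[j] - thresh) j <- j + 1L
    j <- max(j, ii[length(ii)])
    c(onset = onset, end = j, drop = f[onset] - f[j])
  })
  ev <- do.call(rbind, ev)
  # merge events that are implausibly close, keeping the larger drop
  keep <- rep(TRUE, nrow(ev))
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      prev <- max(which(keep[1:(i - 1)]))
      if (ev[i, "onset"] - ev[prev, "end"] < min_cycle_frames) {
        if (ev[i, "drop"] > ev[prev, "drop"]) keep[prev] <- FALSE else keep[i] <- FALSE
      }
    }
  }
  ev <- ev[keep, , drop = FALSE]
  data.frame(onset_frame = as.integer(ev[, "onset"]) - 1L,
             end_frame = as.integer(ev[, "end"]) - 1L,
             onset_t = trace$t_min[ev[, "onset"]],
             end_t = trace$t_min[ev[, "end"]],
             drop_au = ev[, "drop"])
}

#' Fit the plateau-ramp-plateau model to one cycle window
#'
#' Exhaustive least-squares search over breakpoint pairs (t1, t2) on the
#' frame grid for the continuous model F(t) = F1 for t <= t1, a linear ramp
#' for t1 <= t <= t2, and F2 = F1 + slope (t2 - t1) for t >= t2, fitted on
#' all frames from the window start to the anaphase onset `t_ana`. The ramp
#' must span at least `min_ramp_frames` frames and each plateau at least one
#' frame; ties in RSS are broken by the earliest (t1, t2) in lexicographic
#' order. R-squared is computed against the flat-mean null.
#'
#' @param window data.frame with `t_min`, `fluo_au` (frames of one cycle,
#'   starting at the previous drop end or at birth).
#' @param t_ana Anaphase onset time (minutes), from [detect_anaphase_drops()].
#' @param min_ramp_frames Minimum ramp length in frames (default 2).
#' @return A one-row data.frame: `t1`, `t2`, `F1`, `F2`, `ramp_slope`, `rss`,
#'   `r2`, `n_fit`, `fit_ok`, `fit_reason`.
#' @export
fit_piecewise <- function(window, t_ana, min_ramp_frames = 2) {
  t <- window$t_min
  f <- window$fluo_au
  sel <- t <= t_ana + 1e-9
  t <- t[sel]; f <- f[sel]
  m <- length(t)
  fail <- function(reason) data.frame(t1 = NA_real_, t2 = NA_real_, F1 = NA_real_,
                                      F2 = NA_real_, ramp_slope = NA_real_,
                                      rss = NA_real_, r2 = NA_real_, n_fit = m,
                                      fit_ok = FALSE, fit_reason = reason)
  if (m < 6 || m - min_ramp_frames - 1 < 2) return(fail("short"))

  best <- NULL
  best_rss <- Inf
  tss <- sum((f - mean(f))^2)
  for (i in 2:(m - min_ramp_frames - 1)) {          # t1 = t[i]; pre-plateau >= 1 frame
    jmax <- m - 1                                   # post-plateau >= 1 frame
    jmin <- i + min_ramp_frames
    if (jmin > jmax) next
    for (j in jmin:jmax) {
      x <- pmin(pmax(t - t[i], 0), t[j] - t[i])
      sx <- sum(x); sxx <- sum(x * x); sxy <- sum(x * f); sf <- sum(f)
      det <- m * sxx - sx * sx
      if (abs(det) < 1e-12) next
      b <- (m * sxy - sx * sf) / det
      a <- (sf - b * sx) / m
      rss <- sum((f - a - b * x)^2)
      if (rss < best_rss - 1e-12) {
        best_rss <- rss
        best <- list(i = i, j = j, a = a, b = b)
      }
    }
  }
  if (is.null(best)) return(fail("degenerate"))
  t1 <- t[best$i]; t2 <- t[best$j]
  F1 <- best$a; slope <- best$b
  data.frame(t1 = t1, t2 = t2, F1 = F1, F2 = F1 + slope * (t2 - t1),
             ramp_slope = slope, rss = best_rss,
             r2 = if (tss > 0) 1 - best_rss / tss else NA_real_,
             n_fit = m, fit_ok = TRUE, fit_reason = "ok")
}

#' Fill phase durations from fitted breakpoints
#'
#' Cytokinesis is defined as a fixed offset after the end of anaphase
#' (default 5.6 min). Durations are then: T_G1 = t1 - previous cytokinesis,
#' T_S = t2 - t1, T_G2M = t_ana - t2, and
#' T_Ana = (anaphase end + offset) - anaphase onset, so the four phases tile
#' the cytokinesis-to-cytokinesis interval exactly.
#'
#' @param seg data.frame with columns `t1`, `t2`, `t_ana`, `t_ana_end` and
#'   `t_cyto_prev` (NA when the previous cytokinesis is unobserved, in which
#'   case `T_G1` is marked missing).
#' @param cyto_offset_min Anaphase-end-to-cytokinesis offset (default 5.6).
#' @return `seg` with `t_cyto`, `T_G1`, `T_S`, `T_G2M`, `T_Ana` filled.
#' @export
assign_phases <- function(seg, cyto_offset_min = 5.6) {
  seg$t_cyto <- seg$t_ana_end + cyto_offset_min
  seg$T_G1 <- seg$t1 - seg$t_cyto_prev
  seg$T_S <- seg$t2 - seg$t1
  seg$T_G2M <- seg$t_ana - seg$t2
  seg$T_Ana <- seg$t_cyto - seg$t_ana
  seg
}

#' Quality-control policy for fitted cycles
#'
#' The upstream study reports only the pass *rate* of its quality control;
#' the criteria here are an explicit policy: minimum fit R-squared, positive
#' ramp slope, plateau ratio F2/F1 within a band around the expected 2-fold
#' histone doubling, every phase at least one frame long, plausible total
#' cycle length, and a known previous cytokinesis.
#'
#' In addition, a genuine nuclear division roughly halves the total signal
#' (histones are partitioned near-evenly between the two nuclei), so the
#' terminating drop must lose at least `min_drop_frac` of its onset level;
#' shallower dips are transient artifacts, not divisions.
#'
#' @param r2_min Minimum R-squared (default 0.85).
#' @param ratio_min,ratio_max Allowed F2/F1 band (default 1.5, 2.7).
#' @param min_phase_frames Minimum phase duration in frames (default 1).
#' @param cycle_min,cycle_max Allowed cycle length in minutes (default 30, 400).
#' @param min_drop_frac Minimum fractional signal loss of the terminating
#'   anaphase drop (default 0.4; assumes near-even histone partition).
#' @return list of class `"qc_policy"`.
#' @export
qc_policy <- function(r2_min = 0.85, ratio_min = 1.5, ratio_max = 2.7,
                      min_phase_frames = 1, cycle_min = 30, cycle_max = 400,
                      min_drop_frac = 0.4) {
  structure(list(r2_min = r2_min, ratio_min = ratio_min, ratio_max = ratio_max,
                 min_phase_frames = min_phase_frames,
                 cycle_min = cycle_min, cycle_max = cycle_max,
                 min_drop_frac = min_drop_frac),
            class = "qc_policy")
}

#' Apply quality control to fitted cycle segmentations
#'
#' @param segs data.frame of cycle segmentations (from [segment_trace()]).
#' @param policy A [qc_policy()].
#' @param frame_interval_min Frame interval in minutes (default 3).
#' @return `segs` with `qc_pass` and `qc_reason` columns; the rejection-reason
#'   tally is attached as attribute `"qc_tally"`.
#' @export
qc_filter <- function(segs, policy = qc_policy(), frame_interval_min = 3) {
  n <- nrow(segs)
  reason <- rep("pass", n)
  min_dur <- policy$min_phase_frames * frame_interval_min
  for (i in seq_len(n)) {
    s <- segs[i, ]
    shallow <- !is.null(s$drop_frac_meas) && is.finite(s$drop_frac_meas) &&
      s$drop_frac_meas < policy$min_drop_frac
    reason[i] <-
      if (!isTRUE(s$fit_ok)) paste0("fit_", s$fit_reason)
      else if (shallow) "drop_too_shallow"
      else if (is.na(s$t_cyto_prev) || is.na(s$T_G1)) "missing_prev_cyto"
      else if (is.na(s$r2) || s$r2 < policy$r2_min) "r2_low"
      else if (s$ramp_slope <= 0) "slope_nonpositive"
      else if (s$F1 <= 0 || s$F2 / s$F1 < policy$ratio_min ||
               s$F2 / s$F1 > policy$ratio_max) "ratio_out_of_range"
      else if (min(s$T_G1, s$T_S, s$T_G2M, s$T_Ana) < min_dur) "phase_too_short"
      else if (s$T_G1 + s$T_S + s$T_G2M + s$T_Ana < policy$cycle_min ||
               s$T_G1 + s$T_S + s$T_G2M + s$T_Ana > policy$cycle_max)
        "cycle_length_out_of_range"
      else "pass"
  }
  segs$qc_pass <- reason == "pass"
  segs$qc_reason <- reason
  attr(segs, "qc_tally") <- table(reason)
  segs
}

#' Segment every cycle of one cell trace
#'
#' Runs drop detection, delimits cycle windows between consecutive drop ends
#' (the first window starts at the first frame, treated as birth when
#' `birth_at_start`), fits the plateau-ramp-plateau model on each window up
#' to its anaphase onset, and assigns phase durations.
#'
#' @param trace data.frame for one cell (`t_min`, `fluo_au`, ...).
#' @param cyto_offset_min Anaphase-end-to-cytokinesis offset (default 5.6).
#' @param birth_at_start If `TRUE` the trace is assumed to start at the
#'   cell's birth (its previous cytokinesis); otherwise the first cycle has
#'   an unknown T_G1.
#' @param drop_frac,min_cycle_frames Passed to [detect_anaphase_drops()].
#' @param min_ramp_frames Passed to [fit_piecewise()].
#' @return data.frame, one row per complete cycle (a window terminated by a
#'   drop), with breakpoints, plateau levels, durations and fit diagnostics.
#' @export
segment_trace <- function(trace, cyto_offset_min = 5.6, birth_at_start = TRUE,
                          drop_frac = 0.25, min_cycle_frames = 10,
                          min_ramp_frames = 2) {
  drops <- detect_anaphase_drops(trace, drop_frac, min_cycle_frames)
  if (nrow(drops) == 0) return(NULL)
  cell_id <- if ("cell_id" %in% names(trace)) trace$cell_id[1] else NA_character_
  out <- vector("list", nrow(drops))
  for (k in seq_len(nrow(drops))) {
    w_start_t <- if (k == 1) trace$t_min[1] else drops$end_t[k - 1]
    win <- trace[trace$t_min > w_start_t - 1e-9 &
                 trace$t_min <= drops$end_t[k] + 1e-9, , drop = FALSE]
    fit <- fit_piecewise(win, t_ana = drops$onset_t[k],
                         min_ramp_frames = min_ramp_frames)
    fit$cell_id <- cell_id
    fit$cycle_index <- k
    fit$t_ana <- drops$onset_t[k]
    fit$t_ana_end <- drops$end_t[k]
    f_onset <- trace$fluo_au[drops$onset_frame[k] + 1L]
    fit$drop_frac_meas <- if (length(f_onset) == 1 && isTRUE(f_onset > 0))
      drops$drop_au[k] / f_onset else NA_real_
    fit$t_cyto_prev <- if (k == 1) {
      if (birth_at_start) trace$t_min[1] else NA_real_
    } else drops$end_t[k - 1] + cyto_offset_min
    out[[k]] <- fit
  }
  segs <- do.call(rbind, out)
  segs <- assign_phases(segs, cyto_offset_min)
  cols <- c("cell_id", "cycle_index", "t_cyto_prev", "t1", "t2", "t_ana",
            "t_ana_end", "t_cyto", "F1", "F2", "ramp_slope",
            "T_G1", "T_S", "T_G2M", "T_Ana", "rss", "r2", "n_fit",
            "drop_frac_meas", "fit_ok", "fit_reason")
  segs[, cols]
}

#' Segment all cells of a trace table
#'
#' @param traces Frame-level table with a `cell_id` column (schema of
#'   [read_traces()]).
#' @param ... Passed to [segment_trace()].
#' @return data.frame of all cycle segmentations (no QC applied).
#' @export
segment_cohort <- function(traces, ...) {
  parts <- lapply(split(traces, traces$cell_id), function(tr) {
    tr <- tr[order(tr$t_min), ]
    tryCatch(segment_trace(tr, ...), error = function(e) NULL)
  })
  out <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
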