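# ---- cyclestats: per-cycle variables, comparisons, compensation slopes -----

CYCLE_VARS <- c("T_G1", "T_S", "T_G2M", "T_Ana", "T_div",
                "V_birth", "V_G1", "V_S", "V_G2M",
                "Vb_S", "Vb_G2M", "Vb_Ana", "V_div",
                "mu_unb", "mu_bud")

nearest_value <- function(t_query, t_frames, values, floor_only = FALSE) {
  if (is.na(t_query)) return(NA_real_)
  if (t_query < t_frames[1] - 1e-9) return(NA_real_)
  if (floor_only) {
    # last frame at or before the query (used at cytokinesis, after which
    # the bud has detached)
    i <- findInterval(t_query + 1e-9, t_frames)
    return(if (i >= 1) values[i] else NA_real_)
  }
  if (t_query > t_frames[length(t_frames)] + 1e-9) return(NA_real_)
  values[which.min(abs(t_frames - t_query))]
}

ls_slope <- function(t, v) {
  ok <- is.finite(t) & is.finite(v)
  t <- t[ok]; v <- v[ok]
  if (length(t) < 2 || stats::var(t) == 0) return(NA_real_)
  sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)
}

#' Extract per-cycle variables from a segmentation and its trace
#'
#' Computes, for every QC-passed cycle, the 15 analysis variables: the four
#' phase durations and their sum `T_div`; the mother volume at the previous
#' cytokinesis (`V_birth`), at S onset (`V_G1`), S end (`V_S`) and anaphase
#' onset (`V_G2M`); the bud volume at S end (`Vb_S`), anaphase onset
#' (`Vb_G2M`) and cytokinesis (`Vb_Ana`); the total volume at division
#' (`V_div`); and the linear growth rates of the cell during the unbudded
#' interval (`mu_unb`) and of cell+bud during the budded interval (`mu_bud`).
#' Volumes are read at the frame nearest to each boundary time; boundaries
#' outside the trace give missing values and flag the row.
#'
#' A cell is classed `"daughter"` in its first full cycle (replicative age 0)
#' and `"mother"` thereafter.
#'
#' @param segs QC'd segmentations (from [segment_cohort()] + [qc_filter()]);
#'   rows with `qc_pass == FALSE` are dropped.
#' @param traces Frame-level trace table matching `segs$cell_id`.
#' @return data.frame with `cell_id`, `cycle_index`, `lineage_class`,
#'   `replicative_age`, the 15 variables, and `complete` (no missing values).
#' @export
compute_variables <- function(segs, traces) {
  if ("qc_pass" %in% names(segs))
    segs <- segs[segs$qc_pass %in% TRUE, , drop = FALSE]
  if (nrow(segs) == 0) return(NULL)
  tr_by_cell <- split(traces, traces$cell_id)
  rows <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    tr <- tr_by_cell[[as.character(s$cell_id)]]
    tm <- tr$t_min; Vm <- tr$vol_mother_fl; Vb <- tr$vol_bud_fl
    # division volumes are read at the last pre-detachment frame: the frame
    # grid can straddle cytokinesis, after which the bud channel resets to 0
    div_win <- which(tm >= s$t_ana - 1e-9 & tm <= s$t_cyto + 1e-9 & Vb > 0)
    div_idx <- if (length(div_win)) max(div_win) else NA_integer_
    v <- list(
      V_birth = nearest_value(s$t_cyto_prev, tm, Vm),
      V_G1    = nearest_value(s$t1, tm, Vm),
      V_S     = nearest_value(s$t2, tm, Vm),
      V_G2M   = nearest_value(s$t_ana, tm, Vm),
      Vb_S    = nearest_value(s$t2, tm, Vb),
      Vb_G2M  = nearest_value(s$t_ana, tm, Vb),
      Vb_Ana  = if (is.na(div_idx)) NA_real_ else Vb[div_idx],
      V_div   = if (is.na(div_idx)) NA_real_ else Vm[div_idx] + Vb[div_idx]
    )
    unb <- tm >= s$t_cyto_prev - 1e-9 & tm <= s$t1 + 1e-9
    bud <- tm >= s$t1 - 1e-9 & tm <= s$t_ana_end + 1e-9
    mu_unb <- if (!is.na(s$t_cyto_prev)) ls_slope(tm[unb], Vm[unb]) else NA_real_
    mu_bud <- ls_slope(tm[bud], (Vm + Vb)[bud])
    rows[[i]] <- data.frame(
      cell_id = s$cell_id, cycle_index = s$cycle_index,
      lineage_class = if (s$cycle_index == 1) "daughter" else "mother",
      replicative_age = s$cycle_index - 1L,
      T_G1 = s$T_G1, T_S = s$T_S, T_G2M = s$T_G2M, T_Ana = s$T_Ana,
      T_div = s$T_G1 + s$T_S + s$T_G2M + s$T_Ana,
      V_birth = v$V_birth, V_G1 = v$V_G1, V_S = v$V_S, V_G2M = v$V_G2M,
      Vb_S = v$Vb_S, Vb_G2M = v$Vb_G2M, Vb_Ana = v$Vb_Ana, V_div = v$V_div,
      mu_unb = mu_unb, mu_bud = mu_bud,
      complete = !anyNA(unlist(v)) && !is.na(mu_unb) && !is.na(mu_bud),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise phase durations by group
#'
#' @param x data.frame of cycle variables (or any table with the duration
#'   columns).
#' @param by Character vector of grouping columns (e.g. `"lineage_class"`,
#'   `c("strain", "lineage_class")`).
#' @param vars Duration columns to summarise.
#' @return Long data.frame with `variable`, grouping columns, `n`, `mean`,
#'   `sem` (= sd/sqrt(n)), `median`, `sd`.
#' @export
summarize_durations <- function(x, by = "lineage_class",
                                vars = c("T_G1", "T_S", "T_G2M", "T_Ana", "T_div")) {
  parts <- lapply(vars, function(v) {
    g <- split(x[[v]], x[, by, drop = FALSE], drop = TRUE)
    keys <- do.call(rbind, strsplit(names(g), ".", fixed = TRUE))
    df <- as.data.frame(keys, stringsAsFactors = FALSE)
    names(df) <- by
    df$variable <- v
    df$n <- vapply(g, function(z) sum(is.finite(z)), 0L)
    df$mean <- vapply(g, function(z) mean(z, na.rm = TRUE), 0)
    df$sd <- vapply(g, function(z) stats::sd(z, na.rm = TRUE), 0)
    df$sem <- df$sd / sqrt(pmax(df$n, 1))
    df$median <- vapply(g, function(z) stats::median(z, na.rm = TRUE), 0)
    df
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[, c("variable", by, "n", "mean", "sem", "median", "sd")]
}

#' Two-sample Kolmogorov-Smirnov comparison with star levels
#'
#' @param sample_a,sample_b Numeric samples (each n >= 20).
#' @return list with `statistic`, `p_value`, `stars` (`""`, `"*"` p<0.05,
#'   `"**"` p<0.01, `"***"` p<0.001).
#' @export
compare_strains <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (length(sample_a) < 20 || length(sample_b) < 20)
    stop("compare_strains() requires n >= 20 per sample")
  # exact p-values where ties permit: the asymptotic two-sample distribution
  # is conservative at these sample sizes (type-I error well below nominal)
  exact <- !anyDuplicated(c(sample_a, sample_b))
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = exact))
  p <- kt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(statistic = unname(kt$statistic), p_value = p, stars = stars)
}

#' Pearson correlogram of cycle variables, mothers vs daughters
#'
#' Builds the square correlation matrix over the 15 cycle variables with the
#' mother-cell coefficients in the upper triangle and the daughter-cell
#' coefficients in the lower triangle (diagonal = 1). Missing values are
#' dropped pairwise; zero-variance variables give NA entries with a warning.
#' No multiple-testing correction is applied (raw coefficients).
#'
#' @param vars data.frame from [compute_variables()] with a `lineage_class`
#'   column.
#' @param variables Variable set (default the 15 standard ones).
#' @param min_n Minimum pairwise-complete n (default 50); smaller pairs give
#'   NA.
#' @return Numeric matrix with attribute `"legend"`.
#' @export
correlogram <- function(vars, variables = CYCLE_VARS, min_n = 50) {
  stopifnot(all(variables %in% names(vars)))
  corr_tri <- function(d) {
    p <- length(variables)
    r <- matrix(NA_real_, p, p, dimnames = list(variables, variables))
    for (i in seq_len(p)) for (j in seq_len(p)) {
      x <- d[[variables[i]]]; y <- d[[variables[j]]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < min_n) next
      if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
        warning(sprintf("zero-variance variable in pair (%s, %s); entry undefined",
                        variables[i], variables[j]))
        next
      }
      r[i, j] <- stats::cor(x[ok], y[ok])
    }
    r
  }
  rm_ <- corr_tri(vars[vars$lineage_class == "mother", , drop = FALSE])
  rd_ <- corr_tri(vars[vars$lineage_class == "daughter", , drop = FALSE])
  out <- rm_
  out[lower.tri(out)] <- rd_[lower.tri(rd_)]
  diag(out) <- 1
  attr(out, "legend") <- "upper triangle: mothers; lower triangle: daughters"
  out
}

#' Size-compensation slope by robust regression
#'
#' Robust (IRLS/bisquare) linear regression of the volume added during a
#' phase on the volume at phase start. The slope s calibrates the regime:
#' -1 ideal Sizer, 0 Adder, +1 ideal Timer (exponential growth with mean
#' doubling). A 10-bin equal-count mean curve is attached for plotting.
#'
#' @param v_init Volume at phase start (fL).
#' @param delta_v Volume added during the phase (fL).
#' @param phase Label (`"G1"`, `"G2M"`, `"full_cycle"`, ...).
#' @param lineage_class Label carried through.
#' @param n_bins Bins for the mean curve (default 10).
#' @param min_n Minimum number of cells (default 50).
#' @return list of class `"compensation_fit"`: `slope`, `ci95`, `intercept`,
#'   `se`, `n`, `phase`, `lineage_class`, `binned`, `fit`.
#' @export
compensation_slope <- function(v_init, delta_v, phase = "G1",
                               lineage_class = "daughter", n_bins = 10,
                               min_n = 50) {
  ok <- is.finite(v_init) & is.finite(delta_v)
  if (sum(ok) < min_n)
    stop(sprintf("compensation_slope() requires n >= %d finite pairs (got %d)",
                 min_n, sum(ok)))
  fit <- robust_line(v_init[ok], delta_v[ok])
  structure(list(
    phase = phase, lineage_class = lineage_class,
    slope = unname(fit$coefficients["slope"]),
    intercept = unname(fit$coefficients["intercept"]),
    se = unname(fit$se["slope"]), ci95 = fit$ci95, n = fit$n,
    binned = binned_means(v_init[ok], delta_v[ok], n_bins),
    fit = fit
  ), class = "compensation_fit")
}

#' @export
print.compensation_fit <- function(x, ...) {
  cat(sprintf("Size compensation (%s, %s): s = %.3f [%.3f, %.3f], n = %d\n",
              x$phase, x$lineage_class, x$slope, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Compensation slopes for the standard phase set
#'
#' Convenience wrapper computing, per lineage class, the G1 slope
#' (Delta V = V_G1 - V_birth vs V_birth), the G2/M bud slope
#' (Vb_G2M - Vb_S vs Vb_S; set `g2m_whole_cell = TRUE` to use the whole-cell
#' volumes instead, which strongly reduces the apparent slope), and the
#' full-cycle slope (V_div - V_birth vs V_birth).
#'
#' @param vars data.frame from [compute_variables()].
#' @param g2m_whole_cell Use whole-cell rather than bud volumes in G2/M.
#' @param min_n Minimum cells per fit (default 50).
#' @return data.frame with one row per phase x lineage class.
#' @export
compensation_table <- function(vars, g2m_whole_cell = FALSE, min_n = 50) {
  rows <- list()
  for (cl in unique(vars$lineage_class)) {
    d <- vars[vars$lineage_class == cl, ]
    specs <- list(
      G1 = list(x = d$V_birth, y = d$V_G1 - d$V_birth),
      G2M = if (g2m_whole_cell)
        list(x = d$V_S + d$Vb_S, y = (d$V_G2M + d$Vb_G2M) - (d$V_S + d$Vb_S))
      else list(x = d$Vb_S, y = d$Vb_G2M - d$Vb_S),
      full_cycle = list(x = d$V_birth, y = d$V_div - d$V_birth)
    )
    for (ph in names(specs)) {
      res <- tryCatch(
        compensation_slope(specs[[ph]]$x, specs[[ph]]$y, phase = ph,
                           lineage_class = cl, min_n = min_n),
        error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        phase = ph, lineage_class = cl, slope = res$slope,
        ci_lo = res$ci95[1], ci_hi = res$ci95[2],
        intercept = res$intercept, n = res$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
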