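# tracefit: drop detection, piecewise fitting, phase assignment, QC

test_that("detect_anaphase_drops finds constructed drops and ignores monotone rises", {
  t <- seq(0, 120, by = 3)
  f <- c(rep(100, 10), seq(100, 200, length.out = 13), rep(200, 8),
         150, 100, rep(100, 8))
  tr <- data.frame(t_min = t, fluo_au = f)
  ev <- detect_anaphase_drops(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_frame, 30)     # last full-plateau frame (0-based)
  expect_equal(ev$end_frame, 32)       # bottom of the decline

  rising <- data.frame(t_min = t, fluo_au = seq(100, 300, length.out = length(t)))
  expect_equal(nrow(detect_anaphase_drops(rising)), 0)

  expect_error(detect_anaphase_drops(data.frame(t_min = 0:5, fluo_au = rep(1, 6))),
               "at least 10 frames")
  expect_error(detect_anaphase_drops(data.frame(t_min = numeric(0),
                                                fluo_au = numeric(0))), "empty|frames")
})

test_that("drop onsets land within one frame of truth in >= 99% of noisy cells", {
  # oracle: the simulator's true anaphase-onset times, 2% fluorescence noise
  hit <- 0L; tot <- 0L
  for (s in 1:250) {
    sm <- simulate_lineage(sim_config(n_cells = 1, n_generations = 1,
      n_mother_cycles = 1, tau_mat_min = 0, sigma_F = 4, sigma_V = 0,
      seed = 100000 + s))
    dr <- detect_anaphase_drops(sm$traces)
    tot <- tot + 2L
    if (nrow(dr) == 2)
      hit <- hit + sum(abs(dr$onset_t - sm$truth$t_ana_onset) <= 3 + 1e-9)
  }
  expect_gte(hit / tot, 0.99)
})

test_that("fit_piecewise recovers on-grid breakpoints exactly with a 2-fold plateau", {
  w <- make_window()                    # t1 = 15, t2 = 51, F 100 -> 200
  fit <- fit_piecewise(w, t_ana = 57)
  expect_equal(fit$t1, 15)
  expect_equal(fit$t2, 51)
  expect_equal(fit$F2 / fit$F1, 2, tolerance = 1e-9)
  expect_lt(fit$rss, 1e-18)
  expect_error(fit_piecewise(make_window(t_end = 9), t_ana = 9), NA)
  short <- fit_piecewise(make_window(t_end = 12), t_ana = 12)
  expect_false(short$fit_ok)
  expect_equal(short$fit_reason, "short")
})

test_that("fit_piecewise recovers T_S within one frame in >= 95% of noisy windows", {
  set.seed(41)
  ok <- 0L
  for (r in 1:500) {
    w <- make_window(noise_sd = 2)      # 2% of the pre-S plateau
    fit <- fit_piecewise(w, t_ana = 66)
    if (abs((fit$t2 - fit$t1) - 36) <= 3 + 1e-9) ok <- ok + 1L
  }
  expect_gte(ok / 500, 0.95)
})

test_that("fit_piecewise is the global RSS minimiser (random-pair oracle)", {
  set.seed(13)
  w <- make_window(noise_sd = 2)
  fit <- fit_piecewise(w, t_ana = 72)
  t <- w$t_min; f <- w$fluo_au; m <- length(t)
  # independent re-implementation of the per-pair closed-form LS
  rss_pair <- function(i, j) {
    x <- pmin(pmax(t - t[i], 0), t[j] - t[i])
    sx <- sum(x); sxx <- sum(x^2); sxy <- sum(x * f); sf <- sum(f)
    det <- m * sxx - sx^2
    b <- (m * sxy - sx * sf) / det
    a <- (sf - b * sx) / m
    sum((f - a - b * x)^2)
  }
  ok <- TRUE
  for (k in 1:1000) {
    is <- 2:(m - 3); i <- is[sample.int(length(is), 1)]
    js <- (i + 2):(m - 1); j <- js[sample.int(length(js), 1)]
    if (rss_pair(i, j) < fit$rss - 1e-8) ok <- FALSE
  }
  expect_true(ok)
})

test_that("long-maturation reporter degrades the fit: no flat pre-S plateau, ratio < 2", {
  # mCherry-like tau = 45 blurs the synthesis burst; steady-state cells
  # (generation >= 2, born with an immature pool) show a continuously rising
  # signal in which the 2-fold plateau structure is no longer resolvable
  cfg45 <- sim_config(n_cells = 2, n_generations = 2, n_mother_cycles = 0,
                      eta_sd = 0, sigma_F = 0, sigma_V = 0, tau_mat_min = 45,
                      T_S_sd = 0, seed = 3)
  cfg5 <- sim_config(n_cells = 2, n_generations = 2, n_mother_cycles = 0,
                     eta_sd = 0, sigma_F = 0, sigma_V = 0, tau_mat_min = 5,
                     T_S_sd = 0, seed = 3)
  for (chain in 1:2) {
    cid <- sprintf("c%04d_g02", chain)
    tr45 <- simulate_lineage(cfg45)$traces
    tr5 <- simulate_lineage(cfg5)$traces
    s45 <- segment_trace(tr45[tr45$cell_id == cid, ])
    s5 <- segment_trace(tr5[tr5$cell_id == cid, ])
    expect_lt(s45$F2 / s45$F1, 1.7)          # plateau ratio collapses
    expect_gt(s5$F2 / s5$F1, 1.85)           # fast reporter keeps ~2-fold
    # the fitted "pre-S plateau" region is actually rising for tau = 45
    w45 <- tr45[tr45$cell_id == cid & tr45$t_min <= s45$t1, ]
    w5 <- tr5[tr5$cell_id == cid & tr5$t_min <= s5$t1, ]
    slope45 <- stats::coef(stats::lm(fluo_au ~ t_min, w45))[2]
    slope5 <- stats::coef(stats::lm(fluo_au ~ t_min, w5))[2]
    expect_gt(slope45, 0.25)
    expect_lt(abs(slope5), 0.15)
  }
})

test_that("assign_phases arithmetic and additivity", {
  seg <- data.frame(t1 = 20, t2 = 50, t_ana = 60, t_ana_end = 100, t_cyto_prev = 5.6)
  out <- assign_phases(seg, cyto_offset_min = 5.6)
  expect_equal(out$t_cyto, 105.6)
  expect_equal(out$T_Ana, 45.6)        # drop duration + offset
  expect_equal(out$T_G1, 14.4)
  out0 <- assign_phases(seg, cyto_offset_min = 0)
  expect_equal(out0$t_cyto, 100)       # offset 0: cytokinesis = anaphase end
  # unknown previous cytokinesis -> T_G1 missing, others kept
  segNA <- assign_phases(transform(seg, t_cyto_prev = NA_real_))
  expect_true(is.na(segNA$T_G1))
  expect_equal(segNA$T_S, 30)

  # exact additivity on a segmented noisy cohort
  sim <- simulate_lineage(sim_config(n_cells = 10, n_generations = 2, seed = 6))
  segs <- segment_cohort(sim$traces)
  tot <- segs$T_G1 + segs$T_S + segs$T_G2M + segs$T_Ana
  expect_equal(tot, segs$t_cyto - segs$t_cyto_prev, tolerance = 1e-9)
})

test_that("round trip: noiseless cohort recovered to frame-grid resolution", {
  sim <- simulate_lineage(sim_config(n_cells = 50, n_generations = 2,
                                     tau_mat_min = 0, sigma_F = 0, sigma_V = 0,
                                     seed = 21))
  m <- fit_vs_truth(sim)
  expect_true(all(m$qc_pass))
  for (v in c("T_G1", "T_S", "T_G2M", "T_Ana")) {
    err <- abs(m[[v]] - m[[paste0("true_", v)]])
    # both interval ends are independently discretised to the 3-min grid,
    # so the structural bound is two frames; typical error is one frame
    expect_lte(max(err), 6 + 1e-9)
    expect_lte(stats::median(err), 3 + 1e-9)
  }
})

test_that("noise robustness: median timing error within one frame at 2% noise", {
  sim <- simulate_lineage(sim_config(n_cells = 60, n_generations = 2,
                                     tau_mat_min = 0, seed = 22))
  m <- fit_vs_truth(sim)
  m <- m[m$qc_pass, ]
  expect_gte(nrow(m), 200)
  for (v in c("T_G1", "T_S", "T_G2M", "T_Ana"))
    expect_lte(stats::median(abs(m[[v]] - m[[paste0("true_", v)]])), 3 + 1e-9)
})

test_that("qc_filter: clean cohorts pass, policy violations are reasoned", {
  sim <- simulate_lineage(sim_config(n_cells = 20, n_generations = 2,
                                     tau_mat_min = 0, sigma_F = 0, sigma_V = 0,
                                     seed = 31))
  segs <- qc_filter(segment_cohort(sim$traces))
  expect_true(all(segs$qc_pass))
  expect_equal(sum(attr(segs, "qc_tally")), nrow(segs))

  bad <- segment_cohort(sim$traces)[1, ]
  bad$F2 <- bad$F1 * 1.2
  expect_equal(qc_filter(bad)$qc_reason, "ratio_out_of_range")
  bad2 <- segment_cohort(sim$traces)[1, ]
  bad2$r2 <- 0.5
  expect_equal(qc_filter(bad2)$qc_reason, "r2_low")
  bad3 <- segment_cohort(sim$traces)[1, ]
  bad3$t_cyto_prev <- NA_real_; bad3$T_G1 <- NA_real_
  expect_equal(qc_filter(bad3)$qc_reason, "missing_prev_cyto")
})

test_that("qc rejects corrupted traces but keeps clean ones", {
  sim <- simulate_lineage(sim_config(n_cells = 60, n_generations = 1,
                                     n_mother_cycles = 1, tau_mat_min = 0,
                                     seed = 44))
  traces <- sim$traces
  cells <- unique(traces$cell_id)
  set.seed(99)
  corrupted <- sample(cells, 6)        # 10% of cells
  for (cid in corrupted) {
    idx <- which(traces$cell_id == cid)
    mid <- idx[8:11]                   # 4-frame square artifact inside cycle 1
    traces$fluo_au[mid] <- traces$fluo_au[mid] * 1.5
  }
  segs <- qc_filter(segment_cohort(traces))
  cell_fail <- tapply(!segs$qc_pass, segs$cell_id, any)
  frac_corr <- mean(cell_fail[corrupted], na.rm = TRUE)
  frac_clean <- mean(cell_fail[setdiff(cells, corrupted)], na.rm = TRUE)
  expect_gte(frac_corr, 0.9)
  expect_lte(frac_clean, 0.05)
})
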