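# ---- simkit: synthetic lineages with known ground truth --------------------
#
# The generator emulates the signal structure of a histone-2B fluorescent
# reporter in growing/dividing budding yeast: total nuclear fluorescence shows
# a plateau during the unbudded period (G1), a linear ramp while histones are
# synthesised alongside DNA replication (S), a second plateau during the
# budded period (G2/M), and a sudden drop when the nucleus divides at
# anaphase. Phase durations are *volume-target driven* for G1 and G2/M
# (retention coefficient a; ground-truth compensation slope s = a - 1) and
# duration-driven (Timer-like) for S and anaphase.

H0_AU <- 100  # fluorescence of one genome-equivalent of mature histone (AU)

#' Simulation configuration for synthetic histone-reporter lineages
#'
#' Builds and validates the parameter set consumed by [simulate_lineage()].
#' Defaults describe a wild-type-like strain: linear growth within each
#' period, a daughter G1 Sizer of strength s_G1 = a_G1 - 1 = -0.3 and a bud
#' G2/M Sizer of strength -0.4, S duration ~N(36, 3) min, a 12-min
#' anaphase-to-cytokinesis interval, sfGFP-like maturation (5 min), 3-min
#' frames and ~2% fluorescence measurement noise.
#'
#' @param frame_interval_min Acquisition interval in minutes (default 3).
#' @param n_cells Number of founder lineages (first-daughter chains).
#' @param n_generations Chain length: each generation is one physical cell.
#' @param n_mother_cycles Extra cycles each cell is followed for after its
#'   first (daughter) cycle, as a replicatively aging mother (default 1).
#' @param growth_mode `"linear"` (rates `mu_unb`, `mu_bud` in fL/min; the
#'   measured growth rates are linear per period) or `"exponential"`
#'   (specific rate `k_growth` in 1/min; needed for the Timer +1 calibration).
#' @param mu_unb,mu_bud Linear growth rates of the unbudded cell and of the
#'   bud (fL/min).
#' @param k_growth Exponential specific growth rate (1/min).
#' @param a_G1,a_G2M Retention coefficients in \[0, 2\] of the G1 (whole cell)
#'   and G2/M (bud) volume targets; ground-truth compensation slope s = a - 1
#'   (a = 0 ideal Sizer, a = 1 Adder-like increment, a = 2 slope +1).
#' @param V_target_G1 Equilibrium end-of-G1 volume target (fL).
#' @param Vb_target_G2M Equilibrium end-of-G2/M bud volume target (fL).
#' @param T_S_mean,T_S_sd Gaussian S-phase duration (min), truncated > 0.
#' @param T_Ana_mean Fixed anaphase-onset-to-cytokinesis duration (min); must
#'   be >= `cyto_offset_min` (the drop itself lasts the difference).
#' @param eta_sd SD of the additive Gaussian (Langevin) noise on each volume
#'   target (fL); homoscedastic.
#' @param r_div Nominal volume fraction inherited by the daughter, in
#'   (0, 1/2\]; used to place the founder birth-size distribution consistently
#'   with the volume targets (realised asymmetry is emergent).
#' @param dm_fluo_asymmetry Daughter/mother fluorescence partition asymmetry
#'   d: the daughter nucleus receives a fraction d/(1+d) of the histones
#'   (d = 1 is an even split; the measured value is ~0.94).
#' @param tau_mat_min Fluorophore maturation time constant (min): ~5 for
#'   sfGFP-like, ~45 for mCherry-like reporters.
#' @param sigma_F,sigma_V Gaussian measurement noise SD on fluorescence (AU)
#'   and on each volume channel (fL).
#' @param cyto_offset_min Fixed anaphase-end-to-cytokinesis offset (min,
#'   default 5.6).
#' @param founder_v_mean Mean founder birth volume (fL); default `NULL`
#'   computes the equilibrium daughter birth size implied by the bud-target
#'   dynamics.
#' @param founder_v_sd SD of founder birth volumes (fL).
#' @param strain Strain label carried into all outputs.
#' @param division_rule `"bud"` (default): the daughter cell is the bud
#'   compartment at cytokinesis; `"fraction"`: the daughter receives exactly
#'   `r_div` of the total divided volume (the constant-asymmetry assumption
#'   of the linear-map model; intended for ground-truth-only studies, as the
#'   bud channel of the trace is not re-partitioned).
#' @param seed Integer root seed; each founder chain gets a derived stream so
#'   adding chains never perturbs existing ones.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(frame_interval_min = 3, n_cells = 60, n_generations = 4,
                       n_mother_cycles = 1,
                       growth_mode = c("linear", "exponential"),
                       mu_unb = 0.33, mu_bud = 0.4, k_growth = 0.0077,
                       a_G1 = 0.7, a_G2M = 0.6,
                       V_target_G1 = 75, Vb_target_G2M = 29.4,
                       T_S_mean = 36, T_S_sd = 3, T_Ana_mean = 12,
                       eta_sd = 2, r_div = 0.386, dm_fluo_asymmetry = 1,
                       tau_mat_min = 5, sigma_F = 2, sigma_V = 0.5,
                       cyto_offset_min = 5.6, founder_v_mean = NULL,
                       founder_v_sd = 3, strain = "WT", seed = 1L,
                       division_rule = c("bud", "fraction")) {
  growth_mode <- match.arg(growth_mode)
  division_rule <- match.arg(division_rule)
  cfg <- list(frame_interval_min = frame_interval_min, n_cells = as.integer(n_cells),
              n_generations = as.integer(n_generations),
              n_mother_cycles = as.integer(n_mother_cycles),
              growth_mode = growth_mode, mu_unb = mu_unb, mu_bud = mu_bud,
              k_growth = k_growth, a_G1 = a_G1, a_G2M = a_G2M,
              V_target_G1 = V_target_G1, Vb_target_G2M = Vb_target_G2M,
              T_S_mean = T_S_mean, T_S_sd = T_S_sd, T_Ana_mean = T_Ana_mean,
              eta_sd = eta_sd, r_div = r_div,
              dm_fluo_asymmetry = dm_fluo_asymmetry, tau_mat_min = tau_mat_min,
              sigma_F = sigma_F, sigma_V = sigma_V,
              cyto_offset_min = cyto_offset_min,
              founder_v_mean = founder_v_mean, founder_v_sd = founder_v_sd,
              strain = strain, seed = as.integer(seed),
              division_rule = division_rule)
  if (cfg$frame_interval_min <= 0) stop("frame_interval_min must be > 0")
  if (cfg$n_cells < 1 || cfg$n_generations < 1) stop("need n_cells >= 1 and n_generations >= 1")
  if (cfg$n_mother_cycles < 0) stop("n_mother_cycles must be >= 0")
  if (growth_mode == "linear" && (mu_unb <= 0 || mu_bud <= 0))
    stop("linear growth requires mu_unb > 0 and mu_bud > 0 (target unreachable otherwise)")
  if (growth_mode == "exponential" && k_growth <= 0)
    stop("exponential growth requires k_growth > 0")
  if (a_G1 < 0 || a_G1 > 2 || a_G2M < 0 || a_G2M > 2)
    stop("retention coefficients a_G1, a_G2M must lie in [0, 2]")
  if (V_target_G1 <= 0 || Vb_target_G2M <= 0) stop("volume targets must be > 0")
  if (T_S_mean <= 0 || T_S_sd < 0 || T_Ana_mean < 0) stop("invalid S / anaphase durations")
  if (T_Ana_mean < cyto_offset_min)
    stop("T_Ana_mean must be >= cyto_offset_min (the drop lasts their difference)")
  if (eta_sd < 0 || sigma_F < 0 || sigma_V < 0) stop("noise SDs must be >= 0")
  if (r_div <= 0 || r_div > 0.5) stop("r_div must lie in (0, 1/2]")
  if (dm_fluo_asymmetry <= 0) stop("dm_fluo_asymmetry must be > 0")
  if (tau_mat_min < 0) stop("tau_mat_min must be >= 0")
  if (is.null(cfg$founder_v_mean)) {
    # equilibrium daughter birth size implied by the bud-target dynamics
    # (linear-rate formula; a heuristic initialisation in exponential mode,
    # where chains equilibrate within a generation or two anyway)
    vb_s_eq <- mu_bud * T_S_mean
    cfg$founder_v_mean <- a_G2M * vb_s_eq + (1 - a_G2M) * Vb_target_G2M +
      mu_bud * T_Ana_mean
  }
  if (cfg$founder_v_mean <= 0) stop("founder_v_mean must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

# per-chain RNG stream derived from the root seed (kept below 2^31)
child_seed <- function(root, chain) {
  as.integer((as.numeric(root) * 1009 + chain * 7919) %% 2147483647)
}

# draw a volume target a*V0 + (1-a)*Vtgt + eta, resampling eta (max 100
# tries) whenever the implied increment is negative; deterministic configs
# clamp to a zero increment and flag it.
draw_target <- function(V0, a, Vtgt, eta_sd) {
  base <- a * V0 + (1 - a) * Vtgt
  retries <- 0L
  if (eta_sd == 0) {
    clamped <- base < V0
    return(list(target = max(base, V0), retries = 0L, clamped = clamped))
  }
  repeat {
    target <- base + stats::rnorm(1, 0, eta_sd)
    if (target >= V0) return(list(target = target, retries = retries, clamped = FALSE))
    retries <- retries + 1L
    if (retries >= 100L)
      return(list(target = V0, retries = retries, clamped = TRUE))
  }
}

draw_T_S <- function(mean, sd) {
  if (sd == 0) return(max(mean, 1e-6))
  for (i in 1:100) {
    t <- stats::rnorm(1, mean, sd)
    if (t > 1e-6) return(t)
  }
  abs(stats::rnorm(1, mean, sd)) + 1e-6
}

# simulate one full cycle of one cell; returns truth, event times, pool
# segments and the daughter's inherited state
sim_cycle <- function(cfg, V, I, M, t_start, age) {
  g1 <- draw_target(V, cfg$a_G1, cfg$V_target_G1, cfg$eta_sd)
  V1 <- g1$target
  T_G1 <- if (cfg$growth_mode == "linear") (V1 - V) / cfg$mu_unb
          else log(V1 / V) / cfg$k_growth
  T_S <- draw_T_S(cfg$T_S_mean, cfg$T_S_sd)
  Vb_S <- if (cfg$growth_mode == "linear") cfg$mu_bud * T_S
          else V1 * (exp(cfg$k_growth * T_S) - 1)
  g2 <- draw_target(Vb_S, cfg$a_G2M, cfg$Vb_target_G2M, cfg$eta_sd)
  Vb2 <- g2$target
  T_G2M <- if (cfg$growth_mode == "linear") (Vb2 - Vb_S) / cfg$mu_bud
           else log((V1 + Vb2) / (V1 + Vb_S)) / cfg$k_growth
  T_Ana <- cfg$T_Ana_mean
  Vb_cyto <- if (cfg$growth_mode == "linear") Vb2 + cfg$mu_bud * T_Ana
             else V1 * (exp(cfg$k_growth * (T_S + T_G2M + T_Ana)) - 1)

  tS0 <- t_start + T_G1
  tS1 <- tS0 + T_S
  tAna <- tS1 + T_G2M
  tDropEnd <- tAna + (T_Ana - cfg$cyto_offset_min)
  tCyto <- tAna + T_Ana

  pool <- M + I                       # histone content = current genome copy
  rate <- pool / T_S                  # doubles the content linearly across S
  tau <- cfg$tau_mat_min
  seg_t0 <- c(t_start, tS0, tS1)
  seg_t1 <- c(tS0, tS1, tCyto)
  seg_P <- c(0, rate, 0)
  seg_I0 <- seg_M0 <- numeric(3)
  Icur <- I; Mcur <- M
  for (i in 1:3) {
    seg_I0[i] <- Icur; seg_M0[i] <- Mcur
    st <- mature_step(Icur, Mcur, seg_P[i], tau, seg_t1[i] - seg_t0[i])
    Icur <- st[["I"]]; Mcur <- st[["M"]]
  }
  shareD <- cfg$dm_fluo_asymmetry / (1 + cfg$dm_fluo_asymmetry)

  list(
    truth = c(
      replicative_age = age,
      true_T_G1 = T_G1, true_T_S = T_S, true_T_G2M = T_G2M, true_T_Ana = T_Ana,
      true_T_div = T_G1 + T_S + T_G2M + T_Ana,
      true_V_birth = V, true_V_G1 = V1, true_Vb_S = Vb_S, true_Vb_G2M = Vb2,
      true_Vb_cyto = Vb_cyto, true_V_div = V1 + Vb_cyto,
      t_start = t_start, t_S_onset = tS0, t_S_end = tS1,
      t_ana_onset = tAna, t_drop_end = tDropEnd, t_cyto = tCyto,
      retries = g1$retries + g2$retries,
      clamped = as.numeric(g1$clamped || g2$clamped)
    ),
    segs = list(t0 = seg_t0, t1 = seg_t1, P = seg_P, I0 = seg_I0, M0 = seg_M0),
    V1 = V1, Vb_S = Vb_S, Vb2 = Vb2, Vb_cyto = Vb_cyto,
    t_S_onset = tS0, t_ana_onset = tAna, t_drop_end = tDropEnd, t_cyto = tCyto,
    t_start = t_start, V_birth = V,
    shareD = shareD,
    # "bud" rule: the daughter is the bud compartment (mechanistic default);
    # "fraction" rule: the daughter receives a constant fraction r_div of the
    # divided volume, the linear-map model's constant-asymmetry assumption
    daughter_state = list(
      V = if (cfg$division_rule == "bud") Vb_cyto else cfg$r_div * (V1 + Vb_cyto),
      I = Icur * shareD, M = Mcur * shareD),
    mother_state = list(
      V = if (cfg$division_rule == "bud") V1 else (1 - cfg$r_div) * (V1 + Vb_cyto),
      I = Icur * (1 - shareD), M = Mcur * (1 - shareD))
  )
}

# evaluate the observed channels of one physical cell on its frame grid
build_trace <- function(cfg, cycles, cell_id) {
  t_end <- cycles[[length(cycles)]]$t_cyto
  tf <- seq(0, t_end + 1e-9, by = cfg$frame_interval_min)
  cyto_times <- vapply(cycles, function(cy) cy$t_cyto, 0)
  idx <- findInterval(tf, cyto_times + 1e-12) + 1L
  idx[idx > length(cycles)] <- length(cycles)

  Fv <- Vv <- Bv <- numeric(length(tf))
  for (k in seq_along(cycles)) {
    cy <- cycles[[k]]
    sel <- which(idx == k)
    if (!length(sel)) next
    tq <- tf[sel]
    # mature fluorophore from the cycle's constant-production segments
    seg <- cy$segs
    si <- findInterval(tq, seg$t0 + 1e-12) ; si[si < 1] <- 1L; si[si > 3] <- 3L
    M <- mature_at(tq, seg$t0[si], seg$I0[si], seg$M0[si], seg$P[si], cfg$tau_mat_min)
    # nuclear-division partition factor: 1 before the drop, declining linearly
    # to the mother's share across [ana onset, drop end]
    q <- rep(1, length(tq))
    ddur <- cy$t_drop_end - cy$t_ana_onset
    in_drop <- tq >= cy$t_ana_onset & (if (ddur > 0) tq < cy$t_drop_end else FALSE)
    if (ddur > 0)
      q[in_drop] <- 1 - cy$shareD * (tq[in_drop] - cy$t_ana_onset) / ddur
    q[tq >= cy$t_drop_end] <- 1 - cy$shareD
    Fv[sel] <- q * M
    # volumes: mother compartment grows only while unbudded, the bud from S on
    if (cfg$growth_mode == "linear") {
      Vm <- ifelse(tq < cy$t_S_onset,
                   cy$V_birth + cfg$mu_unb * (tq - cy$t_start), cy$V1)
      Vb <- ifelse(tq < cy$t_S_onset, 0, cfg$mu_bud * (tq - cy$t_S_onset))
    } else {
      Vm <- ifelse(tq < cy$t_S_onset,
                   cy$V_birth * exp(cfg$k_growth * (tq - cy$t_start)), cy$V1)
      Vb <- ifelse(tq < cy$t_S_onset, 0,
                   cy$V1 * (exp(cfg$k_growth * (tq - cy$t_S_onset)) - 1))
    }
    Vv[sel] <- Vm; Bv[sel] <- Vb
  }
  if (cfg$sigma_F > 0) Fv <- pmax(0, Fv + stats::rnorm(length(Fv), 0, cfg$sigma_F))
  if (cfg$sigma_V > 0) {
    Vv <- pmax(0.1, Vv + stats::rnorm(length(Vv), 0, cfg$sigma_V))
    pos <- Bv > 0
    Bv[pos] <- pmax(0, Bv[pos] + stats::rnorm(sum(pos), 0, cfg$sigma_V))
  }
  data.frame(cell_id = cell_id, frame = seq_along(tf) - 1L, t_min = tf,
             fluo_au = Fv, vol_mother_fl = Vv, vol_bud_fl = Bv)
}

#' Simulate histone-reporter lineages with known ground truth
#'
#' Generates `n_cells` independent first-daughter chains of `n_generations`
#' physical cells each. Every physical cell is followed from birth through its
#' first (daughter, replicative age 0) cycle and `n_mother_cycles` further
#' mother cycles, on one continuous frame grid; the daughter born from the
#' first cycle founds the next generation. G1 ends when the cell volume
#' reaches `a_G1 * V_birth + (1 - a_G1) * V_target_G1 + eta`; the bud appears
#' at S onset and G2/M ends when the bud reaches the analogous target; S and
#' anaphase are duration-driven. Histone content doubles linearly across S,
#' is observed through the first-order maturation filter plus Gaussian noise,
#' and is partitioned between the two nuclei at anaphase (conserving total
#' fluorescence).
#'
#' @param config A [sim_config()] object.
#' @param traces If `FALSE`, only ground-truth tables are generated (much
#'   faster; used for large statistical cohorts).
#' @return A list of class `"sim_lineage"` with elements `truth` (one row per
#'   cell cycle), `traces` (frame-level table, or `NULL`), `lineage`
#'   (cell_id, mother_id, strain, birth_order) and `config`.
#' @examples
#' sim <- simulate_lineage(sim_config(n_cells = 2, n_generations = 2, seed = 7))
#' head(sim$truth[, c("cell_id", "replicative_age", "true_T_G1", "true_V_birth")])
#' @export
simulate_lineage <- function(config, traces = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_cyc <- 1L + cfg$n_mother_cycles
  n_cells_tot <- cfg$n_cells * cfg$n_generations
  n_rows <- n_cells_tot * n_cyc
  truth_num <- vector("list", n_rows)
  id_col <- character(n_rows); mother_col <- character(n_rows)
  cyc_col <- integer(n_rows); chain_col <- integer(n_rows); gen_col <- integer(n_rows)
  trace_all <- if (traces) vector("list", n_cells_tot) else NULL
  lin_id <- character(n_cells_tot); lin_mother <- character(n_cells_tot)
  row <- 0L; slot <- 0L

  for (chain in seq_len(cfg$n_cells)) {
    set.seed(child_seed(cfg$seed, chain))
    V0 <- max(5, stats::rnorm(1, cfg$founder_v_mean, cfg$founder_v_sd))
    state <- list(V = V0, I = 0, M = H0_AU)
    mother_of <- NA_character_
    for (gen in seq_len(cfg$n_generations)) {
      cell_id <- sprintf("c%04d_g%02d", chain, gen)
      cycles <- vector("list", n_cyc)
      t0 <- 0
      cst <- state
      nxt <- NULL
      for (cyc in seq_len(n_cyc)) {
        cy <- sim_cycle(cfg, cst$V, cst$I, cst$M, t0, age = cyc - 1L)
        cycles[[cyc]] <- cy
        if (cyc == 1L) nxt <- cy$daughter_state
        cst <- cy$mother_state
        t0 <- cy$t_cyto
        row <- row + 1L
        truth_num[[row]] <- cy$truth
        id_col[row] <- cell_id; mother_col[row] <- mother_of
        cyc_col[row] <- cyc; chain_col[row] <- chain; gen_col[row] <- gen
      }
      slot <- slot + 1L
      lin_id[slot] <- cell_id; lin_mother[slot] <- mother_of
      if (traces) trace_all[[slot]] <- build_trace(cfg, cycles, cell_id)
      mother_of <- cell_id
      state <- nxt
    }
  }
  num <- do.call(rbind, truth_num)
  truth <- data.frame(cell_id = id_col, cycle_index = cyc_col,
                      chain = chain_col, generation = gen_col,
                      mother_id = mother_col,
                      lineage_class = ifelse(cyc_col == 1L, "daughter", "mother"),
                      strain = cfg$strain, stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(num))
  truth$replicative_age <- as.integer(truth$replicative_age)
  truth$clamped <- truth$clamped > 0
  out <- list(truth = truth,
              traces = if (traces) do.call(rbind, trace_all) else NULL,
              lineage = data.frame(cell_id = lin_id, mother_id = lin_mother,
                                   strain = cfg$strain, birth_order = 1L,
                                   stringsAsFactors = FALSE),
              config = cfg)
  class(out) <- "sim_lineage"
  out
}

#' @export
print.sim_lineage <- function(x, ...) {
  cat(sprintf("Synthetic lineage: %d chains x %d generations, %d cycles (%s, seed %d)\n",
              x$config$n_cells, x$config$n_generations, nrow(x$truth),
              x$config$strain, x$config$seed))
  if (!is.null(x$traces))
    cat(sprintf("  traces: %d frames at %.3g min\n", nrow(x$traces),
                x$config$frame_interval_min))
  invisible(x)
}

#' Iterate the noisy linear map of daughter birth size
#'
#' One-dimensional stochastic recursion
#' \deqn{V_{n+1} = p V_n + (1 - p) V_{eq} + \eta_n,}
#' with i.i.d. zero-mean Gaussian noise of SD `eta_sd`. For `0 <= p < 1` the
#' stationary distribution has mean `V_eq` and variance
#' `eta_sd^2 / (1 - p^2)`. Draws leading to a non-positive volume are
#' resampled (flagged in the `"retries"` attribute).
#'
#' @param p Memory of the map (effective size-control parameter).
#' @param V_eq Equilibrium daughter birth volume (fL).
#' @param eta_sd SD of the additive noise (fL).
#' @param n_steps Number of iterations.
#' @param V0 Initial volume (fL).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_steps + 1` (including `V0`).
#' @examples
#' simulate_linear_map(0.5, 40, 0, 1, V0 = 60)  # 60 -> 50 in one step
#' @export
simulate_linear_map <- function(p, V_eq, eta_sd, n_steps, V0 = V_eq, seed = NULL) {
  if (p < 0) stop("p must be >= 0")
  if (eta_sd < 0) stop("eta_sd must be >= 0")
  if (V0 <= 0 || V_eq <= 0) stop("volumes must be > 0")
  if (!is.null(seed)) set.seed(seed)
  drive <- rep((1 - p) * V_eq, n_steps) +
    (if (eta_sd > 0) stats::rnorm(n_steps, 0, eta_sd) else 0)
  v <- as.numeric(stats::filter(drive, p, method = "recursive", init = V0))
  retries <- 0L
  bad <- which(v <= 0)
  while (length(bad)) {             # rare: resample the offending draw onward
    i <- bad[1]
    repeat {
      eta <- if (eta_sd > 0) stats::rnorm(1, 0, eta_sd) else 0
      prev <- if (i == 1) V0 else v[i - 1]
      cand <- p * prev + (1 - p) * V_eq + eta
      retries <- retries + 1L
      if (cand > 0) { v[i] <- cand; break }
      if (retries > 1e5) stop("simulate_linear_map(): cannot draw positive volumes")
    }
    if (i < n_steps) {
      drive2 <- rep((1 - p) * V_eq, n_steps - i) +
        (if (eta_sd > 0) stats::rnorm(n_steps - i, 0, eta_sd) else 0)
      v[(i + 1):n_steps] <- as.numeric(stats::filter(drive2, p, method = "recursive",
                                                     init = v[i]))
    }
    bad <- which(v <= 0)
  }
  structure(c(V0, v), retries = retries)
}

#' Calibration cohorts for the Sizer / Adder / Timer slope anchors
#'
#' Directly generates (initial volume, added volume) pairs under the three
#' idealised size-control regimes against which compensation slopes are
#' calibrated: a *Sizer* reaches a fixed final volume (slope -1), an *Adder*
#' adds a volume drawn independently of the initial one (slope 0), and a
#' *Timer* grows exponentially for a fixed duration with mean size doubling
#' (slope +1).
#'
#' @param n Number of cells.
#' @param regime `"sizer"`, `"adder"` or `"timer"`.
#' @param v_mean,v_sd Gaussian initial-volume distribution (fL; default 40, 8).
#' @param v_final,final_sd Sizer final volume and its noise (fL; default 62, 2).
#' @param add_mean,add_sd Adder increment distribution (fL; default 40, 8).
#' @param mult_noise_sd Timer multiplicative log-noise SD (default 0.05).
#' @param seed Optional integer seed.
#' @return data.frame with columns `v_init`, `delta_v`.
#' @export
simulate_calibration_cohort <- function(n, regime = c("sizer", "adder", "timer"),
                                        v_mean = 40, v_sd = 8,
                                        v_final = 62, final_sd = 2,
                                        add_mean = 40, add_sd = 8,
                                        mult_noise_sd = 0.05, seed = NULL) {
  regime <- match.arg(regime)
  if (!is.null(seed)) set.seed(seed)
  v_init <- pmax(1, stats::rnorm(n, v_mean, v_sd))
  delta_v <- switch(regime,
    sizer = (v_final + stats::rnorm(n, 0, final_sd)) - v_init,
    adder = stats::rnorm(n, add_mean, add_sd),
    timer = v_init * (2 * exp(stats::rnorm(n, 0, mult_noise_sd)) - 1))
  data.frame(v_init = v_init, delta_v = delta_v)
}
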