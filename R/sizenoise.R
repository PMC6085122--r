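# ---- sizenoise: CV / Fano noise profiles along the cell cycle --------------

fano_of <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) < 2) return(NA_real_)
  stats::var(v) / mean(v)
}
cv_of <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) < 2) return(NA_real_)
  stats::sd(v) / mean(v)
}

#' Default ordered checkpoints for volume-noise profiling
#'
#' Bud at S end, bud at anaphase onset, daughter at birth, daughter at G1
#' end, daughter at division — an increasing-mean-volume sequence spanning
#' one daughter cycle from bud emergence to the next division.
#' @export
noise_checkpoints <- function() {
  c("bud_S_end", "bud_ana_onset", "daughter_birth", "daughter_G1_end",
    "daughter_division")
}

#' Extract checkpoint volume samples from cycle variables
#'
#' Maps the standard checkpoints onto columns of [compute_variables()]
#' output: bud checkpoints use all cycles, daughter checkpoints use
#' daughter (age 0) cycles only.
#'
#' @param vars data.frame from [compute_variables()].
#' @return Named list of numeric volume vectors in checkpoint order.
#' @export
checkpoint_volumes <- function(vars) {
  d <- vars[vars$lineage_class == "daughter", , drop = FALSE]
  list(bud_S_end = vars$Vb_S,
       bud_ana_onset = vars$Vb_G2M,
       daughter_birth = d$V_birth,
       daughter_G1_end = d$V_G1,
       daughter_division = d$V_div)
}

#' CV and Fano factor per checkpoint with bootstrap errors
#'
#' For each checkpoint the coefficient of variation CV = sd/mean and the
#' Fano factor F = variance/mean (fL) are computed, with standard errors
#' from a cell-level bootstrap (`n_boot` resamples with replacement). Under
#' the central-limit scaling of growth noise, CV = (F/V)^(1/2) with F
#' roughly constant along the cycle, so F is the size-independent noise
#' strength.
#'
#' @param volumes Named list of numeric volume vectors (one per checkpoint),
#'   e.g. from [checkpoint_volumes()].
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Optional integer seed.
#' @param min_n Checkpoints with fewer than `min_n` values are skipped with a
#'   warning (default 100).
#' @return data.frame: `checkpoint`, `n`, `mean_V`, `cv`, `fano`, `cv_se`,
#'   `fano_se`.
#' @export
noise_profile <- function(volumes, n_boot = 1000, seed = NULL, min_n = 100) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (nm in names(volumes)) {
    v <- volumes[[nm]][is.finite(volumes[[nm]])]
    if (length(v) < min_n) {
      warning(sprintf("checkpoint '%s' skipped: n = %d < %d", nm, length(v), min_n))
      next
    }
    bs <- matrix(sample(v, length(v) * n_boot, replace = TRUE), ncol = n_boot)
    cvs <- apply(bs, 2, cv_of)
    fns <- apply(bs, 2, fano_of)
    rows[[nm]] <- data.frame(checkpoint = nm, n = length(v), mean_V = mean(v),
                             cv = cv_of(v), fano = fano_of(v),
                             cv_se = stats::sd(cvs), fano_se = stats::sd(fns),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the CV-volume power law CV = (F/V)^(1/2)
#'
#' Least squares of log CV on the fixed -1/2 slope in log V with a free
#' intercept (1/2) log F, i.e. the single-parameter fit of the Fano constant
#' F across checkpoints.
#'
#' @param mean_V Mean volumes per checkpoint (>= 3 checkpoints).
#' @param cv CVs per checkpoint; non-positive values are dropped.
#' @return list: `F` (fitted Fano constant, fL), `residuals` (per-checkpoint
#'   deviation of log CV from the law), `n`.
#' @export
fit_fano_scaling <- function(mean_V, cv) {
  ok <- is.finite(mean_V) & is.finite(cv) & mean_V > 0 & cv > 0
  mean_V <- mean_V[ok]; cv <- cv[ok]
  if (length(cv) < 3) stop("fit_fano_scaling() needs >= 3 usable checkpoints")
  # model: log cv = 0.5 log F - 0.5 log V  =>  0.5 log F = mean(log cv + 0.5 log V)
  half_logF <- mean(log(cv) + 0.5 * log(mean_V))
  Fhat <- exp(2 * half_logF)
  resid <- log(cv) - (half_logF - 0.5 * log(mean_V))
  list(F = Fhat, residuals = resid, n = length(cv))
}

#' Fano-factor fold change between two checkpoints
#'
#' Ratio of the Fano factor at the end to the start of an interval (e.g. G1:
#' daughter birth -> daughter G1 end), with a paired cell-level bootstrap
#' percentile CI. A ratio below 1 means the interval contracted size noise,
#' the signature of compensatory growth; strong Sizers give ratios well
#' below 1 while Timer-like phases do not reduce noise.
#'
#' @param v_start,v_end Paired volumes (same cells, same order).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf CI level (default 0.95).
#' @param seed Optional integer seed.
#' @return list: `ratio`, `ci` (percentile), `fano_start`, `fano_end`, `n`.
#' @export
fano_fold_change <- function(v_start, v_end, n_boot = 1000, conf = 0.95,
                             seed = NULL) {
  ok <- is.finite(v_start) & is.finite(v_end)
  v_start <- v_start[ok]; v_end <- v_end[ok]
  n <- length(v_start)
  if (n < 3) stop("fano_fold_change() needs >= 3 paired cells")
  f0 <- fano_of(v_start); f1 <- fano_of(v_end)
  if (!is.finite(f0) || f0 == 0) {
    warning("zero/undefined start Fano; fold change undefined")
    return(list(ratio = NA_real_, ci = c(NA_real_, NA_real_),
                fano_start = f0, fano_end = f1, n = n))
  }
  if (!is.null(seed)) set.seed(seed)
  r <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    r[b] <- fano_of(v_end[i]) / fano_of(v_start[i])
  }
  a <- (1 - conf) / 2
  list(ratio = f1 / f0,
       ci = unname(stats::quantile(r, c(a, 1 - a), na.rm = TRUE)),
       fano_start = f0, fano_end = f1, n = n)
}
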