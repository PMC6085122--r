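# ---- linmap: the noisy linear map of daughter birth size -------------------
#
# V_{n+1} = p V_n + (1 - p) V_eq + eta, with p = r a, a = s_tot + 1 (r the
# daughter volume fraction at division, s_tot the full-cycle compensation
# slope). The stationary Fano factor is
#   Fano = (<eta^2>/V_eq) / ((1 - p)(1 + p)),
# diverging as p -> 1 (perfect Timer with symmetric division) and reducing
# to the intrinsic growth noise <eta^2>/V_eq for a perfect Sizer (p = 0).
# The convergence rate of a daughter lineage is lambda = -ln(p)/<T_div>.

#' Fit the return map of consecutive daughter birth sizes
#'
#' Robust (IRLS/bisquare) regression of V_{n+1} on V_n over consecutive
#' daughter-of-daughter birth-size pairs. The slope estimates p, the
#' equilibrium size is intercept/(1 - p), and the noise variance <eta^2> is
#' the variance of the (robust-fit) residuals.
#'
#' @param v_n,v_next Paired consecutive birth sizes; alternatively `v_n` may
#'   be a list of numeric chains (successive first-daughter birth sizes), in
#'   which case consecutive pairs are extracted from each chain.
#' @param min_pairs Minimum pairs (default 200; fewer gives a warning, < 3 an
#'   error).
#' @param ols_residuals If `TRUE`, estimate `<eta^2>` from plain OLS
#'   residuals instead of the robust fit's residuals.
#' @param n_bins Equal-count bins for the return-map curve (default 10).
#' @return list of class `"return_map_fit"`: `p`, `p_se`, `p_ci95`, `V_eq`
#'   (NA and `stationary = FALSE` if p >= 1), `eta_var`, `n`, `binned`,
#'   `fit`.
#' @export
fit_return_map <- function(v_n, v_next = NULL, min_pairs = 200,
                           ols_residuals = FALSE, n_bins = 10) {
  if (is.list(v_n) && is.null(v_next)) {
    pairs <- lapply(v_n, function(ch) {
      ch <- as.numeric(ch)
      if (length(ch) < 2) return(NULL)
      cbind(ch[-length(ch)], ch[-1])
    })
    m <- do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)])
    v_n <- m[, 1]; v_next <- m[, 2]
  }
  ok <- is.finite(v_n) & is.finite(v_next)
  v_n <- v_n[ok]; v_next <- v_next[ok]
  n <- length(v_n)
  if (n < 3) stop("fit_return_map() needs at least 3 pairs")
  if (n < min_pairs)
    warning(sprintf("fit_return_map(): only %d pairs (< %d); estimates unstable",
                    n, min_pairs))
  fit <- robust_line(v_n, v_next)
  p <- unname(fit$coefficients["slope"])
  icpt <- unname(fit$coefficients["intercept"])
  stationary <- p < 1
  if (!stationary)
    warning("fitted p >= 1: map flagged non-stationary, V_eq undefined")
  eta_var <- if (ols_residuals) {
    ols <- stats::lm.fit(cbind(1, v_n), v_next)
    stats::var(ols$residuals)
  } else fit$sigma2_resid
  structure(list(
    p = p, p_se = unname(fit$se["slope"]), p_ci95 = fit$ci95,
    V_eq = if (stationary) icpt / (1 - p) else NA_real_,
    eta_var = eta_var, stationary = stationary, n = n,
    binned = binned_means(v_n, v_next, n_bins), fit = fit
  ), class = "return_map_fit")
}

#' @export
print.return_map_fit <- function(x, ...) {
  cat(sprintf("Return map: p = %.3f [%.3f, %.3f], V_eq = %.2f fL, <eta^2> = %.2f fL^2, n = %d\n",
              x$p, x$p_ci95[1], x$p_ci95[2], x$V_eq, x$eta_var, x$n))
  if (!x$stationary) cat("  ** non-stationary (p >= 1) **\n")
  invisible(x)
}

#' Analytic stationary Fano factor of the linear map
#'
#' Fano = (eta_var/V_eq) / ((1 - p)(1 + p)). At p = 0 this is the intrinsic
#' growth noise eta_var/V_eq; as p -> 1 the Fano factor diverges (complete
#' loss of size homeostasis), returned as `Inf` with a warning.
#'
#' @param p Size-control parameter (0 <= p).
#' @param eta_var Noise variance <eta^2> (fL^2).
#' @param V_eq Equilibrium volume (fL, > 0).
#' @return Predicted Fano factor (fL); `Inf` if `p >= 1`.
#' @export
fano_prediction <- function(p, eta_var, V_eq) {
  if (any(p < 0)) stop("p must be >= 0")
  if (any(V_eq <= 0)) stop("V_eq must be > 0")
  if (any(eta_var < 0)) stop("eta_var must be >= 0")
  out <- (eta_var / V_eq) / ((1 - p) * (1 + p))
  if (any(p >= 1)) {
    warning("p >= 1: Fano factor diverges (loss of size homeostasis)")
    out[p >= 1] <- Inf
  }
  out
}

#' Single-parameter fit of the intrinsic growth noise across strains
#'
#' Least squares over c = eta_var/V_eq of the model
#' Fano_i = c / ((1 - p_i)(1 + p_i)) on a table of per-strain (p, mean Fano)
#' values, with a confidence interval from profiling the residual sum of
#' squares (F-test; default 99% to match dashed-band reporting). Strains
#' with p >= 1 are excluded with a warning.
#'
#' @param p Per-strain size-control parameters.
#' @param fano Per-strain mean Fano factors (fL).
#' @param level CI level (default 0.99).
#' @return list: `c` (intrinsic noise, fL), `ci`, `rss`, `n`, `fitted`.
#' @export
fit_intrinsic_noise <- function(p, fano, level = 0.99) {
  ok <- is.finite(p) & is.finite(fano)
  if (any(ok & p >= 1)) {
    warning(sprintf("%d strain(s) with p >= 1 excluded", sum(ok & p >= 1)))
    ok <- ok & p < 1
  }
  p <- p[ok]; fano <- fano[ok]
  n <- length(p)
  if (n < 1) stop("fit_intrinsic_noise() needs at least 1 strain with 0 <= p < 1")
  g <- 1 / ((1 - p) * (1 + p))
  chat <- sum(fano * g) / sum(g^2)
  rss <- sum((fano - chat * g)^2)
  ci <- if (n >= 2) {
    # RSS(c) = rss + (c - chat)^2 sum(g^2); profile bound from the F(1, n-1) test
    half <- sqrt(stats::qf(level, 1, n - 1) * (rss / (n - 1)) / sum(g^2))
    chat + c(-1, 1) * half
  } else c(NA_real_, NA_real_)
  list(c = chat, ci = ci, rss = rss, n = n, fitted = chat * g)
}

#' Convergence rate of the daughter lineage to equilibrium size
#'
#' From p = exp(-lambda <T_div>): lambda = -ln(p) / <T_div> (1/min). p = 0
#' gives an infinite rate (memoryless map); p >= 1 gives no convergence
#' (returned NA with a warning).
#'
#' @param p Size-control parameter.
#' @param T_div_mean Mean division time (minutes, > 0).
#' @return lambda in 1/min.
#' @export
convergence_rate <- function(p, T_div_mean) {
  if (any(T_div_mean <= 0)) stop("T_div_mean must be > 0")
  if (any(p < 0)) stop("p must be >= 0")
  out <- -log(p) / T_div_mean
  if (any(p == 0)) {
    warning("p = 0: infinite convergence rate (memoryless map)")
    out[p == 0] <- Inf
  }
  if (any(p >= 1)) {
    warning("p >= 1: no convergence to equilibrium")
    out[p >= 1] <- NA_real_
  }
  out
}

#' Mean normalized size of successive daughters from displaced founders
#'
#' Selects founder daughters whose birth size deviates strongly from the
#' equilibrium (above `upper_frac * V_eq` or below `lower_frac * V_eq`),
#' follows their first-daughter chains for `n_gen` generations, and returns
#' the per-generation mean birth size normalized by V_eq for each founder
#' class, with bootstrap CIs over founders. For a linear map with memory p,
#' |mean - 1| decays geometrically with ratio p per generation.
#'
#' @param chains List of numeric chains (successive first-daughter birth
#'   sizes; element 1 is the founder).
#' @param V_eq Equilibrium size (fL).
#' @param upper_frac,lower_frac Founder selection thresholds (defaults 1.5
#'   and 0.7).
#' @param n_gen Generations to follow (default 6).
#' @param min_founders Minimum founders per class; smaller classes are
#'   skipped with a warning (default 30).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Optional integer seed.
#' @return data.frame: `founder_class` ("large"/"small"), `generation`
#'   (0-based), `mean_norm_V`, `ci_lo`, `ci_hi`, `n`.
#' @export
convergence_trajectories <- function(chains, V_eq, upper_frac = 1.5,
                                     lower_frac = 0.7, n_gen = 6,
                                     min_founders = 30, n_boot = 1000,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chains <- chains[vapply(chains, length, 0L) >= n_gen]
  if (!length(chains)) stop("no chains of length >= n_gen")
  founders <- vapply(chains, function(ch) ch[1], 0)
  classes <- list(large = founders > upper_frac * V_eq,
                  small = founders < lower_frac * V_eq)
  rows <- list()
  for (cl in names(classes)) {
    sel <- which(classes[[cl]])
    if (length(sel) < min_founders) {
      warning(sprintf("founder class '%s' skipped: %d < %d founders",
                      cl, length(sel), min_founders))
      next
    }
    m <- do.call(rbind, lapply(chains[sel], function(ch) ch[seq_len(n_gen)])) / V_eq
    mu <- colMeans(m)
    bs <- matrix(NA_real_, n_boot, n_gen)
    for (b in seq_len(n_boot))
      bs[b, ] <- colMeans(m[sample.int(nrow(m), nrow(m), replace = TRUE), , drop = FALSE])
    ci <- apply(bs, 2, stats::quantile, probs = c(0.025, 0.975))
    rows[[cl]] <- data.frame(founder_class = cl, generation = seq_len(n_gen) - 1L,
                             mean_norm_V = mu, ci_lo = ci[1, ], ci_hi = ci[2, ],
                             n = length(sel), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("both founder classes empty at the given thresholds")
  rownames(out) <- NULL
  out
}

#' Assemble the full linear-map model for one strain
#'
#' Combines the return-map fit with the compensation analysis: consistency
#' p = r * a with a = s_tot + 1 is checked when `r` and `s_tot` are
#' supplied, the analytic Fano prediction and the convergence rate are
#' attached, and non-stationary fits are flagged divergent.
#'
#' @param chains List of first-daughter birth-size chains.
#' @param strain Strain label.
#' @param T_div_mean Mean division time in minutes (for lambda), optional.
#' @param r Measured division asymmetry (optional).
#' @param s_tot Measured full-cycle compensation slope (optional).
#' @param ... Passed to [fit_return_map()].
#' @return One-row data.frame with the model fields.
#' @export
linear_map_model <- function(chains, strain = "WT", T_div_mean = NA_real_,
                             r = NA_real_, s_tot = NA_real_, ...) {
  rm_fit <- fit_return_map(chains, ...)
  p <- rm_fit$p
  a <- if (is.finite(s_tot)) s_tot + 1 else NA_real_
  p_consist <- if (is.finite(r) && is.finite(a)) r * a else NA_real_
  fano <- if (rm_fit$stationary && p >= 0)
    fano_prediction(max(p, 0), rm_fit$eta_var, rm_fit$V_eq) else NA_real_
  lambda <- if (rm_fit$stationary && p > 0 && is.finite(T_div_mean))
    convergence_rate(p, T_div_mean) else NA_real_
  data.frame(strain = strain, p = p, p_se = rm_fit$p_se,
             p_ci_lo = rm_fit$p_ci95[1], p_ci_hi = rm_fit$p_ci95[2],
             V_eq = rm_fit$V_eq, eta_var = rm_fit$eta_var,
             r = r, a = a, s_tot = s_tot, p_from_slopes = p_consist,
             fano_pred = fano, lambda_rate = lambda,
             T_div_mean = T_div_mean, n = rm_fit$n,
             divergent = !rm_fit$stationary, stringsAsFactors = FALSE)
}
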