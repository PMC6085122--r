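# ---- iface: file formats, validation, pipeline driver ----------------------

TRACE_COLS <- c("cell_id", "frame", "t_min", "fluo_au", "vol_mother_fl", "vol_bud_fl")

#' Read and validate a trace table
#'
#' Expects a CSV with exactly the columns `cell_id, frame, t_min, fluo_au,
#' vol_mother_fl, vol_bud_fl` (times in minutes, volumes in fL, fluorescence
#' in AU) and optionally a lineage sidecar CSV with `cell_id, mother_id,
#' strain`. Rows are sorted by (cell_id, frame); per cell the frame grid must
#' be uniform with no duplicates and all values non-negative — violations
#' raise a structured error naming the cell and frame.
#'
#' @param path Trace CSV path.
#' @param lineage_path Optional lineage CSV path.
#' @return list with `traces` (validated, sorted data.frame) and `lineage`
#'   (data.frame or NULL).
#' @export
read_traces <- function(path, lineage_path = NULL) {
  if (!file.exists(path)) stop(sprintf("trace file not found: %s", path))
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(TRACE_COLS, names(tr))
  if (length(miss))
    stop(sprintf("trace file %s missing column(s): %s", path, paste(miss, collapse = ", ")))
  tr <- tr[order(tr$cell_id, tr$frame), TRACE_COLS]
  rownames(tr) <- NULL
  for (cid in unique(tr$cell_id)) {
    d <- tr[tr$cell_id == cid, ]
    if (anyDuplicated(d$frame))
      stop(sprintf("cell %s: duplicate frame %d", cid, d$frame[anyDuplicated(d$frame)]))
    if (nrow(d) >= 2) {
      dt <- diff(d$t_min)
      bad <- which(abs(dt - dt[1]) > 1e-6)
      if (length(bad))
        stop(sprintf("cell %s: non-uniform frame spacing at frame %d (missing frame?)",
                     cid, d$frame[bad[1] + 1]))
    }
    neg <- which(d$fluo_au < 0 | d$vol_mother_fl <= 0 | d$vol_bud_fl < 0)
    if (length(neg))
      stop(sprintf("cell %s: negative/invalid value at frame %d", cid, d$frame[neg[1]]))
  }
  lineage <- NULL
  if (!is.null(lineage_path)) {
    if (!file.exists(lineage_path)) stop(sprintf("lineage file not found: %s", lineage_path))
    lineage <- utils::read.csv(lineage_path, stringsAsFactors = FALSE)
    need <- c("cell_id", "mother_id", "strain")
    miss <- setdiff(need, names(lineage))
    if (length(miss))
      stop(sprintf("lineage file missing column(s): %s", paste(miss, collapse = ", ")))
  }
  list(traces = tr, lineage = lineage)
}

#' Write the trace and truth tables of a simulated lineage
#'
#' Emits `traces.csv` (frame-level schema of [read_traces()]), `truth.csv`
#' (per-cycle ground truth) and `lineage.csv` into `dir`.
#'
#' @param sim A `"sim_lineage"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_lineage"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(traces = file.path(dir, "traces.csv"),
             truth = file.path(dir, "truth.csv"),
             lineage = file.path(dir, "lineage.csv"))
  if (is.null(sim$traces)) stop("simulation was run with traces = FALSE")
  utils::write.csv(sim$traces, paths["traces"], row.names = FALSE)
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  utils::write.csv(sim$lineage, paths["lineage"], row.names = FALSE)
  invisible(paths)
}

#' First-daughter birth-size chains from a truth table
#'
#' Reconstructs, per founder chain, the successive daughter birth volumes
#' (the age-0 `V_birth` of each generation) used by the return-map and
#' convergence analyses.
#'
#' @param truth Truth table from [simulate_lineage()] (needs `chain`,
#'   `generation`, `replicative_age`, `true_V_birth`), or a variables table
#'   joined with chain/generation columns and a `V_birth` column.
#' @return List of numeric chains.
#' @export
daughter_chains <- function(truth) {
  vcol <- if ("true_V_birth" %in% names(truth)) "true_V_birth" else "V_birth"
  d <- truth[truth$replicative_age == 0, c("chain", "generation", vcol)]
  d <- d[order(d$chain, d$generation), ]
  lapply(split(d[[vcol]], d$chain), as.numeric)
}

#' Run the full analysis pipeline
#'
#' Sequences simulate (optional) -> drop detection & piecewise fitting ->
#' QC -> per-cycle variables -> duration summaries, correlogram and
#' compensation slopes -> noise profile and Fano fold-changes -> linear-map
#' model, writing every stage's CSV plus a JSON run manifest (seed, config
#' hash, QC tally) into `out_dir`. Reruns with an identical configuration
#' are byte-identical.
#'
#' @param out_dir Output directory.
#' @param config A [sim_config()] to simulate inputs, or `NULL` to read them.
#' @param traces_csv,lineage_csv Input paths (used when `config` is NULL).
#' @param policy A [qc_policy()].
#' @param cyto_offset_min Anaphase-end-to-cytokinesis offset (default 5.6).
#' @param n_boot Bootstrap resamples for noise statistics (default 200).
#' @param seed Root seed for the statistical stages (default: config seed,
#'   or 1).
#' @return Invisibly, a list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(out_dir, config = NULL, traces_csv = NULL,
                         lineage_csv = NULL, policy = qc_policy(),
                         cyto_offset_min = 5.6, n_boot = 200, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- inputs -----------------------------------------------------------
  truth <- NULL
  if (!is.null(config)) {
    stopifnot(inherits(config, "sim_config"))
    sim <- stage("simulate", simulate_lineage(config))
    write_sim(sim, out_dir)
    traces <- sim$traces; lineage <- sim$lineage; truth <- sim$truth
    if (is.null(seed)) seed <- config$seed
    frame_min <- config$frame_interval_min
  } else {
    if (is.null(traces_csv)) stop("either 'config' or 'traces_csv' is required")
    inp <- stage("read", read_traces(traces_csv, lineage_csv))
    traces <- inp$traces; lineage <- inp$lineage
    if (nrow(traces) == 0) stop("empty input: no frames")
    if (is.null(seed)) seed <- 1L
    frame_min <- diff(traces$t_min[traces$cell_id == traces$cell_id[1]])[1]
  }

  # --- fit + QC ---------------------------------------------------------
  segs <- stage("fit", segment_cohort(traces, cyto_offset_min = cyto_offset_min))
  if (is.null(segs) || nrow(segs) == 0) stop("pipeline stage 'fit': no cycles detected")
  segs <- stage("qc", qc_filter(segs, policy, frame_interval_min = frame_min))
  tally <- attr(segs, "qc_tally")
  utils::write.csv(segs, file.path(out_dir, "cycles.csv"), row.names = FALSE)

  # --- per-cycle variables + stats --------------------------------------
  vars <- stage("stats", compute_variables(segs, traces))
  utils::write.csv(vars, file.path(out_dir, "variables.csv"), row.names = FALSE)
  summ <- stage("stats", summarize_durations(vars))
  utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
  corr <- tryCatch(correlogram(vars), warning = function(w) suppressWarnings(correlogram(vars)))
  utils::write.csv(as.data.frame(corr), file.path(out_dir, "correlogram.csv"))
  slopes <- stage("stats", compensation_table(vars))
  utils::write.csv(slopes, file.path(out_dir, "slopes.csv"), row.names = FALSE)

  # --- noise ------------------------------------------------------------
  noise <- stage("noise", suppressWarnings(
    noise_profile(checkpoint_volumes(vars), n_boot = n_boot, seed = seed,
                  min_n = 30)))
  utils::write.csv(noise, file.path(out_dir, "noise_profile.csv"), row.names = FALSE)
  dvars <- vars[vars$lineage_class == "daughter" & vars$complete, ]
  ffc <- stage("noise", data.frame(
    interval = c("G1", "G2M"),
    ratio = c(fano_fold_change(dvars$V_birth, dvars$V_G1, n_boot, seed = seed)$ratio,
              fano_fold_change(dvars$Vb_S, dvars$Vb_G2M, n_boot, seed = seed)$ratio)))
  utils::write.csv(ffc, file.path(out_dir, "fano_foldchange.csv"), row.names = FALSE)

  # --- linear map -------------------------------------------------------
  lin <- NULL
  if (!is.null(truth)) {
    chains <- daughter_chains(truth)
    s_tot <- slopes$slope[slopes$phase == "full_cycle" &
                          slopes$lineage_class == "daughter"]
    r_real <- mean(truth$true_Vb_cyto / truth$true_V_div, na.rm = TRUE)
    lin <- stage("map", linear_map_model(
      chains, strain = if (!is.null(config)) config$strain else "NA",
      T_div_mean = mean(dvars$T_div),
      r = r_real, s_tot = if (length(s_tot)) s_tot else NA_real_,
      min_pairs = 3))
    utils::write.csv(lin, file.path(out_dir, "linmap.csv"), row.names = FALSE)
  }

  # --- manifest ---------------------------------------------------------
  cfg_str <- if (!is.null(config)) paste(deparse(unclass(config)), collapse = "") else ""
  tmp <- tempfile(); writeLines(cfg_str, tmp)
  manifest <- list(
    package = "cyclesizer",
    version = as.character(utils::packageVersion("cyclesizer")),
    seed = seed,
    config_hash = unname(tools::md5sum(tmp)),
    n_cells = length(unique(traces$cell_id)),
    n_cycles = nrow(segs),
    qc_pass = sum(segs$qc_pass),
    qc_tally = as.list(tally)
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(segs = segs, vars = vars, summary = summ, correlogram = corr,
                 slopes = slopes, noise = noise, fano_foldchange = ffc,
                 linmap = lin, manifest = manifest))
}
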