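# End-to-end orchestration: simulate (or load) two-condition cohorts, run
# every analysis stage, compare groups, and write a reproducible result
# bundle.

#' Pipeline run configuration
#'
#' @param seed master seed; every simulated cell derives its own substream
#'   seed from it via [derive_seed()].
#' @param n_sham,n_bbbd cohort sizes (cells per condition). Defaults 9 and 8,
#'   mirroring typical animal counts in the emulated experiment.
#' @param duration_s duration of each spontaneous recording (s).
#' @param dt sampling interval (ms).
#' @param isi paired-pulse inter-stimulus interval analyzed (ms).
#' @param protocols stages to run, subset of `"minis"`, `"paired"`, `"train"`.
#' @param params named list with elements `sham` and `bbbd`
#'   ([pool_model_params()]); defaults to [pool_preset()] for both.
#' @param in_dir optional directory of tabular traces to analyze instead of
#'   simulating (condition/protocol read from each file's metadata).
#' @param out_dir optional output directory for TSV/JSON results.
#' @param make_figures write summary figures (PDF) into `out_dir`.
#' @param alpha significance level for group comparisons.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(seed = 1, n_sham = 9, n_bbbd = 8, duration_s = 100,
                       dt = 0.1, isi = 10,
                       protocols = c("minis", "paired", "train"),
                       params = list(sham = pool_preset("sham"),
                                     bbbd = pool_preset("bbbd")),
                       in_dir = NULL, out_dir = NULL, make_figures = FALSE,
                       alpha = 0.05) {
  stopifnot(n_sham >= 1, n_bbbd >= 1, duration_s > 0, dt > 0)
  protocols <- match.arg(protocols, several.ok = TRUE)
  cfg <- list(seed = seed, n_sham = n_sham, n_bbbd = n_bbbd,
              duration_s = duration_s, dt = dt, isi = isi,
              protocols = protocols, params = params, in_dir = in_dir,
              out_dir = out_dir, make_figures = make_figures, alpha = alpha)
  class(cfg) <- "run_config"
  cfg
}

#' Simulate one cell's recordings for the requested protocols
#'
#' @param params a [pool_model_params()] object.
#' @param protocols subset of `"minis"`, `"paired"`, `"train"`.
#' @param seed cell seed.
#' @param duration_s,dt,isi protocol settings.
#' @param cell_id,condition labels.
#' @return named list of `list(trace, truth)` simulation results.
#' @export
simulate_cell <- function(params, protocols = c("minis", "paired", "train"),
                          seed = NULL, duration_s = 100, dt = 0.1, isi = 10,
                          cell_id = "sim", condition = "unknown") {
  out <- list()
  if ("minis" %in% protocols)
    out$minis <- simulate_minis(params, duration_s = duration_s, dt = dt,
                                seed = derive_seed(seed, 1),
                                cell_id = cell_id, condition = condition)
  if ("paired" %in% protocols)
    out$paired <- simulate_evoked(params, protocol_paired(isi), dt = dt,
                                  seed = derive_seed(seed, 2),
                                  cell_id = cell_id, condition = condition)
  if ("train" %in% protocols)
    out$train <- simulate_evoked(params, protocol_train(), dt = dt,
                                 seed = derive_seed(seed, 3),
                                 cell_id = cell_id, condition = condition)
  out
}

analyze_cell <- function(sims, mini_cfg = mini_config()) {
  row <- list(frequency = NA_real_, n_events = NA_real_,
              median_amplitude = NA_real_, median_rise = NA_real_,
              tau1 = NA_real_, tau2 = NA_real_, a1 = NA_real_,
              ppr = NA_real_, ppr_charge = NA_real_,
              intercept1 = NA_real_, slope1 = NA_real_,
              intercept2 = NA_real_, slope2 = NA_real_,
              tonic_charge = NA_real_, tau_rec = NA_real_)
  if (!is.null(sims$minis)) {
    s <- summarize_minis(sims$minis$trace, cfg = mini_cfg)
    row[c("frequency", "n_events", "median_amplitude", "median_rise",
          "tau1", "tau2", "a1")] <-
      s[c("frequency", "n_events", "median_amplitude", "median_rise",
          "tau1", "tau2", "a1")]
  }
  if (!is.null(sims$paired)) {
    pp <- paired_pulse_ratio(sims$paired$trace)
    row$ppr <- pp$ppr
    row$ppr_charge <- pp$ppr_charge
  }
  if (!is.null(sims$train)) {
    tf <- analyze_train(sims$train$trace)
    if (!tf$excluded) {
      cf <- coef(tf)
      row$intercept1 <- cf[["intercept1"]]; row$slope1 <- cf[["slope1"]]
      row$intercept2 <- cf[["intercept2"]]; row$slope2 <- cf[["slope2"]]
      row$tonic_charge <- tf$tonic_charge
      if (!is.null(tf$recovery)) row$tau_rec <- tf$recovery$tau_rec
    }
  }
  row
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the two-condition cohorts, runs mini detection and
#' kinetics, paired-pulse analysis, and train/RRP analysis per cell, then
#' compares the headline metrics between conditions (mini frequency, fast
#' decay tau1, PPR, phase-1 y-intercept). With `out_dir` set, writes a
#' per-cell TSV, a JSON summary of the group comparisons, and a manifest
#' (config, seed, versions); reruns with the same config are identical.
#'
#' @param config a [run_config()].
#' @return list of class `"pipeline_result"`: `cells` (per-cell data frame),
#'   `comparisons` (named list of [compare_groups()] results), `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$in_dir)) {
    if (!dir.exists(config$in_dir))
      stop("input directory not found: ", config$in_dir, call. = FALSE)
    cells <- analyze_trace_dir(config)
  } else {
    cells <- list()
    conds <- list(sham = config$n_sham, bbbd = config$n_bbbd)
    for (ci in seq_along(conds)) {
      cond <- names(conds)[ci]
      for (j in seq_len(conds[[ci]])) {
        cell_id <- sprintf("%s_%02d", cond, j)
        sims <- simulate_cell(config$params[[cond]],
                              protocols = config$protocols,
                              seed = derive_seed(config$seed, ci, j),
                              duration_s = config$duration_s, dt = config$dt,
                              isi = config$isi, cell_id = cell_id,
                              condition = cond)
        row <- analyze_cell(sims)
        cells[[length(cells) + 1L]] <-
          c(list(cell_id = cell_id, condition = cond), row)
      }
    }
    cells <- do.call(rbind, lapply(cells, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }

  metrics <- c(mini_frequency = "frequency", tau1 = "tau1", ppr = "ppr",
               rrp_intercept1 = "intercept1")
  comparisons <- list()
  for (m in names(metrics)) {
    col <- metrics[[m]]
    if (!col %in% names(cells)) next
    xs <- cells[cells$condition == "sham", col]
    ys <- cells[cells$condition == "bbbd", col]
    xs <- xs[is.finite(xs)]; ys <- ys[is.finite(ys)]
    if (length(xs) >= 5 && length(ys) >= 5)
      comparisons[[m]] <- compare_groups(xs, ys, metric = m,
                                         alpha = config$alpha)
  }
  result <- list(cells = cells, comparisons = comparisons, config = config)
  class(result) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_result_bundle(result)
  result
}

analyze_trace_dir <- function(config) {
  files <- sort(list.files(config$in_dir, pattern = "\\.(txt|tsv)$",
                           full.names = TRUE))
  if (!length(files))
    stop("no trace files in ", config$in_dir, call. = FALSE)
  by_cell <- list()
  for (f in files) {
    tr <- read_trace(f)
    key <- tr$cell_id
    sims <- by_cell[[key]]
    if (is.null(sims)) sims <- list(condition = tr$condition)
    if (tr$protocol == "minis") sims$minis <- list(trace = tr)
    if (tr$protocol == "paired") sims$paired <- list(trace = tr)
    if (tr$protocol == "train") sims$train <- list(trace = tr)
    by_cell[[key]] <- sims
  }
  rows <- lapply(names(by_cell), function(key) {
    sims <- by_cell[[key]]
    row <- analyze_cell(sims[setdiff(names(sims), "condition")])
    as.data.frame(c(list(cell_id = key, condition = sims$condition), row),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_result_bundle <- function(result) {
  cfg <- result$config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$cells, file.path(cfg$out_dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- lapply(result$comparisons, function(cmp) {
    list(metric = cmp$metric,
         median = as.list(stats::setNames(cmp$median, cmp$labels)),
         iqr = as.list(stats::setNames(cmp$iqr, cmp$labels)),
         test = cmp$test, statistic = cmp$statistic, p_value = cmp$p_value,
         significant = cmp$significant)
  })
  jsonlite::write_json(summ, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    seed = cfg$seed, n_sham = cfg$n_sham, n_bbbd = cfg$n_bbbd,
    duration_s = cfg$duration_s, dt = cfg$dt, isi = cfg$isi,
    protocols = cfg$protocols, alpha = cfg$alpha,
    package_version = as.character(utils::packageVersion("gabapool")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (isTRUE(cfg$make_figures)) write_result_figures(result)
  invisible(result)
}

write_result_figures <- function(result) {
  cfg <- result$config
  grDevices::pdf(file.path(cfg$out_dir, "comparisons.pdf"), width = 8,
                 height = 6)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 2))
  for (cmp in result$comparisons) plot(cmp, main = cmp$metric)
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  tab <- table(x$cells$condition)
  cat(sprintf("pipeline result: %s cells\n",
              paste(sprintf("%d %s", tab, names(tab)), collapse = " + ")))
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}
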