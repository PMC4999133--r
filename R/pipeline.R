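# Experiment orchestration: simulate or load cohorts, fit every protocol,
# compute every statistic, and emit tidy report tables.

#' Experiment configuration
#'
#' Collects everything [run_experiment()] needs. All seeds are explicit;
#' nothing is seeded from the wall clock.
#'
#' @param grid Phantom grid (voxel counts). The default is a down-scaled
#'   cross-section that keeps per-ROI voxel counts in the tens while
#'   remaining fast; pass `c(128, 180, 8)` for the full acquisition matrix.
#' @param n_per_group Subjects per group.
#' @param groups Group labels.
#' @param timepoints Timepoint labels.
#' @param protocols Character vector of built-in protocol labels ("A",
#'   "B", "C") or a list of [acquisition_protocol()] objects.
#' @param seed Integer base seed.
#' @param fit_method Tensor fit method, "wls" or "ols".
#' @param noise_sigma,subject_cv,disease_effects,tissue_params Forwarded
#'   to [phantom_spec()].
#' @param out_dir Optional output directory for TSV tables.
#' @param bh_adjust Apply Benjamini-Hochberg correction to comparison
#'   p-values (off by default, matching uncorrected per-ROI testing).
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(grid = c(48L, 48L, 4L),
                              n_per_group = 7L,
                              groups = c("WT", "G93A"),
                              timepoints = c("week10", "week17"),
                              protocols = c("A", "B", "C"),
                              seed = 1L,
                              fit_method = "wls",
                              noise_sigma = 130,
                              subject_cv = 0.05,
                              disease_effects = default_disease_effects(),
                              tissue_params = default_tissue_params(),
                              out_dir = NULL,
                              bh_adjust = FALSE) {
  if (is.character(protocols)) protocols <- as.list(protocols)
  protocols <- lapply(protocols, function(p) {
    if (inherits(p, "acquisition_protocol")) p else builtin_protocol(p)
  })
  if (!is_scalar_number(seed)) stopf("seed must be a single explicit integer")
  cfg <- list(grid = as.integer(grid), n_per_group = as.integer(n_per_group),
              groups = groups, timepoints = timepoints, protocols = protocols,
              seed = as.integer(seed), fit_method = fit_method,
              noise_sigma = noise_sigma, subject_cv = subject_cv,
              disease_effects = disease_effects, tissue_params = tissue_params,
              out_dir = out_dir, bh_adjust = isTRUE(bh_adjust))
  class(cfg) <- "experiment_config"
  cfg
}

#' Read an experiment configuration from a JSON file
#'
#' Recognized top-level keys mirror the [experiment_config()] arguments;
#' `protocols` may list built-in labels or protocol-definition objects
#' (see [protocol_from_config()]).
#'
#' @param path JSON file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("grid", "n_per_group", "groups", "timepoints", "seed",
               "fit_method", "noise_sigma", "subject_cv", "out_dir"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$protocols)) {
    protos <- raw$protocols
    args$protocols <- if (is.character(protos)) as.list(protos)
      else lapply(seq_len(nrow(protos) %||% length(protos)), function(i) {
        p <- if (is.data.frame(protos)) as.list(protos[i, ]) else protos[[i]]
        if (is.character(p) && length(p) == 1L) p else protocol_from_config(p)
      })
  }
  do.call(experiment_config, args)
}

config_hash <- function(config) {
  keep <- config[setdiff(names(config), "out_dir")]
  sprintf("%08x", fnv1a32(paste(deparse(keep), collapse = "")))
}

roi_means_of_study <- function(maps, rois, subject, group, timepoint, protocol,
                               estimator) {
  rows <- list()
  for (metric in c(DTI_METRICS, "theta")) {
    map <- maps[[metric]]
    for (roi in ROI_NAMES) {
      v <- extract_roi(map, rois, roi)
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, group = group, timepoint = timepoint,
        protocol = protocol, metric = metric, roi = roi,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) sample_sd(v) else NA_real_,
        n_voxels = length(v),
        estimator = estimator)
    }
  }
  do.call(rbind, rows)
}

proto_ndir <- function(p) sum(!scheme_is_b0(p$scheme))

#' Run the full protocol-comparison experiment
#'
#' Simulates the cohort, fits every study with the estimator its scheme
#' supports, and assembles the report tables: per-ROI mean metrics, inter-
#' and intra-subject CV (computed on the control group), the best-protocol
#' (argmin CV) table, group/timepoint comparison tables (effect size +
#' Mann-Whitney p), and an SNR/CNR table. Deterministic for a fixed config.
#'
#' @param config An [experiment_config()].
#' @return A `report_bundle`: list of data.frames `roi_stats`,
#'   `mean_metrics`, `cv_inter`, `cv_intra`, `cv_intra_subject`,
#'   `best_protocol`, `comparisons`, `snr_cnr`, plus `config_hash`,
#'   `seed`, `timing`. Written as TSV when `config$out_dir` is set.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- proc.time()[["elapsed"]]
  timing <- list()
  spec <- phantom_spec(grid = config$grid,
                       tissue_params = config$tissue_params,
                       noise_sigma = config$noise_sigma,
                       subject_cv = config$subject_cv,
                       disease_effects = config$disease_effects)
  cohort <- make_cohort(spec, n_per_group = config$n_per_group,
                        groups = config$groups,
                        timepoints = config$timepoints,
                        protocols = config$protocols, seed = config$seed)
  rois <- cohort$rois
  timing$simulate <- proc.time()[["elapsed"]] - t0

  t1 <- proc.time()[["elapsed"]]
  per_study <- list()
  snr_rows <- list()
  mask <- cohort$label_map > 0L
  for (key in names(cohort$studies)) {
    st <- cohort$studies[[key]]
    meta <- st$meta
    mm <- tryCatch(
      compute_metric_maps(st, mask = mask, method = config$fit_method),
      error = function(e) stopf("stage fit failed for subject %s (%s): %s",
                                meta$subject_id, key, conditionMessage(e)))
    per_study[[key]] <- roi_means_of_study(mm$maps, rois, meta$subject_id,
                                           meta$group, meta$timepoint,
                                           meta$protocol, mm$estimator)
    b0mean <- apply(st$data[, , , which(scheme_is_b0(st$scheme)), drop = FALSE],
                    1:3, mean)
    snr_rows[[key]] <- data.frame(
      subject = meta$subject_id, group = meta$group, timepoint = meta$timepoint,
      protocol = meta$protocol,
      snr_wm = snr(b0mean, rois, "wholeWM"),
      snr_gm = snr(b0mean, rois, "wholeGM"),
      cnr_FA = cnr(mm$maps$FA, rois),
      cnr_MD = cnr(mm$maps$MD, rois),
      cnr_AD = cnr(mm$maps$AD, rois),
      cnr_RD = cnr(mm$maps$RD, rois))
    # per-voxel values needed later for intra-subject CV
    attr(per_study[[key]], "maps") <- mm$maps
  }
  roi_stats <- do.call(rbind, unname(lapply(per_study, identity)))
  rownames(roi_stats) <- NULL
  timing$fit <- proc.time()[["elapsed"]] - t1

  t2 <- proc.time()[["elapsed"]]
  ctrl <- config$groups[1]
  pnames <- vapply(config$protocols, function(p) p$name, "")

  # mean metrics per (protocol, metric, roi, group, timepoint); the theta
  # map is reported in roi_stats but not in the four-metric summary
  ms <- roi_stats[roi_stats$metric %in% DTI_METRICS, ]
  agg <- stats::aggregate(mean ~ protocol + metric + roi + group + timepoint,
                          data = ms, FUN = mean)
  sds <- stats::aggregate(mean ~ protocol + metric + roi + group + timepoint,
                          data = ms, FUN = sample_sd)
  names(sds)[names(sds) == "mean"] <- "sd_across_subjects"
  mean_metrics <- merge(agg, sds,
                        by = c("protocol", "metric", "roi", "group", "timepoint"))

  # inter-subject CV on the control group
  cvi_rows <- list()
  cvw_rows <- list()
  cvw_subj_rows <- list()
  for (pn in pnames) for (metric in DTI_METRICS) for (roi in ROI_NAMES)
    for (tp in config$timepoints) {
      sel <- roi_stats$protocol == pn & roi_stats$metric == metric &
        roi_stats$roi == roi & roi_stats$group == ctrl &
        roi_stats$timepoint == tp
      sub <- roi_stats[sel, ]
      if (!nrow(sub)) next
      cvi_rows[[length(cvi_rows) + 1L]] <- data.frame(
        protocol = pn, metric = metric, roi = roi, timepoint = tp,
        cv = cv_inter(sub$mean), kind = "inter")
      # intra-subject: per-subject within-ROI CV = sd/mean from roi_stats
      per <- sub$sd / sub$mean
      cvw_rows[[length(cvw_rows) + 1L]] <- data.frame(
        protocol = pn, metric = metric, roi = roi, timepoint = tp,
        cv = mean(per), kind = "intra")
      cvw_subj_rows[[length(cvw_subj_rows) + 1L]] <- data.frame(
        protocol = pn, metric = metric, roi = roi, timepoint = tp,
        subject = sub$subject, cv = per)
    }
  cv_inter_tab <- do.call(rbind, cvi_rows)
  cv_intra_tab <- do.call(rbind, cvw_rows)
  cv_intra_subject <- do.call(rbind, cvw_subj_rows)

  best_protocol <- if (length(pnames) >= 2L) {
    best_protocol_table(cv_inter_tab, config$protocols)
  } else {
    data.frame(metric = character(), roi = character(),
               timepoint = character(), best = character(), cv = numeric(),
               tie = logical())
  }

  comparisons <- comparison_tables(roi_stats, config)
  if (config$bh_adjust) comparisons$p <- bh_adjust(comparisons$p)
  comparisons$significant <- comparisons$p < 0.05

  snr_cnr <- do.call(rbind, unname(snr_rows))
  rownames(snr_cnr) <- NULL
  timing$analyze <- proc.time()[["elapsed"]] - t2

  bundle <- structure(
    list(roi_stats = roi_stats, mean_metrics = mean_metrics,
         cv_inter = cv_inter_tab, cv_intra = cv_intra_tab,
         cv_intra_subject = cv_intra_subject,
         best_protocol = best_protocol, comparisons = comparisons,
         snr_cnr = snr_cnr, truth = cohort$truth,
         config_hash = config_hash(config), seed = config$seed,
         timing = timing),
    class = "report_bundle")
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' Best-protocol (lowest inter-subject CV) table
#'
#' Per (metric, roi, timepoint), the protocol with the minimum CV. Exact
#' ties are broken toward the protocol with fewer diffusion directions and
#' recorded in the `tie` column.
#'
#' @param cv_table Data frame with columns protocol, metric, roi,
#'   timepoint, cv (as produced by [run_experiment()]).
#' @param protocols List of the `acquisition_protocol`s present (used for
#'   the fewer-directions tie rule).
#' @return Data frame: metric, roi, timepoint, best, cv, tie.
#' @export
best_protocol_table <- function(cv_table, protocols) {
  ndir <- stats::setNames(vapply(protocols, proto_ndir, numeric(1)),
                          vapply(protocols, function(p) p$name, ""))
  cells <- unique(cv_table[, c("metric", "roi", "timepoint")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sub <- cv_table[cv_table$metric == cell$metric & cv_table$roi == cell$roi &
                    cv_table$timepoint == cell$timepoint, ]
    if (nrow(sub) < 2L)
      stopf("best_protocol_table needs >= 2 protocols per cell (%s/%s/%s)",
            cell$metric, cell$roi, cell$timepoint)
    winners <- sub$protocol[sub$cv == min(sub$cv)]
    tie <- length(winners) > 1L
    best <- winners[which.min(ndir[winners])]
    rows[[i]] <- data.frame(metric = cell$metric, roi = cell$roi,
                            timepoint = cell$timepoint, best = best,
                            cv = min(sub$cv), tie = tie)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effect-size and p-value comparison tables
#'
#' For each protocol, metric and ROI: the disease contrast (case group vs
#' control group at each timepoint, control as reference) and the
#' progression contrasts (last vs first timepoint within each group, first
#' timepoint as reference). ES via [effect_size()], p via
#' [mann_whitney()]. A missing group skips the contrast with a warning;
#' degenerate reference groups surface an error with the cell coordinates.
#'
#' @param roi_stats Per-study ROI means (from [run_experiment()]), columns
#'   subject, group, timepoint, protocol, metric, roi, mean.
#' @param config The `experiment_config`.
#' @return Data frame: contrast, protocol, metric, roi, es, p, n_case,
#'   n_control.
#' @export
comparison_tables <- function(roi_stats, config) {
  groups <- config$groups
  tps <- config$timepoints
  pnames <- vapply(config$protocols, function(p) p$name, "")
  contrasts <- list()
  if (length(groups) >= 2L) {
    for (tp in tps)
      contrasts[[paste0(groups[2], "_vs_", groups[1], "_", tp)]] <-
        list(case = list(group = groups[2], timepoint = tp),
             ref = list(group = groups[1], timepoint = tp))
  }
  if (length(tps) >= 2L) {
    for (g in groups)
      contrasts[[paste0(g, "_", tps[length(tps)], "_vs_", tps[1])]] <-
        list(case = list(group = g, timepoint = tps[length(tps)]),
             ref = list(group = g, timepoint = tps[1]))
  }
  pick <- function(cond, pn, metric, roi)
    roi_stats$mean[roi_stats$group == cond$group &
                   roi_stats$timepoint == cond$timepoint &
                   roi_stats$protocol == pn & roi_stats$metric == metric &
                   roi_stats$roi == roi]
  rows <- list()
  for (cn in names(contrasts)) {
    ct <- contrasts[[cn]]
    for (pn in pnames) for (metric in DTI_METRICS) for (roi in ROI_NAMES) {
      case <- pick(ct$case, pn, metric, roi)
      ref <- pick(ct$ref, pn, metric, roi)
      if (!length(case) || !length(ref)) {
        warning(sprintf("contrast %s skipped for %s/%s/%s: group missing",
                        cn, pn, metric, roi), call. = FALSE)
        next
      }
      es <- tryCatch(effect_size(case, ref),
                     error = function(e)
                       stopf("effect size failed at cell (%s, %s, %s, %s): %s",
                             cn, pn, metric, roi, conditionMessage(e)))
      mw <- mann_whitney(case, ref)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = cn, protocol = pn, metric = metric, roi = roi,
        es = es, p = mw$p, n_case = length(case), n_control = length(ref))
    }
  }
  if (!length(rows)) {
    return(data.frame(contrast = character(), protocol = character(),
                      metric = character(), roi = character(),
                      es = numeric(), p = numeric(),
                      n_case = integer(), n_control = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a report bundle as TSV tables
#'
#' Each table carries a `# config_hash` comment line for provenance and a
#' header row; fields are tab-separated.
#'
#' @param bundle A `report_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return Invisible vector of the written paths.
#' @export
write_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory %s", out_dir)
  tables <- c("roi_stats", "mean_metrics", "cv_inter", "cv_intra",
              "cv_intra_subject", "best_protocol", "comparisons", "snr_cnr")
  paths <- character(0)
  for (nm in tables) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    con <- file(p, "w")
    writeLines(sprintf("# config_hash: %s seed: %d", bundle$config_hash,
                       bundle$seed), con)
    utils::write.table(format(bundle[[nm]], digits = 10, trim = TRUE,
                              scientific = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> hash=%s seed=%d\n", x$config_hash, x$seed))
  cat(sprintf("  %d roi_stats rows, %d comparisons, %d best-protocol cells\n",
              nrow(x$roi_stats), nrow(x$comparisons), nrow(x$best_protocol)))
  invisible(x)
}
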