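#' Convert a trace set to / from the long-format table
#'
#' The interchange format is a long TSV with columns `sample_id`,
#' `antibody_id`, `strip_index` (0-based), `mw_kda`, `intensity_rfu`; every
#' (sample, antibody) group must be complete and strictly ordered by strip.
#'
#' @param df long-format data.frame.
#' @return a `dw_traces` object.
#' @export
as_dw_traces <- function(df) {
  need <- c("sample_id", "antibody_id", "strip_index", "mw_kda", "intensity_rfu")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("trace table lacks columns: %s", paste(missing_cols, collapse = ", "))
  if (any(df$intensity_rfu < 0))
    stopf("negative intensity at rows: %s",
          paste(utils::head(which(df$intensity_rfu < 0), 3), collapse = ", "))
  key <- paste(df$sample_id, df$antibody_id, sep = "\r")
  groups <- split(seq_len(nrow(df)), key)
  lens <- lengths(groups)
  if (length(unique(lens)) > 1L)
    stopf("incomplete trace groups (%d vs %d strips): %s",
          min(lens), max(lens),
          paste(utils::head(sub("\r", " / ", names(groups)[lens != max(lens)]), 3),
                collapse = ", "))
  n_strip <- unname(lens[1])
  first <- groups[[1]]
  mw_axis <- df$mw_kda[first[order(df$strip_index[first])]]
  ids <- names(groups)
  mat <- matrix(0, length(groups), n_strip)
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    st <- df$strip_index[g]
    if (anyDuplicated(st) || !setequal(st, 0:(n_strip - 1L)))
      stopf("duplicate or missing strip_index in group %s",
            sub("\r", " / ", ids[i]))
    mat[i, st + 1L] <- df$intensity_rfu[g]
  }
  parts <- strsplit(ids, "\r", fixed = TRUE)
  new_dw_traces(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L),
                mat, mw_axis)
}

#' @rdname as_dw_traces
#' @param traces a `dw_traces` object.
#' @export
as_trace_table <- function(traces) {
  stopifnot(inherits(traces, "dw_traces"))
  n_strip <- ncol(traces$intensities)
  n <- length(traces$sample_id)
  data.frame(
    sample_id = rep(traces$sample_id, each = n_strip),
    antibody_id = rep(traces$antibody_id, each = n_strip),
    strip_index = rep(0:(n_strip - 1L), n),
    mw_kda = rep(traces$mw_axis, n),
    intensity_rfu = as.vector(t(traces$intensities)))
}

#' Read / write the long-format trace TSV
#' @param path file path.
#' @return [read_trace_table()] returns a `dw_traces`;
#'   [write_trace_table()] returns the path invisibly.
#' @export
read_trace_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warnf("empty trace table: %s", path)
    return(new_dw_traces(character(), character(),
                         matrix(0, 0, 0), numeric()))
  }
  as_dw_traces(df)
}

#' @rdname read_trace_table
#' @param traces a `dw_traces` object.
#' @export
write_trace_table <- function(traces, path) {
  utils::write.table(as_trace_table(traces), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a signal matrix as TSV plus a metadata sidecar JSON
#'
#' The TSV holds one row per analyte signal and one column per sample,
#' missing values encoded as `NA`; per-signal metadata travels in
#' `<path>.meta.json`. Values round-trip to within 1e-12.
#'
#' @param matrix a `dw_signal_matrix`.
#' @param path TSV path; the sidecar is written next to it.
#' @export
write_signal_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "dw_signal_matrix"))
  if ("NA" %in% colnames(matrix$values))
    stopf("sample named literal 'NA' would be ambiguous in the TSV")
  df <- data.frame(signal_id = rownames(matrix$values), matrix$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(matrix$signals, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signal_matrix
#' @export
read_signal_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".meta.json")
  if (!file.exists(sidecar)) stopf("missing sidecar metadata: %s", sidecar)
  signals <- jsonlite::fromJSON(sidecar)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$signal_id
  if (!identical(sort(signals$signal_id), sort(df$signal_id)))
    stopf("sidecar metadata does not match the matrix rows")
  new_signal_matrix(v, signals[match(df$signal_id, signals$signal_id), ])
}

#' Read / write sample metadata TSV
#' @param metadata data.frame with `sample_id`, `tumor_type`, `preservation`,
#'   `grade`, `tumor_cell_content`, `pair_id`.
#' @param path file path.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  bad <- setdiff(unique(md$preservation), c("fresh_frozen", "FFPE"))
  if (length(bad)) stopf("unknown preservation values: %s",
                         paste(bad, collapse = ", "))
  if (!is.null(md$tumor_cell_content) &&
      any(md$tumor_cell_content < 0 | md$tumor_cell_content > 100, na.rm = TRUE))
    stopf("tumor_cell_content must be in [0, 100]")
  md
}

config_hash <- function(config) {
  raw <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(raw), f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Composes every stage — cohort simulation, peak quantification, antibody
#' selection, descriptive statistics, nested-cross-validated classification,
#' final-model training and validation-cohort prediction — and writes all
#' stage outputs plus a manifest (config hash, seeds, per-file checksums)
#' and an audit trail of antibody counts at every filter step into `out_dir`.
#'
#' @param config a `dw_config`.
#' @param out_dir output directory (created if needed).
#' @param svm a `dw_svm_config`; defaults to reduced repeats so a full run
#'   stays interactive — pass `svm_config()` for the full design.
#' @param alpha significance level for the concordance selection.
#' @return list with every stage result (`cohort`, `ff`, `ffpe`, `selection`,
#'   `stats`, `report_ff`, `report_ffpe`, `model`, `validation`,
#'   `manifest`), invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         svm = svm_config(outer_repeats = 2L,
                                          inner_repeats = 1L,
                                          seed = config$seed),
                         alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  audit <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  cohort <- stage("simulate", generate_cohort(config))
  write_sample_metadata(cohort$metadata, file.path(out_dir, "metadata.tsv"))
  jsonlite::write_json(cohort$truth[c("antibodies", "samples")],
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  audit$antibodies_initial <- config$n_antibodies

  annotation <- data.frame(antibody_id = cohort$truth$templates$antibody_id,
                           expected_mw = cohort$truth$templates$expected_mw)
  ff <- stage("quantify", build_signal_matrix(
    cohort$ff, annotation, detection_floor = config$detection_floor))
  ffpe <- stage("quantify", build_signal_matrix(
    cohort$ffpe, annotation, detection_floor = config$detection_floor))
  write_signal_matrix(ff, file.path(out_dir, "signals_ff.tsv"))
  write_signal_matrix(ffpe, file.path(out_dir, "signals_ffpe.tsv"))
  audit$signals_ff <- nrow(ff$values)
  audit$signals_ffpe <- nrow(ffpe$values)

  ffpe_meta <- cohort$metadata[cohort$metadata$preservation == "FFPE", ]
  detected <- stage("select", detection_filter(ffpe, ffpe_meta))
  audit$antibodies_detected <- length(detected)

  pairing <- data.frame(ff = paste0(unique(cohort$metadata$pair_id), "_FF"),
                        ffpe = paste0(unique(cohort$metadata$pair_id), "_FFPE"))
  ff_l2 <- log2_transform(ff)
  ffpe_l2 <- log2_transform(ffpe)
  keep_rows <- ff_l2$signals$antibody_id %in% detected
  ff_det <- new_signal_matrix(ff_l2$values[keep_rows, , drop = FALSE],
                              ff_l2$signals[keep_rows, ])
  corr <- stage("select", correlate_ff_ffpe(ff_det, ffpe_l2, pairing,
                                            alpha = alpha))
  # a-priori exclusions: expected MW inside the cross-reaction window, whose
  # specific band cannot be told apart from the artifact
  manual <- if (config$hnsc_crossreaction) crossreaction_excludes(annotation)
            else character()
  sel <- stage("select", select_panel(corr, ff$signals,
                                      manual_excludes = manual, alpha = alpha))
  audit$antibodies_significant <- unname(sel$counts["significant"])
  audit$antibodies_kept <- unname(sel$counts["kept"])
  jsonlite::write_json(
    list(counts = as.list(sel$counts), panel = sel$panel,
         dispositions = sel$dispositions),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  if (nrow(sel$panel) == 0L)
    stopf("stage 'classify' failed: no features (empty antibody panel)")

  panel_rows <- sel$panel$signal_id
  tt_ff <- stage("analyze", pairwise_ttests(
    ff_l2, cohort$metadata,
    panel = intersect(panel_rows, rownames(ff_l2$values))))
  tt_ffpe <- stage("analyze", pairwise_ttests(
    ffpe_l2, cohort$metadata,
    panel = intersect(panel_rows, rownames(ffpe_l2$values))))
  tree_ff <- stage("analyze", hierarchical_cluster(
    ff_l2$values[intersect(panel_rows, rownames(ff_l2$values)), , drop = FALSE]))
  cluster_newick(tree_ff, file.path(out_dir, "cluster_ff.nwk"))

  x_ff <- t(ff_l2$values[intersect(panel_rows, rownames(ff_l2$values)), ,
                         drop = FALSE])
  x_ffpe <- t(ffpe_l2$values[intersect(panel_rows, rownames(ffpe_l2$values)), ,
                             drop = FALSE])
  y_ff <- cohort$metadata$tumor_type[match(rownames(x_ff),
                                           cohort$metadata$sample_id)]
  y_ffpe <- cohort$metadata$tumor_type[match(rownames(x_ffpe),
                                             cohort$metadata$sample_id)]
  report_ff <- stage("classify", nested_cv(x_ff, y_ff, svm))
  report_ffpe <- stage("classify", nested_cv(x_ffpe, y_ffpe, svm))

  model <- stage("classify", train_final(x_ffpe, y_ffpe, svm))
  vcohort <- stage("simulate", generate_validation_cohort(config, cohort$truth))
  vmat <- stage("quantify", build_signal_matrix(
    vcohort$ffpe, annotation, detection_floor = config$detection_floor))
  v_l2 <- log2_transform(vmat)
  xv <- matrix(NA_real_, ncol(v_l2$values), length(model$features),
               dimnames = list(colnames(v_l2$values), model$features))
  have <- intersect(model$features, rownames(v_l2$values))
  xv[, have] <- t(v_l2$values[have, , drop = FALSE])
  preds <- stage("classify", predict_cohort(model, xv, vcohort$metadata))
  utils::write.table(preds, file.path(out_dir, "validation_predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    nested_cv = list(
      ff = list(accuracy_mean = report_ff$accuracy_mean,
                accuracy_sd = report_ff$accuracy_sd,
                matrix = as.data.frame(report_ff$matrix)),
      ffpe = list(accuracy_mean = report_ffpe$accuracy_mean,
                  accuracy_sd = report_ffpe$accuracy_sd,
                  matrix = as.data.frame(report_ffpe$matrix))),
    validation_accuracy = 100 * mean(preds$predicted == preds$true_type),
    significant_counts = count_significant(tt_ff, tt_ffpe))
  jsonlite::write_json(report, file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest[.]json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("digiwest")),
    seed = config$seed,
    config_hash = config_hash(config),
    audit = audit,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, ff = ff, ffpe = ffpe, selection = sel,
                 stats = list(ff = tt_ff, ffpe = tt_ffpe, tree_ff = tree_ff),
                 report_ff = report_ff, report_ffpe = report_ffpe,
                 model = model, validation = preds, manifest = manifest))
}
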