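#' Filter antibodies on per-tumor-type detection frequency
#'
#' An antibody is retained when there is at least one tumor type in which it
#' is detected in at least `min_detected` samples, or in every sample of that
#' type (which matters for types smaller than `min_detected`). An antibody
#' counts as detected in a sample when any of its signal rows is non-missing
#' there.
#'
#' @param matrix a `dw_signal_matrix`.
#' @param metadata sample metadata with `sample_id` and `tumor_type` covering
#'   every matrix column.
#' @param min_detected detection count threshold.
#' @return character vector of retained antibody ids.
#' @export
detection_filter <- function(matrix, metadata, min_detected = 4L) {
  stopifnot(inherits(matrix, "dw_signal_matrix"))
  samples <- colnames(matrix$values)
  ty <- metadata$tumor_type[match(samples, metadata$sample_id)]
  if (anyNA(ty)) stopf("samples missing from metadata: %s",
                       paste(samples[is.na(ty)], collapse = ", "))
  if (nrow(matrix$values) == 0L) {
    warnf("empty signal matrix: no antibodies to filter")
    return(character())
  }
  abs_ <- unique(matrix$signals$antibody_id)
  keep <- vapply(abs_, function(ab) {
    rows <- matrix$signals$antibody_id == ab
    det <- colSums(!is.na(matrix$values[rows, , drop = FALSE])) > 0L
    any(vapply(unique(ty), function(tt) {
      d <- sum(det[ty == tt])
      d >= min_detected || d == sum(ty == tt)
    }, TRUE))
  }, TRUE)
  abs_[keep]
}

#' Correlate fresh-frozen and FFPE signals per analyte
#'
#' For every signal row shared by the two matrices, computes the Pearson
#' correlation between log2 fresh-frozen and FFPE values over the samples in
#' which the signal was detected in both preservations (complete pairs), with
#' the two-sided p-value of `cor.test`, and Benjamini-Hochberg adjusted
#' p-values across all tested signals. Signals with fewer than `min_pairs`
#' complete pairs, or zero variance in either vector, get `NA` correlation
#' and are excluded from the multiple-testing family.
#'
#' @param ff,ffpe `dw_signal_matrix` objects on the log2 scale
#'   (see [log2_transform()]).
#' @param pairing data.frame with columns `ff` and `ffpe` giving the paired
#'   sample ids; must be bijective.
#' @param min_pairs minimum complete pairs to test a signal.
#' @param alpha significance level on the adjusted p-values.
#' @return data.frame: `antibody_id`, `signal_id`, `r`, `n_pairs`, `p`,
#'   `p_bh`, `significant`.
#' @export
correlate_ff_ffpe <- function(ff, ffpe, pairing, min_pairs = 3L, alpha = 0.05) {
  stopifnot(inherits(ff, "dw_signal_matrix"), inherits(ffpe, "dw_signal_matrix"))
  if (anyDuplicated(pairing$ff) || anyDuplicated(pairing$ffpe))
    stopf("pairing must be bijective")
  pairing <- pairing[pairing$ff %in% colnames(ff$values) &
                     pairing$ffpe %in% colnames(ffpe$values), , drop = FALSE]
  if (nrow(pairing) == 0L) stopf("no shared samples between the two matrices")
  shared <- intersect(rownames(ff$values), rownames(ffpe$values))
  res <- lapply(shared, function(sid) {
    x <- ff$values[sid, pairing$ff]
    y <- ffpe$values[sid, pairing$ffpe]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    r <- NA_real_; p <- NA_real_
    if (n >= max(3L, min_pairs) &&
        stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                            alternative = "two.sided")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(antibody_id = ff$signals$antibody_id[
                 match(sid, ff$signals$signal_id)],
               signal_id = sid, r = r, n_pairs = n, p = p)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(antibody_id = character(), signal_id = character(),
                      r = numeric(), n_pairs = integer(), p = numeric())
  out$p_bh <- bh_adjust(out$p)
  out$significant <- !is.na(out$p_bh) & out$p_bh < alpha
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values: sort ascending, `q(i) = min over j >= i of
#' p(j) * m / j`, capped at 1, returned in input order. Missing entries are
#' excluded from the family size `m` and stay missing.
#'
#' @param pvalues numeric vector in [0, 1] (NAs allowed).
#' @return adjusted vector of the same length.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stopf("p-values outside [0, 1]: %s",
                      paste(utils::head(p[bad], 3), collapse = ", "))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Antibodies confoundable by the secondary-antibody cross-reaction band
#'
#' Returns the antibodies whose expected molecular weight lies close enough
#' to the 47-53 kDa cross-reaction band that the specific signal cannot be
#' told apart from the artifact: within the band widened by the band-merge
#' distance of the quantification stage (a few strips, ~18% in molecular
#' weight). These are excluded a priori, before any correlation is computed.
#'
#' @param annotation data.frame with `antibody_id`, `expected_mw`.
#' @param band artifact molecular-weight window, kDa.
#' @param tolerance relative widening of the window.
#' @return character vector of antibody ids.
#' @export
crossreaction_excludes <- function(annotation, band = c(47, 53),
                                   tolerance = 0.18) {
  annotation$antibody_id[annotation$expected_mw >= band[1] / (1 + tolerance) &
                         annotation$expected_mw <= band[2] * (1 + tolerance)]
}

#' Select the concordant antibody panel
#'
#' Applies, in order: (1) a-priori manual exclusions (e.g. antibodies whose
#' specific signal cannot be told apart from the secondary-antibody
#' cross-reaction band); (2) keep signals with adjusted p below `alpha`;
#' (3) per antibody retain only the signal with the highest correlation
#' (ties broken by smaller relative shift, then signal id); (4) drop signals
#' whose band sits more than the shift tolerance away from the expected
#' molecular weight; (5) drop signals flagged as unclear peaks. Every input
#' antibody receives exactly one disposition.
#'
#' @param correlations output of [correlate_ff_ffpe()].
#' @param matched per-signal metadata (`signals` element of a
#'   `dw_signal_matrix`): needs `signal_id`, `relative_shift`, `shift_flag`.
#' @param manual_excludes antibody ids excluded a priori.
#' @param unclear_peaks signal or antibody ids flagged as unclear (manual QC).
#' @param alpha significance level on adjusted p-values.
#' @return list of class `dw_selection`: `panel` (data.frame antibody_id,
#'   signal_id, r, p_bh, band_mw), `dispositions` (per antibody), `counts`
#'   (audit trail of stage counts).
#' @export
select_panel <- function(correlations, matched, manual_excludes = character(),
                         unclear_peaks = character(), alpha = 0.05) {
  cr <- merge(correlations,
              matched[, intersect(c("signal_id", "relative_shift",
                                    "shift_flag", "band_mw"), names(matched))],
              by = "signal_id", all.x = TRUE)
  if (anyNA(cr$relative_shift))
    stopf("signals without matched-signal metadata: %s",
          paste(utils::head(cr$signal_id[is.na(cr$relative_shift)], 3),
                collapse = ", "))
  all_abs <- unique(cr$antibody_id)
  disp <- stats::setNames(rep(NA_character_, length(all_abs)), all_abs)

  # (1) a-priori manual exclusions
  disp[all_abs %in% manual_excludes] <- "manual_exclude"
  cr <- cr[!cr$antibody_id %in% manual_excludes, , drop = FALSE]

  # (2) significance on BH-adjusted p-values
  sig <- cr[!is.na(cr$p_bh) & cr$p_bh < alpha, , drop = FALSE]
  not_detected <- setdiff(unique(cr$antibody_id[is.na(cr$r)]),
                          unique(cr$antibody_id[!is.na(cr$r)]))
  disp[names(disp) %in% not_detected & is.na(disp)] <- "not_detected"
  disp[is.na(disp) & !names(disp) %in% unique(sig$antibody_id)] <- "not_significant"

  # (3) best signal per antibody: max r, ties by smaller shift then id
  sig <- sig[order(sig$antibody_id, -sig$r, sig$relative_shift, sig$signal_id), ]
  best <- sig[!duplicated(sig$antibody_id), , drop = FALSE]

  # (4) shifted bands, (5) unclear peaks
  unclear <- best$signal_id %in% unclear_peaks |
    best$antibody_id %in% unclear_peaks
  disp[best$antibody_id[best$shift_flag & !unclear]] <- "shifted"
  disp[best$antibody_id[unclear]] <- "unclear_peak"
  kept <- best[!best$shift_flag & !unclear, , drop = FALSE]
  disp[kept$antibody_id] <- "kept"

  counts <- c(initial = length(all_abs),
              tested = length(unique(cr$antibody_id[!is.na(cr$r)])),
              significant = length(unique(sig$antibody_id)),
              kept = nrow(kept))
  structure(list(
    panel = kept[, intersect(c("antibody_id", "signal_id", "r", "p_bh",
                               "band_mw", "relative_shift"), names(kept))],
    dispositions = data.frame(antibody_id = names(disp),
                              disposition = unname(disp)),
    counts = counts), class = "dw_selection")
}

#' @export
print.dw_selection <- function(x, ...) {
  cat("<dw_selection>\n")
  cat(sprintf("  %d antibodies -> %d tested -> %d significant -> %d kept\n",
              x$counts["initial"], x$counts["tested"], x$counts["significant"],
              x$counts["kept"]))
  tb <- table(x$dispositions$disposition)
  cat("  dispositions:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      "\n")
  invisible(x)
}
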