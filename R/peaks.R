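#' Calibrate a molecular-weight axis over membrane strips
#'
#' Maps strip index to molecular weight by linear interpolation of log10(MW)
#' in strip index through ladder anchor points, with linear extrapolation of
#' the end segments beyond the outermost anchors. By SDS-PAGE convention the
#' axis decreases with strip index (high molecular weight at the gel top),
#' but any strictly monotone anchor set is accepted.
#'
#' @param trace_length number of strips (default 96).
#' @param anchors two-column matrix or data.frame of (strip index 0-based,
#'   molecular weight in kDa); at least two rows, distinct strips, positive kDa,
#'   strictly monotone kDa along increasing strip.
#' @param at optional (possibly fractional) strip positions at which to return
#'   the molecular weight instead of the full axis.
#' @return numeric vector of molecular weights (kDa): one per strip 0..
#'   `trace_length - 1`, or one per element of `at`.
#' @export
#' @examples
#' mw <- calibrate_mw(96, cbind(c(0, 95), c(250, 10)))
#' mw[1]   # 250 at strip 0
#' mw[96]  # 10 at strip 95
calibrate_mw <- function(trace_length = 96L, anchors, at = NULL) {
  anchors <- as.matrix(anchors)
  if (nrow(anchors) < 2L) stopf("need at least 2 anchors, got %d", nrow(anchors))
  if (anyDuplicated(anchors[, 1L])) stopf("anchor strip indices must be distinct")
  if (any(anchors[, 2L] <= 0)) stopf("anchor molecular weights must be positive")
  ord <- order(anchors[, 1L])
  strip <- anchors[ord, 1L]
  lmw <- log10(anchors[ord, 2L])
  d <- diff(lmw)
  if (!(all(d > 0) || all(d < 0)))
    stopf("anchors must be strictly monotone in molecular weight")
  x <- if (is.null(at)) seq(0L, trace_length - 1L) else at
  # piecewise-linear in log10(MW); end segments extended for extrapolation
  idx <- findInterval(x, strip, rightmost.closed = FALSE, all.inside = TRUE)
  slope <- d / diff(strip)
  lm_out <- lmw[idx] + slope[idx] * (x - strip[idx])
  10^lm_out
}

#' Detect peaks in a fluorescence trace
#'
#' Identifies strict local maxima, extends each to its nearest flanking
#' minima, and filters on prominence and signal-to-noise. Adjacent apexes
#' closer than `min_separation` strips are merged into the higher one, which
#' is how closely spaced bands eluting into neighbouring strips are resolved
#' into a single signal. Noise is estimated as
#' `mad(diff(intensities)) / sqrt(2)`, robust to the peaks themselves.
#'
#' @param intensities numeric vector of non-negative fluorescence values
#'   ordered by strip index.
#' @param mw_axis optional molecular-weight axis (same length) used to report
#'   apex molecular weights.
#' @param min_snr minimum (apex height above local background) / noise.
#' @param min_prominence minimum apex height above the higher flanking
#'   minimum, in RFU.
#' @param min_separation apexes closer than this many strips are merged.
#' @return data.frame with one row per peak, sorted by strip index:
#'   `left_strip`, `apex_strip`, `right_strip` (0-based indices), `apex_mw`
#'   (NA without an axis), `height`, `prominence`, `snr`, `area`,
#'   `background_area`. Empty for flat or all-noise traces.
#' @export
detect_peaks <- function(intensities, mw_axis = NULL, min_snr = 3,
                         min_prominence = 0, min_separation = 3L) {
  y <- as.numeric(intensities)
  if (any(!is.finite(y))) stopf("trace contains non-finite intensities")
  if (!is.null(mw_axis) && length(mw_axis) != length(y))
    stopf("mw_axis length %d != trace length %d", length(mw_axis), length(y))
  m <- detect_peaks_core(y, min_snr, min_prominence, min_separation)
  if (nrow(m) == 0L) return(empty_peaks())
  data.frame(
    left_strip = as.integer(m[, 1L]),
    apex_strip = as.integer(m[, 2L]),
    right_strip = as.integer(m[, 3L]),
    apex_mw = if (is.null(mw_axis)) NA_real_ else mw_axis[m[, 2L] + 1L],
    height = m[, 4L],
    prominence = m[, 5L],
    snr = m[, 6L],
    area = m[, 7L],
    background_area = m[, 8L]
  )
}

# matrix-returning scanner used in the quantification loop; columns are
# left, apex, right (0-based), height, prominence, snr, area, background_area
detect_peaks_core <- function(y, min_snr, min_prominence, min_separation) {
  n <- length(y)
  none <- matrix(0, 0L, 8L)
  if (n < 3L) return(none)
  noise <- stats::mad(diff(y)) / sqrt(2)
  mid <- 2:(n - 1L)
  apex <- mid[y[mid] > y[mid - 1L] & y[mid] > y[mid + 1L]]
  if (length(apex) == 0L) return(none)

  # conservative pre-filter: the local background is a bridge between bound
  # intensities, each >= min(y), so apex height above background (and
  # prominence) is bounded by y[apex] - min(y); candidates below both
  # thresholds cannot survive the final filters, and since the bound is
  # monotone in apex height no dropped candidate can win a merge
  floor_y <- min(y)
  lim <- max(min_prominence, if (noise > 0) min_snr * noise else 0)
  apex <- apex[y[apex] - floor_y >= lim]
  if (length(apex) == 0L) return(none)

  # merge apexes closer than min_separation strips, keeping the higher
  repeat {
    close <- which(diff(apex) < min_separation)
    if (length(close) == 0L) break
    i <- close[1L]
    drop <- if (y[apex[i]] >= y[apex[i + 1L]]) i + 1L else i
    apex <- apex[-drop]
  }

  k <- length(apex)
  out <- matrix(0, k, 8L)
  for (j in seq_len(k)) {
    a <- apex[j]
    l <- a
    while (l > 1L && y[l - 1L] <= y[l]) l <- l - 1L
    r <- a
    while (r < n && y[r + 1L] <= y[r]) r <- r + 1L
    seg <- y[l:r]
    w <- r - l + 1L
    bg <- if (w == 1L) seg else seq.int(seg[1L], seg[w], length.out = w)
    area <- sum(pmax(0, seg - bg))
    prom <- y[a] - max(y[l], y[r])
    bg_apex <- y[l] + (y[r] - y[l]) * (a - l) / max(1L, r - l)
    height <- y[a] - bg_apex
    snr <- if (noise > 0) height / noise else Inf
    out[j, ] <- c(l - 1L, a - 1L, r - 1L, height, prom, snr, area, sum(bg))
  }
  out[out[, 5L] >= min_prominence & out[, 6L] >= min_snr, , drop = FALSE]
}

empty_peaks <- function() {
  data.frame(left_strip = integer(), apex_strip = integer(),
             right_strip = integer(), apex_mw = numeric(), height = numeric(),
             prominence = numeric(), snr = numeric(), area = numeric(),
             background_area = numeric())
}

#' Quantify a peak as its local-background-subtracted area
#'
#' The local background is a linear bridge between the intensities at the
#' peak boundaries; the area is the sum over strips in the peak of the
#' intensity above that bridge, clipped at zero so a concave-down background
#' never produces negative area.
#'
#' @param intensities trace intensity vector.
#' @param left_strip,right_strip 0-based peak bounds, `left <= right`.
#' @return named numeric: `area` (RFU * strips) and `background_area`.
#' @export
quantify_peak <- function(intensities, left_strip, right_strip) {
  y <- as.numeric(intensities)
  l <- as.integer(left_strip) + 1L
  r <- as.integer(right_strip) + 1L
  if (l > r) stopf("inverted peak bounds: left %d > right %d", l - 1L, r - 1L)
  if (l < 1L || r > length(y)) stopf("peak bounds outside trace")
  seg <- y[l:r]
  k <- length(seg)
  bg <- if (k == 1L) seg else seq(seg[1L], seg[k], length.out = k)
  c(area = sum(pmax(0, seg - bg)), background_area = sum(bg))
}

#' Match detected peaks against an antibody's expected molecular weight
#'
#' Annotates each peak with its relative shift from the expected molecular
#' weight and flags peaks shifted beyond the tolerance (20% by default; the
#' tolerance is inclusive, so a shift of exactly 20% is not flagged). The
#' peak with the smallest relative shift is marked primary, and the antibody
#' counts as detected when the primary peak's area exceeds the detection
#' floor.
#'
#' @param peaks data.frame from [detect_peaks()] (must carry `apex_mw`).
#' @param expected_mw expected molecular weight in kDa, > 0.
#' @param shift_tolerance maximum tolerated `|apex_mw - expected| / expected`.
#' @param detection_floor minimum primary-peak area counted as detected.
#' @return `peaks` with added columns `expected_mw`, `relative_shift`,
#'   `shift_flag`, `primary`, plus attribute `detected`.
#' @export
match_signals <- function(peaks, expected_mw, shift_tolerance = 0.20,
                          detection_floor = 0) {
  assert_number(expected_mw, "expected_mw", lower = .Machine$double.eps)
  peaks$expected_mw <- expected_mw
  if (nrow(peaks) == 0L) {
    peaks$relative_shift <- numeric()
    peaks$shift_flag <- logical()
    peaks$primary <- logical()
    attr(peaks, "detected") <- FALSE
    return(peaks)
  }
  peaks$relative_shift <- abs(peaks$apex_mw - expected_mw) / expected_mw
  peaks$shift_flag <- peaks$relative_shift > shift_tolerance
  peaks$primary <- seq_len(nrow(peaks)) == which.min(peaks$relative_shift)
  attr(peaks, "detected") <- peaks$area[peaks$primary] > detection_floor
  peaks
}

#' Build a samples x analyte-signals matrix from a trace set
#'
#' Runs peak detection and quantification on every (antibody, sample) trace,
#' groups peaks across samples into molecular-weight bands (1-D single-linkage
#' on apex strip index: a gap wider than `band_gap` strips starts a new band),
#' and emits one signal row per band. Several bands per antibody therefore
#' yield several signal rows, mirroring antibodies that show more than one
#' band on a blot. Entries with no peak in the band, or with area at or below
#' the detection floor, are missing.
#'
#' @param traces a `dw_traces` set (see [as_dw_traces()]).
#' @param antibodies annotation data.frame with columns `antibody_id` and
#'   `expected_mw` (kDa); every antibody present in `traces` must appear.
#' @param detection_floor minimum background-subtracted area counted as
#'   detected (RFU * strips).
#' @param min_snr,min_prominence,min_separation passed to [detect_peaks()].
#' @param shift_tolerance passed to [match_signals()].
#' @param band_gap strip gap that separates molecular-weight bands.
#' @return object of class `dw_signal_matrix`: list with `values` (signals x
#'   samples numeric matrix, NA = not detected) and `signals` (per-row
#'   metadata: antibody_id, signal_id, band_mw, expected_mw, relative_shift,
#'   shift_flag, n_detected).
#' @export
build_signal_matrix <- function(traces, antibodies, detection_floor = 50,
                                min_snr = 3, min_prominence = 0,
                                min_separation = 3L, shift_tolerance = 0.20,
                                band_gap = 3L) {
  stopifnot(inherits(traces, "dw_traces"))
  ab_ids <- unique(traces$antibody_id)
  unknown <- setdiff(ab_ids, antibodies$antibody_id)
  if (length(unknown) > 0L)
    stopf("antibodies missing from annotation: %s",
          paste(unknown, collapse = ", "))
  samples <- unique(traces$sample_id)
  mw_axis <- traces$mw_axis

  rows <- list()
  values <- list()
  idx_by_ab <- split(seq_along(traces$antibody_id), traces$antibody_id)
  for (ab in ab_ids) {
    idx <- idx_by_ab[[ab]]
    expected <- antibodies$expected_mw[match(ab, antibodies$antibody_id)]
    pk_by_sample <- lapply(idx, function(i) {
      p <- detect_peaks_core(traces$intensities[i, ], min_snr,
                             min_prominence, min_separation)
      if (nrow(p) == 0L) return(NULL)
      cbind(p, match(traces$sample_id[i], samples))
    })
    all_pk <- do.call(rbind, pk_by_sample)
    if (is.null(all_pk) || nrow(all_pk) == 0L) next

    # single-linkage 1-D band clustering on apex strip
    all_pk <- all_pk[order(all_pk[, 2L]), , drop = FALSE]
    band <- cumsum(c(1L, diff(all_pk[, 2L]) > band_gap))

    band_meta <- lapply(split(seq_len(nrow(all_pk)), band), function(bi) {
      b <- all_pk[bi, , drop = FALSE]
      mw <- stats::median(mw_axis[b[, 2L] + 1L])
      v <- rep(NA_real_, length(samples))
      names(v) <- samples
      for (si in unique(b[, 9L])) {
        a <- max(b[b[, 9L] == si, 7L])
        if (a > detection_floor) v[si] <- a
      }
      shift <- abs(mw - expected) / expected
      list(values = v, band_mw = mw, relative_shift = shift,
           shift_flag = shift > shift_tolerance, n_detected = sum(!is.na(v)))
    })
    band_meta <- band_meta[vapply(band_meta, function(b) b$n_detected, 1L) > 0L]
    if (length(band_meta) == 0L) next
    # signal ids ranked by closeness to the expected molecular weight
    shifts <- vapply(band_meta, function(b) b$relative_shift, 1)
    rank_ord <- order(shifts)
    for (k in seq_along(rank_ord)) {
      b <- band_meta[[rank_ord[k]]]
      sid <- sprintf("%s@s%d", ab, k)
      rows[[sid]] <- data.frame(
        antibody_id = ab, signal_id = sid, band_mw = b$band_mw,
        expected_mw = expected, relative_shift = b$relative_shift,
        shift_flag = b$shift_flag, n_detected = b$n_detected)
      values[[sid]] <- b$values
    }
  }
  if (length(rows) == 0L) {
    return(new_signal_matrix(
      matrix(NA_real_, 0L, length(samples), dimnames = list(NULL, samples)),
      do.call(rbind, rows)))
  }
  val <- do.call(rbind, values)
  rownames(val) <- names(values)
  new_signal_matrix(val, do.call(rbind, rows))
}

new_signal_matrix <- function(values, signals) {
  if (is.null(signals))
    signals <- data.frame(antibody_id = character(), signal_id = character(),
                          band_mw = numeric(), expected_mw = numeric(),
                          relative_shift = numeric(), shift_flag = logical(),
                          n_detected = integer())
  rownames(signals) <- NULL
  structure(list(values = values, signals = signals),
            class = "dw_signal_matrix")
}

#' @export
print.dw_signal_matrix <- function(x, ...) {
  cat(sprintf("<dw_signal_matrix> %d signals (%d antibodies) x %d samples, %.1f%% detected\n",
              nrow(x$values), length(unique(x$signals$antibody_id)),
              ncol(x$values), 100 * mean(!is.na(x$values))))
  invisible(x)
}

#' @export
dim.dw_signal_matrix <- function(x) dim(x$values)
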