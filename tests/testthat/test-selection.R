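# small signal matrix with controlled detection patterns
toy_matrix <- function(values, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  colnames(values) <- samples
  rownames(values) <- sprintf("%s@s1", sprintf("AB%02d", seq_len(nrow(values))))
  sig <- data.frame(
    antibody_id = sprintf("AB%02d", seq_len(nrow(values))),
    signal_id = rownames(values),
    band_mw = 50, expected_mw = 50, relative_shift = 0,
    shift_flag = FALSE, n_detected = rowSums(!is.na(values)))
  digiwest:::new_signal_matrix(values, sig)
}

test_that("detection filter keeps antibodies with a well-detected tumor type", {
  md <- data.frame(sample_id = sprintf("S%02d", 1:12),
                   tumor_type = rep(c("HNSC", "LUSC", "COAD"), each = 4))
  v <- matrix(NA_real_, 3, 12)
  v[1, 1:4] <- 1                       # 4 of 4 HNSC -> kept (>= 4)
  v[2, c(1:3, 5:7, 9:11)] <- 1         # 3 in every type of 4 -> dropped
  v[3, 9:10] <- 1                      # only 2 detected anywhere
  m <- toy_matrix(v)
  expect_equal(detection_filter(m, md, min_detected = 4L), "AB01")

  # the all-samples clause keeps full coverage of a small group
  md2 <- data.frame(sample_id = sprintf("S%02d", 1:12),
                    tumor_type = c(rep("HNSC", 4), rep("LUSC", 4),
                                   rep("COAD", 2), rep("PAAD", 2)))
  expect_true("AB03" %in% detection_filter(m, md2, min_detected = 4L))

  empty <- digiwest:::new_signal_matrix(
    matrix(NA_real_, 0, 12, dimnames = list(NULL, md$sample_id)), NULL)
  expect_warning(out <- detection_filter(empty, md), "empty")
  expect_length(out, 0)
})

test_that("FF/FFPE correlation matches cor.test over complete pairs", {
  pairing <- data.frame(ff = sprintf("F%d", 1:5), ffpe = sprintf("P%d", 1:5))
  vals <- rbind(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1), c(1, 2, 3, 4, 5))
  ff <- toy_matrix(vals[c(1, 1, 1), ], samples = pairing$ff)
  ffpe <- toy_matrix(rbind(vals[1, ], 6 - vals[1, ], c(1, 2, 3, 4, 6)),
                     samples = pairing$ffpe)
  out <- correlate_ff_ffpe(ff, ffpe, pairing)
  expect_equal(out$r[1], 1)
  expect_lt(out$p[1], 1e-8)
  expect_equal(out$r[2], -1)
  # textbook covariance/sd formula to 1e-12
  x <- c(1, 2, 3, 4, 5); y <- c(1, 2, 3, 4, 6)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r[3], r_hand, tolerance = 1e-12)
  expect_true(all(out$p_bh >= out$p))

  # incomplete pairs below the minimum are reported but not tested
  ff2 <- toy_matrix(rbind(c(1, 2, NA, NA, NA)), samples = pairing$ff)
  fp2 <- toy_matrix(rbind(c(1, 2, 3, 4, 5)), samples = pairing$ffpe)
  out2 <- correlate_ff_ffpe(ff2, fp2, pairing)
  expect_true(is.na(out2$r))
  expect_equal(out2$n_pairs, 2L)

  expect_error(correlate_ff_ffpe(ff, ffpe,
                                 data.frame(ff = "nope", ffpe = "nope2")),
               "no shared samples")
  expect_error(correlate_ff_ffpe(ff, ffpe,
                                 data.frame(ff = c("F1", "F1"),
                                            ffpe = c("P1", "P2"))),
               "bijective")
})

test_that("Benjamini-Hochberg adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "outside")
  # NAs excluded from the family, preserved in place
  out <- bh_adjust(c(0.02, NA, 0.04))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], c(0.04, 0.04))
  # random vectors against the independent step-up oracle
  set.seed(11)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("panel selection applies exclusions, significance, best-signal and shift rules in order", {
  corr <- data.frame(
    antibody_id = c("A", "A", "B", "C", "D", "E"),
    signal_id = c("A@s1", "A@s2", "B@s1", "C@s1", "D@s1", "E@s1"),
    r = c(0.9, 0.5, 0.8, 0.7, NA, 0.85),
    n_pairs = c(10, 10, 10, 10, 1, 10),
    p = c(1e-5, 1e-3, 1e-4, 1e-4, NA, 1e-4))
  corr$p_bh <- bh_adjust(corr$p)
  corr$significant <- !is.na(corr$p_bh) & corr$p_bh < 0.05
  matched <- data.frame(
    signal_id = corr$signal_id,
    relative_shift = c(0.01, 0.3, 0.05, 0.25, 0.0, 0.02),
    shift_flag = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    band_mw = 50)
  sel <- select_panel(corr, matched, manual_excludes = "E",
                      unclear_peaks = "B@s1")
  d <- setNames(sel$dispositions$disposition, sel$dispositions$antibody_id)
  # A keeps its higher-correlation signal; B unclear; C shifted; D never
  # detected enough to test; E excluded a priori
  expect_equal(sel$panel$signal_id, "A@s1")
  expect_equal(unname(d[c("A", "B", "C", "D", "E")]),
               c("kept", "unclear_peak", "shifted", "not_detected",
                 "manual_exclude"))
  # dispositions partition the antibody set and match the audit counts
  expect_equal(nrow(sel$dispositions), 5L)
  expect_equal(unname(sel$counts["initial"]), 5L)
  expect_equal(unname(sel$counts["kept"]), 1L)

  # everything insignificant: empty panel
  corr2 <- corr
  corr2$p_bh <- 1
  corr2$significant <- FALSE
  sel2 <- select_panel(corr2, matched)
  expect_equal(nrow(sel2$panel), 0L)
  expect_true(all(sel2$dispositions$disposition %in%
                    c("not_significant", "not_detected")))

  # identical inputs give identical results
  expect_identical(select_panel(corr, matched, manual_excludes = "E",
                                unclear_peaks = "B@s1"), sel)
})

test_that("planted concordance is recovered on a synthetic cohort", {
  co <- cached("paired17", generate_cohort(cohort_config(seed = 17)))
  run <- cached("sel17", run_selection(co, cached("paired17q", quantify_cohort(co))))
  tr <- co$truth$antibodies
  conc <- setdiff(tr$antibody_id[tr$concordant], run$excl)
  sig <- unique(run$corr$antibody_id[run$corr$significant])
  expect_gt(mean(conc %in% sig), 0.85)
  expect_lt(mean(!(sig %in% conc)), 0.15)
  # disposition partition over the screened antibodies
  tb <- table(run$sel$dispositions$disposition)
  expect_equal(sum(tb), length(unique(run$corr$antibody_id)) +
                 sum(run$excl %in% run$sel$dispositions$antibody_id))
})
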