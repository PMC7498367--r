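test_that("trace generation is noise-free-exact, attenuation-multiplicative, and deterministic", {
  cfg <- cohort_config(noise_sd = 0, baseline_level = 0, seed = 5)
  tpl <- data.frame(antibody_id = "AB1", expected_mw = 50, is_phospho = FALSE,
                    concordant = TRUE, ffpe_attenuation = 0.5,
                    shift_factor = 1, base_log2 = 9)
  tpl$extra_peaks <- I(list(list()))
  tpl$class_effect <- I(list(c(HNSC = 0, LUSC = 0, LUAD = 0, COAD = 0, PAAD = 0)))
  axis <- config_mw_axis(cfg)
  target_strip <- which.min(abs(log(axis) - log(50)))

  y_ff <- generate_trace(tpl, log2(100), "fresh_frozen", cfg, seed = 11)
  expect_equal(which.max(y_ff), target_strip)
  expect_equal(max(y_ff), 100)

  y_fp <- generate_trace(tpl, log2(100), "FFPE", cfg, seed = 11)
  expect_equal(which.max(y_fp), target_strip)
  expect_equal(max(y_fp), 50)  # attenuation 0.5 is multiplicative

  cfg_noisy <- cohort_config(seed = 5)
  a <- generate_trace(tpl, 9, "fresh_frozen", cfg_noisy, seed = 123)
  b <- generate_trace(tpl, 9, "fresh_frozen", cfg_noisy, seed = 123)
  expect_identical(a, b)
  expect_true(all(a >= 0))

  tpl_out <- tpl
  tpl_out$expected_mw <- 600
  expect_error(generate_trace(tpl_out, 9, "fresh_frozen", cfg, seed = 1),
               "outside")
  expect_error(generate_trace(tpl, 9, "frozen", cfg, seed = 1), "preservation")
})

test_that("paired cohorts have a bijective FF/FFPE pairing over the stated design", {
  co <- cached("small1", generate_cohort(small_config(seed = 1)))
  md <- co$metadata
  expect_equal(nrow(md), 2 * 3 * 5)
  expect_equal(sum(md$preservation == "fresh_frozen"), 15)
  ff <- md[md$preservation == "fresh_frozen", ]
  fp <- md[md$preservation == "FFPE", ]
  expect_setequal(ff$pair_id, fp$pair_id)
  expect_false(anyDuplicated(ff$pair_id) > 0)
  expect_false(anyDuplicated(fp$pair_id) > 0)
  expect_equal(as.integer(table(ff$tumor_type)[co$config$tumor_types]),
               rep(3L, 5L))
  # grades and tumor content within their vocabularies
  expect_true(all(md$grade %in% c("G1", "G2", "G2-3", "G3")))
  expect_true(all(md$tumor_cell_content >= 30 & md$tumor_cell_content <= 100))
  # ground truth covers every antibody and sample exactly once
  expect_equal(sort(co$truth$antibodies$antibody_id),
               sort(co$truth$templates$antibody_id))
  expect_setequal(co$truth$samples$sample_id, md$sample_id)
})

test_that("cohort generation is reproducible and seed-sensitive", {
  a <- generate_cohort(small_config(seed = 9))
  b <- generate_cohort(small_config(seed = 9))
  expect_identical(a$ff$intensities, b$ff$intensities)
  expect_identical(a$metadata, b$metadata)
  c <- generate_cohort(small_config(seed = 10))
  expect_false(identical(a$ff$intensities, c$ff$intensities))
})

test_that("FFPE amplitude never exceeds fresh-frozen for a fixed template and abundance", {
  cfg <- cohort_config(noise_sd = 0, baseline_level = 0)
  tplbase <- data.frame(antibody_id = "AB1", expected_mw = 40,
                        is_phospho = FALSE, concordant = TRUE,
                        shift_factor = 1, base_log2 = 9)
  for (att in c(0.1, 0.5, 1)) {
    tpl <- tplbase
    tpl$ffpe_attenuation <- att
    tpl$extra_peaks <- I(list(list()))
    tpl$class_effect <- I(list(c(HNSC = 0, LUSC = 0, LUAD = 0, COAD = 0, PAAD = 0)))
    expect_lte(max(generate_trace(tpl, 8, "FFPE", cfg, 3)),
               max(generate_trace(tpl, 8, "fresh_frozen", cfg, 3)))
  }
})

test_that("concordant antibodies share latent abundance; null cohorts decorrelate", {
  # noiseless identity: full concordance, no attenuation, no extra noise
  cfg_id <- small_config(seed = 4, fraction_concordant = 1,
                         ffpe_attenuation_range = c(1, 1), ffpe_noise_sd = 0,
                         noise_sd = 0, baseline_level = 0,
                         hnsc_crossreaction = FALSE, extra_peak_prob = 0,
                         shift_prob = 0)
  co <- generate_cohort(cfg_id)
  q <- quantify_cohort(co)
  corr <- correlate_ff_ffpe(log2_transform(q$ff), log2_transform(q$ffpe),
                            pairing_of(co))
  tested <- corr[!is.na(corr$r), ]
  expect_gt(nrow(tested), 20)
  expect_equal(tested$r, rep(1, nrow(tested)), tolerance = 1e-9)

  # fully null cohort: mean correlation near zero
  cfg0 <- small_config(seed = 6, fraction_concordant = 0,
                       hnsc_crossreaction = FALSE)
  co0 <- generate_cohort(cfg0)
  q0 <- quantify_cohort(co0)
  corr0 <- correlate_ff_ffpe(log2_transform(q0$ff), log2_transform(q0$ffpe),
                             pairing_of(co0))
  expect_lt(abs(mean(corr0$r, na.rm = TRUE)), 0.2)
})

test_that("fresh-frozen signals are detected at least as often as FFPE on average", {
  co <- cached("paired17", generate_cohort(cohort_config(seed = 17)))
  q <- cached("paired17q", quantify_cohort(co))
  det <- function(m) {
    s1 <- grepl("@s1$", m$signals$signal_id)
    mean(rowSums(!is.na(m$values[s1, , drop = FALSE])))
  }
  expect_gt(det(q$ff), det(q$ffpe))
})

test_that("validation cohorts reuse the panel but draw fresh samples", {
  co <- cached("small1", generate_cohort(small_config(seed = 1)))
  v1 <- generate_validation_cohort(small_config(seed = 1), co$truth)
  expect_equal(nrow(v1$metadata), 2 * 5)
  expect_equal(as.integer(table(v1$metadata$tumor_type)[co$config$tumor_types]),
               rep(2L, 5L))
  expect_length(intersect(v1$metadata$sample_id, co$metadata$sample_id), 0)
  expect_setequal(unique(v1$ffpe$antibody_id), co$truth$templates$antibody_id)
  # seed change: same metadata skeleton, different intensities
  v2 <- generate_validation_cohort(small_config(seed = 2),
                                   generate_cohort(small_config(seed = 2))$truth)
  expect_identical(v1$metadata$sample_id, v2$metadata$sample_id)
  expect_identical(v1$metadata$tumor_type, v2$metadata$tumor_type)
  expect_false(identical(v1$ffpe$intensities, v2$ffpe$intensities))
  # panel mismatch is an error
  cfg_mismatch <- cohort_config(n_per_type = 3L, n_antibodies = 10L,
                                n_validation_per_type = 2L)
  expect_error(generate_validation_cohort(cfg_mismatch, co$truth),
               "panel mismatch")
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_per_type = 1), "n_per_type")
  expect_error(cohort_config(trace_length = 4), "trace_length")
  expect_error(cohort_config(mw_range = c(100, 10)), "mw_range")
  expect_error(cohort_config(ffpe_attenuation_range = c(0, 0.5)), "attenuation")
  expect_error(cohort_config(fraction_concordant = 1.2), "fraction_concordant")
})
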