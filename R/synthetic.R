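#' Configuration for a synthetic DigiWest cohort
#'
#' Bundles every tunable of the cohort generator: the paired design (five
#' tumor types, five patients each, fresh-frozen and FFPE aliquots of the
#' same tumors), the trace geometry (96 strips over a decreasing
#' molecular-weight axis), the latent log2 abundance model, and the FFPE
#' degradation model (multiplicative signal attenuation plus extra
#' measurement noise, which together depress both intensities and detection
#' frequency relative to fresh-frozen material).
#'
#' @param n_per_type patients per tumor type in the paired cohort.
#' @param tumor_types tumor type labels.
#' @param n_antibodies size of the simulated antibody panel.
#' @param fraction_concordant fraction of antibodies whose FFPE signal tracks
#'   the fresh-frozen latent abundance; the rest are redrawn independently
#'   (epitope destroyed by fixation).
#' @param trace_length strips per trace.
#' @param mw_range (min, max) kDa of the calibrated axis.
#' @param peak_width Gaussian peak sd in strips.
#' @param baseline_level additive trace baseline, RFU.
#' @param noise_sd i.i.d. trace noise sd, RFU.
#' @param detection_floor minimum background-subtracted peak area counted as
#'   detected, RFU * strips.
#' @param hnsc_crossreaction add the 47-53 kDa secondary-antibody
#'   cross-reaction band to every head-and-neck squamous (HNSC) sample,
#'   stronger in fresh-frozen than FFPE material.
#' @param seed global integer seed; all randomness derives from it through
#'   stable per-(sample, antibody) substreams.
#' @param base_log2_mean,base_log2_sd per-antibody baseline log2 amplitude.
#' @param tau sd of the per-sample random effect (log2).
#' @param omega sd of the per-(sample, antibody) residual (log2).
#' @param ffpe_noise_sd extra log2 noise on concordant FFPE abundances.
#' @param ffpe_attenuation_range uniform range of the per-antibody FFPE
#'   multiplicative attenuation, in (0, 1].
#' @param marker_prob probability an antibody carries a tumor-type effect.
#' @param marker_effect_mean,marker_effect_sd log2 effect size of markers.
#' @param shift_prob probability an antibody's band sits > 20% away from its
#'   expected molecular weight.
#' @param extra_peak_prob probability of a secondary band.
#' @param n_validation_per_type patients per type in the validation cohort.
#' @return validated list of class `dw_config`.
#' @export
cohort_config <- function(n_per_type = 5L,
                          tumor_types = c("HNSC", "LUSC", "LUAD", "COAD", "PAAD"),
                          n_antibodies = 300L,
                          fraction_concordant = 1 / 3,
                          trace_length = 96L,
                          mw_range = c(10, 250),
                          peak_width = 2,
                          baseline_level = 30,
                          noise_sd = 12,
                          detection_floor = 400,
                          hnsc_crossreaction = TRUE,
                          seed = 1L,
                          base_log2_mean = 9,
                          base_log2_sd = 1.4,
                          tau = 0.75,
                          omega = 0.8,
                          ffpe_noise_sd = 0.45,
                          ffpe_attenuation_range = c(0.25, 0.8),
                          marker_prob = 0.4,
                          marker_effect_mean = 2.5,
                          marker_effect_sd = 0.5,
                          shift_prob = 0.05,
                          extra_peak_prob = 0.15,
                          n_validation_per_type = 5L) {
  cfg <- list(n_per_type = as.integer(n_per_type), tumor_types = tumor_types,
              n_antibodies = as.integer(n_antibodies),
              fraction_concordant = fraction_concordant,
              trace_length = as.integer(trace_length), mw_range = mw_range,
              peak_width = peak_width, baseline_level = baseline_level,
              noise_sd = noise_sd, detection_floor = detection_floor,
              hnsc_crossreaction = isTRUE(hnsc_crossreaction),
              seed = as.integer(seed),
              base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
              tau = tau, omega = omega, ffpe_noise_sd = ffpe_noise_sd,
              ffpe_attenuation_range = ffpe_attenuation_range,
              marker_prob = marker_prob,
              marker_effect_mean = marker_effect_mean,
              marker_effect_sd = marker_effect_sd,
              shift_prob = shift_prob, extra_peak_prob = extra_peak_prob,
              n_validation_per_type = as.integer(n_validation_per_type))
  validate_config(cfg)
  class(cfg) <- "dw_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_per_type < 2L) stopf("n_per_type must be >= 2")
  if (cfg$trace_length < 8L) stopf("trace_length must be >= 8")
  if (length(cfg$tumor_types) < 2L) stopf("need at least two tumor types")
  if (cfg$mw_range[1] >= cfg$mw_range[2]) stopf("mw_range must be (min, max) with min < max")
  for (nm in c("peak_width", "baseline_level", "noise_sd", "detection_floor",
               "base_log2_sd", "tau", "omega", "ffpe_noise_sd"))
    if (cfg[[nm]] < 0) stopf("'%s' must be non-negative", nm)
  if (cfg$fraction_concordant < 0 || cfg$fraction_concordant > 1)
    stopf("fraction_concordant must be in [0, 1]")
  att <- cfg$ffpe_attenuation_range
  if (att[1] <= 0 || att[2] > 1 || att[1] > att[2])
    stopf("ffpe_attenuation_range must be within (0, 1]")
  invisible(cfg)
}

#' Default molecular-weight axis for a configuration
#' @param config a `dw_config`.
#' @return decreasing kDa axis of length `trace_length`.
#' @export
config_mw_axis <- function(config) {
  calibrate_mw(config$trace_length,
               cbind(c(0, config$trace_length - 1L),
                     c(config$mw_range[2], config$mw_range[1])))
}

#' Draw the antibody panel templates for a configuration
#'
#' Templates are deterministic given the config (panel membership, expected
#' molecular weights, planted tumor-type effects, concordance flags, FFPE
#' attenuation factors, molecular-weight shifts, secondary bands); they are
#' the ground truth the selection and classification stages are scored
#' against. Exactly `round(n_antibodies * fraction_concordant)` antibodies
#' are planted concordant.
#'
#' @param config a `dw_config`.
#' @return data.frame of class `dw_templates`, one row per antibody, with a
#'   list-column `class_effect` (named log2 offsets per tumor type) and
#'   list-column `extra_peaks`.
#' @export
antibody_templates <- function(config) {
  n <- config$n_antibodies
  mw_lo <- config$mw_range[1] * 1.5
  mw_hi <- config$mw_range[2] * 0.8
  n_conc <- round(n * config$fraction_concordant)
  conc_idx <- with_seed(substream_seed(config$seed, "concordant-set"),
                        sample.int(n, n_conc))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- with_seed(substream_seed(config$seed, "template", i), {
      expected_mw <- 10^stats::runif(1, log10(mw_lo), log10(mw_hi))
      effects <- stats::setNames(rep(0, length(config$tumor_types)),
                                 config$tumor_types)
      if (stats::runif(1) < config$marker_prob) {
        canon <- c("HNSC", "LUSC", "LUAD", "COAD", "PAAD")
        if (all(canon %in% config$tumor_types)) {
          # markers follow tumor biology: lineage-shared patterns (squamous,
          # lung, adenocarcinoma) leave closely related types separable by
          # fewer antibodies than distant ones
          who <- switch(
            sample(c("single", "squamous", "lung", "adeno"), 1,
                   prob = c(0.55, 0.15, 0.15, 0.15)),
            single = sample(config$tumor_types, 1),
            squamous = c("HNSC", "LUSC"),
            lung = c("LUSC", "LUAD"),
            adeno = c("LUAD", "COAD", "PAAD"))
        } else {
          who <- sample(config$tumor_types, sample(1:2, 1))
        }
        eff <- stats::rnorm(1, config$marker_effect_mean,
                            config$marker_effect_sd)
        effects[who] <- eff
      }
      shift_factor <- 1
      if (stats::runif(1) < config$shift_prob) {
        u <- stats::runif(1, 0.25, 0.45)
        f_up <- 1 + u
        f_dn <- 1 - u
        shift_factor <- if (expected_mw * f_up <= config$mw_range[2]) f_up
                        else f_dn
        if (expected_mw * shift_factor < config$mw_range[1]) shift_factor <- f_up
      }
      extra <- list()
      if (stats::runif(1) < config$extra_peak_prob) {
        emw <- 10^stats::runif(1, log10(mw_lo), log10(mw_hi))
        extra <- list(c(mw = emw, rel_height = stats::runif(1, 0.3, 0.8)))
      }
      data.frame(
        antibody_id = sprintf("AB%04d", i),
        expected_mw = expected_mw,
        is_phospho = stats::runif(1) < 0.15,
        concordant = i %in% conc_idx,
        ffpe_attenuation = stats::runif(1, config$ffpe_attenuation_range[1],
                                        config$ffpe_attenuation_range[2]),
        shift_factor = shift_factor,
        base_log2 = stats::rnorm(1, config$base_log2_mean, config$base_log2_sd),
        extra_peaks = I(list(extra)),
        class_effect = I(list(effects)))
    })
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dw_templates", class(out))
  out
}

#' Generate one fluorescence trace
#'
#' Builds a 96-point trace as baseline + Gaussian-in-strip-index band(s)
#' centred at the strip nearest `expected_mw * shift_factor`, plus i.i.d.
#' Gaussian noise, clipped at zero RFU. The peak amplitude is
#' `2^abundance`; for FFPE material it is multiplied by the template's
#' attenuation factor. Secondary bands scale with the main amplitude.
#'
#' @param template one-row slice of [antibody_templates()] (or an equivalent
#'   list with the same fields).
#' @param abundance latent log2 amplitude.
#' @param preservation `"fresh_frozen"` or `"FFPE"`.
#' @param config a `dw_config`.
#' @param seed integer substream seed for the trace noise.
#' @param crossreaction optional `c(mw = , amplitude = )` additive artifact
#'   band (the HNSC secondary-antibody cross-reaction).
#' @return numeric intensity vector of length `trace_length`.
#' @export
generate_trace <- function(template, abundance, preservation, config, seed,
                           crossreaction = NULL) {
  if (!preservation %in% c("fresh_frozen", "FFPE"))
    stopf("preservation must be 'fresh_frozen' or 'FFPE', got '%s'", preservation)
  assert_number(abundance, "abundance")
  axis <- config_mw_axis(config)
  target <- template$expected_mw * template$shift_factor
  if (target < min(axis) || target > max(axis))
    stopf("antibody %s: peak center %.1f kDa outside the %g-%g kDa axis",
          template$antibody_id, target, min(axis), max(axis))
  amp <- 2^abundance
  if (preservation == "FFPE") amp <- amp * template$ffpe_attenuation

  strips <- seq_len(config$trace_length)
  gauss_at <- function(mw, a) {
    ctr <- which.min(abs(log(axis) - log(mw)))
    a * exp(-(strips - ctr)^2 / (2 * config$peak_width^2))
  }
  y <- rep(config$baseline_level, config$trace_length)
  y <- y + gauss_at(target, amp)
  extras <- if (is.list(template$extra_peaks) && length(template$extra_peaks) == 1L &&
                is.list(template$extra_peaks[[1]])) template$extra_peaks[[1]]
            else template$extra_peaks
  for (ep in extras) y <- y + gauss_at(ep[["mw"]], amp * ep[["rel_height"]])
  if (!is.null(crossreaction))
    y <- y + gauss_at(crossreaction[["mw"]], crossreaction[["amplitude"]])
  if (config$noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(config$trace_length, 0, config$noise_sd))
  pmax(0, y)
}

new_dw_traces <- function(sample_id, antibody_id, intensities, mw_axis) {
  structure(list(sample_id = sample_id, antibody_id = antibody_id,
                 intensities = intensities, mw_axis = mw_axis),
            class = "dw_traces")
}

#' @export
print.dw_traces <- function(x, ...) {
  cat(sprintf("<dw_traces> %d traces (%d samples x %d antibodies), %d strips\n",
              length(x$sample_id), length(unique(x$sample_id)),
              length(unique(x$antibody_id)), ncol(x$intensities)))
  invisible(x)
}

sample_grades <- function(n, seed, pool = c(rep("G1", 1), rep("G2", 18),
                                            rep("G2-3", 2), rep("G3", 4))) {
  # grade mix of a realistic surgical cohort; resampled when n != pool size
  with_seed(seed, {
    if (n == length(pool)) sample(pool) else sample(pool, n, replace = TRUE)
  })
}

latent_abundance_ff <- function(tpl, type, sample_effect, seed, config) {
  tpl$base_log2 + tpl$class_effect[[1]][[type]] + sample_effect +
    with_seed(seed, stats::rnorm(1, 0, config$omega))
}

#' Generate a paired fresh-frozen / FFPE cohort
#'
#' Produces the paired design the analysis assumes: `n_per_type` patients per
#' tumor type, each measured as a fresh-frozen and an FFPE aliquot over the
#' same antibody panel. Concordant antibodies share the per-sample latent
#' abundance across preservation (FFPE attenuated, plus extra FFPE noise);
#' non-concordant antibodies draw independent FFPE abundances with no
#' tumor-type structure. With the cross-reaction enabled, every HNSC sample
#' additionally carries an artifact band at a uniform random position in
#' 47-53 kDa, stronger in fresh-frozen material.
#'
#' @param config a `dw_config`.
#' @return list of class `dw_cohort`: `ff` and `ffpe` (`dw_traces`),
#'   `metadata` (per-sample data.frame), `truth` (ground truth incl. the
#'   antibody templates), `config`.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  templates <- antibody_templates(config)
  n_samples <- config$n_per_type * length(config$tumor_types)
  pair_id <- sprintf("P%02d", seq_len(n_samples))
  type <- rep(config$tumor_types, each = config$n_per_type)
  grade <- sample_grades(n_samples, substream_seed(config$seed, "grades"))
  tcc <- with_seed(substream_seed(config$seed, "tcc"), {
    ff <- pmin(95, pmax(30, round(stats::rnorm(n_samples, 70, 12))))
    fp <- pmin(95, pmax(40, round(stats::rnorm(n_samples, 68, 12))))
    list(ff = ff, ffpe = fp)
  })
  metadata <- rbind(
    data.frame(sample_id = paste0(pair_id, "_FF"), tumor_type = type,
               preservation = "fresh_frozen", grade = grade,
               tumor_cell_content = tcc$ff, pair_id = pair_id),
    data.frame(sample_id = paste0(pair_id, "_FFPE"), tumor_type = type,
               preservation = "FFPE", grade = grade,
               tumor_cell_content = tcc$ffpe, pair_id = pair_id))

  mats <- build_trace_block(templates, pair_id, type, config,
                            cohort_tag = "paired")
  truth <- list(
    templates = templates,
    antibodies = data.frame(
      antibody_id = templates$antibody_id,
      concordant = templates$concordant,
      shifted = templates$shift_factor != 1,
      marker = vapply(templates$class_effect, function(e) any(e != 0), TRUE)),
    samples = metadata[, c("sample_id", "tumor_type", "preservation", "grade")])
  structure(list(ff = mats$ff, ffpe = mats$ffpe, metadata = metadata,
                 truth = truth, config = config),
            class = "dw_cohort")
}

# Shared trace construction for paired (FF + FFPE) and validation (FFPE only)
# cohorts. For the paired block the FF latent abundance is drawn once per
# (patient, antibody) and reused for concordant FFPE aliquots.
build_trace_block <- function(templates, pair_id, type, config, cohort_tag,
                              ffpe_only = FALSE) {
  n_ab <- nrow(templates)
  n_s <- length(pair_id)
  axis <- config_mw_axis(config)
  ff_mat <- if (!ffpe_only)
    matrix(0, n_s * n_ab, config$trace_length) else NULL
  fp_mat <- matrix(0, n_s * n_ab, config$trace_length)
  s_ids <- character(n_s * n_ab)
  a_ids <- character(n_s * n_ab)

  sample_eff <- vapply(pair_id, function(p)
    with_seed(substream_seed(config$seed, cohort_tag, "sample-effect", p),
              stats::rnorm(1, 0, config$tau)), 1)

  row <- 0L
  for (si in seq_len(n_s)) {
    p <- pair_id[si]
    ty <- type[si]
    is_hnsc <- identical(ty, "HNSC") && config$hnsc_crossreaction
    for (ai in seq_len(n_ab)) {
      tpl <- templates[ai, ]
      ab <- tpl$antibody_id
      row <- row + 1L
      s_ids[row] <- p
      a_ids[row] <- ab
      L_ff <- latent_abundance_ff(
        tpl, ty, sample_eff[si],
        substream_seed(config$seed, cohort_tag, "latent", p, ab), config)
      if (tpl$concordant) {
        L_fp <- L_ff + with_seed(
          substream_seed(config$seed, cohort_tag, "ffpe-noise", p, ab),
          stats::rnorm(1, 0, config$ffpe_noise_sd))
      } else {
        L_fp <- tpl$base_log2 + with_seed(
          substream_seed(config$seed, cohort_tag, "ffpe-indep", p, ab),
          stats::rnorm(1, 0, sqrt(config$tau^2 + config$omega^2)))
      }
      xr <- NULL
      if (is_hnsc) {
        # the cross-reacting protein runs at one position per tumor (drawn
        # per sample, shared across antibodies); amplitudes are drawn
        # independently per preservation and antibody aliquot (separate
        # extracts and incubations), fresh-frozen stronger than FFPE
        xr_mw <- with_seed(
          substream_seed(config$seed, cohort_tag, "xreact-mw", p),
          stats::runif(1, 47, 53))
        xr_jit <- with_seed(
          substream_seed(config$seed, cohort_tag, "xreact", p, ab),
          stats::rnorm(2, 0, 0.4))
      }
      if (!ffpe_only) {
        if (is_hnsc)
          xr <- c(mw = xr_mw, amplitude = 350 * 2^xr_jit[1])
        ff_mat[row, ] <- generate_trace(
          tpl, L_ff, "fresh_frozen", config,
          substream_seed(config$seed, cohort_tag, "trace-ff", p, ab), xr)
      }
      if (is_hnsc)
        xr <- c(mw = xr_mw, amplitude = 120 * 2^xr_jit[2])
      fp_mat[row, ] <- generate_trace(
        tpl, L_fp, "FFPE", config,
        substream_seed(config$seed, cohort_tag, "trace-ffpe", p, ab), xr)
    }
  }
  list(
    ff = if (!ffpe_only)
      new_dw_traces(paste0(s_ids, "_FF"), a_ids, ff_mat, axis) else NULL,
    ffpe = new_dw_traces(
      paste0(s_ids, if (ffpe_only) "" else "_FFPE"), a_ids, fp_mat, axis))
}

#' Generate an independent FFPE validation cohort
#'
#' New patients, same antibody panel and planted tumor-type effect structure
#' as the paired cohort the ground truth came from, fresh noise, disjoint
#' sample identifiers.
#'
#' @param config a `dw_config` (its `n_validation_per_type` and
#'   `n_validation seed` fields drive the cohort).
#' @param truth ground truth from a prior [generate_cohort()] call; its
#'   antibody templates define the panel.
#' @return list of class `dw_cohort` with `ffpe`, `metadata`, `truth`,
#'   `config` (no `ff` component).
#' @export
generate_validation_cohort <- function(config, truth) {
  validate_config(config)
  templates <- truth$templates
  if (is.null(templates) || nrow(templates) != config$n_antibodies)
    stopf("antibody panel mismatch: truth has %s templates, config expects %d",
          if (is.null(templates)) "no" else nrow(templates), config$n_antibodies)
  n_samples <- config$n_validation_per_type * length(config$tumor_types)
  sid <- sprintf("V%02d", seq_len(n_samples))
  type <- rep(config$tumor_types, each = config$n_validation_per_type)
  grade <- sample_grades(n_samples,
                         substream_seed(config$seed, "validation-grades"),
                         pool = c(rep("G2", 18), rep("G3", 7)))
  tcc <- with_seed(substream_seed(config$seed, "validation-tcc"),
                   pmin(95, pmax(40, round(stats::rnorm(n_samples, 68, 12)))))
  metadata <- data.frame(sample_id = sid, tumor_type = type,
                         preservation = "FFPE", grade = grade,
                         tumor_cell_content = tcc, pair_id = NA_character_)
  mats <- build_trace_block(templates, sid, type, config,
                            cohort_tag = "validation", ffpe_only = TRUE)
  structure(list(ffpe = mats$ffpe, metadata = metadata,
                 truth = truth, config = config),
            class = "dw_cohort")
}

#' @export
print.dw_cohort <- function(x, ...) {
  cat(sprintf("<dw_cohort> %d samples, %d antibodies%s\n",
              length(unique(x$metadata$sample_id)),
              x$config$n_antibodies,
              if (is.null(x$ff)) " (FFPE validation)" else " (paired FF/FFPE)"))
  invisible(x)
}
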