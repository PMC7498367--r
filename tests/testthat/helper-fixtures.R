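# Shared fixtures, all generated in code.

# small paired cohort for fast structural tests
small_config <- function(seed = 1L, n_antibodies = 40L, ...) {
  cohort_config(n_per_type = 3L, n_antibodies = n_antibodies, seed = seed,
                n_validation_per_type = 2L, ...)
}

# cache expensive cohorts within one test run
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# quantify both preservations of a paired cohort
quantify_cohort <- function(cohort) {
  ann <- data.frame(antibody_id = cohort$truth$templates$antibody_id,
                    expected_mw = cohort$truth$templates$expected_mw)
  floor_ <- cohort$config$detection_floor
  list(ann = ann,
       ff = build_signal_matrix(cohort$ff, ann, detection_floor = floor_),
       ffpe = build_signal_matrix(cohort$ffpe, ann, detection_floor = floor_))
}

pairing_of <- function(cohort) {
  p <- unique(cohort$metadata$pair_id)
  data.frame(ff = paste0(p, "_FF"), ffpe = paste0(p, "_FFPE"))
}

# run the concordance screen the way the pipeline does (a-priori exclusion
# of the cross-reaction window, then correlation on the detected FF signals)
run_selection <- function(cohort, q = quantify_cohort(cohort)) {
  excl <- crossreaction_excludes(q$ann)
  ffl <- log2_transform(q$ff)
  keep <- !(ffl$signals$antibody_id %in% excl)
  ffk <- digiwest:::new_signal_matrix(ffl$values[keep, , drop = FALSE],
                                      ffl$signals[keep, ])
  corr <- correlate_ff_ffpe(ffk, log2_transform(q$ffpe), pairing_of(cohort))
  sel <- select_panel(corr, q$ff$signals, manual_excludes = excl)
  list(corr = corr, sel = sel, excl = excl, q = q)
}

# noise-free trace with Gaussian bumps at given strips (1-based centers)
bump_trace <- function(n = 96, centers, heights, sd = 2, baseline = 0) {
  y <- rep(baseline, n)
  for (i in seq_along(centers))
    y <- y + heights[i] * exp(-(seq_len(n) - centers[i])^2 / (2 * sd^2))
  y
}

# independent brute-force peak finder: scan strict local maxima, merge close
# apexes keeping the higher, walk to flanking minima, direct summation
oracle_peaks <- function(y, min_snr = 3, min_prominence = 0,
                         min_separation = 3) {
  n <- length(y)
  noise <- stats::mad(diff(y)) / sqrt(2)
  apexes <- integer()
  for (i in 2:(n - 1)) if (y[i] > y[i - 1] && y[i] > y[i + 1])
    apexes <- c(apexes, i)
  repeat {
    if (length(apexes) < 2) break
    d <- diff(apexes)
    j <- which(d < min_separation)
    if (!length(j)) break
    j <- j[1]
    apexes <- apexes[-(if (y[apexes[j]] >= y[apexes[j + 1]]) j + 1 else j)]
  }
  out <- NULL
  for (a in apexes) {
    l <- a; while (l > 1 && y[l - 1] <= y[l]) l <- l - 1
    r <- a; while (r < n && y[r + 1] <= y[r]) r <- r + 1
    k <- r - l + 1
    bg <- if (k == 1) y[l] else seq(y[l], y[r], length.out = k)
    area <- sum(pmax(0, y[l:r] - bg))
    prom <- y[a] - max(y[l], y[r])
    bga <- y[l] + (y[r] - y[l]) * (a - l) / max(1, r - l)
    snr <- if (noise > 0) (y[a] - bga) / noise else Inf
    if (prom >= min_prominence && snr >= min_snr)
      out <- rbind(out, c(left = l - 1, apex = a - 1, right = r - 1,
                          area = area))
  }
  if (is.null(out)) matrix(0, 0, 4) else out
}

# independent Benjamini-Hochberg step-up oracle
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}

# naive O(n^3) average-linkage agglomeration returning sorted merge heights
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric()
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# explicit pooled-sd t-test over all groups for one pair (a, b)
oracle_pooled_t <- function(x, g, a, b) {
  g <- as.character(g)
  groups <- split(x, g)
  ss <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
  df <- sum(lengths(groups) - 1L)
  sp <- sqrt(ss / df)
  na <- length(groups[[a]]); nb <- length(groups[[b]])
  tstat <- (mean(groups[[a]]) - mean(groups[[b]])) /
    (sp * sqrt(1 / na + 1 / nb))
  2 * stats::pt(-abs(tstat), df)
}

# separable five-class feature matrix: one clean marker block per class;
# noise_sd = 0 gives the separable limit (all members of a class identical)
separable_matrix <- function(n_per_class = 5, classes = c("A", "B", "C", "D", "E"),
                             n_noise = 0, seed = 1, noise_sd = 0.05) {
  set.seed(seed)
  y <- rep(classes, each = n_per_class)
  n <- length(y)
  x <- matrix(rnorm(n * (length(classes) + n_noise)) * noise_sd, n)
  for (k in seq_along(classes)) x[y == classes[k], k] <- x[y == classes[k], k] + 3
  rownames(x) <- sprintf("S%02d", seq_len(n))
  colnames(x) <- sprintf("F%02d", seq_len(ncol(x)))
  list(x = x, y = y)
}

# one full study replicate for the acceptance checks: paired cohort,
# quantification, a-priori exclusion, concordance screen, panel matrices,
# final FFPE model and validation-cohort features
study_replicate <- function(seed, svm_seed = seed) {
  cfg <- cohort_config(seed = seed)
  co <- generate_cohort(cfg)
  q <- quantify_cohort(co)
  run <- run_selection(co, q)
  tr <- co$truth$antibodies
  conc <- setdiff(tr$antibody_id[tr$concordant], run$excl)
  sig <- unique(run$corr$antibody_id[run$corr$significant])
  ffl <- log2_transform(q$ff)
  fpl <- log2_transform(q$ffpe)
  panel_ff <- intersect(run$sel$panel$signal_id, rownames(ffl$values))
  panel_fp <- intersect(run$sel$panel$signal_id, rownames(fpl$values))
  x_ff <- t(ffl$values[panel_ff, , drop = FALSE])
  x_fp <- t(fpl$values[panel_fp, , drop = FALSE])
  y_ff <- co$metadata$tumor_type[match(rownames(x_ff), co$metadata$sample_id)]
  y_fp <- co$metadata$tumor_type[match(rownames(x_fp), co$metadata$sample_id)]
  vc <- generate_validation_cohort(cfg, co$truth)
  vm <- log2_transform(build_signal_matrix(vc$ffpe, q$ann,
                                           detection_floor = cfg$detection_floor))
  xv <- matrix(NA_real_, ncol(vm$values), ncol(x_fp),
               dimnames = list(colnames(vm$values), colnames(x_fp)))
  have <- intersect(colnames(x_fp), rownames(vm$values))
  xv[, have] <- t(vm$values[have, , drop = FALSE])
  yv <- vc$metadata$tumor_type[match(rownames(xv), vc$metadata$sample_id)]
  list(seed = seed,
       sensitivity = mean(conc %in% sig),
       fdp = if (length(sig)) mean(!(sig %in% conc)) else 0,
       x_ff = x_ff, y_ff = y_ff, x_fp = x_fp, y_fp = y_fp,
       xv = xv, yv = yv, v_metadata = vc$metadata)
}

study_replicates <- function(seeds = 1:10) {
  cached(paste0("reps_", paste(range(seeds), collapse = "_")),
         lapply(seeds, study_replicate))
}
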