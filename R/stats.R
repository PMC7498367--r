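#' Log2-transform a signal matrix
#'
#' `value -> log2(max(value, floor))`; missing entries stay missing. The
#' floor keeps near-zero areas from exploding downwards and doubles as the
#' imputation value the classifier uses for undetected signals.
#'
#' @param matrix a `dw_signal_matrix` (or plain numeric matrix).
#' @param floor positive RFU floor.
#' @return object of the same type, log2 scale.
#' @export
log2_transform <- function(matrix, floor = 1) {
  assert_number(floor, "floor", lower = .Machine$double.xmin)
  if (inherits(matrix, "dw_signal_matrix")) {
    matrix$values <- log2(pmax(matrix$values, floor))
    return(matrix)
  }
  log2(pmax(matrix, floor))
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Clusters sample profiles with distance `1 - Pearson r` (pairwise-complete
#' over shared non-missing analytes) and average linkage. Leaves are ordered
#' deterministically: at every merge node the subtree with fewer leaves comes
#' first, ties broken by the lexicographically smallest leaf label.
#'
#' @param matrix a `dw_signal_matrix` or numeric matrix (rows = analytes,
#'   columns = samples), normally log2 scale.
#' @return list of class `dw_cluster_tree`: `hclust` (the merge sequence),
#'   `order` (deterministic leaf labels), `dist` (the distance matrix).
#' @export
hierarchical_cluster <- function(matrix) {
  v <- if (inherits(matrix, "dw_signal_matrix")) matrix$values else matrix
  if (ncol(v) < 2L) stopf("need at least 2 samples to cluster")
  cc <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  zero_var <- apply(v, 2, function(x) stats::sd(x, na.rm = TRUE) == 0 ||
                                        sum(!is.na(x)) < 3L)
  if (any(zero_var)) {
    warnf("zero-variance or near-empty profiles get maximal distance: %s",
          paste(colnames(v)[zero_var], collapse = ", "))
    cc[zero_var, ] <- -1
    cc[, zero_var] <- -1
  }
  diag(cc) <- 1
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, order = deterministic_leaf_order(hc),
                 dist = d), class = "dw_cluster_tree")
}

# smaller-subtree-first recursive leaf order with lexicographic tie-break
deterministic_leaf_order <- function(hc) {
  leaves_of <- function(node) {
    if (node < 0L) return(hc$labels[-node])
    m <- hc$merge[node, ]
    c(leaves_of(m[1L]), leaves_of(m[2L]))
  }
  order_of <- function(node) {
    if (node < 0L) return(hc$labels[-node])
    m <- hc$merge[node, ]
    a <- order_of(m[1L]); b <- order_of(m[2L])
    swap <- length(a) > length(b) ||
      (length(a) == length(b) && min(b) < min(a))
    if (swap) c(b, a) else c(a, b)
  }
  order_of(nrow(hc$merge))
}

#' Export a cluster tree as a Newick string
#' @param tree a `dw_cluster_tree`.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when writing to a file.
#' @export
cluster_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

tumor_type_pairs <- function(types) {
  cmb <- utils::combn(sort(unique(types)), 2L)
  data.frame(a = cmb[1L, ], b = cmb[2L, ],
             pair = paste(cmb[1L, ], cmb[2L, ], sep = " vs "))
}

#' Pairwise t-tests between tumor types for every panel analyte
#'
#' For each analyte, t-tests every pair of tumor types with a common pooled
#' standard deviation estimated across all groups (the default behaviour of
#' `pairwise.t.test`), then applies Benjamini-Hochberg correction. The
#' multiple-testing family is, by default, the analytes within each
#' tumor-type pair (one family per heatmap row); `bh_scope = "global"`
#' corrects across all pair x analyte cells at once.
#'
#' @param matrix a `dw_signal_matrix` or numeric matrix (rows = analytes,
#'   columns = samples), log2 scale.
#' @param metadata sample metadata with `sample_id`, `tumor_type`.
#' @param panel optional analyte (row) subset.
#' @param bh_scope `"per_pair"` or `"global"`.
#' @param alpha significance level on adjusted p-values.
#' @return list of class `dw_pairwise_tests`: `p_raw` and `p_bh` (pairs x
#'   analytes matrices), `significant_counts` (per pair), `alpha`.
#' @export
pairwise_ttests <- function(matrix, metadata, panel = NULL,
                            bh_scope = c("per_pair", "global"), alpha = 0.05) {
  bh_scope <- match.arg(bh_scope)
  v <- if (inherits(matrix, "dw_signal_matrix")) matrix$values else matrix
  if (!is.null(panel)) v <- v[panel, , drop = FALSE]
  grp <- metadata$tumor_type[match(colnames(v), metadata$sample_id)]
  if (anyNA(grp)) stopf("samples missing from metadata")
  pairs <- tumor_type_pairs(grp)
  p_raw <- matrix(NA_real_, nrow(pairs), nrow(v),
                  dimnames = list(pairs$pair, rownames(v)))
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    ok <- !is.na(x)
    # groups with < 2 non-missing values cannot contribute to the pooled sd
    # (a single observation has no within-group variance) and are dropped
    cnt <- table(factor(grp[ok], unique(grp)))
    ok <- ok & grp %in% names(cnt)[cnt >= 2L]
    if (sum(ok) == 0L) next
    g <- factor(grp[ok])
    tab <- table(g)
    if (length(tab) < 2L) next
    pt <- suppressWarnings(
      stats::pairwise.t.test(x[ok], g, p.adjust.method = "none",
                             pool.sd = TRUE))
    for (j in seq_len(nrow(pairs))) {
      a <- pairs$a[j]; b <- pairs$b[j]
      if (!(a %in% levels(g)) || !(b %in% levels(g))) next
      if (tab[a] < 2L || tab[b] < 2L) next
      pv <- pt$p.value
      val <- if (b %in% rownames(pv) && a %in% colnames(pv)) pv[b, a]
             else if (a %in% rownames(pv) && b %in% colnames(pv)) pv[a, b]
             else NA_real_
      p_raw[j, i] <- val
    }
  }
  p_bh <- p_raw
  if (bh_scope == "per_pair") {
    for (j in seq_len(nrow(p_raw))) p_bh[j, ] <- bh_adjust(p_raw[j, ])
  } else {
    p_bh[] <- bh_adjust(as.vector(p_raw))
  }
  structure(list(
    p_raw = p_raw, p_bh = p_bh,
    significant_counts = rowSums(p_bh < alpha, na.rm = TRUE),
    alpha = alpha), class = "dw_pairwise_tests")
}

#' @export
print.dw_pairwise_tests <- function(x, ...) {
  cat(sprintf("<dw_pairwise_tests> %d pairs x %d analytes, alpha = %g\n",
              nrow(x$p_bh), ncol(x$p_bh), x$alpha))
  print(x$significant_counts)
  invisible(x)
}

#' Count significant analytes per tumor-type pair across preservations
#'
#' Given pairwise test tables for fresh-frozen and FFPE data over the same
#' analyte panel, counts the analytes significant in each and in both.
#'
#' @param ff,ffpe `dw_pairwise_tests` objects over identical panels.
#' @return data.frame: `pair`, `ff`, `ffpe`, `overlap`.
#' @export
count_significant <- function(ff, ffpe) {
  if (!identical(dimnames(ff$p_bh), dimnames(ffpe$p_bh)))
    stopf("mismatched panels or tumor-type pairs between the two tables")
  sig_ff <- !is.na(ff$p_bh) & ff$p_bh < ff$alpha
  sig_fp <- !is.na(ffpe$p_bh) & ffpe$p_bh < ffpe$alpha
  data.frame(pair = rownames(ff$p_bh),
             ff = rowSums(sig_ff),
             ffpe = rowSums(sig_fp),
             overlap = rowSums(sig_ff & sig_fp),
             row.names = NULL)
}
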