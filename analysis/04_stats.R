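#!/usr/bin/env Rscript
# Descriptive statistics on the selected panel: average-linkage clustering
# of samples on Pearson-correlation distance, pairwise pooled-sd t-tests
# between tumor types per antibody with per-pair Benjamini-Hochberg
# correction, and the fresh-frozen vs FFPE significant-count comparison.

library(digiwest)

out <- "results"
ff <- log2_transform(read_signal_matrix(file.path(out, "signals_ff.tsv")))
fp <- log2_transform(read_signal_matrix(file.path(out, "signals_ffpe.tsv")))
md <- read_sample_metadata(file.path(out, "metadata.tsv"))
sel <- jsonlite::fromJSON(file.path(out, "selection.json"))
panel <- sel$panel$signal_id

for (nm in c("ff", "ffpe")) {
  m <- if (nm == "ff") ff else fp
  rows <- intersect(panel, rownames(m$values))
  tree <- hierarchical_cluster(m$values[rows, , drop = FALSE])
  cluster_newick(tree, file.path(out, sprintf("cluster_%s.nwk", nm)))
  cat(sprintf("%s: clustered %d samples on %d panel signals\n",
              nm, ncol(m$values), length(rows)))
}

tt_ff <- pairwise_ttests(ff, md, panel = intersect(panel, rownames(ff$values)))
tt_fp <- pairwise_ttests(fp, md, panel = intersect(panel, rownames(fp$values)))
write.table(data.frame(pair = rownames(tt_ff$p_bh), tt_ff$p_bh,
                       check.names = FALSE),
            file.path(out, "pairwise_tests_ff.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(pair = rownames(tt_fp$p_bh), tt_fp$p_bh,
                       check.names = FALSE),
            file.path(out, "pairwise_tests_ffpe.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

counts <- count_significant(tt_ff, tt_fp)
write.table(counts, file.path(out, "significant_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("antibodies significant per tumor-type pair (p-BH < 0.05):\n")
print(counts)
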