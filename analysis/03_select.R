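#!/usr/bin/env Rscript
# Antibody selection: a-priori exclusion of the 47-53 kDa cross-reaction
# window, detection filter, per-signal Pearson correlation between log2
# fresh-frozen and FFPE signals with Benjamini-Hochberg correction,
# best-signal retention and shift filtering. Writes the selection report
# and the volcano-plot table (r vs -log10 p-BH).

library(digiwest)

out <- "results"
ff <- log2_transform(read_signal_matrix(file.path(out, "signals_ff.tsv")))
fp <- log2_transform(read_signal_matrix(file.path(out, "signals_ffpe.tsv")))
md <- read_sample_metadata(file.path(out, "metadata.tsv"))
panel <- read.delim(file.path(out, "antibody_panel.tsv"))

excl <- crossreaction_excludes(panel)
cat(sprintf("a-priori cross-reaction exclusions: %d antibodies\n", length(excl)))

ffpe_md <- md[md$preservation == "FFPE" & !is.na(md$pair_id), ]
detected <- detection_filter(fp, ffpe_md)
cat(sprintf("detectable in >= 4 samples or a full tumor type: %d antibodies\n",
            length(detected)))

pairs <- unique(md$pair_id[!is.na(md$pair_id)])
pairing <- data.frame(ff = paste0(pairs, "_FF"), ffpe = paste0(pairs, "_FFPE"))
keep <- ff$signals$antibody_id %in% setdiff(detected, excl)
ffk <- digiwest:::new_signal_matrix(ff$values[keep, , drop = FALSE],
                                    ff$signals[keep, ])
corr <- correlate_ff_ffpe(ffk, fp, pairing)
sel <- select_panel(corr, ff$signals, manual_excludes = excl)
print(sel)

jsonlite::write_json(list(counts = as.list(sel$counts), panel = sel$panel,
                          dispositions = sel$dispositions),
                     file.path(out, "selection.json"), auto_unbox = TRUE)
volcano <- corr[!is.na(corr$r), c("antibody_id", "signal_id", "r", "p", "p_bh")]
volcano$neg_log10_p_bh <- -log10(pmax(volcano$p_bh, 1e-300))
write.table(volcano, file.path(out, "volcano.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
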