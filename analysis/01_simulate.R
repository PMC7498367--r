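#!/usr/bin/env Rscript
# Simulate the study cohorts: 25 paired fresh-frozen/FFPE primary tumors
# (five each of HNSC, LUSC, LUAD, COAD, PAAD) over a 300-antibody panel,
# plus an independent 25-sample FFPE validation cohort. Writes the raw
# long-format traces, sample metadata and the generator's ground truth.

library(digiwest)

seed <- as.integer(Sys.getenv("DW_SEED", "17"))
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
validation <- generate_validation_cohort(cfg, cohort$truth)

write_trace_table(cohort$ff, file.path(out, "traces_ff.tsv"))
write_trace_table(cohort$ffpe, file.path(out, "traces_ffpe.tsv"))
write_trace_table(validation$ffpe, file.path(out, "traces_validation.tsv"))
write_sample_metadata(rbind(cohort$metadata, validation$metadata),
                      file.path(out, "metadata.tsv"))
jsonlite::write_json(cohort$truth[c("antibodies", "samples")],
                     file.path(out, "ground_truth.json"), auto_unbox = TRUE)
write.table(data.frame(antibody_id = cohort$truth$templates$antibody_id,
                       expected_mw = cohort$truth$templates$expected_mw,
                       is_phospho = cohort$truth$templates$is_phospho),
            file.path(out, "antibody_panel.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("seed %d: %d paired samples + %d validation samples, %d antibodies\n",
            seed, nrow(cohort$metadata) / 2, nrow(validation$metadata),
            cfg$n_antibodies))
cat(sprintf("planted concordant antibodies: %d\n",
            sum(cohort$truth$antibodies$concordant)))
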