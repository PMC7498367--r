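#!/usr/bin/env Rscript
# Tissue-of-origin classification: repeated nested cross-validated RBF-SVM
# on the fresh-frozen and FFPE panel matrices (5-fold outer x 10 repeats,
# 4-fold inner x 5 repeats, C in 10^(0:3), sigma in 0.01*10^(-3:3)),
# lung-class merging re-score, final FFPE model, and prediction of the
# independent validation cohort with class probabilities.

library(digiwest)

seed <- as.integer(Sys.getenv("DW_SEED", "17"))
out <- "results"
ff <- log2_transform(read_signal_matrix(file.path(out, "signals_ff.tsv")))
fp <- log2_transform(read_signal_matrix(file.path(out, "signals_ffpe.tsv")))
vm <- log2_transform(read_signal_matrix(file.path(out, "signals_validation.tsv")))
md <- read_sample_metadata(file.path(out, "metadata.tsv"))
sel <- jsonlite::fromJSON(file.path(out, "selection.json"))
panel <- sel$panel$signal_id
svm <- svm_config(seed = seed)

reports <- list()
for (nm in c("ff", "ffpe")) {
  m <- if (nm == "ff") ff else fp
  x <- t(m$values[intersect(panel, rownames(m$values)), , drop = FALSE])
  y <- md$tumor_type[match(rownames(x), md$sample_id)]
  rep_ <- nested_cv(x, y, svm)
  cat(sprintf("%s nested CV: %.1f%% overall accuracy (sd %.1f%% over %d repeats)\n",
              nm, rep_$accuracy_mean, rep_$accuracy_sd, rep_$repeats))
  print(rep_)
  reports[[nm]] <- rep_
}

merged <- merge_class_report(reports$ffpe,
                             c(HNSC = "HNSC", PAAD = "PAAD", COAD = "COAD",
                               LUSC = "LUNG", LUAD = "LUNG"))
cat(sprintf("FFPE with lung classes merged: %.1f%% overall\n",
            merged$accuracy_mean))

x_fp <- t(fp$values[intersect(panel, rownames(fp$values)), , drop = FALSE])
y_fp <- md$tumor_type[match(rownames(x_fp), md$sample_id)]
model <- train_final(x_fp, y_fp, svm)
print(model)

xv <- matrix(NA_real_, ncol(vm$values), length(model$features),
             dimnames = list(colnames(vm$values), model$features))
have <- intersect(model$features, rownames(vm$values))
xv[, have] <- t(vm$values[have, , drop = FALSE])
preds <- predict_cohort(model, xv, md)
cat(sprintf("validation cohort: %.0f%% accuracy (%d of %d)\n",
            100 * mean(preds$predicted == preds$true_type),
            sum(preds$predicted == preds$true_type), nrow(preds)))
grade <- probability_by_grade(preds)
cat(sprintf("mean correct-class probability: G2 %.2f vs G3 %.2f (p = %.3f)\n",
            grade$means["G2"], grade$means["G3"], grade$p))

write.table(preds, file.path(out, "validation_predictions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(ff = list(accuracy_mean = reports$ff$accuracy_mean,
                 accuracy_sd = reports$ff$accuracy_sd,
                 matrix = as.data.frame(reports$ff$matrix)),
       ffpe = list(accuracy_mean = reports$ffpe$accuracy_mean,
                   accuracy_sd = reports$ffpe$accuracy_sd,
                   matrix = as.data.frame(reports$ffpe$matrix)),
       ffpe_merged_lung = merged$accuracy_mean,
       final_model = list(C = model$C, sigma = model$sigma),
       grade_comparison = list(means = as.list(grade$means), p = grade$p)),
  file.path(out, "classification.json"), auto_unbox = TRUE)
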