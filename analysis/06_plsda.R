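#!/usr/bin/env Rscript
# Stage 6: PLS-DA of pre vs post intervention on (a) fasting values and
# (b) excursion AUCs; jackknife weight-based feature selection on each; the
# combined model (selected fasting + selected AUC + clinical indices) with
# add-back accounting; and permutation validation of the fasting model.

library(ogttmetab)

out <- "results"
seed <- 1
panel <- read_panel(file.path(out, "normalized_panel.tsv"))
records <- read_subject_records(file.path(out, "subject_records.tsv"))
ci <- cohort_indices(records)

fit_block <- function(x, label) {
  x <- ogttmetab:::usable_features(x)
  y <- matrix_phase(x)
  model <- plsda(x, y)
  sel <- suppressWarnings(select_features(model))
  cat(sprintf("%s model: %d features, %d components, Q2 = %.3f, %d selected\n",
              label, ncol(x), model$ncomp, max(model$q2, na.rm = TRUE),
              sum(sel$selected)))
  ogttmetab:::write_tsv_comment(sel, file.path(out, paste0(label, "_selection.tsv")))
  write_report_json(list(ncomp = model$ncomp, q2 = model$q2,
                         n_imputed = model$n_imputed,
                         feature_ids = model$feature_ids,
                         lv1_weights = model$weights[, 1],
                         lv1_loadings = model$loadings[, 1]),
                    file.path(out, paste0(label, "_model.json")))
  list(x = x, y = y, model = model, sel = sel)
}

fx <- fasting_matrix(panel)
ax <- auc_matrix(panel)
fasting <- fit_block(fx, "fasting")
aucm <- fit_block(ax, "auc")

# align the AUC block to the fasting rows (fasting-only subjects lack AUCs)
common <- intersect(rownames(fasting$x), rownames(aucm$x))
clin <- clinical_matrix(ci, fasting$x)[common, , drop = FALSE]
cm <- combined_model(fasting$x[common, , drop = FALSE], fasting$sel,
                     aucm$x[common, , drop = FALSE], aucm$sel,
                     clinical_x = clin,
                     y = matrix_phase(fasting$x)[match(common, rownames(fasting$x))])
ogttmetab:::write_tsv_comment(cm$table, file.path(out, "combined_model_table.tsv"))
cat(sprintf("combined model: %d candidates, %d re-selected, %d add-backs\n",
            nrow(cm$table), sum(cm$table$selected_refit),
            sum(cm$table$added_back)))
print(table(cm$table$category[cm$table$in_final]))

pr <- performance_distributions(fasting$x, fasting$y, n_splits = 100,
                                seed = seed)
write_report_json(list(observed = pr$observed, null = pr$null, p = pr$p,
                       n_splits = pr$n_splits),
                  file.path(out, "fasting_permutation_report.json"))
cat(sprintf(paste0("permutation validation (n=100 splits): median AUROC %.3f",
                   " (null mean %.3f), median Q2 %.3f, p[auroc] = %.3f\n"),
            median(pr$observed$auroc), mean(pr$null$auroc),
            median(pr$observed$q2), pr$p$auroc))

# per-sample scores for the pre/post separation plots
sc <- data.frame(sample = rownames(fasting$x), phase = fasting$y,
                 lv1 = fasting$model$scores[, 1],
                 lv2 = if (fasting$model$ncomp >= 2)
                   fasting$model$scores[, 2] else NA_real_)
ogttmetab:::write_tsv_comment(sc, file.path(out, "fasting_scores.tsv"))
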