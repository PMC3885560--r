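#!/usr/bin/env Rscript
# Stage 8: loading-prefiltered Spearman cross-correlation of phenotype and
# metabolite variables, one panel per intervention phase. Only variables
# whose fasting-model LV1 loading deviates from the mean loading by more
# than 1 SD enter, alongside the clinical indices.

library(ogttmetab)

out <- "results"
panel <- read_panel(file.path(out, "normalized_panel.tsv"))
records <- read_subject_records(file.path(out, "subject_records.tsv"))
ci <- cohort_indices(records)

fx <- ogttmetab:::usable_features(fasting_matrix(panel))
ax <- ogttmetab:::usable_features(auc_matrix(panel))
fmod <- plsda(fx, matrix_phase(fx), fold_weights = FALSE)
amod <- plsda(ax, matrix_phase(ax), fold_weights = FALSE)

keep_f <- loading_prefilter(setNames(fmod$loadings[, 1], fmod$feature_ids))
keep_a <- loading_prefilter(setNames(amod$loadings[, 1], amod$feature_ids))
cat(sprintf("prefilter: %d fasting and %d AUC variables beyond 1 SD\n",
            length(keep_f), length(keep_a)))

clin <- clinical_matrix(ci, fx)
fsub <- fx[, keep_f, drop = FALSE]
colnames(fsub) <- paste0("fasting:", colnames(fsub))
asub <- ax[match(rownames(fx), rownames(ax)), keep_a, drop = FALSE]
colnames(asub) <- paste0("auc:", colnames(asub))
vars <- cbind(clin, fsub, asub)

tabs <- lapply(c("pre", "post"), function(ph) {
  rows <- matrix_phase(fx) == ph
  tab <- ccp(vars[rows, , drop = FALSE], phase = ph)
  ogttmetab:::write_tsv_comment(tab, file.path(out, paste0("ccp_", ph, ".tsv")))
  m <- tab[tab$var_a == "matsuda" | tab$var_b == "matsuda", ]
  cat(sprintf("%s phase: %d pairs, %d at p<=0.05; Matsuda-correlated metabolites: %d\n",
              ph, nrow(tab), sum(tab$p <= 0.05),
              sum(m$stars != "" & grepl(":", paste(m$var_a, m$var_b)))))
  tab
})

pre <- tabs[[1]]
mi <- pre[(pre$var_a == "matsuda" & pre$var_b == "fasting_insulin") |
            (pre$var_b == "matsuda" & pre$var_a == "fasting_insulin"), ]
cat(sprintf("pre-phase Matsuda vs fasting insulin: rho = %.3f (p = %.2g)\n",
            mi$rho, mi$p))
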