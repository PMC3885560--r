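#!/usr/bin/env Rscript
# Stage 4: incremental post-OGTT AUC per metabolite/subject/phase, one-sample
# tests against zero, responsiveness classes, and the pre-vs-post AUC
# comparison through the mixed model.

library(ogttmetab)

out <- "results"
panel <- read_panel(file.path(out, "normalized_panel.tsv"))

aucs <- cohort_aucs(panel)
ogttmetab:::write_tsv_comment(aucs$results, file.path(out, "excursions.tsv"))
ogttmetab:::write_tsv_comment(aucs$subject_aucs,
                              file.path(out, "subject_aucs.tsv"))

classes <- responsiveness_table(aucs$results)
ogttmetab:::write_tsv_comment(classes, file.path(out, "responsiveness.tsv"))

nz <- sum(classes$class != "neither")
cat(sprintf("metabolites with nonzero excursion in >= 1 phase: %d of %d\n",
            nz, nrow(classes)))
print(table(classes$class))

cmp <- univariate_table(panel, "auc")
ogttmetab:::write_tsv_comment(cmp, file.path(out, "auc_intervention.tsv"))
cat(sprintf("AUC intervention effects: %d raw p<0.05, %d past FDR (q<=0.05)\n",
            sum(cmp$raw_significant, na.rm = TRUE),
            sum(cmp$reject_q, na.rm = TRUE)))
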