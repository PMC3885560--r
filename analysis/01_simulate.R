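#!/usr/bin/env Rscript
# Stage 1: draw the synthetic cohort that stands in for the plasma GC-TOF
# study: 15 subjects pre-intervention (13 with OGTT series), 12 completers,
# 321 metabolites at 0/30/60/90/120 min, 20 planted intervention responders
# (half fasting-level, half excursion), plus glucose/insulin series and
# clustered chemical fingerprints.

library(ogttmetab)

seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)

prov <- c(paste("seed:", seed),
          paste("n_subjects_pre:", cfg$n_subjects_pre),
          paste("n_completers:", cfg$n_completers),
          paste("n_metabolites:", cfg$n_metabolites),
          paste("n_planted:", cfg$n_planted))
write_panel(cohort$panel, file.path(out, "panel.tsv"), provenance = prov)
write_subject_records(cohort$records, file.path(out, "subject_records.tsv"),
                      provenance = prov)
ogttmetab:::write_tsv_comment(cohort$truth,
                              file.path(out, "planted_truth.tsv"), prov)

fps <- generate_fingerprints(unique(cohort$panel$metabolite_id),
                             n_bits = 256, n_clusters = 8, seed = seed)
write_fingerprints(fps, file.path(out, "fingerprints.tsv"), provenance = prov)

df <- as.data.frame(cohort$panel)
cat(sprintf("wrote %d panel rows (%d metabolites, %.1f%% missing)\n",
            nrow(df), length(unique(df$metabolite_id)),
            100 * mean(is.na(df$intensity))))
cat(sprintf("planted responders: %d fasting, %d auc, %d both\n",
            sum(cohort$truth$channel == "fasting"),
            sum(cohort$truth$channel == "auc"),
            sum(cohort$truth$channel == "both")))
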