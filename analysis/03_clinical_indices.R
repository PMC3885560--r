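#!/usr/bin/env Rscript
# Stage 3: Matsuda, QUICKI and HOMA per subject-phase, phase summaries
# (mean +/- SEM) and the completer paired test on the Matsuda index.

library(ogttmetab)

out <- "results"
records <- read_subject_records(file.path(out, "subject_records.tsv"))
ci <- cohort_indices(records)

ogttmetab:::write_tsv_comment(ci$indices, file.path(out, "clinical_indices.tsv"))
ogttmetab:::write_tsv_comment(ci$summary,
                              file.path(out, "clinical_indices_summary.tsv"))
write_report_json(list(summary = ci$summary, matsuda_paired = ci$matsuda_paired),
                  file.path(out, "clinical_indices_summary.json"))

s <- ci$summary
fmt <- function(ix, ph) {
  r <- s[s$index == ix & s$phase == ph, ]
  sprintf("%.2f +/- %.2f", r$mean, r$sem)
}
cat("Matsuda index: pre", fmt("matsuda", "pre"), " post", fmt("matsuda", "post"), "\n")
cat("QUICKI:        pre", fmt("quicki", "pre"), " post", fmt("quicki", "post"), "\n")
cat("fasting insulin: pre", fmt("fasting_insulin", "pre"),
    " post", fmt("fasting_insulin", "post"), "\n")
cat(sprintf("paired Matsuda test (n=%d completers): t = %.2f, p = %.4f\n",
            ci$matsuda_paired$n, ci$matsuda_paired$t, ci$matsuda_paired$p))
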