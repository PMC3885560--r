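#!/usr/bin/env Rscript
# Stage 2: reporting filter (>= 50% presence), sum-intensity normalization
# to relative abundances, and per-metabolite transform-to-normality report.

library(ogttmetab)

out <- "results"
panel <- read_panel(file.path(out, "panel.tsv"))

filtered <- presence_filter(panel, min_frac = 0.5)
dropped <- attr(filtered, "dropped")
cat(sprintf("presence filter: %d of %d metabolites retained (%d dropped)\n",
            length(unique(filtered$metabolite_id)),
            length(unique(panel$metabolite_id)), nrow(dropped)))
if (nrow(dropped)) {
  ogttmetab:::write_tsv_comment(dropped, file.path(out, "dropped_metabolites.tsv"))
}

norm <- sum_normalize(filtered)
write_panel(norm, file.path(out, "normalized_panel.tsv"),
            provenance = "sum-intensity normalized, min presence 0.5")

tr <- transform_report(norm)
ogttmetab:::write_tsv_comment(tr, file.path(out, "transform_report.tsv"))
cat("transform families chosen:\n")
print(table(tr$family, useNA = "ifany"))
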