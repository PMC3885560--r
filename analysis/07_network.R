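#!/usr/bin/env Rscript
# Stage 7: OGTT time-course PLS model on intervention-adjusted data, then
# the chemical-similarity network: Tanimoto edges (> 0.7) over fingerprints,
# vertices sized by |LV1 loading| and colored by direction of change.

library(ogttmetab)

out <- "results"
panel <- read_panel(file.path(out, "normalized_panel.tsv"))
fps <- read_fingerprints(file.path(out, "fingerprints.tsv"))

tm <- ogtt_time_model(panel)
cat(sprintf("time model: %d components, Q2 = %.3f, score-time r = %.3f\n",
            tm$model$ncomp, max(tm$model$q2, na.rm = TRUE),
            cor(tm$scores$lv1, tm$scores$time_min)))
ogttmetab:::write_tsv_comment(tm$scores, file.path(out, "ogtt_time_scores.tsv"))
ogttmetab:::write_tsv_comment(
  data.frame(metabolite_id = names(tm$loadings), loading_lv1 = tm$loadings),
  file.path(out, "ogtt_time_loadings.tsv"))

net <- build_network(fps, loadings = tm$loadings, threshold = 0.7)
write_network_graphml(net, file.path(out, "chem_network.graphml"))
comp <- attr(net, "components")
ogttmetab:::write_tsv_comment(comp, file.path(out, "network_components.tsv"))
cat(sprintf("network: %d vertices, %d edges, %d connected components\n",
            igraph::vcount(net), igraph::ecount(net), nrow(comp)))
print(table(igraph::vertex_attr(net, "direction")))
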