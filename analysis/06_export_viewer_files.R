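#!/usr/bin/env Rscript
# Export the thresholded group graphs as BrainNet Viewer .node/.edge text
# files (whole brain and visual network) for surface visualization in
# external viewers. Expects results/group_matrix_*.csv. Writes under
# results/brainnet/.

suppressPackageStartupMessages(library(rsfcnet))

atlas <- aal90_atlas()
networks <- default_networks()
dir.create("results/brainnet", showWarnings = FALSE, recursive = TRUE)

read_group <- function(grp) {
  df <- read.csv(sprintf("results/group_matrix_%s.csv", grp),
                 check.names = FALSE)
  m <- as.matrix(df[, -1])
  dimnames(m) <- list(df$label, df$label)
  fc_matrix(m, space = "r")
}

vn_idx <- resolve_members(atlas, networks$VN, one_based = TRUE)
for (grp in c("control", "patient")) {
  C <- read_group(grp)
  G <- apply_threshold(C, 0.5, "binary")
  export_brainnet(atlas, G,
                  sprintf("results/brainnet/%s_whole_brain.node", grp),
                  sprintf("results/brainnet/%s_whole_brain.edge", grp))
  vn <- fc_matrix(unclass(C)[vn_idx, vn_idx],
                  labels = atlas$label[vn_idx], space = "r")
  export_brainnet(atlas, apply_threshold(vn, 0.5, "binary"),
                  sprintf("results/brainnet/%s_VN.node", grp),
                  sprintf("results/brainnet/%s_VN.edge", grp))
  cat(sprintf("%s: exported whole-brain and VN node/edge files\n", grp))
}
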