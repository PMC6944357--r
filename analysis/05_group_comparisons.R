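#!/usr/bin/env Rscript
# Between-group comparison of nodal metrics: Wilcoxon rank-sum (normal
# approximation, tie-corrected, no continuity correction) on degree,
# clustering and local efficiency, one observation per node of each group
# graph, per scope, with BH-FDR adjustment across the full metric x scope
# family. Expects results/group_matrix_*.csv. Writes
# results/nodal_comparisons.csv.

suppressPackageStartupMessages(library(rsfcnet))

atlas <- aal90_atlas()
networks <- default_networks()

read_group <- function(grp) {
  df <- read.csv(sprintf("results/group_matrix_%s.csv", grp),
                 check.names = FALSE)
  m <- as.matrix(df[, -1])
  dimnames(m) <- list(df$label, df$label)
  fc_matrix(m, space = "r")
}
group_matrices <- list(control = read_group("control"),
                       patient = read_group("patient"))

report <- analyze_group_matrices(group_matrices, atlas, networks)
write.csv(report$comparisons, "results/nodal_comparisons.csv",
          row.names = FALSE)

cat("Nodal metric comparisons (control vs patient), FDR family size",
    report$comparisons$fdr_family_size[1], ":\n")
print(report$comparisons[, c("scope", "metric", "z", "p", "p_fdr")],
      row.names = FALSE, digits = 3)
sig <- subset(report$comparisons, p_fdr < 0.05)
cat("\nFDR-significant differences:",
    if (nrow(sig)) paste(paste(sig$scope, sig$metric), collapse = ", ")
    else "none", "\n")
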