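#!/usr/bin/env Rscript
# Replication-timing side of the panel: per-replicate RT profiles from
# simulated early/late fraction counts, genome-wide score distributions and
# their bimodality, replica correlation with hierarchical clustering, and
# timing-change classification of each genotype against the wild-type-like
# reference.

library(rtcompart)

outdir <- "results/replication_timing"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

bundle <- run_experiment(experiment_config(synth = synth_config(seed = 1L)))

cat("== RT distribution shape (mean of 3 replicas per genotype) ==\n")
for (nm in bundle$genotypes) {
  bi <- bundle$bimodality[[nm]]
  cat(sprintf("  %-9s BIC improvement %8.1f -> %s (component means %.2f / %.2f)\n",
              nm, bi$score, if (bi$is_bimodal) "bimodal" else "unimodal",
              bi$means[1], bi$means[2]))
  h <- bundle$rt_distribution[[nm]]
  write.table(data.frame(mid = h$mids, density = h$density),
              file.path(outdir, paste0("rt_density_", gsub("[^A-Za-z0-9]", "_", nm), ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cat("\n== Replica correlation and clustering ==\n")
print(round(bundle$correlation, 3))
cl <- bundle$clustering
cat("2-cluster cut:\n")
print(cl$clusters)
cat("Dendrogram:", cl$newick, "\n")
writeLines(cl$newick, file.path(outdir, "dendrogram.nwk"))
write.table(round(bundle$correlation, 6), file.path(outdir, "replica_correlation.tsv"),
            sep = "\t", quote = FALSE)

cat("\n== Timing changes versus WT-like ==\n")
for (nm in bundle$genotypes) {
  ch <- bundle$rt_changes[[nm]]
  if (is.null(ch)) next
  fr <- ch$fractions
  cat(sprintf("  %-9s switches (EtoL+LtoE): %5.1f%%  changes: %5.1f%%  stable: %5.1f%%\n",
              nm, 100 * sum(fr[c("EtoL", "LtoE")]),
              100 * sum(fr[c("toward_zero", "away_from_zero")]),
              100 * fr[["stable"]]))
  write.table(data.frame(category = names(fr), fraction = as.numeric(fr)),
              file.path(outdir, paste0("rt_changes_", gsub("[^A-Za-z0-9]", "_", nm), ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cat("\nThe hemizygous-like genotype is indistinguishable from wild type on\n")
cat("every timing readout, while the knockout-like genotype loses bimodality\n")
cat("and shows a reprogrammed, compressed timing landscape.\n")
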