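#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study inputs with known ground truth.
#
# Emulates the mesh-bag field design: per-plot chemistry for two horizons and
# two N treatments, C1s NEXAFS spectra for two treatment classes (3
# replicates), FTIR spectra for the same contrast, and a replicated ITS OTU
# sequencing experiment. All downstream stages read only the files written
# here.

library(meshbagr)

seed <- 1
dir.create("results/spectra", showWarnings = FALSE, recursive = TRUE)

## chemistry: 3 plots x {humus, mineral} x {control, fertilized}
chem <- gen_chemistry_table(chemistry_scenario(seed = seed), t_years = 17 / 12)
write.csv(chem, "results/chemistry.csv", row.names = FALSE)
truth <- attr(chem, "truth")
writeLines(c(
  sprintf("t_years: %.6f", truth$t_years),
  sprintf("decay_rate_%s: %.4f", names(truth$c_final_true),
          truth$scenario$horizon_decay_rates),
  sprintf("delta13c_true: %.4f", truth$delta13c_true),
  sprintf("new_c_fraction: %.4f", truth$scenario$new_c_fraction),
  sprintf("cn_final_true: %.6f", truth$cn_final_true)
), "results/chemistry_truth.txt")
cat(sprintf("chemistry: %d samples; true delta13C %.2f permil\n",
            nrow(chem), truth$delta13c_true))

## NEXAFS: carboxyl-rich (control) vs aromatic-rich (fertilized) C1s spectra
ab <- list(
  control = c("aromatic-C" = 0.25, "phenolic-C" = 0.15, "aliphatic-C" = 0.2,
              "carboxyl-C" = 0.25, "O-alkyl-C" = 0.15),
  fertilized = c("aromatic-C" = 0.3, "phenolic-C" = 0.15, "aliphatic-C" = 0.2,
                 "carboxyl-C" = 0.2, "O-alkyl-C" = 0.15))
truth_lines <- character(0)
for (trt in names(ab)) {
  for (r in 1:3) {
    id <- sprintf("%s_rep%d", trt, r)
    g <- gen_nexafs_spectrum(nexafs_truth("C1s", ab[[trt]], noise_sd = 0.01,
                                          seed = seed + 10 * r +
                                            100 * match(trt, names(ab))))
    write_spectrum(g$spectrum, sprintf("results/spectra/nexafs_%s.txt", id))
    truth_lines <- c(truth_lines, sprintf(
      "%s: %s", id, paste(names(ab[[trt]]), ab[[trt]], sep = "=",
                          collapse = " ")))
  }
}
writeLines(truth_lines, "results/spectra/nexafs_truth.txt")
cat(sprintf("nexafs: %d spectra written (contrast: carboxyl-C %.2f vs %.2f)\n",
            6, ab$control[["carboxyl-C"]], ab$fertilized[["carboxyl-C"]]))

## FTIR: carbohydrate-rich vs aromatic/carbonyl-rich dissolved OM
weights <- list(control = c(carbohydrate = 1.0, "aliphatic-OH" = 0.4,
                            carbonyl = 0.3),
                fertilized = c(carbohydrate = 0.6, aromatic = 0.3,
                               carbonyl = 0.5))
for (trt in names(weights)) {
  for (r in 1:3) {
    s <- gen_ftir_spectrum(weights[[trt]], noise_sd = 0.005,
                           seed = seed + 10 * r + 500 * match(trt,
                                                              names(weights)))
    write_spectrum(s, sprintf("results/spectra/ftir_%s_rep%d.txt", trt, r))
  }
}
cat("ftir: 6 spectra written\n")

## OTU experiment: 6 biological samples x 3 technical replicates
ex <- gen_otu_experiment(otu_scenario(seed = seed))
write.table(data.frame(OTU = rownames(ex$table$counts), ex$table$counts,
                       check.names = FALSE),
            "results/otu_counts.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(data.frame(column = names(ex$table$replicate_groups),
                       sample = ex$table$replicate_groups),
            "results/otu_replicates.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(data.frame(OTU = names(ex$truth$guild), guild = ex$truth$guild),
            "results/otu_guilds.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
writeLines(ex$truth$filter_targets, "results/otu_filter_targets.txt")
cat(sprintf("otu: %d OTUs x %d columns; %d planted filter targets\n",
            nrow(ex$table$counts), ncol(ex$table$counts),
            length(ex$truth$filter_targets)))
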