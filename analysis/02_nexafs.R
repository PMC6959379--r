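#!/usr/bin/env Rscript
# Stage 2 — NEXAFS deconvolution.
#
# Normalizes each C1s spectrum to unit edge jump, fits the canonical
# component model (7 pi* Gaussians + 2 sigma resonances + error-function
# step) and tabulates relative pi* abundances; a covariance PCA of the
# abundance table summarizes the treatment contrast.

library(meshbagr)

files <- list.files("results/spectra", pattern = "^nexafs_.*rep\\d\\.txt$",
                    full.names = TRUE)
stopifnot(length(files) > 0)
model <- default_component_model("C1s")

rows <- lapply(files, function(f) {
  id <- sub("^nexafs_(.*)\\.txt$", "\\1", basename(f))
  s <- read_spectrum(f)
  s$meta$edge <- "C1s"
  fit <- fit_spectrum(normalize_edge_jump(s), model)
  data.frame(sample = id, t(relative_pi_abundances(fit)), rss = fit$rss,
             converged = fit$converged, check.names = FALSE)
})
ab <- do.call(rbind, rows)
write.csv(ab, "results/nexafs_abundances.csv", row.names = FALSE)
cat(sprintf("fitted %d spectra; all converged: %s\n", nrow(ab),
            all(ab$converged)))

trt <- sub("_rep\\d$", "", ab$sample)
for (comp in c("carboxyl-C", "aromatic-C")) {
  m <- tapply(ab[[comp]], trt, mean)
  cat(sprintf("%s mean relative abundance: control %.3f, fertilized %.3f\n",
              comp, m[["control"]], m[["fertilized"]]))
}

pi_cols <- model$label[model$kind == "gaussian_pi"]
X <- as.matrix(ab[, intersect(pi_cols, names(ab))])
rownames(X) <- ab$sample
pca <- pca_fingerprint(X)
write.csv(data.frame(sample = rownames(pca$scores), pca$scores),
          "results/nexafs_pca_scores.csv", row.names = FALSE)
cat(sprintf("PCA of pi* abundances: PC1 %.1f%%, PC2 %.1f%% of variance\n",
            pca$explained_variance_pct[1], pca$explained_variance_pct[2]))
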