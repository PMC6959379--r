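#' Fungal community processing of ITS OTU tables
#'
#' Post-clustering steps of the community analysis: taxonomy-assignment rank
#' from BLAST-style hit tables, rare-OTU filtering, technical-replicate
#' averaging, rarefaction to a common depth, relative-abundance and guild
#' profiles, Bray-Curtis dissimilarity and PERMANOVA.
#'
#' @name community
NULL

#' OTU count tables
#'
#' @param counts non-negative numeric matrix, OTUs in rows (rownames = OTU
#'   ids), sample columns (colnames = column ids); every column sum > 0.
#' @param replicate_groups named character vector mapping each column to its
#'   biological sample; default one group per column.
#' @param taxonomy optional named character vector, OTU -> taxon name.
#' @param guild optional named character vector, OTU -> ecological guild
#'   (`ECM`, `saprotroph`, `pathogen`, `unknown`).
#' @return an `otu_table` object.
#' @export
otu_table <- function(counts, replicate_groups = NULL, taxonomy = NULL,
                      guild = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have OTU rownames and sample colnames")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) <= 0)) stop("every sample column must have reads")
  if (is.null(replicate_groups)) {
    replicate_groups <- stats::setNames(colnames(counts), colnames(counts))
  }
  if (!setequal(names(replicate_groups), colnames(counts))) {
    stop("replicate_groups must map exactly the count columns")
  }
  structure(list(counts = counts,
                 replicate_groups = replicate_groups[colnames(counts)],
                 taxonomy = taxonomy, guild = guild),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d OTUs x %d columns (%d biological samples)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$replicate_groups))))
  invisible(x)
}

#' Taxonomic rank assignable from a BLAST hit
#'
#' Species when identity >= 96% with >= 80% query coverage; genus when
#' identity is in [94, 96) with >= 80% coverage; otherwise unassigned. The
#' coverage gate applies to both tiers.
#'
#' @param identity_pct,coverage_pct percent identity and query coverage of
#'   the top hit, both in [0, 100]; vectorized.
#' @return character vector: `"species"`, `"genus"` or `"unassigned"`.
#' @export
assign_rank <- function(identity_pct, coverage_pct) {
  if (any(identity_pct < 0 | identity_pct > 100) ||
      any(coverage_pct < 0 | coverage_pct > 100)) {
    stop("identity and coverage must be percentages in [0, 100]")
  }
  ifelse(identity_pct >= 96 & coverage_pct >= 80, "species",
         ifelse(identity_pct >= 94 & identity_pct < 96 & coverage_pct >= 80,
                "genus", "unassigned"))
}

#' Remove rare OTUs
#'
#' The removal rule combines a total-read threshold and a prevalence
#' threshold (presence counted over biological samples when replicate groups
#' are defined). Mode `"either"` (default) removes an OTU failing either
#' condition (< `min_reads` total reads OR present in fewer than
#' `min_samples` samples); mode `"both"` removes only OTUs failing both, the
#' literal conjunction. The removed OTU ids and the mode are recorded in
#' `attr(, "removal_log")`.
#'
#' @param t an [otu_table].
#' @param min_reads minimum total reads (default 10).
#' @param min_samples minimum number of samples with presence (default 2).
#' @param mode `"either"` or `"both"`.
#' @return the filtered [otu_table].
#' @export
filter_rare_otus <- function(t, min_reads = 10, min_samples = 2,
                             mode = c("either", "both")) {
  stopifnot(inherits(t, "otu_table"))
  mode <- match.arg(mode)
  total <- rowSums(t$counts)
  groups <- unique(t$replicate_groups)
  present <- sapply(groups, function(g) {
    rowSums(t$counts[, t$replicate_groups == g, drop = FALSE]) > 0
  })
  n_samples <- rowSums(as.matrix(present))
  low_reads <- total < min_reads
  low_prev <- n_samples < min_samples
  remove <- if (mode == "either") low_reads | low_prev else low_reads & low_prev
  out <- t
  out$counts <- t$counts[!remove, , drop = FALSE]
  if (!is.null(t$taxonomy)) out$taxonomy <- t$taxonomy[rownames(out$counts)]
  if (!is.null(t$guild)) out$guild <- t$guild[rownames(out$counts)]
  attr(out, "removal_log") <- list(mode = mode, min_reads = min_reads,
                                   min_samples = min_samples,
                                   removed = rownames(t$counts)[remove])
  out
}

#' Average technical replicates
#'
#' Collapses replicate columns to one column per biological sample by the
#' arithmetic mean of read counts; averaged counts may be non-integer.
#'
#' @param t an [otu_table] with replicate groups.
#' @return an [otu_table] with one column per biological sample.
#' @export
average_replicates <- function(t) {
  stopifnot(inherits(t, "otu_table"))
  groups <- unique(t$replicate_groups)
  avg <- sapply(groups, function(g) {
    cols <- which(t$replicate_groups == g)
    if (!length(cols)) stop(sprintf("replicate group '%s' is empty", g))
    rowMeans(t$counts[, cols, drop = FALSE])
  })
  avg <- matrix(avg, nrow = nrow(t$counts),
                dimnames = list(rownames(t$counts), groups))
  otu_table(avg, taxonomy = t$taxonomy, guild = t$guild)
}

#' Rarefy an OTU table to a common depth
#'
#' Each column is subsampled without replacement to exactly `depth` reads.
#' Non-integer (averaged) counts are rounded to the nearest integer first,
#' since subsampling requires whole reads. The default depth is the lower
#' median of the column sums — an achievable depth for at least half the
#' samples. Columns with fewer reads than `depth` raise an error naming the
#' sample unless `drop_shallow = TRUE`, which excludes them.
#'
#' @param t an [otu_table].
#' @param depth target reads per sample; default lower median of column sums.
#' @param seed integer seed for the subsampling.
#' @param drop_shallow drop columns below `depth` instead of erroring.
#' @return the rarefied [otu_table]; the depth and seed are recorded in
#'   `attr(, "rarefaction")`.
#' @export
rarefy <- function(t, depth = NULL, seed = 1, drop_shallow = FALSE) {
  stopifnot(inherits(t, "otu_table"))
  counts <- round(t$counts)
  sums <- colSums(counts)
  if (is.null(depth)) {
    depth <- lower_median(sums)
  }
  depth <- as.integer(depth)
  if (depth < 1) stop("rarefaction depth must be at least 1")
  shallow <- sums < depth
  if (any(shallow)) {
    if (!drop_shallow) {
      stop(sprintf("sample(s) below rarefaction depth %d: %s", depth,
                   paste(colnames(counts)[shallow], collapse = ", ")))
    }
    counts <- counts[, !shallow, drop = FALSE]
  }
  out_counts <- withr::with_seed(as.integer(seed), {
    apply(counts, 2, function(col) {
      picked <- sample(rep.int(seq_along(col), col), depth)
      tabulate(picked, nbins = length(col))
    })
  })
  dimnames(out_counts) <- dimnames(counts)
  out <- otu_table(out_counts + 0,
                   replicate_groups = t$replicate_groups[colnames(counts)],
                   taxonomy = t$taxonomy, guild = t$guild)
  attr(out, "rarefaction") <- list(depth = depth, seed = as.integer(seed),
                                   dropped = colnames(t$counts)[shallow])
  out
}

# lower median: for an even count, the smaller of the two central values
# (an achievable read depth, unlike the midpoint)
lower_median <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

#' Relative abundances per sample
#'
#' @param t an [otu_table].
#' @return matrix of per-sample relative abundances; columns sum to 1.
#' @export
relative_abundance <- function(t) {
  stopifnot(inherits(t, "otu_table"))
  sweep(t$counts, 2, colSums(t$counts), "/")
}

#' Guild profile of a community table
#'
#' Sums relative abundance per ecological guild and sample, and reports the
#' display subset of OTUs with more than `display_min_reads` total reads
#' (strict inequality).
#'
#' @param t an [otu_table] with a guild annotation covering all OTUs.
#' @param display_min_reads display threshold (default 50 reads).
#' @return list: `profile` (guild x sample relative abundance, columns sum to
#'   1), `display_otus` (ids with > `display_min_reads` reads),
#'   `display_read_fraction` (share of reads the display subset covers).
#' @export
guild_profile <- function(t, display_min_reads = 50) {
  stopifnot(inherits(t, "otu_table"))
  if (is.null(t$guild) || any(!rownames(t$counts) %in% names(t$guild))) {
    stop("guild annotation must cover every OTU")
  }
  if (any(colSums(t$counts) <= 0)) stop("zero-read sample in table")
  rel <- relative_abundance(t)
  g <- factor(t$guild[rownames(t$counts)])
  profile <- apply(rel, 2, function(col) tapply(col, g, sum, default = 0))
  profile <- matrix(profile, nrow = nlevels(g),
                    dimnames = list(levels(g), colnames(rel)))
  total <- rowSums(t$counts)
  display <- rownames(t$counts)[total > display_min_reads]
  list(profile = profile, display_otus = display,
       display_read_fraction = sum(total[display]) / sum(total))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over OTUs, computed with
#' [vegan::vegdist]; symmetric, zero diagonal, values in [0, 1].
#'
#' @param t an [otu_table] or a samples-in-columns abundance matrix.
#' @return a sample x sample `dist` object.
#' @export
bray_curtis <- function(t) {
  m <- if (inherits(t, "otu_table")) t$counts else as.matrix(t)
  if (any(m < 0)) stop("abundances must be non-negative")
  if (any(colSums(m) == 0)) {
    stop("all-zero sample: Bray-Curtis dissimilarity undefined")
  }
  vegan::vegdist(t(m), method = "bray")
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance in Anderson's
#' distance-based formulation: with `SS_total = sum(d^2) / n` over all pairs
#' and `SS_within` the analogous within-group sums, the pseudo-F is
#' `(SS_among / (g - 1)) / (SS_within / (n - g))`. Group labels are permuted
#' freely (no strata) `n_perm` times under the given seed and the p-value is
#' `(1 + #[F_perm >= F_obs]) / (1 + n_perm)`. R-squared is
#' `SS_among / SS_total`.
#'
#' @param d a `dist` object or square symmetric dissimilarity matrix.
#' @param groups factor or vector of group labels, >= 2 groups with >= 2
#'   samples each.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return `permanova_result` list: `f_statistic`, `r_squared`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  D <- as.matrix(d)
  n <- nrow(D)
  groups <- factor(groups)
  if (length(groups) != n) stop("groups must label every sample")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  D2 <- D^2
  g <- nlevels(groups)
  ss_total <- sum(D2[upper.tri(D2)]) / n

  Z0 <- stats::model.matrix(~ 0 + groups)
  sizes <- colSums(Z0)
  f_stat <- function(lab_idx) {
    Z <- Z0[lab_idx, , drop = FALSE]
    ss_within <- sum(colSums(Z * (D2 %*% Z)) / (2 * sizes))
    ss_among <- ss_total - ss_within
    c(f = (ss_among / (g - 1)) / (ss_within / (n - g)),
      r2 = ss_among / ss_total)
  }
  obs <- f_stat(seq_len(n))
  perm_f <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) f_stat(sample(n))[["f"]], numeric(1))
  })
  structure(list(f_statistic = obs[["f"]], r_squared = obs[["r2"]],
                 p_value = (1 + sum(perm_f >= obs[["f"]])) / (1 + n_perm),
                 n_permutations = n_perm, seed = as.integer(seed)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova> F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$f_statistic, x$r_squared, x$p_value, x$n_permutations))
  invisible(x)
}

#' Standard community-processing pipeline
#'
#' Applies, in order: rare-OTU filtering, technical-replicate averaging,
#' rarefaction to the (lower) median depth, and conversion to relative
#' abundance — the canonical processing order for replicated ITS OTU tables.
#'
#' @param t an [otu_table].
#' @param min_reads,min_samples,mode passed to [filter_rare_otus].
#' @param depth,seed,drop_shallow passed to [rarefy]. Unlike the strict
#'   default of [rarefy] itself, the composed pipeline drops samples below
#'   the rarefaction depth by default: rarefying to the median depth
#'   necessarily leaves up to half the samples shallow.
#' @return list: `relative` (OTU x biological-sample relative abundances),
#'   `table` (the rarefied [otu_table]), `removal_log`, `rarefaction`
#'   metadata.
#' @export
process_community <- function(t, min_reads = 10, min_samples = 2,
                              mode = "either", depth = NULL, seed = 1,
                              drop_shallow = TRUE) {
  filtered <- filter_rare_otus(t, min_reads = min_reads,
                               min_samples = min_samples, mode = mode)
  averaged <- average_replicates(filtered)
  rare <- rarefy(averaged, depth = depth, seed = seed,
                 drop_shallow = drop_shallow)
  list(relative = relative_abundance(rare), table = rare,
       removal_log = attr(filtered, "removal_log"),
       rarefaction = attr(rare, "rarefaction"))
}
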