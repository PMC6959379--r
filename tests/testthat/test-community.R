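test_that("taxonomic rank assignment applies both identity tiers and the coverage gate", {
  expect_equal(assign_rank(97.2, 85), "species")
  expect_equal(assign_rank(96, 80), "species")
  expect_equal(assign_rank(94.5, 90), "genus")
  expect_equal(assign_rank(95.9, 80), "genus")
  expect_equal(assign_rank(93.9, 95), "unassigned")
  # coverage gate applies to both tiers
  expect_equal(assign_rank(97.2, 70), "unassigned")
  expect_equal(assign_rank(94.5, 79), "unassigned")
  expect_equal(assign_rank(c(97, 94, 90), c(90, 90, 90)),
               c("species", "genus", "unassigned"))
  expect_error(assign_rank(101, 50), "\\[0, 100\\]")
})

test_that("rare-OTU filter modes implement disjunction vs conjunction", {
  counts <- rbind(
    low_both   = c(9, 0, 0),   # 9 reads, 1 sample: removed in both modes
    low_reads  = c(3, 3, 3),   # 9 reads, 3 samples: removed in "either" only
    low_prev   = c(10, 0, 0),  # 10 reads, 1 sample: removed in "either" only
    keeper     = c(20, 5, 1)
  )
  t <- toy_otu(counts)
  either <- filter_rare_otus(t, mode = "either")
  expect_setequal(rownames(either$counts), "keeper")
  expect_setequal(attr(either, "removal_log")$removed,
                  c("low_both", "low_reads", "low_prev"))
  both <- filter_rare_otus(t, mode = "both")
  expect_setequal(rownames(both$counts),
                  c("low_reads", "low_prev", "keeper"))
  # prevalence counts biological samples, not replicate columns
  t2 <- toy_otu(cbind(a1 = c(6, 5), a2 = c(6, 5), b1 = c(6, 1)),
                reps = c(a1 = "A", a2 = "A", b1 = "B"))
  rownames(t2$counts) <- c("shared", "one_sample_10")
  # OTU2 has 11 reads but its presence in B is a single read in one replicate:
  # prevalence is 2 biological samples for both OTUs, so both are kept; with
  # the B read removed, OTU2 occurs in one sample only and is dropped
  f2 <- filter_rare_otus(t2, mode = "either")
  expect_setequal(rownames(f2$counts), c("shared", "one_sample_10"))
  t2$counts["one_sample_10", "b1"] <- 0
  t2$counts["one_sample_10", "a1"] <- 6
  f3 <- filter_rare_otus(t2, mode = "either")
  expect_true("shared" %in% rownames(f3$counts))
  expect_false("one_sample_10" %in% rownames(f3$counts))
})

test_that("technical replicates average to one column per biological sample", {
  counts <- cbind(s1_r1 = c(10, 0), s1_r2 = c(20, 0), s1_r3 = c(30, 0),
                  s2_r1 = c(4, 8))
  t <- toy_otu(counts, reps = c(s1_r1 = "s1", s1_r2 = "s1", s1_r3 = "s1",
                                s2_r1 = "s2"))
  avg <- average_replicates(t)
  expect_equal(colnames(avg$counts), c("s1", "s2"))
  expect_equal(avg$counts["OTU1", "s1"], 20)       # mean of 10, 20, 30
  expect_equal(avg$counts["OTU1", "s2"], 4)        # single replicate: identity
  expect_equal(avg$counts["OTU2", "s1"], 0)        # all-zero OTU stays zero
})

test_that("rarefaction subsamples every column to exactly the target depth", {
  set.seed(99)
  counts <- matrix(rpois(60, 40), nrow = 6,
                   dimnames = list(paste0("O", 1:6), paste0("S", 1:10)))
  t <- toy_otu(counts)
  r <- rarefy(t, depth = 100, seed = 1)
  expect_true(all(colSums(r$counts) == 100))
  expect_true(all(r$counts <= counts))
  # depth equal to a column sum leaves that column unchanged
  one <- toy_otu(cbind(S1 = c(7, 3, 40)))
  expect_equal(rarefy(one, depth = 50, seed = 2)$counts, one$counts + 0)
  # strict policy errors naming the shallow sample
  expect_error(rarefy(t, depth = 10000), "S1")
  dropped <- rarefy(t, depth = max(colSums(counts)), seed = 1,
                    drop_shallow = TRUE)
  expect_lt(ncol(dropped$counts), ncol(counts))
})

test_that("rarefied proportions follow the hypergeometric expectation", {
  # one OTU at true proportion 0.25; over 200 seeds, the mean rarefied
  # proportion stays within [0.23, 0.27]
  t <- toy_otu(cbind(S1 = c(250, 750)))
  props <- vapply(1:200, function(sd) {
    rarefy(t, depth = 400, seed = sd)$counts[1, 1] / 400
  }, numeric(1))
  expect_gte(mean(props), 0.23)
  expect_lte(mean(props), 0.27)
})

test_that("default rarefaction depth is the lower median of column sums", {
  counts <- sapply(c(100, 200, 300, 400), function(d) c(d - 10, 10))
  dimnames(counts) <- list(c("a", "b"), paste0("S", 1:4))
  r <- rarefy(toy_otu(counts), seed = 1, drop_shallow = TRUE)
  expect_equal(attr(r, "rarefaction")$depth, 200L)
  expect_setequal(attr(r, "rarefaction")$dropped, "S1")
})

test_that("guild profiles sum to 1 and the display cutoff is strict", {
  counts <- cbind(S1 = c(60, 50, 30), S2 = c(10, 51, 39))
  rownames(counts) <- c("e1", "s1", "s2")
  t <- toy_otu(counts, guild = c(e1 = "ECM", s1 = "saprotroph",
                                 s2 = "saprotroph"))
  gp <- guild_profile(t, display_min_reads = 50)
  expect_equal(colSums(gp$profile), c(S1 = 1, S2 = 1), tolerance = 1e-9)
  expect_equal(gp$profile["ECM", "S1"], 60 / 140)
  # e1 (70 reads) and s1 (101) shown; s2 has 69 > 50 so shown; exactly-50 excluded
  t50 <- toy_otu(cbind(S1 = c(50, 51)), guild = c(OTU1 = "ECM",
                                                  OTU2 = "saprotroph"))
  gp50 <- guild_profile(t50)
  expect_false("OTU1" %in% gp50$display_otus)
  expect_true("OTU2" %in% gp50$display_otus)
  # single guild: profile 1.0
  t1 <- toy_otu(cbind(S1 = c(5, 5)), guild = c(OTU1 = "ECM", OTU2 = "ECM"))
  expect_equal(unname(guild_profile(t1)$profile["ECM", 1]), 1)
})

test_that("bray-curtis matches hand computation and metric axioms", {
  m <- cbind(x = c(1, 0, 1), y = c(0, 1, 1), z = c(1, 0, 1))
  rownames(m) <- paste0("O", 1:3)
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["x", "y"], 0.5)        # sum|diff| / sum(total) = 2/4
  expect_equal(d["x", "z"], 0)          # identical samples
  disjoint <- cbind(a = c(3, 0), b = c(0, 7))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)
  set.seed(12)
  counts <- null_community(n_samples = 6)
  D <- as.matrix(bray_curtis(counts))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
  # hand formula on every pair
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(D[i, j], sum(abs(counts[, i] - counts[, j])) /
                   sum(counts[, i] + counts[, j]), tolerance = 1e-12)
  }
  expect_error(bray_curtis(cbind(a = c(0, 0), b = c(1, 1))), "all-zero")
})

test_that("permanova agrees with vegan::adonis2 and brute-force enumeration", {
  set.seed(42)
  counts <- null_community(n_samples = 8, n_otus = 20, depth = 500)
  counts[, 1:4] <- counts[, 1:4] + matrix(rpois(4 * 20, 3), 20, 4)
  d <- bray_curtis(counts)
  groups <- rep(c("a", "b"), each = 4)
  res <- permanova(d, groups, n_perm = 999, seed = 7)
  ad <- vegan::adonis2(d ~ g, data = data.frame(g = groups),
                       permutations = 999)
  expect_equal(res$r_squared, ad$R2[1], tolerance = 1e-10)
  expect_equal(res$f_statistic, ad$F[1], tolerance = 1e-10)

  # brute force on 4 samples: exact p over all 4! label orderings
  d4 <- as.matrix(d)[1:4, 1:4]
  g4 <- c("a", "a", "b", "b")
  f_of <- function(idx) {
    D2 <- d4^2
    gl <- g4[order(idx)]  # relabelling; equivalently permute labels
    ss_tot <- sum(D2[upper.tri(D2)]) / 4
    ss_w <- sum(sapply(unique(gl), function(g) {
      sel <- which(gl == g)
      sum(D2[sel, sel][upper.tri(D2[sel, sel])]) / length(sel)
    }))
    ((ss_tot - ss_w) / 1) / (ss_w / 2)
  }
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  fs <- apply(perms, 1, f_of)
  f_obs <- f_of(1:4)
  exact_p <- mean(fs >= f_obs - 1e-12)
  res4 <- permanova(d4, g4, n_perm = 9999, seed = 3)
  expect_equal(res4$f_statistic, f_obs, tolerance = 1e-10)
  expect_equal(res4$p_value, exact_p, tolerance = 0.05)

  expect_error(permanova(d, c("a", rep("b", 7))), "at least 2 samples")
  expect_error(permanova(d, rep("a", 8)), "2 groups")
})

test_that("strong separation saturates permanova significance", {
  set.seed(3)
  # the two groups occupy disjoint OTU sets: between-group dissimilarity 1.
  # With 10 + 10 samples the chance a random permutation recreates the true
  # partition (the only way to tie the observed F) is ~1e-5 per draw, so the
  # p-value saturates at its floor 1/(n_perm + 1)
  counts <- matrix(0, 20, 20,
                   dimnames = list(paste0("O", 1:20), paste0("S", 1:20)))
  counts[1:10, 1:10] <- matrix(rpois(100, 50), 10, 10)
  counts[11:20, 11:20] <- matrix(rpois(100, 50), 10, 10)
  d <- bray_curtis(counts)
  res <- permanova(d, rep(c("a", "b"), each = 10), n_perm = 999, seed = 1)
  expect_equal(res$p_value, 1 / 1000)
  expect_true(res$r_squared > 0.9 && res$r_squared <= 1)
})

test_that("the composed pipeline removes exactly the planted OTUs and normalizes", {
  ex <- gen_otu_experiment(otu_scenario(n_otus = 60, rare_otu_fraction = 0.15,
                                        seed = 17))
  proc <- process_community(ex$table, seed = 4)
  expect_setequal(proc$removal_log$removed, ex$truth$filter_targets)
  expect_false(any(ex$truth$filter_targets %in% rownames(proc$relative)))
  expect_equal(unname(colSums(proc$relative)),
               rep(1, ncol(proc$relative)), tolerance = 1e-9)
  depth <- proc$rarefaction$depth
  expect_true(all(colSums(proc$table$counts) == depth))
  # recovered compositions track the generating compositions
  kept <- intersect(rownames(proc$relative), rownames(ex$truth$compositions))
  for (s in colnames(proc$relative)) {
    expect_gt(cor(proc$relative[kept, s], ex$truth$compositions[kept, s]),
              0.95)
  }
})
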