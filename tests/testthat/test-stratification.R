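block_table <- function(n_per_block = 6, n_otus = 30, seed = 1) {
  # two sample blocks with disjoint OTU support
  set.seed(seed)
  half <- n_otus / 2
  a <- cbind(matrix(rpois(n_per_block * half, 20) + 1, n_per_block),
             matrix(0, n_per_block, half))
  b <- cbind(matrix(0, n_per_block, half),
             matrix(rpois(n_per_block * half, 20) + 1, n_per_block))
  m <- rbind(a, b)
  dimnames(m) <- list(paste0("s", seq_len(2 * n_per_block)),
                      sprintf("OTU%02d", seq_len(n_otus)))
  otu_table(m)
}

test_that("steady states separate disjoint community blocks exactly", {
  tab <- block_table()
  res <- identify_steady_states(tab, prevalence_min = 0.2, k = 2,
                                permutations = 99, seed = 1)
  expect_length(unique(res$labels[1:6]), 1)
  expect_length(unique(res$labels[7:12]), 1)
  expect_false(res$labels[1] == res$labels[7])
  # clearly separated clusters: minimal permutation p and cohesive groups
  expect_equal(res$permanova_result$p_value, 1 / 100)
  expect_true(all(res$verification$frac_significant_positive > 0.9))
})

test_that("steady-state labels are invariant to sample order and scaling", {
  tab <- block_table(seed = 5)
  res1 <- identify_steady_states(tab, k = 2, permutations = 9)
  ord <- sample(nrow(tab$counts))
  shuffled <- otu_table(tab$counts[ord, ])
  res2 <- identify_steady_states(shuffled, k = 2, permutations = 9)
  expect_equal(adjusted_rand(res1$labels[rownames(shuffled$counts)],
                             res2$labels), 1)
  scaled <- tab$counts; scaled["s3", ] <- scaled["s3", ] * 7
  res3 <- identify_steady_states(otu_table(scaled), k = 2, permutations = 9)
  expect_equal(adjusted_rand(res1$labels, res3$labels), 1)
})

test_that("prevalence filter failure is reported", {
  tab <- block_table()
  expect_error(identify_steady_states(tab, prevalence_min = 1.01), "filter")
})

test_that("CAGs recover two perfectly co-varying genus blocks", {
  set.seed(8)
  n <- 40
  base1 <- rlnorm(n); base2 <- rlnorm(n)
  counts <- cbind(sapply(1:5, function(i) round(base1 * 50 * i)),
                  sapply(1:5, function(i) round(base2 * 50 * i)))
  counts <- counts + 1
  dimnames(counts) <- list(paste0("s", 1:n), sprintf("OTU%02d", 1:10))
  tax <- sprintf("k__Bacteria;p__P;c__C;o__O;f__F;g__Gen%02d", 1:10)
  res <- identify_cags(otu_table(counts, tax), min_abundance = 0,
                       min_samples = 1, k = 2)
  blocks <- substr(names(res$genus_labels), 1, 10)
  expect_equal(adjusted_rand(res$genus_labels,
                             rep(c("x", "y"), each = 5)[match(
                               names(res$genus_labels),
                               sprintf("Gen%02d", 1:10))]), 1)
  # all intra-block pairs significant, edge significance symmetric
  expect_true(all(res$q[1:5, 1:5][upper.tri(diag(5))] <= 0.05))
  expect_equal(res$q, t(res$q))
  expect_true(res$dominant[1] %in% names(res$genus_labels))
})

test_that("kendall tau-b of a perfectly concordant pair is 1", {
  tab <- random_otu_table(20, 10, n_genera = 5, seed = 2)
  counts <- tab$counts
  # make genus G1 and G2 profiles perfectly concordant
  g1 <- which(rep_len(paste0("G", 1:5), 10) == "G1")
  g2 <- which(rep_len(paste0("G", 1:5), 10) == "G2")
  counts[, g2] <- counts[, g1] * 2
  res <- identify_cags(otu_table(counts, tab$taxonomy), min_abundance = 0,
                       min_samples = 1, k = 2)
  expect_equal(res$tau["G1", "G2"], 1)
})

test_that("cag filter reports when too few genera survive", {
  tab <- random_otu_table(6, 8, n_genera = 4, seed = 9)
  expect_error(identify_cags(tab), "at least 5")
})

test_that("wiggum ratios follow the closed forms", {
  set.seed(12)
  tax <- sprintf("k__B;p__P;c__C;o__O;f__F;g__G%02d", 1:10)
  # genus G01 holds a constant share of every sample while the rest varies:
  # its over-abundance ratio must be 1 in every cluster
  counts <- matrix(rexp(60) + 0.1, 6, 10,
                   dimnames = list(paste0("s", 1:6), sprintf("OTU%02d", 1:10)))
  counts <- counts / rowSums(counts) * 100
  counts[, 1] <- 50
  counts[, -1] <- counts[, -1] / rowSums(counts[, -1]) * 50
  tab <- otu_table(counts, tax)
  states <- structure(list(labels = setNames(rep(c("C1", "C2"), 3),
                                             paste0("s", 1:6))),
                      class = "steady_state_result")
  cags <- identify_cags(tab, min_abundance = 0, min_samples = 1, k = 2)
  wig <- wiggum_overabundance(tab, states, cags)
  g1 <- wig$ratios[wig$ratios$genus == "G01", ]
  expect_true(all(abs(g1$ratio - 1) < 1e-9))

  # genus exclusive to one cluster: ratio = n_samples / n_cluster there, 0 elsewhere
  counts2 <- matrix(rpois(80, 30) + 1, 8, 10,
                    dimnames = list(paste0("s", 1:8), sprintf("OTU%02d", 1:10)))
  states2 <- structure(list(labels = setNames(rep(c("C1", "C2"), each = 4),
                                              paste0("s", 1:8))),
                       class = "steady_state_result")
  counts2[5:8, 1] <- 0                      # OTU01/G01 only in C1
  rel_even <- counts2
  rel_even[1:4, -1] <- rep(rel_even[1, -1], each = 4)  # equalize C1 shares
  tot1 <- sum(rel_even[1, ])
  rel_even[1:4, 1] <- tot1                  # same total share of G01 in each C1 sample
  tab2 <- otu_table(rel_even, tax)
  cags2 <- identify_cags(tab2, min_abundance = 0, min_samples = 1, k = 2)
  wig2 <- wiggum_overabundance(tab2, states2, cags2)
  g1 <- wig2$ratios[wig2$ratios$genus == "G01", ]
  expect_equal(g1$ratio[g1$cluster == "C2"], 0)
  expect_equal(g1$ratio[g1$cluster == "C1"], 8 / 4, tolerance = 1e-9)

  # size-weighted cluster ratios average to 1 for every genus
  sizes <- table(states2$labels)
  for (g in unique(wig2$ratios$genus)) {
    sub <- wig2$ratios[wig2$ratios$genus == g, ]
    expect_equal(sum(sub$ratio * as.numeric(sizes[sub$cluster])) / sum(sizes),
                 1, tolerance = 1e-9)
  }
})

test_that("diet groups split well-separated CA scores and relabel consistently", {
  set.seed(21)
  foods <- food_reference()
  # two diet archetypes concentrated on disjoint food halves
  t1 <- c(rep(5, 25), rep(0.05, 25)); t2 <- rev(t1)
  vals <- rbind(t(replicate(10, t1 * rlnorm(50, 0, 0.1))),
                t(replicate(10, t2 * rlnorm(50, 0, 0.1))))
  dimnames(vals) <- list(paste0("s", 1:20), foods$food)
  res <- identify_diet_groups(ffq_table(vals), m = 2)
  expect_length(unique(res$labels[1:10]), 1)
  expect_length(unique(res$labels[11:20]), 1)
  expect_false(res$labels[1] == res$labels[11])
  # permuting sample order permutes labels identically
  ord <- sample(20)
  res2 <- identify_diet_groups(ffq_table(vals[ord, ]), m = 2)
  expect_equal(adjusted_rand(res$labels[rownames(vals)[ord]], res2$labels), 1)
  # groups named by ascending axis-1 mean
  means <- tapply(res$axis1, res$labels, mean)
  expect_true(all(diff(means[order(names(means))]) > 0))
})

test_that("diet groups depend on the FFQ only through the CA axis-1 scores", {
  set.seed(22)
  foods <- food_reference()
  t1 <- c(rep(5, 25), rep(0.05, 25)); t2 <- rev(t1)
  vals <- rbind(t(replicate(8, t1 * rlnorm(50, 0, 0.1))),
                t(replicate(8, t2 * rlnorm(50, 0, 0.1))))
  dimnames(vals) <- list(paste0("s", 1:16), foods$food)
  res <- identify_diet_groups(ffq_table(vals), m = 2)
  # rescaling all consumptions (axis-preserving) must not move anyone
  res_scaled <- identify_diet_groups(ffq_table(vals * 3), m = 2)
  expect_equal(adjusted_rand(res$labels, res_scaled$labels), 1)
  expect_equal(res$axis1, res_scaled$axis1, tolerance = 1e-9)
})

test_that("pairing statistic counts mutual nearest-neighbour subject pairs", {
  # duplicated samples per subject: statistic = #subjects, minimal p
  set.seed(33)
  base <- matrix(rnorm(10 * 3), 10, 3)
  pts <- base[rep(1:10, each = 2), ] + rnorm(60, 0, 1e-4)
  ids <- paste0("s", 1:20)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(ids, ids)
  subj <- setNames(rep(paste0("P", 1:10), each = 2), ids)
  res <- pairing_statistic(distance_matrix(d, "e"), subj,
                           permutations = 199, seed = 1)
  expect_equal(res$statistic, 10)
  expect_equal(res$p_value, 1 / 200)

  # adversarial distances pairing across subjects: statistic 0
  d2 <- matrix(c(0, 9, 1, 9,
                 9, 0, 9, 1,
                 1, 9, 0, 9,
                 9, 1, 9, 0), 4, 4,
               dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  subj2 <- setNames(c("P1", "P1", "P2", "P2"), paste0("s", 1:4))
  res2 <- pairing_statistic(distance_matrix(d2, "t"), subj2,
                            permutations = 99, seed = 1)
  expect_equal(res2$statistic, 0)

  expect_error(pairing_statistic(distance_matrix(d2, "t"),
                                 setNames(c("P1", "P1", "P1", "P2"),
                                          paste0("s", 1:4)),
                                 permutations = 9), "exactly 2")
})

test_that("pairing statistic matches its permutation null on random distances", {
  set.seed(44)
  n_subj <- 30
  pts <- matrix(rnorm(2 * n_subj * 3), 2 * n_subj, 3)
  ids <- paste0("s", seq_len(2 * n_subj))
  d <- as.matrix(dist(pts)); dimnames(d) <- list(ids, ids)
  subj <- setNames(rep(paste0("P", seq_len(n_subj)), each = 2), ids)
  obs <- vapply(1:60, function(i) {
    perm <- setNames(sample(subj), ids)
    pairing_statistic(distance_matrix(d, "e"), perm,
                      permutations = 0, seed = i)$statistic
  }, numeric(1))
  # exact null mean: a random subject pair is any of the C(n,2) sample pairs
  # with equal probability, so E[stat] = n_subj * M / C(n,2) with M the
  # number of mutual nearest-neighbour pairs in the distance matrix
  dd <- d; diag(dd) <- Inf
  nn <- apply(dd, 1, which.min)
  M <- sum(vapply(seq_along(nn), function(i) nn[nn[i]] == i, logical(1))) / 2
  expected <- n_subj * M / choose(2 * n_subj, 2)
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expected), 3 * se)
})
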