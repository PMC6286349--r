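test_that("FFQ categories convert to daily frequencies", {
  raw <- matrix(c("2 times per day", "1-3 times per week",
                  "never or less than once a week", "4 or more times per day",
                  "4-6 times per week", "1 time per day"),
                nrow = 1,
                dimnames = list("s1", c("milk_full_fat", "fish", "crisps",
                                        "fruit_fresh", "vegetables_raw",
                                        "wholemeal_bread")))
  ffq <- convert_ffq_frequencies(raw)
  expect_equal(unname(ffq$values["s1", ]), c(2, 2 / 7, 0, 4, 5 / 7, 1))
  # en-dash variant of a range category is accepted
  raw2 <- raw; raw2[1, 2] <- "1–3 times per week"
  expect_equal(convert_ffq_frequencies(raw2)$values["s1", "fish"], 2 / 7)
  raw3 <- raw; raw3[1, 1] <- "sometimes"
  expect_error(convert_ffq_frequencies(raw3), "sometimes")
})

test_that("median regression recovers a noiseless coefficient", {
  set.seed(61)
  axis <- rnorm(30)
  marker <- 2 * axis
  res <- median_regression(marker, axis, age = rep(9, 30),
                           inference = "bootstrap", resamples = 49, seed = 1)
  expect_equal(res$beta, 2, tolerance = 1e-9)
  expect_equal(res$rc_sd, 2 * sd(axis), tolerance = 1e-9)
  expect_equal(res$rc_range, 2 * diff(range(axis)), tolerance = 1e-9)
  expect_equal(sign(res$rc_range), sign(res$rc_sd))
})

test_that("median regression matches a derivative-free check-loss minimiser", {
  set.seed(67)
  for (rep in 1:4) {
    n <- 15
    axis <- rnorm(n); age <- runif(n, 6, 12)
    y <- 1 + 0.8 * axis - 0.2 * age + rt(n, df = 3)
    res <- median_regression(y, axis, age, inference = "wald")
    oracle <- oracle_l1_fit(y, cbind(axis, age))
    expect_equal(res$beta, unname(oracle[2]), tolerance = 1e-4)
  }
})

test_that("median regression is equivariant under axis rescaling", {
  set.seed(71)
  axis <- rnorm(25); age <- runif(25, 6, 12)
  y <- 0.5 * axis + 0.1 * age + rnorm(25)
  r1 <- median_regression(y, axis, age, inference = "wald")
  r2 <- median_regression(y, axis * 10, age, inference = "wald")
  expect_equal(r2$beta, r1$beta / 10, tolerance = 1e-8)
  expect_equal(r2$rc_sd, r1$rc_sd, tolerance = 1e-8)
  expect_equal(r2$rc_range, r1$rc_range, tolerance = 1e-8)
})

test_that("median regression validates its inputs", {
  expect_error(median_regression(rnorm(5), rnorm(5), rnorm(5)), "10")
  expect_error(median_regression(rnorm(20), rep(1, 20), rnorm(20)),
               "constant")
  y <- rnorm(20); y[1:3] <- NA
  expect_message(median_regression(y, rnorm(20), runif(20, 6, 10),
                                   inference = "wald"), "3 incomplete")
})

test_that("fisher exact matches the printed worked examples", {
  res <- fisher_exact(matrix(c(3, 0, 0, 3), 2))
  expect_equal(res$p_two_sided, 0.1, tolerance = 1e-12)
  expect_equal(res$p_one_sided, 0.05, tolerance = 1e-12)

  flat <- fisher_exact(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$p_two_sided, 1)
  expect_equal(flat$odds_ratio, 1)

  skew <- fisher_exact(matrix(c(7, 0, 29, 34), 2))
  expect_equal(skew$p_one_sided, 0.00696351, tolerance = 1e-6)
  expect_gt(skew$odds_ratio, 1)   # Haldane-corrected despite the zero cell
  expect_true(is.finite(skew$odds_ratio))

  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("fisher exact equals exhaustive enumeration on random tables", {
  set.seed(73)
  for (rep in 1:50) {
    m <- matrix(rpois(4, 6), 2)
    if (sum(m) == 0) m[1, 1] <- 1
    res <- fisher_exact(m)
    want <- oracle_fisher(m)
    expect_equal(res$p_two_sided, want$two, tolerance = 1e-10)
    expect_equal(res$p_one_sided, want$one, tolerance = 1e-10)
  }
})

test_that("combination enrichment works at subject level with the any-sample rule", {
  samples <- paste0("s", 1:8)
  subj <- setNames(rep(paste0("P", 1:4), each = 2), samples)
  states <- setNames(c("C3", "C1", "C3", "C3", "C1", "C1", "C4", "C1"), samples)
  diets <- setNames(c("D2", "D2", "D1", "D2", "D1", "D1", "D2", "D1"), samples)
  phen <- setNames(c(TRUE, TRUE, FALSE, FALSE), paste0("P", 1:4))
  res <- combination_enrichment(states, diets, phen, subj,
                                state_set = c("C3", "C4"), diet_set = "D2")
  # P1 (s1 C3/D2), P2 (s4 C3/D2), P4 (s7 C4/D2) in; P3 out
  expect_equal(unname(res$table["yes", "in"]), 2)
  expect_equal(unname(res$table["no", "in"]), 1)
  expect_equal(unname(res$table["no", "out"]), 1)
  expect_equal(sum(res$table), 4)

  # a subject in the combination at either time point counts exactly once
  states2 <- states; states2["s2"] <- "C4"   # P1 now qualifies twice
  res2 <- combination_enrichment(states2, diets, phen, subj,
                                 state_set = c("C3", "C4"), diet_set = "D2")
  expect_identical(res2$table, res$table)
})

test_that("perfect phenotype-combination association is maximally significant", {
  samples <- paste0("s", 1:20)
  subj <- setNames(rep(paste0("P", 1:10), each = 2), samples)
  in_comb <- rep(c(TRUE, FALSE), each = 10)   # subjects P1-P5 in
  states <- setNames(ifelse(in_comb, "C3", "C1"), samples)
  diets <- setNames(ifelse(in_comb, "D2", "D1"), samples)
  phen <- setNames(rep(c(TRUE, FALSE), each = 5), paste0("P", 1:10))
  res <- combination_enrichment(states, diets, phen, subj, "C3", "D2")
  expect_equal(res$p_one_sided, 1 / choose(10, 5), tolerance = 1e-12)
})

test_that("combination enrichment is uniform under a permuted phenotype", {
  set.seed(79)
  samples <- paste0("s", 1:40)
  subj <- setNames(rep(paste0("P", 1:20), each = 2), samples)
  states <- setNames(sample(c("C1", "C3"), 40, TRUE), samples)
  diets <- setNames(sample(c("D1", "D2"), 40, TRUE), samples)
  ps <- vapply(1:200, function(i) {
    phen <- setNames(sample(c(TRUE, FALSE), 20, TRUE), paste0("P", 1:20))
    combination_enrichment(states, diets, phen, subj, "C3", "D2")$p_two_sided
  }, numeric(1))
  # Fisher p is conservative and discrete; check super-uniformity, not shape
  expect_gte(mean(ps), 0.45)
  expect_lte(mean(ps <= 0.05), 0.07)
})

test_that("group tests filter, test and adjust per feature", {
  tab <- random_otu_table(20, 12, n_genera = 6, seed = 83)
  groups <- rep(c("a", "b"), each = 10)
  counts <- tab$counts
  counts[groups == "b", 1] <- counts[groups == "b", 1] + 500  # strong shift
  res <- group_tests(otu_table(counts, tab$taxonomy), groups)
  expect_equal(res$feature[which.min(res$p_adjusted)], "OTU001")
  expect_true(all(res$p_adjusted >= res$p, na.rm = TRUE))
  expect_equal(res$test[1], "mann-whitney")

  # identical groups: nothing significant, zero-variance features flagged
  same <- rbind(counts[1:10, ], counts[1:10, ])
  rownames(same) <- paste0("s", 1:20)
  res2 <- group_tests(otu_table(same, tab$taxonomy), groups)
  expect_true(all(res2$p[!res2$zero_variance] > 0.99))

  # three groups dispatch to kruskal-wallis
  res3 <- group_tests(otu_table(counts, tab$taxonomy),
                      rep(c("a", "b", "c"), length.out = 20))
  expect_equal(res3$test[1], "kruskal-wallis")

  # paired test requires a complete pairing
  subj <- setNames(rep(paste0("P", 1:10), times = 2), paste0("s", 1:20))
  res4 <- group_tests(otu_table(counts, tab$taxonomy), groups, pairing = subj)
  expect_equal(res4$test[1], "wilcoxon-paired")
  expect_error(group_tests(otu_table(counts, tab$taxonomy), groups,
                           pairing = subj[1:5]), "pairing")
})

test_that("HFD index follows its closed forms and invariances", {
  foods <- food_reference()
  one <- matrix(0, 1, 50, dimnames = list("s1", foods$food))
  one[1, "fish"] <- 3
  expect_equal(unname(hfd_index(ffq_table(one))), 0)

  for (n in c(2, 5, 10)) {
    even <- matrix(0, 1, 50, dimnames = list("s1", foods$food))
    even[1, seq_len(n)] <- 1
    got <- hfd_index(even[, , drop = FALSE], health_values = rep(1, 50))
    expect_equal(unname(got), 1 - 1 / n, tolerance = 1e-12)
  }

  two <- matrix(c(1, 1), 1, dimnames = list("s1", c("good", "bad")))
  expect_equal(unname(hfd_index(two, health_values = c(1, 0))), 0.25)

  # scale invariance and bounds
  set.seed(89)
  vals <- matrix(rlnorm(200), 4, 50,
                 dimnames = list(paste0("s", 1:4), foods$food))
  h1 <- hfd_index(ffq_table(vals))
  h2 <- hfd_index(ffq_table(vals * 13))
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_true(all(h1 >= 0 & h1 <= 1 - 1 / 50))

  zero <- vals; zero["s2", ] <- 0
  expect_error(hfd_index(ffq_table(zero)), "s2")
})

test_that("macronutrient shares follow 4/9/4 arithmetic", {
  foods <- data.frame(food = c("pure_carb", "protein_fat", "fibrous"),
                      food_group = "test", health_value = 0.5,
                      protein_g = c(0, 50, 0), fat_g = c(0, 50, 0),
                      carb_g = c(25, 0, 100), fibre_g = c(0, 0, 10),
                      kcal = c(100, 650, 2000))
  m <- matrix(c(1, 0, 0,
                0, 1, 0,
                0, 0, 1), 3, byrow = TRUE,
              dimnames = list(c("carb_only", "pf", "fib"), foods$food))
  res <- macronutrient_summary(ffq_table(m, foods = foods))
  expect_equal(res["carb_only", "carb_pct"], 100)
  expect_equal(res["pf", "protein_pct"], 100 * 200 / 650, tolerance = 1e-12)
  expect_equal(res["pf", "fat_pct"], 100 * 450 / 650, tolerance = 1e-12)
  expect_equal(res["fib", "fibre_g_per_1000kcal"], 5)
  expect_true(all(res$protein_pct + res$fat_pct + res$carb_pct +
                    res$other_pct <= 100 + 1e-9))
})

test_that("storey q-values control and cap correctly", {
  p <- c(0.001, 0.002, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95)
  q <- qvalues(p)
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))     # monotone in p
  expect_equal(qvalues(p, method = "BH"), p.adjust(p, "BH"))
  # pi0 < 1 makes Storey no more conservative than BH
  expect_true(all(q <= p.adjust(p, "BH") + 1e-12))
  expect_error(qvalues(c(0.5, 1.2)), "0, 1")
})
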