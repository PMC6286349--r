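test_that("pseudo-F matches the projection-trace oracle over all relabelings", {
  set.seed(17)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  base <- c("a", "a", "a", "b", "b", "b")
  perms <- unique(combinat_perms(base))
  for (lab in perms[seq(1, length(perms), by = 3)]) {
    got <- permanova(distance_matrix(d, "euclidean"), lab,
                     permutations = 5, seed = 1)$statistic
    expect_equal(got, oracle_pseudo_f(d, lab), tolerance = 1e-10)
  }
})

test_that("pseudo-F is invariant to distance-matrix reordering", {
  set.seed(19)
  pts <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
  lab <- rep(c("a", "b"), each = 5)
  f1 <- permanova(distance_matrix(d, "e"), lab, permutations = 9)$statistic
  ord <- sample(10)
  f2 <- permanova(distance_matrix(d[ord, ord], "e"), lab[ord],
                  permutations = 9)$statistic
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("permanova agrees with vegan's adonis2 statistic", {
  skip_if_not_installed("vegan")
  set.seed(29)
  pts <- matrix(rnorm(30), 15, 2)
  d <- dist(pts)
  lab <- rep(c("a", "b", "c"), each = 5)
  dm <- as.matrix(d); dimnames(dm) <- list(paste0("s", 1:15), paste0("s", 1:15))
  got <- permanova(distance_matrix(dm, "e"), lab, permutations = 19)$statistic
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = lab), permutations = 19)
  expect_equal(got, ref$F[1], tolerance = 1e-10)
})

test_that("maximal separation yields the minimal permutation p", {
  d <- matrix(10, 8, 8); diag(d) <- 0
  d[1:4, 1:4] <- 0.01; d[5:8, 5:8] <- 0.01; diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  res <- permanova(distance_matrix(d, "toy"), rep(c("a", "b"), each = 4),
                   permutations = 199, seed = 3)
  # only a permutation reproducing the two clouds (or its label swap) can tie
  # the observed F, so p cannot exceed (ties + 1)/(B + 1); with 8 samples the
  # tie probability per permutation is 2/choose(8,4)
  expect_lte(res$p_value, 20 / 200)
  expect_gte(res$p_value, 1 / 200)
})

test_that("permanova validates its groups", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_error(permanova(distance_matrix(d, "t"), c("a", "a", "a", "a"), 9),
               "2 groups")
  expect_error(permanova(distance_matrix(d, "t"), c("a", "a", "a", "b"), 9),
               "size 1")
})

test_that("envfit recovers an axis-aligned variable exactly", {
  set.seed(37)
  pts <- matrix(rnorm(40), 20, 2)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
  ord <- pcoa(distance_matrix(d, "e"))
  v <- matrix(ord$coordinates[, 1], ncol = 1, dimnames = list(NULL, "ax1"))
  fit <- fit_env_vectors(ord, v, axes = 1:2, permutations = 99, seed = 1)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(abs(fit$dir.PCo1), 1, tolerance = 1e-8)
  expect_equal(fit$p, 1 / 100)
})

test_that("envfit r2 matches an independent least-squares solve", {
  set.seed(41)
  pts <- matrix(rnorm(60), 30, 2)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:30), paste0("s", 1:30))
  ord <- pcoa(distance_matrix(d, "e"))
  y <- rnorm(30)
  fit <- fit_env_vectors(ord, matrix(y, ncol = 1, dimnames = list(NULL, "y")),
                         axes = 1:2, permutations = 19, seed = 1)
  ref <- summary(lm(y ~ ord$coordinates[, 1] + ord$coordinates[, 2]))$r.squared
  expect_equal(fit$r2, ref, tolerance = 1e-10)
})

test_that("envfit r2 matches vegan::envfit", {
  skip_if_not_installed("vegan")
  set.seed(43)
  pts <- matrix(rnorm(50), 25, 2)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:25), paste0("s", 1:25))
  ord <- pcoa(distance_matrix(d, "e"))
  y <- rnorm(25)
  got <- fit_env_vectors(ord, matrix(y, ncol = 1, dimnames = list(NULL, "y")),
                         axes = 1:2, permutations = 19, seed = 1)
  ref <- vegan::envfit(ord$coordinates[, 1:2], data.frame(y = y),
                       permutations = 19)
  expect_equal(got$r2, unname(ref$vectors$r), tolerance = 1e-10)
})

test_that("constant variables are flagged with r2 = 0 and p = 1", {
  set.seed(47)
  pts <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
  ord <- pcoa(distance_matrix(d, "e"))
  v <- matrix(rep(3, 10), ncol = 1, dimnames = list(NULL, "const"))
  expect_warning(fit <- fit_env_vectors(ord, v, permutations = 9), "constant")
  expect_equal(fit$r2, 0)
  expect_equal(fit$p, 1)
})

test_that("permutational association dispatches on covariate type", {
  set.seed(53)
  pts <- matrix(rnorm(32), 16, 2)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:16), paste0("s", 1:16))
  ord <- pcoa(distance_matrix(d, "e"))
  cont <- permutational_association(ord, ord$coordinates[, 1],
                                    permutations = 99, seed = 1)
  expect_equal(cont$p_value, 1 / 100)
  expect_error(permutational_association(ord, rep("girl", 16)), "single")
  cat_res <- permutational_association(ord, rep(c("m", "f"), 8),
                                       permutations = 49, seed = 1)
  expect_s3_class(cat_res, "perm_test")
  expect_gt(cat_res$p_value, 0)
})

test_that("shuffled covariates give uniform-centred p-values", {
  set.seed(59)
  pts <- matrix(rnorm(24), 12, 2)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:12), paste0("s", 1:12))
  ord <- pcoa(distance_matrix(d, "e"))
  ps <- vapply(1:120, function(i) {
    y <- rnorm(12)
    permutational_association(ord, y, permutations = 49, seed = i)$p_value
  }, numeric(1))
  se <- sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - 0.5), 3 * se + 0.02)
})
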