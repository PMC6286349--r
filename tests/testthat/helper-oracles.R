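# Independent oracles used by the unit and acceptance tests. These share no
# code with the package implementation paths they check.

# tiny reference tree used by several worked examples: ((A:1,B:1):1,C:2);
toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

toy_table <- function(rows, otus = c("A", "B", "C")) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), otus)
  otu_table(m)
}

# Brute-force UniFrac: descendant tip sets per edge come from
# phangorn::Descendants (an independent traversal), and every pair is
# recomputed from first principles.
oracle_unifrac <- function(counts, tree, variant) {
  stopifnot(requireNamespace("phangorn", quietly = TRUE))
  tips <- tree$tip.label
  counts <- counts[, tips, drop = FALSE]
  props <- counts / rowSums(counts)
  edges <- tree$edge
  desc <- phangorn::Descendants(tree, edges[, 2], type = "tips")
  len <- tree$edge.length
  root_dist <- stats::setNames(numeric(length(tips)), tips)
  for (t in seq_along(tips)) {
    on_path <- vapply(desc, function(s) t %in% s, logical(1))
    root_dist[t] <- sum(len[on_path])
  }
  n <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0; raw <- 0; norm <- 0
    for (e in seq_along(len)) {
      tips_e <- tips[desc[[e]]]
      in_a <- sum(counts[i, tips_e]) > 0
      in_b <- sum(counts[j, tips_e]) > 0
      pa <- sum(props[i, tips_e]); pb <- sum(props[j, tips_e])
      if (in_a || in_b) den <- den + len[e]
      if (xor(in_a, in_b)) num <- num + len[e]
      raw <- raw + len[e] * abs(pa - pb)
    }
    norm <- sum(root_dist * (props[i, ] + props[j, ]))
    d[i, j] <- d[j, i] <- switch(variant,
      unweighted = if (den > 0) num / den else 0,
      weighted_raw = raw,
      weighted_normalized = if (norm > 0) raw / norm else 0)
  }
  d
}

# Exhaustive Fisher two-sided p by enumerating all tables with the observed
# margins (minimum-likelihood rule); one-sided tail in the observed
# direction.
oracle_fisher <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, function(k) stats::dhyper(k, r1, r2, c1), numeric(1))
  obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  two <- sum(probs[probs <= obs * (1 + 1e-7)])
  direction_up <- m[1, 1] * m[2, 2] >= m[1, 2] * m[2, 1]
  one <- if (direction_up) sum(probs[ks >= m[1, 1]]) else sum(probs[ks <= m[1, 1]])
  list(one = min(one, 1), two = min(two, 1))
}

# PERMANOVA pseudo-F via the projection-trace route: F = (tr(HGH)/(g-1)) /
# (tr((I-H) G (I-H))/(n-g)) with G the Gower-centred matrix and H the hat
# matrix of the group dummies — algebraically equivalent, computationally
# independent of the within-group sum formulation used by the package.
oracle_pseudo_f <- function(dmat, labels) {
  n <- nrow(dmat)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% dmat^2 %*% J
  X <- stats::model.matrix(~ factor(labels))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  g <- length(unique(labels))
  num <- sum(diag(H %*% G %*% H)) / (g - 1)
  den <- sum(diag((diag(n) - H) %*% G %*% (diag(n) - H))) / (n - g)
  num / den
}

# Derivative-free minimiser of the median check loss for the optimisation
# oracle: Nelder-Mead restarted from several points.
oracle_l1_fit <- function(y, X) {
  loss <- function(b) sum(abs(y - cbind(1, X) %*% b))
  starts <- list(rep(0, ncol(X) + 1),
                 stats::coef(stats::lm(y ~ X)),
                 stats::coef(stats::lm(y ~ X)) + 0.5)
  fits <- lapply(starts, function(s)
    stats::optim(s, loss, control = list(maxit = 5000, reltol = 1e-12)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  stats::optim(best$par, loss,
               control = list(maxit = 5000, reltol = 1e-14))$par
}

# small random OTU table with taxonomy over g genera
random_otu_table <- function(n_samples, n_otus, n_genera = 5, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_otus, 20), n_samples, n_otus,
                   dimnames = list(paste0("s", seq_len(n_samples)),
                                   sprintf("OTU%03d", seq_len(n_otus))))
  genus <- rep_len(paste0("G", seq_len(n_genera)), n_otus)
  tax <- sprintf("k__Bacteria;p__P1;c__C1;o__O1;f__F%d;g__%s",
                 rep_len(1:2, n_otus), genus)
  otu_table(counts, tax)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# all distinct arrangements of a label vector (used by the exhaustive oracle)
combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- combinat_perms(x[-i])
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out[!duplicated(vapply(out, paste, character(1), collapse = ""))]
}
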