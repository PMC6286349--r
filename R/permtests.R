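#' Permutational MANOVA (distance-based, one factor)
#'
#' Partitions the total sum of squared distances (`SS_total = sum of
#' squared pairwise distances / N`) into between- and within-group parts and
#' forms the pseudo-F ratio `(SS_between/(g-1)) / (SS_within/(N-g))`. The
#' null distribution is obtained by permuting the group labels; the p-value
#' uses the add-one convention `(#{F* >= F} + 1)/(B + 1)` and is therefore
#' never zero.
#'
#' @param d a [distance_matrix] (or `dist` / square symmetric matrix).
#' @param labels group label per sample (character or factor), aligned with
#'   the rows of `d`; every group must contain at least 2 samples.
#' @param permutations number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return a `perm_test` with `statistic_name = "pseudo-F"`.
#' @export
permanova <- function(d, labels, permutations = 999, seed = 1L) {
  mat <- as_distance_input(d)
  n <- nrow(mat)
  labels <- as.character(labels)
  if (length(labels) != n) stop_invalid("labels must align with the distance matrix")
  sizes <- table(labels)
  if (length(sizes) < 2) stop_invalid("need at least 2 groups")
  if (any(sizes < 2))
    stop_invalid("groups of size 1 are not allowed: ",
                 paste(names(sizes)[sizes < 2], collapse = ", "))
  d2 <- mat^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  g <- length(sizes)
  pseudo_f <- function(lab) {
    ss_within <- 0
    for (grp in unique(lab)) {
      idx <- which(lab == grp)
      ss_within <- ss_within +
        sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
  }
  f_obs <- pseudo_f(labels)
  set.seed(seed)
  f_perm <- replicate(permutations, pseudo_f(sample(labels)))
  new_perm_test(f_obs, permutations, perm_pvalue(f_obs, f_perm), "pseudo-F")
}

#' Fit external variables onto an ordination (vector fitting)
#'
#' For each variable, regresses the centered variable on the chosen
#' ordination axes by least squares; reports the squared multiple
#' correlation r2, the unit direction vector of the coefficients, and a
#' permutation p-value (variable values shuffled against the axes, add-one
#' convention). When two or more variables are fitted, Benjamini-Hochberg
#' adjusted q-values are added.
#'
#' @param ord an [ordination].
#' @param variables samples x variables numeric matrix or data frame,
#'   row-aligned with the ordination.
#' @param axes which axes to fit on (default `1:2`).
#' @param permutations permutation count (default 999).
#' @param seed integer seed.
#' @return data frame with one row per variable: `variable, r2, p, q` and
#'   direction cosines `dir.<axis>`.
#' @export
fit_env_vectors <- function(ord, variables, axes = 1:2,
                            permutations = 999, seed = 1L) {
  X <- ord$coordinates[, axes, drop = FALSE]
  if (any(apply(X, 2, stats::sd) == 0))
    stop_invalid("ordination axes must not be constant")
  variables <- as.matrix(variables)
  if (nrow(variables) != nrow(X))
    stop_invalid("variables must be row-aligned with the ordination samples")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  XtXinv <- solve(crossprod(Xc))
  r2_of <- function(y) {
    yc <- y - mean(y)
    tot <- sum(yc^2)
    if (tot == 0) return(list(r2 = NA_real_, beta = NULL))
    beta <- XtXinv %*% crossprod(Xc, yc)
    list(r2 = sum((Xc %*% beta)^2) / tot, beta = drop(beta))
  }
  set.seed(seed)
  rows <- lapply(seq_len(ncol(variables)), function(j) {
    y <- variables[, j]
    fit <- r2_of(y)
    if (is.na(fit$r2)) {
      warning("constant variable: ", colnames(variables)[j])
      return(c(r2 = 0, p = 1, dir = rep(NA_real_, ncol(X))))
    }
    r2_perm <- replicate(permutations, r2_of(sample(y))$r2)
    dir <- fit$beta / sqrt(sum(fit$beta^2))
    c(r2 = fit$r2, p = perm_pvalue(fit$r2, r2_perm), dir = dir)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("r2", "p", paste0("dir.", colnames(X)))
  out <- cbind(variable = colnames(variables) %||% paste0("V", seq_len(ncol(variables))),
               out)
  out$q <- if (nrow(out) >= 2) stats::p.adjust(out$p, "BH") else out$p
  rownames(out) <- NULL
  out[, c("variable", "r2", "p", "q", paste0("dir.", colnames(X)))]
}

#' Permutation association of a covariate with an ordination
#'
#' Continuous covariates are tested by vector fitting (r2 statistic) on the
#' leading axes; categorical covariates dispatch to [permanova] on the
#' ordination's source distance matrix.
#'
#' @param ord an [ordination]; for categorical covariates it must carry its
#'   source [distance_matrix] (PCoA results do).
#' @param covariate per-sample numeric vector, or character/factor labels.
#' @param n_axes leading axis count for continuous covariates (default 3).
#' @param permutations,seed permutation controls.
#' @return a `perm_test`.
#' @export
permutational_association <- function(ord, covariate, n_axes = 3,
                                      permutations = 999, seed = 1L) {
  if (is.numeric(covariate)) {
    axes <- seq_len(min(n_axes, ncol(ord$coordinates)))
    fit <- fit_env_vectors(ord, matrix(covariate, ncol = 1,
                                       dimnames = list(NULL, "covariate")),
                           axes = axes, permutations = permutations, seed = seed)
    new_perm_test(fit$r2, permutations, fit$p, "envfit r2")
  } else if (is.character(covariate) || is.factor(covariate)) {
    if (length(unique(as.character(covariate))) < 2)
      stop_invalid("categorical covariate has a single level")
    if (is.null(ord$source_distance))
      stop_invalid("ordination carries no source distance matrix; run permanova directly")
    permanova(ord$source_distance, covariate,
              permutations = permutations, seed = seed)
  } else {
    stop_invalid("covariate must be numeric or categorical, not mixed")
  }
}
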