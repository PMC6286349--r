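#' Age-adjusted median regression of a marker on an ordination axis
#'
#' Fits `marker ~ axis + age` at the median (quantile tau = 0.5,
#' minimizing the check loss), as is standard for skewed inflammatory
#' markers where outliers should not dominate. The axis coefficient is
#' reported on two interpretable scales: `rc_range` (coefficient times the
#' full span of the axis) and `rc_sd` (coefficient times one axis standard
#' deviation). Inference on the axis coefficient is by seeded xy-pair
#' bootstrap (default) or a Wald test with the `nid` sandwich standard
#' error.
#'
#' @param marker per-sample response; non-finite values are dropped (with a
#'   message) together with their covariates.
#' @param axis per-sample ordination coordinate (non-constant).
#' @param age per-sample age covariate.
#' @param inference `"bootstrap"` (default) or `"wald"`.
#' @param resamples bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return a one-row data frame of class `quantreg_row`: `parameter`,
#'   `beta`, `rc_range`, `rc_sd`, `p_value`, `n`.
#' @export
median_regression <- function(marker, axis, age,
                              inference = c("bootstrap", "wald"),
                              resamples = 2000, seed = 1L,
                              parameter = "marker") {
  inference <- match.arg(inference)
  ok <- is.finite(marker) & is.finite(axis) & is.finite(age)
  dropped <- sum(!ok)
  if (dropped) message(dropped, " incomplete cases dropped")
  marker <- marker[ok]; axis <- axis[ok]; age <- age[ok]
  n <- length(marker)
  if (n < 10) stop_invalid("fewer than 10 complete cases")
  if (stats::sd(axis) == 0) stop_invalid("axis is constant")
  # a constant age carries no information and would alias the intercept
  X <- if (stats::sd(age) == 0) cbind(intercept = 1, axis = axis)
       else cbind(intercept = 1, axis = axis, age = age)
  rq_beta <- function(Xb, yb) {
    tryCatch(unname(quantreg::rq.fit.br(Xb, yb, tau = 0.5)$coefficients[2]),
             error = function(e) NA_real_)
  }
  beta <- rq_beta(X, marker)
  if (is.na(beta)) stop_invalid("median regression fit failed")
  if (inference == "bootstrap") {
    set.seed(seed)
    boot <- vapply(seq_len(resamples), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      rq_beta(X[idx, , drop = FALSE], marker[idx])
    }, numeric(1))
    # basic bootstrap test of H0: beta = 0 via the centred resampling
    # distribution, add-one convention
    p <- (sum(abs(boot - beta) >= abs(beta), na.rm = TRUE) + 1) /
      (sum(!is.na(boot)) + 1)
  } else {
    dat <- data.frame(y = marker, axis = axis, age = age)
    fml <- if (stats::sd(age) == 0) y ~ axis else y ~ axis + age
    fit <- suppressWarnings(quantreg::rq(fml, tau = 0.5, data = dat,
                                         method = "br"))
    p <- tryCatch({
      sm <- suppressWarnings(quantreg::summary.rq(fit, se = "nid"))
      sm$coefficients["axis", ncol(sm$coefficients)]
    }, error = function(e) {
      warning("Wald inference failed (degenerate fit); p set to NA")
      NA_real_
    })
  }
  out <- data.frame(parameter = parameter, beta = beta,
                    rc_range = beta * diff(range(axis)),
                    rc_sd = beta * stats::sd(axis),
                    p_value = p, n = n, stringsAsFactors = FALSE)
  class(out) <- c("quantreg_row", class(out))
  out
}

#' Median-regression table for several markers across several axes
#'
#' Convenience wrapper mirroring the usual reporting layout: one row per
#' marker, `rc_range`/`rc_sd`/`p` columns per axis.
#'
#' @param markers samples x markers matrix or data frame.
#' @param ord an [ordination].
#' @param age per-sample ages.
#' @param axes axis indices (default 1:3).
#' @inheritParams median_regression
#' @return data frame, one row per (marker, axis).
#' @export
median_regression_table <- function(markers, ord, age, axes = 1:3,
                                    inference = c("bootstrap", "wald"),
                                    resamples = 2000, seed = 1L) {
  inference <- match.arg(inference)
  markers <- as.matrix(markers)
  coords <- ord$coordinates
  axes <- axes[axes <= ncol(coords)]
  rows <- list()
  for (j in seq_len(ncol(markers))) for (a in axes) {
    row <- median_regression(markers[, j], coords[, a], age,
                             inference = inference, resamples = resamples,
                             seed = seed + a, parameter = colnames(markers)[j])
    row$axis <- colnames(coords)[a]
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  out[, c("parameter", "axis", "beta", "rc_range", "rc_sd", "p_value", "n")]
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test. The one-sided p-value is the tail in the
#' observed direction of association; the two-sided p-value sums the
#' probabilities of all tables (with fixed margins) no more likely than the
#' observed one, with a 1e-7 relative slack for floating-point ties. The
#' odds ratio is the sample cross-product ratio, with the Haldane 0.5
#' correction applied to every cell when any cell is zero.
#'
#' @param table2x2 2x2 matrix of non-negative integer counts.
#' @return object of class `enrichment_result`: `table`, `odds_ratio`,
#'   `p_one_sided`, `p_two_sided`.
#' @export
#' @examples
#' fisher_exact(matrix(c(3, 0, 0, 3), 2))  # two-sided 0.1, one-sided 0.05
fisher_exact <- function(table2x2) {
  m <- as.matrix(table2x2)
  if (!all(dim(m) == 2)) stop_invalid("expected a 2x2 table")
  if (any(m < 0) || any(m != round(m)) || any(!is.finite(m)))
    stop_invalid("cells must be non-negative integers")
  if (sum(m) == 0) stop_invalid("table is empty")
  two <- stats::fisher.test(m)$p.value
  direction <- if (m[1, 1] * m[2, 2] >= m[1, 2] * m[2, 1]) "greater" else "less"
  one <- stats::fisher.test(m, alternative = direction)$p.value
  or <- if (any(m == 0)) {
    h <- m + 0.5
    (h[1, 1] * h[2, 2]) / (h[1, 2] * h[2, 1])
  } else {
    (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  }
  structure(list(table = m, odds_ratio = or,
                 p_one_sided = min(one, 1), p_two_sided = min(two, 1)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("odds ratio %.3g; one-sided p = %.4g; two-sided p = %.4g\n",
              x$odds_ratio, x$p_one_sided, x$p_two_sided))
  invisible(x)
}

#' Enrichment of a diet-by-microbiota combination in a phenotype
#'
#' Tests whether subjects carrying a given combination of microbiota steady
#' state and dietary group are enriched in a binary phenotype (e.g.
#' development of obesity). The unit of analysis is the subject: a subject
#' is "in the combination" if any of its samples has a state in `state_set`
#' and a diet group in `diet_set` simultaneously. The resulting 2x2 table
#' (phenotype x combination membership) is passed to [fisher_exact].
#'
#' @param states named per-sample state labels (e.g. from
#'   [identify_steady_states]).
#' @param diet_groups named per-sample diet labels.
#' @param phenotype named per-subject logical (or 0/1) vector.
#' @param subject_map named character vector sample id -> subject id.
#' @param state_set,diet_set label sets defining the combination (e.g.
#'   `c("C3", "C4")` and `"D2"`).
#' @return an `enrichment_result`; the contingency table rows are
#'   phenotype-positive/negative, columns in/out of the combination.
#' @export
combination_enrichment <- function(states, diet_groups, phenotype,
                                   subject_map, state_set, diet_set) {
  samples <- intersect(names(states), names(diet_groups))
  if (!length(samples)) stop_invalid("states and diet_groups share no samples")
  if (!all(samples %in% names(subject_map)))
    stop_invalid("subject_map is missing samples")
  in_comb_sample <- states[samples] %in% state_set &
    diet_groups[samples] %in% diet_set
  subj <- subject_map[samples]
  in_comb <- tapply(in_comb_sample, subj, any)
  subjects <- names(in_comb)
  if (!all(subjects %in% names(phenotype)))
    stop_invalid("phenotype is missing subjects: ",
                 paste(setdiff(subjects, names(phenotype)), collapse = ", "))
  ph <- as.logical(phenotype[subjects])
  tab <- matrix(c(sum(ph & in_comb), sum(ph & !in_comb),
                  sum(!ph & in_comb), sum(!ph & !in_comb)),
                2, 2, byrow = TRUE,
                dimnames = list(phenotype = c("yes", "no"),
                                combination = c("in", "out")))
  fisher_exact(tab)
}

#' Per-feature group difference tests with FDR control
#'
#' Applies a prevalence filter (feature present in at least
#' `prevalence_min` of the samples), converts to relative abundances, and
#' tests each feature across groups: Wilcoxon rank-sum (Mann-Whitney) for
#' two unpaired groups, Wilcoxon signed-rank when a subject map pairs the
#' two groups, Kruskal-Wallis for three or more groups. Raw p-values are
#' Benjamini-Hochberg adjusted across features. Zero-variance features get
#' `p = NA` and are flagged.
#'
#' @param features an [abundance_table] or [otu_table].
#' @param groups per-sample group labels.
#' @param pairing optional named character vector sample id -> subject id
#'   requesting the paired test (two groups only).
#' @param prevalence_min prevalence filter (default 0.20).
#' @return data frame: feature, per-group mean and SEM, test, p, p_adjusted.
#' @export
group_tests <- function(features, groups, pairing = NULL,
                        prevalence_min = 0.20) {
  vals <- abundance_values(features)
  groups <- as.character(groups)
  if (length(groups) != nrow(vals)) stop_invalid("groups must align with samples")
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop_invalid("need at least 2 groups")
  rel <- vals / pmax(rowSums(vals), .Machine$double.eps)
  keep <- colMeans(vals > 0) >= prevalence_min
  rel <- rel[, keep, drop = FALSE]
  paired <- !is.null(pairing)
  if (paired) {
    if (length(lev) != 2) stop_invalid("paired test requires exactly 2 groups")
    if (is.null(rownames(vals)) || !all(rownames(vals) %in% names(pairing)))
      stop_invalid("pairing map incomplete for these samples")
    subj <- pairing[rownames(vals)]
    a_idx <- which(groups == lev[1]); b_idx <- which(groups == lev[2])
    b_order <- match(subj[a_idx], subj[b_idx])
    if (anyNA(b_order) || length(a_idx) != length(b_idx))
      stop_invalid("pairing map does not pair the two groups one-to-one")
    b_idx <- b_idx[b_order]
  }
  test_name <- if (length(lev) > 2) "kruskal-wallis"
               else if (paired) "wilcoxon-paired" else "mann-whitney"
  rows <- lapply(colnames(rel), function(feat) {
    x <- rel[, feat]
    p <- if (stats::sd(x) == 0) NA_real_
    else if (length(lev) > 2)
      stats::kruskal.test(x, factor(groups))$p.value
    else if (paired)
      suppressWarnings(stats::wilcox.test(x[a_idx], x[b_idx], paired = TRUE)$p.value)
    else
      suppressWarnings(stats::wilcox.test(x[groups == lev[1]],
                                          x[groups == lev[2]])$p.value)
    stats_row <- data.frame(feature = feat, test = test_name, p = p,
                            stringsAsFactors = FALSE)
    for (g in lev) {
      xg <- x[groups == g]
      stats_row[[paste0("mean_", g)]] <- mean(xg)
      stats_row[[paste0("sem_", g)]] <- stats::sd(xg) / sqrt(length(xg))
    }
    stats_row
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, "BH")
  out$zero_variance <- is.na(out$p)
  stat_cols <- setdiff(names(out), c("feature", "test", "p", "p_adjusted",
                                     "zero_variance"))
  out[, c("feature", stat_cols, "test", "p", "p_adjusted", "zero_variance")]
}
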