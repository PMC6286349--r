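#' Identify gut microbiota steady states
#'
#' Clusters samples into recurrent community configurations ("steady
#' states"): OTUs are filtered for prevalence (fraction of samples in which
#' they occur) of at least `prevalence_min`, converted to relative
#' abundances, inter-sample Spearman correlations are computed and mapped to
#' the distance `(1 - rho)/2`, and the samples are clustered by Ward
#' linkage. The tree is cut at `k` clusters (`k = "auto"` selects 2..8 by
#' maximum mean silhouette width on the same distance). Two verifications
#' are attached: per cluster, the fraction of intra-cluster sample pairs
#' whose positive Spearman correlation is significant after
#' Benjamini-Hochberg correction across all intra-cluster tests, and a
#' [permanova] of the Spearman distance matrix against the cluster labels.
#'
#' @param table an [otu_table].
#' @param prevalence_min minimum fraction of samples an OTU must occur in
#'   (default 0.20).
#' @param k number of clusters, or `"auto"`.
#' @param distance_mode `"shift"` for `(1 - rho)/2` (default) or `"abs"`
#'   for `1 - |rho|`.
#' @param ward `"ward.D2"` (default) or `"ward.D"`.
#' @param permutations,seed controls for the verification PERMANOVA.
#' @return object of class `steady_state_result`: per-sample `labels`
#'   (`"C1"`..`"Ck"`, ordered by decreasing cluster size), `linkage`
#'   (hclust), `distance` ([distance_matrix]), `verification` (per-cluster
#'   data frame) and `permanova_result`.
#' @export
identify_steady_states <- function(table, prevalence_min = 0.20, k = "auto",
                                   distance_mode = c("shift", "abs"),
                                   ward = c("ward.D2", "ward.D"),
                                   permutations = 999, seed = 1L) {
  distance_mode <- match.arg(distance_mode)
  ward <- match.arg(ward)
  counts <- abundance_values(table)
  if (nrow(counts) < 4) stop_invalid("need at least 4 samples")
  prevalence <- colMeans(counts > 0)
  keep <- prevalence >= prevalence_min
  if (!any(keep))
    stop_invalid("prevalence filter at ", prevalence_min, " removed every OTU")
  rel <- relative_abundance(otu_table_like(counts))$values[, keep, drop = FALSE]
  rho <- stats::cor(t(rel), method = "spearman")
  dm <- if (distance_mode == "shift") (1 - rho) / 2 else 1 - abs(rho)
  diag(dm) <- 0; dm[dm < 0] <- 0
  dmat <- distance_matrix((dm + t(dm)) / 2, metric = "spearman")
  d <- stats::as.dist(dmat$matrix)
  hc <- stats::hclust(d, method = ward)
  if (identical(k, "auto")) k <- select_k_silhouette(hc, d)
  if (!is_count(k, min = 2)) stop_invalid("k must be an integer >= 2 or 'auto'")
  raw <- stats::cutree(hc, k = k)
  labels <- relabel_by_size(raw, prefix = "C")
  verification <- cluster_cohesion(rho, labels, m = sum(keep))
  pmv <- permanova(dmat, labels, permutations = permutations, seed = seed)
  structure(list(labels = labels, k = k, linkage = hc, distance = dmat,
                 retained_otus = colnames(rel), verification = verification,
                 permanova_result = pmv),
            class = "steady_state_result")
}

## wrap a plain matrix so relative_abundance() can be reused
otu_table_like <- function(mat) {
  structure(list(counts = mat, taxonomy = NULL), class = "otu_table")
}

## rename integer cluster ids to prefix1..prefixK by decreasing size
relabel_by_size <- function(raw, prefix, order_stat = NULL) {
  ord <- if (is.null(order_stat)) order(-table(raw)[as.character(sort(unique(raw)))])
         else order(order_stat)
  new_names <- character(max(raw))
  new_names[sort(unique(raw))[ord]] <- paste0(prefix, seq_along(ord))
  stats::setNames(new_names[raw], names(raw))
}

cluster_cohesion <- function(rho, labels, m) {
  pairs <- list(); cl <- c(); rh <- c()
  for (grp in unique(labels)) {
    idx <- which(labels == grp)
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    cl <- c(cl, rep(grp, ncol(cmb)))
    rh <- c(rh, rho[cbind(cmb[1, ], cmb[2, ])])
  }
  p <- spearman_p(rh, m)
  sig <- stats::p.adjust(p, "BH") <= 0.05 & rh > 0
  out <- data.frame(cluster = sort(unique(cl)))
  out$n_pairs <- as.integer(table(cl)[out$cluster])
  out$frac_significant_positive <-
    vapply(out$cluster, function(g) mean(sig[cl == g]), numeric(1))
  out
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("steady states: %d clusters over %d samples (%s)\n", x$k,
              length(x$labels),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  cat(sprintf("  PERMANOVA pseudo-F = %.3f, p = %.4g\n",
              x$permanova_result$statistic, x$permanova_result$p_value))
  invisible(x)
}

#' Identify co-abundance groups (CAGs) of genera
#'
#' Aggregates the OTU table at genus level, retains genera whose relative
#' abundance exceeds `min_abundance` in at least `min_samples` samples,
#' computes all pairwise Kendall tau-b correlations with two-sided p-values,
#' converts them to q-values (Storey, lambda = 0.5, with a BH fallback), and
#' clusters genera by Ward linkage on the Spearman-correlation distance
#' between genus abundance profiles (optionally on the Kendall-derived
#' distance instead). Edges with `q <= fdr` form the co-abundance network;
#' each CAG is named for its dominant genus (highest cohort-wide mean
#' relative abundance).
#'
#' @param table an [otu_table] with genus-level taxonomy.
#' @param min_abundance relative-abundance threshold (default 0.001, i.e.
#'   0.1%).
#' @param min_samples minimum samples exceeding the threshold (default 2).
#' @param fdr q-value threshold for edges (default 0.05).
#' @param k CAG count or `"auto"` (silhouette, 2..8).
#' @param cluster_metric `"spearman"` (default) or `"kendall"` distance for
#'   the genus clustering.
#' @param qvalue_method `"storey"` or `"BH"`.
#' @return object of class `cag_result`: `genus_labels`, `tau` (tau-b
#'   matrix), `q` (q-value matrix), `edges` (data frame of significant
#'   pairs), `dominant` (per-CAG dominant genus), `mean_abundance`,
#'   `linkage`.
#' @export
identify_cags <- function(table, min_abundance = 0.001, min_samples = 2,
                          fdr = 0.05, k = "auto",
                          cluster_metric = c("spearman", "kendall"),
                          qvalue_method = c("storey", "BH")) {
  cluster_metric <- match.arg(cluster_metric)
  qvalue_method <- match.arg(qvalue_method)
  genus <- aggregate_taxonomy(table, "genus")
  rel <- relative_abundance(genus)$values
  rel <- rel[, colnames(rel) != "Unclassified", drop = FALSE]
  keep <- colSums(rel > min_abundance) >= min_samples
  if (sum(keep) < 5)
    stop_invalid(sprintf(
      "only %d genera pass the filter (>%g relative abundance in >=%d samples); need at least 5",
      sum(keep), min_abundance, min_samples))
  rel <- rel[, keep, drop = FALSE]
  g <- ncol(rel)
  tau <- matrix(1, g, g, dimnames = list(colnames(rel), colnames(rel)))
  pmat <- matrix(0, g, g, dimnames = dimnames(tau))
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    ct <- suppressWarnings(
      stats::cor.test(rel[, i], rel[, j], method = "kendall", exact = FALSE))
    tau[i, j] <- tau[j, i] <- unname(ct$estimate)
    pmat[i, j] <- pmat[j, i] <- ct$p.value
  }
  pv <- pmat[upper.tri(pmat)]
  qv <- qvalues(pv, method = qvalue_method)
  qmat <- matrix(0, g, g, dimnames = dimnames(tau))
  qmat[upper.tri(qmat)] <- qv
  qmat <- qmat + t(qmat)
  if (cluster_metric == "spearman") {
    d <- correlation_distance(t(rel), method = "spearman")
  } else {
    dk <- (1 - tau) / 2; diag(dk) <- 0; dk[dk < 0] <- 0
    d <- stats::as.dist(dk)
  }
  hc <- stats::hclust(d, method = "ward.D2")
  if (identical(k, "auto")) k <- select_k_silhouette(hc, d)
  if (!is_count(k, min = 2)) stop_invalid("k must be an integer >= 2 or 'auto'")
  raw <- stats::cutree(hc, k = k)
  mean_ab <- colMeans(rel)
  # name CAG1..CAGk by decreasing mean abundance of their dominant genus
  dom_by_cluster <- vapply(sort(unique(raw)), function(cl)
    names(which.max(mean_ab[raw == cl])), character(1))
  ord <- order(-mean_ab[dom_by_cluster])
  labels <- relabel_by_size(raw, prefix = "CAG",
                            order_stat = rank(-mean_ab[dom_by_cluster]))
  dominant <- stats::setNames(dom_by_cluster[ord],
                              paste0("CAG", seq_along(ord)))
  idx <- which(upper.tri(qmat) & qmat <= fdr, arr.ind = TRUE)
  edges <- data.frame(
    genus_a = rownames(qmat)[idx[, 1]],
    genus_b = colnames(qmat)[idx[, 2]],
    tau_b = tau[idx],
    q = qmat[idx],
    sign = ifelse(tau[idx] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  structure(list(genus_labels = labels, k = k, tau = tau, p = pmat, q = qmat,
                 edges = edges, dominant = dominant, mean_abundance = mean_ab,
                 linkage = hc, fdr = fdr),
            class = "cag_result")
}

#' @export
print.cag_result <- function(x, ...) {
  cat(sprintf("CAGs: %d groups over %d genera; %d significant edges (q <= %g)\n",
              x$k, length(x$genus_labels), nrow(x$edges), x$fdr))
  for (cag in names(x$dominant))
    cat(sprintf("  %s: dominant genus %s\n", cag, x$dominant[cag]))
  invisible(x)
}

#' Wiggum over-abundance layout
#'
#' For every (steady state, genus) pair, the over-abundance ratio: the mean
#' relative abundance of the genus within the cluster divided by its mean
#' over the whole cohort. In a Wiggum plot these ratios are rendered as disc
#' sizes; here they are returned as a table together with the CAG network
#' edges, ready for export to graph tools.
#'
#' @param table the [otu_table] both results were computed on.
#' @param states a `steady_state_result`.
#' @param cags a `cag_result`.
#' @return object of class `wiggum_layout`: data frame `ratios` (cluster,
#'   genus, cag, ratio) and the `edges` of the CAG network.
#' @export
wiggum_overabundance <- function(table, states, cags) {
  genus <- aggregate_taxonomy(table, "genus")
  rel <- relative_abundance(genus)$values
  genera <- names(cags$genus_labels)
  if (!all(genera %in% colnames(rel)))
    stop_invalid("CAG genera missing from the table")
  rel <- rel[names(states$labels), genera, drop = FALSE]
  cohort_mean <- colMeans(rel)
  absent <- cohort_mean <= 0
  if (any(absent)) {
    warning("genera absent cohort-wide excluded: ",
            paste(genera[absent], collapse = ", "))
    rel <- rel[, !absent, drop = FALSE]
    genera <- genera[!absent]
    cohort_mean <- cohort_mean[!absent]
  }
  clusters <- sort(unique(states$labels))
  rows <- do.call(rbind, lapply(clusters, function(cl) {
    in_cl <- states$labels == cl
    data.frame(cluster = cl, genus = genera,
               cag = unname(cags$genus_labels[genera]),
               ratio = colMeans(rel[in_cl, , drop = FALSE]) / cohort_mean,
               row.names = NULL)
  }))
  structure(list(ratios = rows, edges = cags$edges,
                 cluster_sizes = table(states$labels)),
            class = "wiggum_layout")
}

#' Identify dietary groups from an FFQ table
#'
#' Runs a [correspondence_analysis] on the samples x foods consumption
#' matrix, takes the sample scores on the first axis, clusters them with
#' Ward linkage on the Euclidean (1-D) distance, and cuts at `m` groups.
#' Groups are renamed D1..Dm by ascending within-group mean axis-1 score.
#'
#' @param ffq samples x foods non-negative matrix (daily consumptions), or
#'   an `ffq_table`.
#' @param m group count, or `"auto"` (silhouette, 2..8). Default 5.
#' @return object of class `diet_cluster_result`: per-sample `labels`,
#'   `axis1` scores, `linkage`, and the `ca` ordination.
#' @export
identify_diet_groups <- function(ffq, m = 5) {
  mat <- ffq_values(ffq)
  ca <- correspondence_analysis(mat)
  axis1 <- ca$coordinates[, 1]
  d <- stats::dist(axis1)
  hc <- stats::hclust(d, method = "ward.D2")
  if (identical(m, "auto")) m <- select_k_silhouette(hc, d)
  if (!is_count(m, min = 2)) stop_invalid("m must be an integer >= 2 or 'auto'")
  raw <- stats::cutree(hc, k = m)
  group_mean <- tapply(axis1, raw, mean)
  labels <- relabel_by_size(raw, prefix = "D",
                            order_stat = rank(group_mean))
  names(labels) <- rownames(ca$coordinates)
  structure(list(labels = labels, m = m, axis1 = axis1, linkage = hc, ca = ca),
            class = "diet_cluster_result")
}

#' @export
print.diet_cluster_result <- function(x, ...) {
  cat(sprintf("diet groups: %d groups over %d samples (%s); CA axis 1 explains %.1f%%\n",
              x$m, length(x$labels),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", "),
              100 * x$ca$proportion_explained[1]))
  invisible(x)
}

#' Within-subject pairing statistic
#'
#' Counts the subjects whose two samples are mutual nearest neighbours in a
#' distance matrix (each sample's closest other sample is its partner), and
#' compares the count against a null in which the sample-to-subject
#' assignment is permuted. The p-value uses the add-one convention.
#'
#' @param d a [distance_matrix] (e.g. the Spearman distance from
#'   [identify_steady_states], available as `$distance`).
#' @param subject_map named character vector: sample id -> subject id. Every
#'   subject must have exactly 2 samples.
#' @param permutations,seed permutation controls.
#' @return a `perm_test` with `statistic_name = "paired subjects"`.
#' @export
pairing_statistic <- function(d, subject_map, permutations = 999, seed = 1L) {
  mat <- as_distance_input(d)
  ids <- rownames(mat)
  if (!all(ids %in% names(subject_map)))
    stop_invalid("subject_map is missing samples: ",
                 paste(setdiff(ids, names(subject_map)), collapse = ", "))
  subj <- subject_map[ids]
  if (any(table(subj) != 2))
    stop_invalid("every subject must have exactly 2 samples; offending: ",
                 paste(names(which(table(subj) != 2)), collapse = ", "))
  diag(mat) <- Inf
  nn <- apply(mat, 1, which.min)
  mutual_pairs <- function(subj_vec) {
    # subjects whose two samples are mutual rank-1 neighbours
    count <- 0L
    for (s in unique(subj_vec)) {
      pair <- which(subj_vec == s)
      if (nn[pair[1]] == pair[2] && nn[pair[2]] == pair[1]) count <- count + 1L
    }
    count
  }
  obs <- mutual_pairs(subj)
  set.seed(seed)
  null <- replicate(permutations, mutual_pairs(sample(subj)))
  new_perm_test(obs, permutations, perm_pvalue(obs, null), "paired subjects")
}
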