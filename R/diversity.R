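#' Sample-by-sample distance matrix
#'
#' @param mat square symmetric numeric matrix with matching dimnames.
#' @param metric name of the distance (free text, e.g. `"unweighted_unifrac"`).
#' @return object of class `distance_matrix` wrapping the matrix.
#' @export
distance_matrix <- function(mat, metric = "unknown") {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop_invalid("distance matrix must be square")
  if (any(!is.finite(mat))) stop_invalid("distance matrix contains non-finite values")
  if (max(abs(mat - t(mat))) > 1e-12)
    stop_invalid("distance matrix is not symmetric")
  if (any(mat < 0)) stop_invalid("distances must be non-negative")
  if (any(abs(diag(mat)) > 1e-12)) stop_invalid("distance diagonal must be zero")
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  if (is.null(rownames(mat)))
    stop_invalid("distance matrix must carry sample ids as dimnames")
  colnames(mat) <- rownames(mat)
  structure(list(matrix = mat, ids = rownames(mat), metric = metric),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d samples, metric = %s\n",
              length(x$ids), x$metric))
  invisible(x)
}

#' @export
as.dist.distance_matrix <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(m$matrix, diag = diag, upper = upper)

as_distance_input <- function(d) {
  if (inherits(d, "distance_matrix")) d$matrix
  else if (inherits(d, "dist")) as.matrix(d)
  else if (is.matrix(d)) distance_matrix(d)$matrix  # validates
  else stop_invalid("expected a distance_matrix, dist or square matrix")
}

#' Alpha diversity per sample
#'
#' Computes within-sample diversity: Shannon entropy over the non-zero
#' proportions (log base 2 by default, following the 16S toolchain
#' convention), observed features (count of features with abundance > 0), or
#' Faith's phylogenetic diversity (total branch length of the union of
#' root-to-tip paths of observed tips, root path included).
#'
#' @param table [otu_table] or [abundance_table].
#' @param metric `"shannon"`, `"observed"` or `"faith_pd"`.
#' @param tree rooted `phylo` tree over the OTU ids; required for
#'   `"faith_pd"`.
#' @param base logarithm base for Shannon (default 2).
#' @return named numeric vector, one value per sample.
#' @export
#' @examples
#' m <- matrix(c(5, 5, 7, 0), 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("A", "B")))
#' alpha_diversity(otu_table(m), "shannon")  # s1 = 1, s2 = 0
alpha_diversity <- function(table, metric = c("shannon", "observed", "faith_pd"),
                            tree = NULL, base = 2) {
  metric <- match.arg(metric)
  vals <- abundance_values(table)
  tot <- rowSums(vals)
  if (inherits(table, "otu_table") && min(tot) > 0 &&
      max(tot) / min(tot) > 10)
    warning("library sizes vary more than 10-fold; alpha diversity is computed on full counts (no rarefaction)")
  switch(metric,
    shannon = apply(vals, 1, function(x) {
      p <- x[x > 0]
      if (!length(p)) return(0)
      p <- p / sum(p)
      -sum(p * log(p, base = base))
    }),
    observed = rowSums(vals > 0),
    faith_pd = {
      if (is.null(tree)) stop_invalid("faith_pd requires a phylogenetic tree")
      faith_pd(vals, tree)
    })
}

## Edge-level decomposition of a rooted phylo tree: for every edge, the set
## of tips below it, plus edge lengths and root-to-tip distances.
tree_edge_structure <- function(tree) {
  if (!inherits(tree, "phylo")) stop_invalid("tree must be an ape phylo object")
  if (!ape::is.rooted(tree)) stop_invalid("tree must be rooted")
  if (is.null(tree$edge.length)) stop_invalid("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop_invalid("branch lengths must be >= 0")
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  nedge <- nrow(edge)
  desc <- vector("list", max(edge))              # tips under each node
  for (i in seq_len(ntip)) desc[[i]] <- i
  ord <- ape::postorder(tree)
  for (e in ord) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  incidence <- matrix(FALSE, nedge, ntip,
                      dimnames = list(NULL, tree$tip.label))
  for (e in seq_len(nedge)) incidence[e, desc[[edge[e, 2]]]] <- TRUE
  root_depth <- as.numeric(tree$edge.length %*% incidence)  # root-to-tip distances
  list(incidence = incidence, lengths = tree$edge.length,
       tip_labels = tree$tip.label, root_depth = root_depth)
}

align_to_tips <- function(vals, es) {
  present <- colnames(vals)[colSums(vals) > 0]
  missing <- setdiff(present, es$tip_labels)
  if (length(missing))
    stop_invalid("OTUs absent from the tree: ", paste(missing, collapse = ", "))
  aligned <- matrix(0, nrow(vals), length(es$tip_labels),
                    dimnames = list(rownames(vals), es$tip_labels))
  common <- intersect(colnames(vals), es$tip_labels)
  aligned[, common] <- vals[, common, drop = FALSE]
  aligned
}

faith_pd <- function(vals, tree) {
  es <- tree_edge_structure(tree)
  aligned <- align_to_tips(vals, es)
  occupancy <- (aligned > 0) %*% t(es$incidence) > 0   # samples x edges
  as.numeric(occupancy %*% es$lengths) |>
    stats::setNames(rownames(vals))
}

#' UniFrac distances between samples
#'
#' Phylogeny-aware beta diversity. The unweighted variant is the fraction of
#' total branch length leading exclusively to tips observed in only one of
#' the two samples; the weighted variant sums branch lengths times the
#' absolute difference of the proportion of each sample's reads descending
#' through the branch. `"weighted_normalized"` divides the raw weighted sum
#' by the maximum attainable value, `sum_j d_j (p_A(j) + p_B(j))` over tips
#' `j` with root distance `d_j`; `"weighted"` is an alias for the normalized
#' form.
#'
#' @param table [otu_table] (counts) or [abundance_table].
#' @param tree rooted `phylo` covering every OTU with non-zero count.
#' @param variant `"unweighted"`, `"weighted_raw"`, `"weighted_normalized"`
#'   or `"weighted"`.
#' @return a [distance_matrix].
#' @export
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' m <- matrix(c(1, 1, 0, 1, 0, 1), 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' unifrac(otu_table(m), tree, "unweighted")$matrix["s1", "s2"]  # 0.6
unifrac <- function(table, tree,
                    variant = c("unweighted", "weighted_normalized",
                                "weighted_raw", "weighted")) {
  variant <- match.arg(variant)
  if (variant == "weighted") variant <- "weighted_normalized"
  vals <- abundance_values(table)
  if (any(rowSums(vals) <= 0))
    stop_invalid("empty samples: ",
                 paste(rownames(vals)[rowSums(vals) <= 0], collapse = ", "))
  es <- tree_edge_structure(tree)
  aligned <- align_to_tips(vals, es)
  props <- aligned / rowSums(aligned)
  n <- nrow(props)
  len <- es$lengths
  d <- matrix(0, n, n, dimnames = list(rownames(props), rownames(props)))
  if (variant == "unweighted") {
    occ <- (aligned > 0) %*% t(es$incidence) > 0       # samples x edges
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- occ[i, ]; b <- occ[j, ]
      denom <- sum(len[a | b])
      d[i, j] <- d[j, i] <- if (denom > 0) sum(len[xor(a, b)]) / denom else 0
    }
  } else {
    bp <- props %*% t(es$incidence)                    # samples x edges
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      raw <- sum(len * abs(bp[i, ] - bp[j, ]))
      if (variant == "weighted_raw") {
        d[i, j] <- d[j, i] <- raw
      } else {
        norm <- sum(es$root_depth * (props[i, ] + props[j, ]))
        d[i, j] <- d[j, i] <- if (norm > 0) raw / norm else 0
      }
    }
  }
  distance_matrix(d, metric = paste0(variant, "_unifrac"))
}
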