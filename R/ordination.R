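#' Ordination result (PCoA or CA)
#'
#' @param coordinates samples x axes matrix of sample scores.
#' @param eigenvalues per-axis eigenvalues (non-increasing).
#' @param proportion_explained per-axis fraction of (positive) inertia.
#' @param method `"pcoa"` or `"ca"`.
#' @param extra optional list of method-specific fields (e.g. negative
#'   eigenvalue magnitudes, column scores, the source distance matrix).
#' @return object of class `ordination`.
#' @export
ordination <- function(coordinates, eigenvalues, proportion_explained,
                       method, extra = list()) {
  if (any(diff(eigenvalues) > 1e-8))
    stop_invalid("eigenvalues must be non-increasing")
  if (sum(proportion_explained) > 1 + 1e-9)
    stop_invalid("proportion_explained sums to more than 1")
  if (ncol(coordinates) > nrow(coordinates) - 1)
    stop_invalid("axis count must be at most samples - 1")
  structure(c(list(coordinates = coordinates, eigenvalues = eigenvalues,
                   proportion_explained = proportion_explained,
                   method = method), extra),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination (%s): %d samples, %d axes; first axes explain %s\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * utils::head(x$proportion_explained, 3)),
                    collapse = ", ")))
  invisible(x)
}

## Deterministic eigenvector sign: make the largest-magnitude loading positive.
fix_signs <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Gower double-centering of the squared distances, `B = -1/2 J D^2 J`,
#' followed by an eigendecomposition. Coordinates are eigenvectors scaled by
#' the square root of their (positive) eigenvalues; axes with negative
#' eigenvalues are dropped and their magnitudes reported in
#' `$negative_eigenvalues`. Proportions explained use the sum of positive
#' eigenvalues as denominator. Optionally applies the Cailliez additive
#' correction before decomposing.
#'
#' @param d a [distance_matrix] (or square symmetric matrix / `dist`).
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return an [ordination] with `method = "pcoa"`.
#' @export
pcoa <- function(d, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  mat <- as_distance_input(d)
  n <- nrow(mat)
  if (n < 3) stop_invalid("PCoA needs at least 3 samples")
  if (correction == "cailliez") {
    # smallest additive constant making the configuration Euclidean
    res <- ape::pcoa(mat, correction = "cailliez")
    mat <- as.matrix(stats::dist(res$vectors.cor %||% res$vectors))
    dimnames(mat) <- dimnames(as_distance_input(d))
  }
  A <- -0.5 * mat^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- which(eig$values > tol)
  neg <- eig$values[eig$values < -tol]
  lambda <- eig$values[pos]
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda), length(pos))
  rownames(coords) <- rownames(mat)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  coords <- fix_signs(coords)
  ordination(coords, lambda, lambda / sum(lambda), "pcoa",
             extra = list(negative_eigenvalues = abs(neg),
                          source_distance = if (inherits(d, "distance_matrix")) d else NULL))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correspondence analysis of a non-negative table
#'
#' Chi-square-metric ordination: with `P = f / total`, row masses `r` and
#' column masses `c`, the standardized residuals
#' `S = Dr^{-1/2} (P - r c') Dc^{-1/2}` are decomposed by SVD. Row principal
#' coordinates are `Dr^{-1/2} U S`; principal inertias (eigenvalues) are the
#' squared singular values and sum to the independence chi-square statistic
#' divided by the grand total.
#'
#' @param f non-negative numeric matrix (e.g. samples x food items).
#'   All-zero rows or columns are dropped with a warning.
#' @return an [ordination] with `method = "ca"`; column principal
#'   coordinates are available as `$column_coordinates`.
#' @export
correspondence_analysis <- function(f) {
  f <- as.matrix(f)
  if (any(f < 0)) stop_invalid("correspondence analysis requires non-negative entries")
  if (sum(f) <= 0) stop_invalid("grand total must be positive")
  zr <- rowSums(f) == 0; zc <- colSums(f) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero rows/columns: ",
            paste(c(rownames(f)[zr], colnames(f)[zc]), collapse = ", "))
    f <- f[!zr, !zc, drop = FALSE]
  }
  P <- f / sum(f)
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  tol <- max(1e-10, max(sv$d) * 1e-8)
  keep <- which(sv$d > tol)
  keep <- keep[keep <= min(nrow(f), ncol(f)) - 1]
  if (!length(keep)) stop_invalid("degenerate correspondence analysis: zero inertia")
  d <- sv$d[keep]
  rowcoord <- (sv$u[, keep, drop = FALSE] * d[col(sv$u[, keep, drop = FALSE])]) / sqrt(r)
  colcoord <- (sv$v[, keep, drop = FALSE] * d[col(sv$v[, keep, drop = FALSE])]) / sqrt(cc)
  dimnames(rowcoord) <- list(rownames(f), paste0("CA", seq_along(keep)))
  dimnames(colcoord) <- list(colnames(f), paste0("CA", seq_along(keep)))
  # sign convention applied to rows; columns must flip with them
  for (j in seq_len(ncol(rowcoord))) {
    i <- which.max(abs(rowcoord[, j]))
    if (rowcoord[i, j] < 0) {
      rowcoord[, j] <- -rowcoord[, j]
      colcoord[, j] <- -colcoord[, j]
    }
  }
  lambda <- d^2
  ordination(rowcoord, lambda, lambda / sum(lambda), "ca",
             extra = list(column_coordinates = colcoord,
                          total_inertia = sum(lambda)))
}
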