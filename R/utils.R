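#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

stop_invalid <- function(...) {
  stop(structure(
    class = c("microstrat_invalid_argument", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

#' Spearman correlation p-value via the t approximation
#'
#' Two-sided p for H0: rho = 0 using t = rho * sqrt((n-2)/(1-rho^2)).
#' Adequate for the sample sizes used here (tens to hundreds of features).
#' @noRd
spearman_p <- function(rho, n) {
  rho <- pmin(1, pmax(-1, rho))
  p <- rep(NA_real_, length(rho))
  ok <- is.finite(rho) & n > 2
  t <- rho[ok] * sqrt((n - 2) / pmax(1 - rho[ok]^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(-abs(t), df = n - 2)
  pmin(p, 1)
}

#' Storey q-values with fixed lambda
#'
#' q-value analogue of the p-value for FDR control. pi0 is estimated as
#' \#\{p > lambda\} / ((1 - lambda) m), capped at 1, and the q-values are the
#' pi0-scaled Benjamini-Hochberg step-up values. `method = "BH"` forces
#' pi0 = 1, i.e. plain Benjamini-Hochberg.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param lambda tuning constant for the pi0 estimate (default 0.5).
#' @param method `"storey"` (default) or `"BH"`.
#' @return numeric vector of q-values, same length as `p`.
#' @export
#' @examples
#' qvalues(c(0.001, 0.01, 0.2, 0.8, 0.9))
qvalues <- function(p, lambda = 0.5, method = c("storey", "BH")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1))) stop_invalid("p-values must lie in [0, 1]")
  m <- sum(!is.na(p))
  if (m == 0L) return(p)
  pi0 <- if (method == "BH") 1 else
    min(1, sum(p > lambda, na.rm = TRUE) / ((1 - lambda) * m))
  if (pi0 <= 0) pi0 <- 1 / m  # all p tiny: keep q positive and ordered
  pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

#' Pick a cluster count by mean silhouette width
#'
#' Cuts a hierarchical tree at k = 2..k_max and returns the k with the
#' largest mean silhouette width on the supplied distance matrix.
#' @noRd
select_k_silhouette <- function(hc, d, k_max = 8L) {
  n <- attr(d, "Size")
  ks <- 2:min(k_max, n - 1L)
  width <- vapply(ks, function(k) {
    sil <- cluster::silhouette(stats::cutree(hc, k = k), d)
    mean(sil[, "sil_width"])
  }, numeric(1))
  ks[which.max(width)]
}

#' Permutation p-value with the +1 convention
#' @noRd
perm_pvalue <- function(observed, permuted) {
  (sum(permuted >= observed, na.rm = TRUE) + 1) / (sum(!is.na(permuted)) + 1)
}

new_perm_test <- function(statistic, permutations, p_value, name) {
  structure(
    list(statistic = statistic, permutations = permutations,
         p_value = p_value, statistic_name = name),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test: %s = %.6g, p = %.4g (%d permutations)\n",
              x$statistic_name, x$statistic, x$p_value, x$permutations))
  invisible(x)
}

## Correlation-based distance between rows of a matrix.
## mode "shift": (1 - rho)/2 maps [-1,1] -> [1,0]; mode "abs": 1 - |rho|.
correlation_distance <- function(mat, method = "spearman",
                                 mode = c("shift", "abs")) {
  mode <- match.arg(mode)
  rho <- suppressWarnings(stats::cor(t(mat), method = method))
  rho[is.na(rho)] <- 0   # constant profiles: no information, mid-distance
  d <- if (mode == "shift") (1 - rho) / 2 else 1 - abs(rho)
  diag(d) <- 0
  d[d < 0] <- 0
  stats::as.dist(d)
}
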