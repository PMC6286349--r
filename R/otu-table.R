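#' OTU count table
#'
#' The central abundance container: a samples x OTUs matrix of non-negative
#' integer counts plus a Greengenes-style taxonomy lineage per OTU
#' (`"k__...;p__...;c__...;o__...;f__...;g__..."`; ranks may be empty).
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns. Row and
#'   column names are required and must be unique.
#' @param taxonomy character vector of lineage strings, one per OTU, either
#'   named by OTU id or in column order. May be `NULL` (no taxonomy).
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer-valued matrix) and `taxonomy` (named character or `NULL`).
#' @export
#' @examples
#' m <- matrix(c(2, 2, 4, 0, 1, 3), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("o1", "o2", "o3")))
#' tab <- otu_table(m, c(o1 = "k__Bacteria;p__A;c__;o__;f__F1;g__G1",
#'                       o2 = "k__Bacteria;p__A;c__;o__;f__F1;g__G1",
#'                       o3 = "k__Bacteria;p__B;c__;o__;f__F2;g__G2"))
#' tab
otu_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_invalid("counts must be a numeric matrix (samples x OTUs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_invalid("counts must have sample row names and OTU column names")
  if (anyDuplicated(rownames(counts)))
    stop_invalid("duplicate sample ids: ",
                 paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_invalid("duplicate OTU ids: ",
                 paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_invalid("counts must be finite and non-negative")
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) {
      if (length(taxonomy) != ncol(counts))
        stop_invalid("taxonomy length does not match the number of OTUs")
      names(taxonomy) <- colnames(counts)
    }
    missing <- setdiff(names(taxonomy), colnames(counts))
    if (length(missing))
      stop_invalid("taxonomy refers to unknown OTU ids: ",
                   paste(missing, collapse = ", "))
    taxonomy <- taxonomy[colnames(counts)]
    names(taxonomy) <- colnames(counts)
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "" else " (with taxonomy)"))
  invisible(x)
}

sample_ids <- function(x) rownames(x$counts)
otu_ids <- function(x) colnames(x$counts)

#' Abundance table (counts or relative abundances at some taxonomic level)
#'
#' @param values numeric samples x features matrix.
#' @param level one of `"otu"`, `"genus"`, `"family"`, `"phylum"`.
#' @param normalization `"counts"` or `"relative"`.
#' @return object of class `abundance_table`.
#' @export
abundance_table <- function(values, level = "otu",
                            normalization = c("counts", "relative")) {
  normalization <- match.arg(normalization)
  if (any(!is.finite(values)) || any(values < 0))
    stop_invalid("abundances must be finite and non-negative")
  if (normalization == "relative") {
    tot <- rowSums(values)
    bad <- abs(tot - 1) > 1e-9 & tot > 0
    if (any(bad))
      stop_invalid("relative abundance rows must sum to 1; offending samples: ",
                   paste(rownames(values)[bad], collapse = ", "))
  }
  structure(list(values = values, level = level, normalization = normalization),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d features (%s, %s)\n",
              nrow(x$values), ncol(x$values), x$level, x$normalization))
  invisible(x)
}

#' Convert counts to relative abundances
#'
#' Each sample (row) is divided by its total count. Samples with a zero
#' total cannot be normalized and raise an error naming them.
#'
#' @param table an [otu_table] or [abundance_table].
#' @return an [abundance_table] with `normalization = "relative"`; the
#'   feature level is unchanged.
#' @export
#' @examples
#' m <- matrix(c(2, 2, 4), 1, dimnames = list("s1", c("a", "b", "c")))
#' relative_abundance(otu_table(m))$values  # 0.25 0.25 0.50
relative_abundance <- function(table) {
  vals <- abundance_values(table)
  tot <- rowSums(vals)
  if (any(tot <= 0))
    stop_invalid("samples with zero total count cannot be normalized: ",
                 paste(rownames(vals)[tot <= 0], collapse = ", "))
  abundance_table(vals / tot, level = abundance_level(table),
                  normalization = "relative")
}

abundance_values <- function(table) {
  if (inherits(table, "otu_table")) table$counts
  else if (inherits(table, "abundance_table")) table$values
  else if (is.matrix(table)) table
  else stop_invalid("expected an otu_table, abundance_table or matrix")
}

abundance_level <- function(table) {
  if (inherits(table, "abundance_table")) table$level else "otu"
}

#' Parse taxonomy lineage strings into a rank matrix
#'
#' @param lineages character vector of `k__;p__;c__;o__;f__;g__` strings.
#' @return character matrix with columns kingdom..genus; empty string where
#'   the rank is unassigned.
#' @export
parse_taxonomy <- function(lineages) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__")
  out <- matrix("", nrow = length(lineages), ncol = 6,
                dimnames = list(names(lineages), ranks))
  parts <- strsplit(ifelse(is.na(lineages), "", lineages), ";")
  for (i in seq_along(parts)) {
    for (field in trimws(parts[[i]])) {
      hit <- which(startsWith(field, prefixes))
      if (length(hit) == 1)
        out[i, hit] <- substring(field, 4)
    }
  }
  out
}

#' Aggregate an OTU table at a taxonomic rank
#'
#' Sums OTU counts sharing the same taxon name at the requested rank. OTUs
#' with no assignment at that rank are pooled into a reserved
#' `"Unclassified"` feature, so per-sample totals are conserved exactly.
#'
#' @param table an [otu_table] with taxonomy.
#' @param level `"phylum"`, `"family"` or `"genus"`.
#' @return an [abundance_table] of summed counts at the requested level.
#' @export
aggregate_taxonomy <- function(table, level = c("genus", "family", "phylum")) {
  if (!inherits(table, "otu_table")) stop_invalid("expected an otu_table")
  level <- tryCatch(match.arg(level),
                    error = function(e) stop_invalid(
                      "unknown rank; use one of genus, family, phylum"))
  if (is.null(table$taxonomy))
    stop_invalid("table has no taxonomy; cannot aggregate")
  ranks <- parse_taxonomy(table$taxonomy)
  taxon <- ranks[, level]
  taxon[is.na(taxon) | taxon == ""] <- "Unclassified"
  groups <- factor(taxon)
  agg <- t(rowsum(t(table$counts), groups))
  colnames(agg) <- levels(groups)
  abundance_table(agg, level = level, normalization = "counts")
}
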