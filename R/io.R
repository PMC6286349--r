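## File readers and writers. Every writer accepts `comment` lines (written
## as leading "# " lines, used by the pipeline for provenance: config hash
## and seed); every reader skips them.

write_header_comments <- function(path, comment) {
  con <- file(path, "w")
  if (length(comment)) writeLines(paste0("# ", comment), con)
  con
}

#' Write / read an OTU table as TSV
#'
#' Dialect: OTUs in rows, first column `otu_id`, one column per sample,
#' last column `taxonomy` (lineage string; empty when absent). Leading
#' `#` lines are comments.
#'
#' @param table an [otu_table].
#' @param path file path.
#' @param comment optional character vector of provenance comment lines.
#' @return `write_otu_tsv` returns `path` invisibly; `read_otu_tsv`
#'   returns an [otu_table].
#' @export
write_otu_tsv <- function(table, path, comment = character()) {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(otu_id = otu_ids(table), t(table$counts),
                   check.names = FALSE)
  df$taxonomy <- if (is.null(table$taxonomy)) "" else
    unname(table$taxonomy[otu_ids(table)])
  con <- write_header_comments(path, comment)
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_tsv
#' @export
read_otu_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "otu_id" || utils::tail(names(df), 1) != "taxonomy")
    stop_invalid("malformed OTU TSV: expected otu_id first and taxonomy last, got ",
                 paste(names(df)[c(1, ncol(df))], collapse = "/"))
  if (anyDuplicated(df$otu_id))
    stop_invalid("duplicate OTU ids in ", path, ": ",
                 paste(unique(df$otu_id[duplicated(df$otu_id)]), collapse = ", "))
  samples <- setdiff(names(df), c("otu_id", "taxonomy"))
  counts <- t(as.matrix(df[, samples, drop = FALSE]))
  dimnames(counts) <- list(samples, df$otu_id)
  tax <- stats::setNames(as.character(df$taxonomy), df$otu_id)
  if (all(tax == "")) tax <- NULL
  otu_table(counts, tax)
}

#' Read a BIOM-JSON OTU table
#'
#' Reads the JSON dialect of the BIOM format via the biomformat package;
#' taxonomy is taken from the observation metadata when present.
#'
#' @param path path to a `.biom` JSON file.
#' @return an [otu_table].
#' @export
read_biom_json <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop_invalid("reading BIOM files requires the biomformat package")
  b <- biomformat::read_biom(path)
  mat <- as(biomformat::biom_data(b), "matrix")     # observations x samples
  counts <- t(mat)
  md <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  tax <- NULL
  if (!is.null(md) && length(md)) {
    collapse <- function(x) paste(unlist(x), collapse = ";")
    tax <- if (is.data.frame(md)) apply(md, 1, paste, collapse = ";")
           else vapply(md, collapse, character(1))
    names(tax) <- colnames(counts)
  }
  otu_table(counts, tax)
}

#' Write / read a phylogenetic tree in newick format
#' @param tree a `phylo`.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

read_csv_checked <- function(path, id_col) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!id_col %in% names(df))
    stop_invalid("missing '", id_col, "' column in ", path)
  if (anyDuplicated(df[[id_col]]))
    stop_invalid("duplicate ", id_col, " in ", path, ": ",
                 paste(unique(df[[id_col]][duplicated(df[[id_col]])]),
                       collapse = ", "))
  df
}

#' Write / read the per-sample metadata table as CSV
#' @param metadata data frame with a `sample` column.
#' @param path file path.
#' @param comment provenance comment lines.
#' @export
write_metadata_csv <- function(metadata, path, comment = character()) {
  con <- write_header_comments(path, comment)
  on.exit(close(con))
  utils::write.csv(metadata, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) read_csv_checked(path, "sample")

#' Write / read an FFQ daily-consumption table as CSV
#'
#' Samples in rows (`sample` id column), one column per food.
#' @param ffq an [ffq_table] or samples x foods matrix.
#' @param path file path.
#' @param comment provenance comment lines.
#' @param foods annotation table used when re-reading.
#' @export
write_ffq_csv <- function(ffq, path, comment = character()) {
  vals <- ffq_values(ffq)
  df <- data.frame(sample = rownames(vals), vals, check.names = FALSE)
  con <- write_header_comments(path, comment)
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ffq_csv
#' @export
read_ffq_csv <- function(path, foods = food_reference()) {
  df <- read_csv_checked(path, "sample")
  mat <- as.matrix(df[, setdiff(names(df), "sample"), drop = FALSE])
  rownames(mat) <- df$sample
  ffq_table(mat, foods = foods)
}

#' Write / read a distance matrix as square TSV
#' @param d a [distance_matrix].
#' @param path file path.
#' @param comment provenance comment lines.
#' @export
write_distance_tsv <- function(d, path, comment = character()) {
  stopifnot(inherits(d, "distance_matrix"))
  df <- data.frame(sample = d$ids, d$matrix, check.names = FALSE)
  con <- write_header_comments(path, c(comment, paste0("metric: ", d$metric)))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  header <- readLines(path, n = 20)
  metric <- sub("^# metric: ", "", grep("^# metric: ", header, value = TRUE))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  distance_matrix(mat, metric = if (length(metric)) metric[1] else "unknown")
}

#' Write an ordination as TSV with an eigenvalue sidecar
#'
#' The main file holds `sample` plus one column per axis; the sidecar
#' (`<path>.eigen.tsv`) holds per-axis eigenvalues and proportions.
#' @param ord an [ordination].
#' @param path file path for the coordinates.
#' @param comment provenance comment lines.
#' @export
write_ordination_tsv <- function(ord, path, comment = character()) {
  df <- data.frame(sample = rownames(ord$coordinates), ord$coordinates,
                   check.names = FALSE)
  con <- write_header_comments(path, c(comment, paste0("method: ", ord$method)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  side <- data.frame(axis = colnames(ord$coordinates),
                     eigenvalue = ord$eigenvalues,
                     proportion_explained = ord$proportion_explained)
  con2 <- write_header_comments(paste0(path, ".eigen.tsv"), comment)
  utils::write.table(side, con2, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con2)
  invisible(path)
}

#' Write per-sample labels (states, diet groups) as CSV
#' @param labels named character vector (sample id -> label), or a data
#'   frame of several label columns with a `sample` column.
#' @param path file path.
#' @param comment provenance comment lines.
#' @param name column name when `labels` is a vector.
#' @export
write_labels_csv <- function(labels, path, comment = character(),
                             name = "label") {
  df <- if (is.data.frame(labels)) labels
        else stats::setNames(data.frame(names(labels), unname(labels),
                                        stringsAsFactors = FALSE),
                             c("sample", name))
  con <- write_header_comments(path, comment)
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) read_csv_checked(path, "sample")

#' Write the CAG network edge list as TSV
#' @param edges edge data frame (`genus_a, genus_b, tau_b, q, sign`).
#' @param path file path.
#' @param comment provenance comment lines.
#' @export
write_edges_tsv <- function(edges, path, comment = character()) {
  con <- write_header_comments(path, comment)
  on.exit(close(con))
  utils::write.table(edges, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Writes the OTU table (TSV), tree (newick), FFQ and metadata (CSV),
#' truth labels (CSV) and a `manifest.json` recording paths and the seed.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest as a list, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed_line <- paste0("seed: ", cohort$config$seed)
  paths <- list(
    otu_table = file.path(dir, "otu_table.tsv"),
    tree = file.path(dir, "tree.nwk"),
    ffq = file.path(dir, "ffq.csv"),
    metadata = file.path(dir, "metadata.csv"),
    truth = file.path(dir, "truth.csv")
  )
  write_otu_tsv(cohort$otu_table, paths$otu_table, comment = seed_line)
  write_newick(cohort$tree, paths$tree)
  write_ffq_csv(cohort$ffq, paths$ffq, comment = seed_line)
  write_metadata_csv(cohort$metadata, paths$metadata, comment = seed_line)
  truth_df <- data.frame(sample = names(cohort$truth$state),
                         state = unname(cohort$truth$state),
                         diet = unname(cohort$truth$diet[names(cohort$truth$state)]),
                         subject = unname(cohort$truth$subject_map),
                         stringsAsFactors = FALSE)
  write_labels_csv(truth_df, paths$truth, comment = seed_line)
  manifest <- c(list(seed = cohort$config$seed), lapply(paths, basename))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
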