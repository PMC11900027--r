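# Readers and writers for the pipeline's plain-text interchange formats.
# All numeric output uses a fixed %.6g format and LF newlines so that file
# hashes are reproducible across runs and platforms.

write_table_fixed <- function(df, path, sep) {
  df2 <- df
  for (j in seq_along(df2))
    if (is.double(df2[[j]])) df2[[j]] <- fmt_num(df2[[j]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df2), collapse = sep), con, sep = "\n")
  if (nrow(df2))
    writeLines(do.call(paste, c(unname(as.list(df2)), list(sep = sep))),
               con, sep = "\n")
  invisible(path)
}

#' Write / read a count matrix as TSV (genes in rows)
#'
#' @param counts integer gene x sample matrix.
#' @param path file path.
#' @return the path (write) or the matrix (read), invisibly for writes.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table_fixed(df, path, sep = "\t")
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}

#' Write / read the sample metadata table as CSV
#'
#' @param samples sample table.
#' @param path file path.
#' @export
write_samples_csv <- function(samples, path) {
  write_table_fixed(samples, path, sep = ",")
}

#' @rdname write_samples_csv
#' @export
read_samples_csv <- function(path) {
  read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' Write / read ground truth as TSV
#'
#' Flat layout: gene_id, set, then one true-log2-fold-change column per
#' treatment.
#'
#' @param truth ground-truth list from [generate_counts()].
#' @param path file path.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- data.frame(gene_id = truth$gene_id, set = unname(truth$set),
                   truth$lfc, check.names = FALSE, stringsAsFactors = FALSE)
  write_table_fixed(df, path, sep = "\t")
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  lfc <- as.matrix(df[, setdiff(names(df), c("gene_id", "set")),
                      drop = FALSE])
  rownames(lfc) <- df$gene_id
  list(lfc = lfc, set = setNames(df$set, df$gene_id), gene_id = df$gene_id)
}

#' Write a DE result table as TSV
#'
#' Stable column order: gene_id, base_mean, log2fc, se, wald_z, pvalue,
#' fdr, significant.
#'
#' @param de DE result data frame.
#' @param path file path.
#' @export
write_de_tsv <- function(de, path) {
  cols <- c("gene_id", "base_mean", "log2fc", "se", "wald_z", "pvalue",
            "fdr", "significant")
  df <- de[, cols]
  df$significant <- as.integer(df$significant)
  write_table_fixed(df, path, sep = "\t")
}

#' @rdname write_de_tsv
#' @export
read_de_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df$significant <- df$significant == 1
  df
}
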