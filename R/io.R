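# Plain-text I/O: tab-separated tables, FASTA/FASTQ reads (via Biostrings),
# and BED output for island calls. All tables are written without quoting
# so runs are byte-reproducible.

.write_tsv <- function(x, path) {
  # serialise doubles at full precision so persisted intermediates
  # round-trip exactly and stage reruns are byte-reproducible
  for (j in seq_along(x))
    if (is.double(x[[j]])) x[[j]] <- sprintf("%.17g", x[[j]])
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

#' Read a gene x sample expression matrix with its sample annotation
#'
#' The matrix file is tab-separated with gene ids in the first column and
#' sample ids as header; the annotation sidecar has columns `sample`,
#' `stage` and optionally `context`.
#'
#' @param matrix_path path to the matrix TSV.
#' @param samples_path path to the sample annotation TSV.
#' @param stage_levels stage order (default normal, adenoma, CRC).
#' @return list with `matrix` and `samples` (stage as ordered factor).
#' @export
read_expression_matrix <- function(matrix_path, samples_path,
                                   stage_levels = c("normal", "adenoma", "CRC")) {
  tab <- .read_tsv(matrix_path, check.names = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- tab[[1L]]
  ann <- .read_tsv(samples_path)
  if (!all(c("sample", "stage") %in% names(ann)))
    .stopf("sample annotation needs 'sample' and 'stage' columns")
  miss <- setdiff(colnames(mat), ann$sample)
  if (length(miss))
    .stopf("sample(s) missing from annotation: %s", paste(miss, collapse = ", "))
  ann <- ann[match(colnames(mat), ann$sample), , drop = FALSE]
  ann$stage <- factor(ann$stage, levels = stage_levels)
  if (anyNA(ann$stage)) .stopf("unknown stage label(s) in annotation")
  list(matrix = mat, samples = ann)
}

#' Write an expression matrix and its sample annotation
#'
#' @param x list with `matrix` and `samples` as returned by
#'   [gen_staged_expression()] or [read_expression_matrix()].
#' @param matrix_path,samples_path output paths.
#' @export
write_expression_matrix <- function(x, matrix_path, samples_path) {
  tab <- data.frame(gene = rownames(x$matrix), x$matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(tab, matrix_path)
  .write_tsv(x$samples, samples_path)
  invisible(c(matrix_path, samples_path))
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' @param path input path; format from the extension (`.fq`/`.fastq` read
#'   as FASTQ, anything else as FASTA).
#' @return named character vector of read sequences.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  fmt <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads to FASTA or FASTQ
#'
#' @param reads named character vector of sequences.
#' @param path output path.
#' @param format `"fasta"` (default) or `"fastq"` (constant dummy quality).
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(reads)
  if (format == "fastq") {
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(
        vapply(nchar(reads), function(n)
          paste(rep("I", n), collapse = ""), character(1))))
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' Write island calls as a BED file
#'
#' Converts the package's 1-based closed island coordinates to BED's
#' 0-based half-open convention.
#'
#' @param islands data.frame from [predict_islands()].
#' @param path output path.
#' @param name sequence name for the first BED column.
#' @export
write_islands_bed <- function(islands, path, name = "seq") {
  bed <- data.frame(chrom = name,
                    start = islands$start - 1L,
                    end = islands$end,
                    name = sprintf("CpG_island_%d", seq_len(nrow(islands))),
                    score = round(islands$obs_exp, 4),
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a miRNA plate table
#'
#' Expects tab-separated columns `mirna`, `sample`, `plate`, `ct`,
#' `is_calibrator` (and optionally `group`).
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_ct_plates <- function(path) {
  df <- .read_tsv(path)
  .check_plate_df(df)
  df$is_calibrator <- as.logical(df$is_calibrator)
  df
}

#' Read a miRNA target-prediction table
#'
#' Tab-separated with columns `mirna` and `gene` (extra columns such as
#' `source` are kept). Stands in for database queries.
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_targets_table <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("mirna", "gene") %in% names(df)))
    .stopf("target table needs 'mirna' and 'gene' columns")
  df
}

#' Read an IHC core score table
#'
#' Tab-separated with columns `group` and either `qscore` or
#' `percent_positive` + `intensity`.
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_qscore_table <- function(path) {
  df <- .read_tsv(path)
  if (!"group" %in% names(df)) .stopf("core table needs a 'group' column")
  df
}
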