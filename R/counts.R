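#' Validate a gene-by-sample read-count matrix
#'
#' The expression input of the whole pipeline is a matrix of non-negative
#' integer read counts with unique gene symbols as row names (HGNC symbols
#' for real data) and unique sample identifiers as column names. This
#' function checks those invariants and returns the matrix unchanged
#' (coercing a data.frame whose first column holds gene symbols).
#'
#' @param x A numeric matrix with row and column names, or a data.frame in
#'   the on-disk TSV layout (first column gene symbols).
#' @return The validated integer-valued matrix.
#' @export
as_count_matrix <- function(x) {
  if (is.data.frame(x)) {
    genes <- as.character(x[[1L]])
    m <- as.matrix(x[, -1L, drop = FALSE])
    rownames(m) <- genes
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("counts must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count matrix needs gene symbols as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene symbols in count matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample ids in count matrix", call. = FALSE)
  }
  if (anyNA(x) || any(x < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  if (any(x != round(x))) {
    stop("counts must be integral read counts", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' Read / write a count matrix as TSV
#'
#' On-disk layout: tab-separated, header row of sample ids, first column
#' named `gene` holding the gene symbols.
#'
#' @param path File path.
#' @return `read_counts_tsv` returns the validated matrix;
#'   `write_counts_tsv` returns `path` invisibly.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_count_matrix(df)
}

#' @rdname read_counts_tsv
#' @param counts A count (or expression) matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample annotation (labels) as TSV
#'
#' Two mandatory columns: `sample_id` and `status`
#' (\code{"positive"}/\code{"negative"} putative GD2 status). Optional
#' columns `type` (tissue / sample-type label, used for sample-type
#' ranking) and `class` (three-level phenotype \code{"GD2++"},
#' \code{"GD2+"}, \code{"GD2-"}, used for the congruence screen).
#'
#' @param path File path.
#' @return A data.frame with at least `sample_id` and `status`.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "status")
  if (!all(need %in% names(df))) {
    stop("annotation TSV must have columns 'sample_id' and 'status'",
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in annotation", call. = FALSE)
  }
  bad <- setdiff(unique(df$status), c("positive", "negative"))
  if (length(bad)) {
    stop("status must be 'positive' or 'negative'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_annotation_tsv
#' @param annotation Annotation data.frame.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a gene-pool list (one symbol per line)
#'
#' The pool stands in for a curated null set of genes, e.g. the GO "lipid
#' metabolic process" genes used to build the random-pair null.
#'
#' @param path File path.
#' @return Character vector of gene symbols.
#' @export
read_pool <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' @rdname read_pool
#' @param genes Character vector of gene symbols.
#' @export
write_pool <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

# Coerce user-supplied labels (named logical / character / factor, or an
# annotation data.frame) to a named logical vector aligned with `samples`;
# TRUE = GD2-positive.
.as_binary_labels <- function(labels, samples) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$status, labels$sample_id)
  }
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("positive", "negative"))
    if (length(bad)) {
      stop("labels must be 'positive'/'negative'; found: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    labels <- stats::setNames(labels == "positive", names(labels))
  }
  if (!is.logical(labels)) {
    stop("labels must be logical or 'positive'/'negative'", call. = FALSE)
  }
  if (is.null(names(labels))) {
    if (length(labels) != length(samples)) {
      stop("unnamed labels must match the number of samples", call. = FALSE)
    }
    names(labels) <- samples
  }
  missing <- setdiff(samples, names(labels))
  if (length(missing)) {
    stop("samples without labels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  labels[samples]
}
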