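#' Relative fluorescence intensity (RFI) per cell line
#'
#' RFI is the ratio of a cell line's GD2-antibody-stained mean fluorescence
#' to its unstained autofluorescence. With replicate measurements the RFI
#' is the mean of the per-replicate stained/unstained ratios (not the
#' ratio of means).
#'
#' @param records data.frame of flow-cytometry summaries with columns
#'   `cell_line`, `replicate`, `mfi_stained`, `mfi_unstained` (both MFIs
#'   strictly positive).
#' @return data.frame with one row per cell line: `cell_line`, `rfi`,
#'   `n_replicates`.
#' @export
compute_rfi <- function(records) {
  need <- c("cell_line", "mfi_stained", "mfi_unstained")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("records must have columns cell_line, mfi_stained, mfi_unstained",
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("no flow records", call. = FALSE)
  if (any(records$mfi_stained <= 0) || any(records$mfi_unstained <= 0)) {
    stop("MFI values must be strictly positive", call. = FALSE)
  }
  ratio <- records$mfi_stained / records$mfi_unstained
  agg <- stats::aggregate(ratio, by = list(cell_line = records$cell_line),
                          FUN = mean)
  n <- stats::aggregate(ratio, by = list(cell_line = records$cell_line),
                        FUN = length)
  out <- data.frame(cell_line = agg$cell_line, rfi = agg$x,
                    n_replicates = n$x, stringsAsFactors = FALSE)
  out[order(out$cell_line), , drop = FALSE]
}

#' Three-level GD2 phenotype from RFI
#'
#' Cell lines are categorized as GD2-overexpressing (`GD2++`, RFI > 10),
#' GD2-positive (`GD2+`, 1.5 <= RFI <= 10) or GD2-negative (`GD2-`,
#' RFI < 1.5). The published cut-offs are strict inequalities that leave
#' the boundary values 1.5 and 10 unassigned; here both boundaries fall in
#' the middle class (configurable via `boundaries`).
#'
#' @param rfi Positive numeric RFI value(s).
#' @param boundaries Length-2 numeric: lower and upper class cut-offs
#'   (default `c(1.5, 10)`).
#' @return Factor with levels `GD2++`, `GD2+`, `GD2-` (vectorized).
#' @examples
#' classify_rfi(c(12, 5, 1.2))  # GD2++, GD2+, GD2-
#' @export
classify_rfi <- function(rfi, boundaries = c(1.5, 10)) {
  if (any(!is.finite(rfi)) || any(rfi <= 0)) {
    stop("RFI must be positive and finite", call. = FALSE)
  }
  stopifnot(length(boundaries) == 2L, boundaries[1L] < boundaries[2L])
  cls <- ifelse(rfi > boundaries[2L], "GD2++",
                ifelse(rfi < boundaries[1L], "GD2-", "GD2+"))
  factor(cls, levels = .gd2_levels)
}

#' Binary collapse of the GD2 phenotype
#'
#' `GD2++` and `GD2+` are GD2-positive; `GD2-` is GD2-negative. This is
#' the ground-truth labelling the signature screen and the classifier
#' evaluation use.
#'
#' @param cls Factor/character of GD2 classes.
#' @return Character vector `"positive"`/`"negative"`, names preserved.
#' @export
gd2_binary <- function(cls) {
  cls_chr <- .as_gd2_class(cls, names(cls) %||% seq_along(cls))
  out <- ifelse(cls_chr == "GD2-", "negative", "positive")
  names(out) <- names(cls)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phenotype table from flow records
#'
#' Convenience wrapper: RFI per cell line, three-level class, and binary
#' status, as one table ready to serve as ground truth.
#'
#' @param records Flow-record data.frame (see [compute_rfi()]).
#' @param boundaries Passed to [classify_rfi()].
#' @return data.frame: `cell_line`, `rfi`, `class`, `binary_status`.
#' @export
phenotype_table <- function(records, boundaries = c(1.5, 10)) {
  rfi <- compute_rfi(records)
  cls <- classify_rfi(rfi$rfi, boundaries)
  data.frame(cell_line = rfi$cell_line, rfi = rfi$rfi,
             class = as.character(cls),
             binary_status = unname(gd2_binary(cls)),
             stringsAsFactors = FALSE)
}

#' Read / write flow-cytometry records as CSV
#'
#' Columns: `cell_line`, `replicate`, `mfi_stained`, `mfi_unstained`.
#'
#' @param path File path.
#' @export
read_flow_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "replicate", "mfi_stained", "mfi_unstained")
  if (!all(need %in% names(df))) {
    stop("flow CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_flow_csv
#' @param records Flow-record data.frame.
#' @export
write_flow_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
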