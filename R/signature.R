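#' The six-gene ganglioside biosynthesis panel
#'
#' The panel covers the glycosyl/sialyltransferases around GD2: ST3GAL5
#' (GM3 synthase), ST8SIA1 (GD3 synthase) and B4GALNT1 (GD2 synthase) act
#' in the synthesis direction and carry sign +1; ST8SIA5 and B3GALT4
#' catalyze downstream reactions that consume GD2 and carry sign -1;
#' B4GALT6 supplies the upstream lactosylceramide and carries +1. The signs
#' are the ones applied when pair signatures are enumerated.
#'
#' @return A data.frame with columns `gene` and `sign`.
#' @export
gd2_panel <- function() {
  data.frame(
    gene = c("ST3GAL5", "ST8SIA1", "ST8SIA5", "B3GALT4", "B4GALNT1", "B4GALT6"),
    sign = c(1L, 1L, -1L, -1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Construct a gene-signature specification
#'
#' A signature is an ordered set of (gene, sign) terms; its score for a
#' sample is the signed sum of the genes' decimal-log expression values.
#' The canonical name joins the genes with "+" or "-" according to their
#' signs, positively-signed genes first (e.g. "ST8SIA1+B4GALNT1",
#' "B4GALT6-B3GALT4").
#'
#' @param genes Character vector of distinct gene symbols.
#' @param signs Integer vector of +1/-1, recycled if length 1.
#' @return An object of class `signature_spec` with elements `genes`,
#'   `signs`, `name`.
#' @export
signature_spec <- function(genes, signs = 1L) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    stop("genes within a signature must be distinct", call. = FALSE)
  }
  if (length(signs) == 1L) signs <- rep(signs, length(genes))
  signs <- as.integer(signs)
  if (length(signs) != length(genes) || !all(signs %in% c(-1L, 1L))) {
    stop("signs must be +1 or -1, one per gene", call. = FALSE)
  }
  structure(
    list(genes = genes, signs = signs, name = .signature_name(genes, signs)),
    class = "signature_spec"
  )
}

# Canonical name: positive genes first, then negative genes; within each
# sign group panel genes keep pathway (panel) order and other genes follow
# alphabetically. "+"/"-" separators, leading "+" omitted. This reproduces
# the field's strings, e.g. "ST8SIA1+B4GALNT1", "B4GALT6-B3GALT4".
.signature_name <- function(genes, signs) {
  panel_pos <- match(genes, gd2_panel()$gene)
  panel_pos[is.na(panel_pos)] <- length(gd2_panel()$gene) + 1L
  ord <- order(-signs, panel_pos, genes)
  genes <- genes[ord]
  signs <- signs[ord]
  sep <- ifelse(signs > 0, "+", "-")
  sep[1L] <- if (signs[1L] > 0) "" else "-"
  paste0(paste0(sep, genes), collapse = "")
}

#' @export
print.signature_spec <- function(x, ...) {
  cat("<signature_spec> ", x$name, "\n", sep = "")
  invisible(x)
}

#' The flagship ST8SIA1 + B4GALNT1 signature
#'
#' The two most GD2-proximal enzymes: GD3 synthase (ST8SIA1) and GD2
#' synthase (B4GALNT1), both with sign +1.
#'
#' @return A `signature_spec`.
#' @export
gd2_signature <- function() {
  signature_spec(c("ST8SIA1", "B4GALNT1"), c(1L, 1L))
}

#' Score a signature on a decimal-log expression matrix
#'
#' For each sample j the score is `sum over terms of sign *
#' logexpr[gene, j]`. A single-gene spec returns that gene's log-expression
#' row.
#'
#' @param logexpr Matrix of log10-transformed normalized expression
#'   (genes x samples, see [log10_transform()]).
#' @param spec A `signature_spec`.
#' @return Named numeric vector of per-sample scores.
#' @export
score_signature <- function(logexpr, spec) {
  stopifnot(inherits(spec, "signature_spec"))
  missing <- setdiff(spec$genes, rownames(logexpr))
  if (length(missing)) {
    stop("signature gene(s) absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- logexpr[spec$genes, , drop = FALSE]
  drop(crossprod(sub, spec$signs))[colnames(logexpr)]
}

#' Enumerate all 2-gene signatures over a panel
#'
#' All C(n, 2) unordered gene pairs, each gene carrying the sign assigned
#' to it by the panel. For the six-gene ganglioside panel this yields 15
#' candidate signatures. Order is deterministic: lexicographic by the
#' sorted gene pair.
#'
#' @param panel A panel data.frame with columns `gene` and `sign`
#'   (default [gd2_panel()]).
#' @return List of `signature_spec` objects.
#' @export
enumerate_pair_signatures <- function(panel = gd2_panel()) {
  stopifnot(is.data.frame(panel), all(c("gene", "sign") %in% names(panel)))
  if (anyDuplicated(panel$gene)) {
    stop("panel genes must be distinct", call. = FALSE)
  }
  genes <- sort(panel$gene)
  signs <- stats::setNames(panel$sign, panel$gene)
  pairs <- utils::combn(genes, 2L, simplify = FALSE)
  lapply(pairs, function(p) signature_spec(p, signs[p]))
}

#' Two-class congruence of signature scores
#'
#' A signature is congruent with known GD2 statuses when every
#' GD2-positive sample scores strictly higher than every GD2-negative
#' sample (ties fail).
#'
#' @param scores Named numeric score vector.
#' @param status Labels accepted by the package: named logical, or
#'   "positive"/"negative" character/factor, or an annotation data.frame.
#' @return `TRUE` or `FALSE`.
#' @export
check_congruence <- function(scores, status) {
  pos <- .as_binary_labels(status, names(scores))
  if (!any(pos) || all(pos)) {
    stop("both GD2 statuses must be present", call. = FALSE)
  }
  min(scores[pos]) > max(scores[!pos])
}

#' Three-level congruence (GD2++ / GD2+ / GD2-)
#'
#' Strict separation across all three phenotype tiers: every GD2++ score
#' exceeds every GD2+ score, and every GD2+ score exceeds every GD2-
#' score.
#'
#' @param scores Named numeric score vector.
#' @param cls Named vector/factor of classes "GD2++", "GD2+", "GD2-".
#' @return `TRUE` or `FALSE`.
#' @export
check_three_level_congruence <- function(scores, cls) {
  cls <- .as_gd2_class(cls, names(scores))
  by_class <- split(unname(scores), cls)
  if (any(lengths(by_class) == 0L)) {
    stop("all three GD2 classes must be present", call. = FALSE)
  }
  min(by_class[["GD2++"]]) > max(by_class[["GD2+"]]) &&
    min(by_class[["GD2+"]]) > max(by_class[["GD2-"]])
}

.gd2_levels <- c("GD2++", "GD2+", "GD2-")

.as_gd2_class <- function(cls, samples) {
  if (is.factor(cls)) cls <- stats::setNames(as.character(cls), names(cls))
  cls <- gsub("−", "-", cls)  # tolerate unicode minus
  bad <- setdiff(unique(cls), .gd2_levels)
  if (length(bad)) {
    stop("GD2 class must be one of GD2++, GD2+, GD2-; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(names(cls))) {
    missing <- setdiff(samples, names(cls))
    if (length(missing)) {
      stop("samples without class: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    cls <- cls[samples]
  } else if (length(cls) != length(samples)) {
    stop("unnamed classes must match the number of samples", call. = FALSE)
  }
  factor(cls, levels = .gd2_levels)
}

#' Serialize signature specs to / from JSON
#'
#' @param spec A `signature_spec` (or list of them for `specs_to_json`).
#' @param path File path.
#' @return `spec_from_json` returns a `signature_spec`.
#' @export
spec_to_json <- function(spec, path) {
  stopifnot(inherits(spec, "signature_spec"))
  jsonlite::write_json(
    list(name = spec$name, genes = spec$genes, signs = spec$signs),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname spec_to_json
#' @export
spec_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  signature_spec(x$genes, x$signs)
}

#' Write per-sample scores as two-column TSV
#'
#' @param scores Named numeric score vector.
#' @param path File path.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(
    data.frame(sample_id = names(scores), score = unname(scores)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
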