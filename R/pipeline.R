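#' Assemble a pipeline run configuration
#'
#' Exactly one expression source must be supplied: either file paths
#' (`counts` + `annotation`, optionally `pool` and `flow`) or a
#' [simulation_config()]. All randomness downstream of the input (label
#' permutations, random-pair draws) is controlled by `seed`, so the whole
#' report bundle is a pure function of the configuration.
#'
#' @param counts,annotation,pool,flow Input file paths (counts TSV,
#'   annotation TSV, gene-pool list, flow-cytometry CSV).
#' @param sim A `simulation_config` to generate the cohort instead.
#' @param pseudocount Pseudocount for [log10_transform()].
#' @param n_perm Label permutations per predictor in the panel evaluation.
#' @param n_pairs Random pairs for the null distribution (default 1000).
#' @param seed Integer seed for evaluation randomness.
#' @param out_dir Output directory for the report bundle.
#' @param fallback Size-factor fallback mode (see
#'   [estimate_size_factors()]).
#' @return A `run_config` list.
#' @export
run_config <- function(counts = NULL, annotation = NULL, pool = NULL,
                       flow = NULL, sim = NULL, pseudocount = 1,
                       n_perm = 100L, n_pairs = 1000L, seed = 1L,
                       out_dir = "gd2sig_report",
                       fallback = c("none", "poscounts")) {
  has_paths <- !is.null(counts) || !is.null(annotation)
  has_sim <- !is.null(sim)
  if (has_paths == has_sim) {
    .stop_input("supply exactly one of {counts+annotation paths, sim}")
  }
  if (has_paths && (is.null(counts) || is.null(annotation))) {
    .stop_input("both counts and annotation paths are required")
  }
  if (has_sim && !inherits(sim, "simulation_config")) {
    .stop_input("sim must be a simulation_config")
  }
  structure(
    list(counts = counts, annotation = annotation, pool = pool, flow = flow,
         sim = sim, pseudocount = pseudocount, n_perm = as.integer(n_perm),
         n_pairs = as.integer(n_pairs), seed = as.integer(seed),
         out_dir = out_dir, fallback = match.arg(fallback)),
    class = "run_config"
  )
}

.stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("gd2sig_input_error",
                                             "error", "condition")))
}

.stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("gd2sig_degenerate_error",
                                             "error", "condition")))
}

#' Rank sample types by aggregate signature score
#'
#' Per-type aggregate is the median of the per-sample signature scores
#' (robust to outlier samples); types are ordered by descending aggregate,
#' ties broken lexicographically by type label. This is the row ordering
#' the published heatmaps use.
#'
#' @param scores Named numeric per-sample score vector.
#' @param types Named character vector (or factor) mapping sample id to
#'   sample-type label; every sample must have a type.
#' @return data.frame: `type`, `median_score`, `n`, in ranked order.
#' @export
rank_sample_types <- function(scores, types) {
  if (is.factor(types)) types <- stats::setNames(as.character(types),
                                                 names(types))
  if (is.null(names(types))) {
    if (length(types) != length(scores)) {
      .stop_input("unnamed types must match the number of samples")
    }
    names(types) <- names(scores)
  }
  missing <- setdiff(names(scores), names(types))
  if (length(missing)) {
    .stop_input("samples without a type: ", paste(missing, collapse = ", "))
  }
  types <- types[names(scores)]
  med <- tapply(unname(scores), types, stats::median)
  n <- tapply(unname(scores), types, length)
  type <- names(med)
  ord <- order(-unname(med), type)
  data.frame(type = type[ord], median_score = unname(med)[ord],
             n = as.integer(unname(n)[ord]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Run the full analysis and write the report bundle
#'
#' Loads (or simulates) the cohort, normalizes counts by median-of-ratios
#' size factors, log10-transforms, scores the six panel genes and the
#' ST8SIA1 + B4GALNT1 signature, screens all 15 candidate pair signatures
#' for congruence, evaluates every predictor at the equal-error threshold
#' with permutation p-values, builds the random-pair null when a gene pool
#' is available, ranks sample types, and writes everything to
#' `config$out_dir`:
#'
#' * `per_sample_scores.tsv` — per-sample decimal-log expression of the
#'   six panel genes plus the signature score, sorted by descending
#'   signature score
#' * `congruence.tsv` — the 15 pair signatures with binary (and, when
#'   three-level classes are supplied, three-level) congruence flags
#' * `panel_evaluation.tsv` — predictor, MCC, threshold, confusion, p_perm
#' * `null_mccs.txt`, `null_summary.json` — random-pair null (if a pool
#'   with >= 2 matrix genes was supplied or simulated)
#' * `sample_type_ranking.tsv` — types by descending median score
#' * `size_factors.tsv`, `phenotypes.tsv` (if flow records supplied),
#'   `provenance.json`
#'
#' Identical configurations produce byte-identical bundles.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`scores`,
#'   `congruence`, `panel`, `null`, `ranking`, `size_factors`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$sim)) {
    dataset <- simulate_counts(config$sim)
    counts <- dataset$counts
    annotation <- data.frame(
      sample_id = names(dataset$labels),
      type = ifelse(dataset$labels == "positive", "GD2pos", "GD2neg"),
      status = unname(dataset$labels), stringsAsFactors = FALSE)
    pool <- dataset$pool_genes
  } else {
    if (!file.exists(config$counts)) .stop_input("counts file not found: ",
                                                 config$counts)
    if (!file.exists(config$annotation)) {
      .stop_input("annotation file not found: ", config$annotation)
    }
    counts <- tryCatch(read_counts_tsv(config$counts),
                       error = function(e) .stop_input("malformed counts TSV: ",
                                                       conditionMessage(e)))
    annotation <- tryCatch(read_annotation_tsv(config$annotation),
                           error = function(e) .stop_input("malformed annotation TSV: ",
                                                           conditionMessage(e)))
    pool <- if (!is.null(config$pool)) read_pool(config$pool) else character(0)
  }
  extra <- setdiff(annotation$sample_id, colnames(counts))
  if (length(extra) || !all(colnames(counts) %in% annotation$sample_id)) {
    .stop_input("annotation and count matrix sample sets differ")
  }
  annotation <- annotation[match(colnames(counts), annotation$sample_id), ]
  statuses <- unique(annotation$status)
  if (length(statuses) < 2L) {
    .stop_degenerate("all samples share the single class '", statuses,
                     "'; both GD2 statuses are required")
  }
  panel <- gd2_panel()
  missing <- setdiff(panel$gene, rownames(counts))
  if (length(missing)) {
    .stop_input("panel gene(s) missing from the count matrix: ",
                paste(missing, collapse = ", "))
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- stats::setNames(annotation$status, annotation$sample_id)

  s <- estimate_size_factors(counts, fallback = config$fallback)
  logexpr <- log10_transform(normalize_counts(counts, s), config$pseudocount)
  signature <- gd2_signature()
  sig_scores <- score_signature(logexpr, signature)

  # (a) per-sample score table, sorted by descending signature score
  score_tab <- data.frame(sample_id = colnames(logexpr),
                          status = unname(labels),
                          t(logexpr[panel$gene, , drop = FALSE]),
                          signature = unname(sig_scores),
                          check.names = FALSE, stringsAsFactors = FALSE)
  score_tab <- score_tab[order(-score_tab$signature, score_tab$sample_id), ]
  utils::write.table(score_tab, file.path(config$out_dir, "per_sample_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # (b) 15-pair congruence screen
  specs <- enumerate_pair_signatures(panel)
  has_classes <- "class" %in% names(annotation) &&
    !anyNA(annotation$class) &&
    length(unique(annotation$class)) == 3L
  congruence <- do.call(rbind, lapply(specs, function(sp) {
    sc <- score_signature(logexpr, sp)
    three <- if (has_classes) {
      check_three_level_congruence(sc, stats::setNames(annotation$class,
                                                       annotation$sample_id))
    } else NA
    data.frame(signature = sp$name,
               congruent = check_congruence(sc, labels),
               three_level_congruent = three, stringsAsFactors = FALSE)
  }))
  utils::write.table(congruence, file.path(config$out_dir, "congruence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # (c) per-predictor evaluation (6 genes + signature)
  panel_evals <- evaluate_panel(logexpr, labels, panel, signature,
                                n_perm = config$n_perm, seed = config$seed)
  ptab <- panel_table(panel_evals)
  write_panel_tsv(ptab, file.path(config$out_dir, "panel_evaluation.tsv"))

  # (d) random-pair null
  null <- NULL
  pool_present <- intersect(pool, rownames(counts))
  if (length(pool_present) >= 2L) {
    null <- random_pair_null(logexpr, labels, pool_present,
                             n_pairs = config$n_pairs,
                             seed = config$seed + 1L, observed = signature)
    write_null_distribution(null, file.path(config$out_dir, "null_mccs.txt"),
                            file.path(config$out_dir, "null_summary.json"))
  }

  # (e) sample-type ranking
  ranking <- NULL
  if ("type" %in% names(annotation)) {
    ranking <- rank_sample_types(sig_scores,
                                 stats::setNames(annotation$type,
                                                 annotation$sample_id))
    utils::write.table(ranking,
                       file.path(config$out_dir, "sample_type_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # flow phenotyping (optional)
  phenotypes <- NULL
  if (!is.null(config$flow) && is.character(config$flow)) {
    phenotypes <- phenotype_table(read_flow_csv(config$flow))
    utils::write.table(phenotypes, file.path(config$out_dir, "phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  write_size_factors_tsv(s, file.path(config$out_dir, "size_factors.tsv"))

  # (f) provenance: full configuration, versions; no timestamp so that
  # identical configs give byte-identical bundles
  prov <- list(
    config = .config_provenance(config),
    package = "gd2sig",
    package_version = as.character(utils::packageVersion("gd2sig")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  invisible(list(scores = score_tab, congruence = congruence, panel = ptab,
                 null = null, ranking = ranking, size_factors = s,
                 phenotypes = phenotypes))
}

.config_provenance <- function(config) {
  out <- unclass(config)
  if (!is.null(out$sim)) out$sim <- unclass(out$sim)
  # out_dir is where the bundle lives, not what it contains; dropping it
  # keeps bundles from identical analyses byte-identical across locations
  out$out_dir <- NULL
  out[!vapply(out, is.null, logical(1))]
}
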