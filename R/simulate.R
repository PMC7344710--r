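#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the statistical structure the downstream
#' analysis assumes: two sample groups (GD2-positive / GD2-negative),
#' negative-binomial read counts whose group-specific mean shifts are
#' concentrated on ST8SIA1 and B4GALNT1, an uninformative background gene
#' pool (the random-pair null pool), and log-normal per-sample library
#' sizes. All parameters are free choices reported in the output metadata;
#' they are not estimates of any real cohort.
#'
#' Defaults: 200 + 200 samples; baseline negative-group means for the six
#' panel genes spanning the range typical of moderately expressed
#' transferase genes in bulk RNA-seq; log2 fold-change +1 on ST8SIA1 and
#' B4GALNT1 in the positive group and 0 elsewhere; NB dispersion 0.1
#' (variance = mu + 0.1 mu^2); 520 background genes (the size of the GO
#' lipid-metabolism pool) with baseline means uniform on [10, 1000];
#' library-size log-SD 0.3.
#'
#' @param n_pos,n_neg Number of GD2-positive / GD2-negative samples.
#' @param panel_means Named vector of baseline (negative-group) mean
#'   counts; must contain all six panel genes.
#' @param log2_effects Named vector of log2 fold-changes applied in the
#'   positive group (genes not named get 0; background genes may be named
#'   to inject effects for null-robustness experiments).
#' @param dispersion NB dispersion, scalar or per-gene named vector; 0
#'   gives Poisson counts.
#' @param n_background Number of uninformative pool genes.
#' @param background_mean_range Length-2 interval for background baseline
#'   means.
#' @param libsize_log_sd SD of the per-sample log library-size factor.
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_pos = 200L, n_neg = 200L,
                              panel_means = c(ST3GAL5 = 2000, ST8SIA1 = 150,
                                              ST8SIA5 = 50, B3GALT4 = 400,
                                              B4GALNT1 = 100, B4GALT6 = 800),
                              log2_effects = c(ST8SIA1 = 1, B4GALNT1 = 1),
                              dispersion = 0.1,
                              n_background = 520L,
                              background_mean_range = c(10, 1000),
                              libsize_log_sd = 0.3,
                              seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1, n_background >= 0,
            all(dispersion >= 0), libsize_log_sd >= 0,
            length(background_mean_range) == 2L,
            background_mean_range[1L] > 0,
            background_mean_range[1L] <= background_mean_range[2L])
  panel <- gd2_panel()$gene
  missing <- setdiff(panel, names(panel_means))
  if (length(missing)) {
    stop("panel_means must include all six panel genes; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(panel_means <= 0)) {
    stop("panel means must be positive", call. = FALSE)
  }
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         panel_means = panel_means, log2_effects = log2_effects,
         dispersion = dispersion, n_background = as.integer(n_background),
         background_mean_range = background_mean_range,
         libsize_log_sd = libsize_log_sd, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a two-group RNA-seq cohort
#'
#' Counts for gene g in sample j are drawn from a negative binomial with
#' mean `L_j * mu_g * 2^(beta_g * I[j positive])` and variance
#' `mu + dispersion * mu^2`, where `L_j = exp(N(0, libsize_log_sd^2))` is
#' the sample's library-size factor. Dispersion 0 degrades to Poisson.
#' Background pool genes are i.i.d. with baseline means drawn uniformly
#' from `background_mean_range` and, by default, no group effect.
#' Identical config (including seed) reproduces the matrix bit-exactly.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_dataset`: list with `counts` (matrix), `labels`
#'   (named "positive"/"negative"), `true_params` (the config),
#'   `pool_genes` (background gene symbols).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  panel_genes <- names(config$panel_means)
  bg_genes <- if (config$n_background > 0) {
    sprintf("POOL%04d", seq_len(config$n_background))
  } else character(0)
  if (length(intersect(panel_genes, bg_genes))) {
    stop("duplicate gene symbols between panel and background pool",
         call. = FALSE)
  }
  genes <- c(panel_genes, bg_genes)
  n <- config$n_pos + config$n_neg
  samples <- c(sprintf("POS%04d", seq_len(config$n_pos)),
               sprintf("NEG%04d", seq_len(config$n_neg)))
  is_pos <- c(rep(TRUE, config$n_pos), rep(FALSE, config$n_neg))

  bg_means <- stats::runif(config$n_background,
                           config$background_mean_range[1L],
                           config$background_mean_range[2L])
  base_mu <- c(unname(config$panel_means), bg_means)
  beta <- rep(0, length(genes))
  names(beta) <- genes
  eff <- config$log2_effects[names(config$log2_effects) %in% genes]
  beta[names(eff)] <- eff

  # scalar dispersion applies to all genes; a named vector overrides the
  # package default (0.1) gene by gene
  disp <- config$dispersion
  if (is.null(names(disp))) {
    disp <- rep(disp, length.out = length(genes))
  } else {
    d <- rep(0.1, length(genes))
    names(d) <- genes
    hit <- intersect(names(disp), genes)
    d[hit] <- disp[hit]
    disp <- unname(d)
  }

  L <- exp(stats::rnorm(n, 0, config$libsize_log_sd))
  mu <- outer(base_mu, L) * 2^(outer(beta, as.numeric(is_pos)))
  counts <- matrix(0, nrow = length(genes), ncol = n,
                   dimnames = list(genes, samples))
  for (g in seq_along(genes)) {
    counts[g, ] <- if (disp[g] == 0) {
      stats::rpois(n, mu[g, ])
    } else {
      stats::rnbinom(n, size = 1 / disp[g], mu = mu[g, ])
    }
  }
  structure(
    list(counts = counts,
         labels = stats::setNames(ifelse(is_pos, "positive", "negative"),
                                  samples),
         true_params = config,
         pool_genes = bg_genes),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d genes x %d samples (%d positive, %d negative), seed %d\n",
              nrow(x$counts), ncol(x$counts), sum(x$labels == "positive"),
              sum(x$labels == "negative"), x$true_params$seed))
  invisible(x)
}

#' Simulate replicate flow-cytometry MFI records
#'
#' Each cell line has a target RFI; per replicate an unstained MFI is
#' drawn around a baseline of 100 and the stained MFI is the unstained
#' value times the target RFI times multiplicative log-normal noise with
#' coefficient of variation `noise_cv` (mean exactly 1), so the expected
#' stained/unstained ratio equals the target RFI. `noise_cv = 0` gives
#' exact ratios.
#'
#' @param cell_line_rfis Named numeric vector: target RFI per cell line
#'   (all > 0).
#' @param n_replicates Replicates per cell line (>= 1; flow experiments
#'   are typically run in at least three replicates).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return data.frame of flow records (see [read_flow_csv()]).
#' @export
simulate_flow_records <- function(cell_line_rfis, n_replicates = 3L,
                                  noise_cv = 0.1, seed = 1L) {
  if (is.null(names(cell_line_rfis)) || any(cell_line_rfis <= 0)) {
    stop("cell_line_rfis must be a named vector of positive target RFIs",
         call. = FALSE)
  }
  stopifnot(n_replicates >= 1, noise_cv >= 0)
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  rnoise <- function(k) {
    if (noise_cv == 0) rep(1, k) else exp(stats::rnorm(k, -sdlog^2 / 2, sdlog))
  }
  out <- lapply(names(cell_line_rfis), function(cl) {
    unstained <- 100 * rnoise(n_replicates)
    stained <- unstained * cell_line_rfis[[cl]] * rnoise(n_replicates)
    data.frame(cell_line = cl, replicate = seq_len(n_replicates),
               mfi_stained = stained, mfi_unstained = unstained,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a simulated dataset to a directory
#'
#' Emits `counts.tsv` (gene x sample matrix), `annotation.tsv`
#' (sample_id, type, status), `pool.txt` (one background gene per line)
#' and `simulation_config.json` (the generating parameters, so the
#' synthetic provenance is always on disk next to the data).
#'
#' @param dataset A `simulated_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts_tsv(dataset$counts, file.path(dir, "counts.tsv"))
  ann <- data.frame(sample_id = names(dataset$labels),
                    type = ifelse(dataset$labels == "positive",
                                  "GD2pos", "GD2neg"),
                    status = unname(dataset$labels),
                    stringsAsFactors = FALSE)
  write_annotation_tsv(ann, file.path(dir, "annotation.tsv"))
  write_pool(dataset$pool_genes, file.path(dir, "pool.txt"))
  cfg <- unclass(dataset$true_params)
  jsonlite::write_json(cfg, file.path(dir, "simulation_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
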