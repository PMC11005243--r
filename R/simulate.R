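# Multi-study synthetic RNA-seq generator. The generative model, on the
# log2 scale:
#   value[g, i] = baseline[g] + batch_shift[g, study(i)]
#                 + class_effect[g, label(i)] + Normal(0, noise_sd)
# where the class effect is planted on gene *pairs*: for each planted
# pair (x, y), responders get x shifted +delta/2 and y shifted -delta/2
# and non-responders the reverse, so the informative signal lives exactly
# in the relative-ordering feature space. Values are then exponentiated,
# multiplied by a per-sample strictly positive scale factor
# exp(Normal(0, batch_sample_scale_sd)) -- a monotone within-sample
# distortion -- and normalized to TPM. Response annotations are emitted
# in study-specific vocabularies to exercise annotation standardization.

#' Configuration for the multi-study simulator
#'
#' Defaults emulate the three-melanoma-cohort setting the pipeline is
#' designed for: studies of 42, 27 and 56 patients with roughly one third
#' responders, a 26-gene checkpoint panel on top of 2,000 background
#' genes, per-study batch distortions, and a planted class signal on 10
#' anchor-containing pairs.
#'
#' @param samples_per_study Integer sample sizes, one per study (each >=
#'   4); default `c(42, 27, 56)`.
#' @param response_rate Probability a patient responds (default 1/3).
#' @param n_background_genes Number of non-panel genes (default 2000).
#' @param panel Checkpoint panel tibble (default [checkpoint_panel()]).
#' @param n_planted_pairs Number of informative pairs drawn from
#'   [enumerate_pairs()] when `planted_pairs` is `NULL` (default 10).
#' @param planted_pairs Optional explicit pair tibble (subset of the
#'   enumerable pairs) to plant the class signal on.
#' @param effect_delta Log2-scale mean separation driving class-dependent
#'   pair orderings (>= 0; 0 = null data).
#' @param batch_gene_shift_sd SD of the per-gene, per-study log2 shift
#'   (the batch effect; default 1).
#' @param batch_sample_scale_sd SD of the per-sample log scale factor, a
#'   monotone within-sample distortion (default 0.2).
#' @param noise_sd Residual log2-scale noise SD (> 0, default 1).
#' @param baseline_mean,baseline_sd Log2-scale distribution of per-gene
#'   baseline expression (defaults 5 and 2).
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the config.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(samples_per_study = c(42, 27, 56),
                              response_rate = 1 / 3,
                              n_background_genes = 2000,
                              panel = checkpoint_panel(),
                              n_planted_pairs = 10,
                              planted_pairs = NULL,
                              effect_delta = 1,
                              batch_gene_shift_sd = 1,
                              batch_sample_scale_sd = 0.2,
                              noise_sd = 1,
                              baseline_mean = 5, baseline_sd = 2,
                              seed = 1) {
  cfg <- list(samples_per_study = as.integer(samples_per_study),
              response_rate = response_rate,
              n_background_genes = as.integer(n_background_genes),
              panel = panel, n_planted_pairs = as.integer(n_planted_pairs),
              planted_pairs = planted_pairs, effect_delta = effect_delta,
              batch_gene_shift_sd = batch_gene_shift_sd,
              batch_sample_scale_sd = batch_sample_scale_sd,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (length(cfg$samples_per_study) < 1 || any(cfg$samples_per_study < 4)) {
    abort("each study needs at least 4 samples")
  }
  if (cfg$response_rate <= 0 || cfg$response_rate >= 1) {
    abort("response_rate must be in (0, 1)")
  }
  if (min(cfg$samples_per_study) * cfg$response_rate < 1) {
    abort("infeasible config: expected responders per study below 1")
  }
  if (cfg$effect_delta < 0 || cfg$batch_gene_shift_sd < 0 ||
      cfg$batch_sample_scale_sd < 0) {
    abort("effect and distortion magnitudes must be >= 0")
  }
  if (cfg$noise_sd <= 0) abort("noise_sd must be > 0")
  validate_panel(cfg$panel)
  if (!is.null(cfg$planted_pairs)) {
    all_pairs <- enumerate_pairs(cfg$panel)
    if (!all(cfg$planted_pairs$pair %in% all_pairs$pair)) {
      abort("planted_pairs must be a subset of enumerate_pairs(panel)")
    }
  } else if (cfg$n_planted_pairs > nrow(enumerate_pairs(cfg$panel))) {
    abort("n_planted_pairs exceeds the number of enumerable pairs")
  }
  invisible(cfg)
}

# Default planted set: a "star" of pairs sharing one randomly chosen
# anchor hub (high in responders) against distinct non-anchor partners
# (low in responders). Confining the shifted genes to the planted pairs'
# own genes means no *other* candidate pair contains two shifted genes,
# so non-planted pairs carry at most half the planted separation -- the
# planted signal lives exactly where it is declared.
default_planted_pairs <- function(cfg, pairs) {
  anchors <- cfg$panel$gene_id[cfg$panel$is_anchor]
  partners <- cfg$panel$gene_id[!cfg$panel$is_anchor]
  if (cfg$n_planted_pairs > length(partners)) {
    abort("default planting needs n_planted_pairs <= non-anchor panel genes")
  }
  hub <- anchors[sample.int(length(anchors), 1)]
  second <- sort(sample(partners, cfg$n_planted_pairs))
  planted <- tibble(first = hub, second = second,
                    pair = paste0(hub, ">", second))
  stopifnot(all(planted$pair %in% pairs$pair))
  planted
}

# study-specific annotation vocabularies, cycled over studies
annotation_vocabularies <- list(
  list(response = c("Complete Response", "Partial Response"),
       `non-response` = c("Progressive Disease", "Stable Disease")),
  list(response = c("CR", "PR"),
       `non-response` = c("PD", "SD")),
  list(response = c("complete response", "partial response"),
       `non-response` = c("nonresponse", "progressive disease"))
)

#' Simulate multi-study expression data with a planted pair signal
#'
#' Generates one [study_dataset()] per entry of `samples_per_study` under
#' the generative model described in the package vignette, plus the
#' ground truth needed for recovery testing. Reproducible: the output is
#' a deterministic function of the config (including its seed). If a
#' study draws a single-class label vector it is redrawn from the running
#' RNG stream (with a message), so every study has both classes.
#'
#' @param config A [simulation_config()].
#' @return A list of class `icb_simulation`: `studies` (list of
#'   `study_dataset`), `truth` (labels, planted pairs, per-study gene
#'   shifts, per-sample scale factors, gene lengths, config).
#' @export
simulate_studies <- function(config) {
  validate_simulation_config(config)
  cfg <- config
  set.seed(cfg$seed)

  panel_genes <- cfg$panel$gene_id
  bg <- if (cfg$n_background_genes > 0) {
    sprintf("BG%04d", seq_len(cfg$n_background_genes))
  } else character(0)
  genes <- c(panel_genes, bg)
  n_genes <- length(genes)

  baseline <- rnorm(n_genes, cfg$baseline_mean, cfg$baseline_sd)
  names(baseline) <- genes
  lengths <- tibble(gene_id = genes,
                    length_kb = round(runif(n_genes, 0.5, 8), 3))

  pairs <- enumerate_pairs(cfg$panel)
  planted <- cfg$planted_pairs %||% default_planted_pairs(cfg, pairs)

  # Planted pairs are baseline-matched: the second gene inherits the
  # first gene's baseline, so the pair's ordering is driven by the class
  # shifts and noise alone and its class-conditional frequency difference
  # equals 2*pnorm(effect_delta / (sqrt(2) * noise_sd)) - 1. Without
  # this, a planted pair whose genes happen to sit far apart at baseline
  # is frozen in one orientation and carries no signal.
  baseline[planted$second] <- baseline[planted$first]

  # Per-gene class shift implied by the planted pairs: +delta/2 for genes
  # on the high-in-responders side, -delta/2 for the low side. The shift
  # is role-based, not summed over pairs, so every planted pair's
  # indicator has the closed-form class-frequency difference
  # 2*pnorm(delta / (sqrt(2) * noise_sd)) - 1 regardless of how often a
  # gene (e.g. an anchor) recurs across planted pairs.
  first_role <- genes %in% planted$first
  second_role <- genes %in% planted$second
  if (any(first_role & second_role)) {
    warn("gene(s) on both sides of planted pairs get a net zero class shift")
  }
  class_shift <- setNames(
    (first_role - second_role) * cfg$effect_delta / 2, genes)

  n_studies <- length(cfg$samples_per_study)
  studies <- vector("list", n_studies)
  shifts <- vector("list", n_studies)
  scales <- vector("list", n_studies)
  for (b in seq_len(n_studies)) {
    n <- cfg$samples_per_study[b]
    study_id <- sprintf("study%d", b)
    labels01 <- rbinom(n, 1, cfg$response_rate)
    while (length(unique(labels01)) < 2) {
      message("redrawing labels for ", study_id,
              " to ensure both classes are present")
      labels01 <- rbinom(n, 1, cfg$response_rate)
    }
    shift <- rnorm(n_genes, 0, cfg$batch_gene_shift_sd)
    names(shift) <- genes
    # antisymmetric class effect: responders +shift, non-responders -shift
    eff <- outer(class_shift, ifelse(labels01 == 1, 1, -1))
    lg <- baseline + shift + eff +
      matrix(rnorm(n_genes * n, 0, cfg$noise_sd), n_genes, n)
    sample_scale <- exp(rnorm(n, 0, cfg$batch_sample_scale_sd))
    lin <- sweep(2^lg, 2, sample_scale, "*")
    tpm <- sweep(lin, 2, colSums(lin), "/") * 1e6
    sample_ids <- sprintf("%s_s%02d", study_id, seq_len(n))
    dimnames(tpm) <- list(genes, sample_ids)

    voc <- annotation_vocabularies[[(b - 1) %% 3 + 1]]
    annotation <- ifelse(
      labels01 == 1,
      sample(voc$response, n, replace = TRUE),
      sample(voc$`non-response`, n, replace = TRUE))
    metadata <- tibble(sample_id = sample_ids,
                       response_annotation = annotation) |>
      standardize_response()

    studies[[b]] <- study_dataset(
      study_id, expression_from_matrix(tpm, "TPM"), metadata)
    shifts[[b]] <- shift
    scales[[b]] <- setNames(sample_scale, sample_ids)
  }
  names(studies) <- names(shifts) <- names(scales) <-
    vapply(studies, function(s) s$study_id, character(1))

  structure(list(
    studies = studies,
    truth = list(
      labels = bind_rows(map(studies, "metadata"))[
        , c("sample_id", "study_id", "label")],
      planted_pairs = planted,
      class_shift = class_shift,
      batch_gene_shifts = shifts,
      sample_scales = scales,
      gene_lengths = lengths,
      config = cfg)
  ), class = "icb_simulation")
}

#' @export
print.icb_simulation <- function(x, ...) {
  cat(sprintf(
    "<icb_simulation: %d studies (%s samples), %d planted pairs, delta %.2g>\n",
    length(x$studies),
    paste(x$truth$config$samples_per_study, collapse = "/"),
    nrow(x$truth$planted_pairs), x$truth$config$effect_delta))
  invisible(x)
}

#' Permute a study's labels (negative control)
#'
#' Returns the study with its label rows permuted uniformly at random
#' (annotation and binary label travel together); expression is
#' untouched. Useful as a null harness: downstream cross-validated AUC on
#' permuted labels should hover around 0.5.
#'
#' @param study A [study_dataset()].
#' @param seed Integer seed making the permutation reproducible.
#' @return A `study_dataset` with permuted labels.
#' @export
null_permutation <- function(study, seed) {
  stopifnot(inherits(study, "study_dataset"))
  set.seed(seed)
  perm <- sample.int(nrow(study$metadata))
  metadata <- study$metadata
  keep <- c("sample_id", "study_id")
  shuffled <- metadata[perm, setdiff(names(metadata), keep), drop = FALSE]
  metadata <- bind_cols(metadata[keep], shuffled)
  study_dataset(study$study_id, study$expression,
                metadata[setdiff(names(metadata), "study_id")])
}

#' Write a simulation to disk as plain-text files
#'
#' One expression TSV per study, a combined metadata TSV (`sample_id`,
#' `study_id`, `response_annotation`), a gene-length TSV, the panel TSV
#' and a ground-truth JSON -- the input layout expected by
#' [experiment_config()].
#'
#' @param sim An [simulate_studies()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "icb_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in sim$studies) {
    write_expression(s$expression,
                     file.path(dir, paste0(s$study_id, "_expression.tsv")))
  }
  metadata <- bind_rows(map(sim$studies, "metadata"))
  readr::write_tsv(
    metadata[c("sample_id", "study_id", "response_annotation")],
    file.path(dir, "metadata.tsv"))
  readr::write_tsv(sim$truth$gene_lengths,
                   file.path(dir, "gene_lengths.tsv"))
  readr::write_tsv(
    mutate(sim$truth$config$panel, is_anchor = as.integer(.data$is_anchor)),
    file.path(dir, "panel.tsv"))
  truth <- list(
    planted_pairs = sim$truth$planted_pairs$pair,
    labels = sim$truth$labels,
    seed = sim$truth$config$seed,
    effect_delta = sim$truth$config$effect_delta
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
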