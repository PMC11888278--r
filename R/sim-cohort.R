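#' Draw the gene programs underlying a synthetic cohort
#'
#' Partitions a slice of the gene universe into disjoint programs: a shared
#' positive age program (log-expression rises with age in every class), a
#' shared negative program, per-study age programs (active only in their
#' study), and per-class marker genes (low baseline, strong in-class boost).
#' Remaining genes get stable baselines.
#'
#' @param config A [sim_config()].
#' @return A list of class `"gene_programs"` with elements `shared_pos`,
#'   `shared_neg`, `study_specific` (list study -> genes), `markers`
#'   (list class -> genes), and `baseline_log_means` (named numeric over the
#'   whole universe).
#' @export
generate_programs <- function(config) {
  validate_sim_config(config)
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  studies <- sprintf("study%d", seq_len(config$n_studies))
  seeds <- child_seeds(config$seed, 1L)
  with_seed(seeds[1], {
    baseline <- stats::setNames(stats::rnorm(config$n_genes, 0, 1), genes)
    pool <- sample(genes)
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    shared_pos <- take(config$n_shared_pos_genes)
    shared_neg <- take(config$n_shared_neg_genes)
    study_specific <- stats::setNames(
      lapply(studies, function(s) take(config$n_study_specific_age_genes)),
      studies)
    markers <- stats::setNames(
      lapply(config$cell_classes,
             function(cl) take(config$n_marker_genes_per_class)),
      config$cell_classes)
    baseline[unlist(markers)] <- config$marker_baseline
    structure(
      list(shared_pos = shared_pos, shared_neg = shared_neg,
           study_specific = study_specific, markers = markers,
           baseline_log_means = baseline, genes = genes),
      class = "gene_programs")
  })
}

# Per-gene age slopes for one study: shared programs everywhere,
# study-specific genes (alternating sign) only in their own study.
gene_age_slopes <- function(config, programs, study_id) {
  slopes <- stats::setNames(numeric(config$n_genes), programs$genes)
  slopes[programs$shared_pos] <- config$age_effect_size
  slopes[programs$shared_neg] <- -config$age_effect_size
  own <- programs$study_specific[[study_id]]
  if (!is.null(own) && length(own)) {
    slopes[own] <- rep_len(c(1, -1), length(own)) * config$age_effect_size
  }
  slopes
}

# Evenly spaced age grid with jitter; >= 4 distinct ages enforced by
# construction (grid spacing dominates the jitter, then uniqueness is checked).
draw_ages <- function(config) {
  rng <- config$age_range_weeks
  grid <- seq(rng[1], rng[2], length.out = config$samples_per_study)
  ages <- grid + stats::rnorm(config$samples_per_study, 0, config$age_jitter_sd)
  ages <- pmin(pmax(ages, rng[1]), rng[2])
  ages <- round(ages, 1)
  if (length(unique(ages)) < min(4L, config$samples_per_study)) {
    ages <- round(grid, 1)  # degenerate jitter collision: fall back to the grid
  }
  sort(ages)
}

# Core sampler shared by the human, organoid and cross-species generators.
# `latent_ages` drive expression and composition; `native` is the observed
# time axis recorded in the cell table.
simulate_profiles <- function(config, programs, study_id, latent_ages,
                              native, native_col) {
  k <- length(config$cell_classes)
  conserved <- config$cell_classes %in% config$conserved_classes
  offset_sd <- ifelse(conserved,
                      config$composition_offset_sd * config$conserved_offset_factor,
                      config$composition_offset_sd)
  comp_offsets <- stats::setNames(stats::rnorm(k, 0, offset_sd),
                                  config$cell_classes)
  batch <- stats::setNames(stats::rnorm(config$n_genes, 0, config$batch_sd),
                           programs$genes)
  slopes <- gene_age_slopes(config, programs, study_id)
  baseline <- programs$baseline_log_means[programs$genes]
  size <- 1 / config$nb_dispersion
  meanlog <- log(config$mean_libsize) - config$libsize_lognormal_sd^2 / 2

  true_props <- composition_trajectory(config, latent_ages, comp_offsets)
  blocks <- vector("list", length(latent_ages))
  meta <- vector("list", length(latent_ages))
  for (i in seq_along(latent_ages)) {
    age <- latent_ages[i]
    sample_id <- sprintf("%s_s%02d", study_id, i)
    n_cells <- as.vector(stats::rmultinom(1, config$cells_per_sample,
                                          true_props[i, ]))
    eta_base <- baseline + slopes * age + batch
    cls_blocks <- vector("list", k)
    for (j in seq_len(k)) {
      m <- n_cells[j]
      if (m == 0L) next
      eta <- eta_base
      mk <- programs$markers[[config$cell_classes[j]]]
      if (!is.null(mk)) eta[mk] <- eta[mk] + config$marker_boost
      rate <- exp(eta - max(eta))
      rate <- rate / sum(rate)
      lib <- stats::rlnorm(m, meanlog, config$libsize_lognormal_sd)
      mu <- outer(rate, lib)
      cls_blocks[[j]] <- matrix(
        stats::rnbinom(length(mu), mu = mu, size = size),
        nrow = config$n_genes)
    }
    counts <- do.call(cbind, cls_blocks[!vapply(cls_blocks, is.null, TRUE)])
    blocks[[i]] <- counts
    cls <- rep(config$cell_classes, n_cells)
    meta[[i]] <- data.frame(
      cell_id = sprintf("%s_c%04d", sample_id, seq_along(cls)),
      study = study_id,
      sample_id = sample_id,
      age_weeks = age,
      native_time = native[i],
      author_cell_type = paste0(cls, "_author"),
      broad_class = cls,
      stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, blocks)
  cells <- do.call(rbind, meta)
  if (!is.null(native_col)) names(cells)[names(cells) == "native_time"] <- native_col
  else cells$native_time <- NULL
  rownames(counts) <- programs$genes
  colnames(counts) <- cells$cell_id
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  list(counts = counts, cells = cells,
       truth = list(study = study_id, latent_ages = latent_ages,
                    native = native, comp_offsets = comp_offsets,
                    true_proportions = true_props))
}

#' Simulate one fetal-brain-like study
#'
#' Draws donor ages on a jittered grid, study-specific composition offsets and
#' batch effects, then negative-binomial counts for every cell.
#'
#' @param config A [sim_config()].
#' @param programs Output of [generate_programs()] on the same config.
#' @param study_id Study label (e.g. `"study1"`); selects that study's
#'   study-specific age program.
#' @param seed Integer seed for this study.
#' @return List with `counts` (sparse gene x cell matrix), `cells`
#'   (per-cell data.frame with study, sample_id, age_weeks, author_cell_type,
#'   broad_class) and `truth` (composition offsets, noise-free proportions).
#' @export
simulate_study <- function(config, programs, study_id, seed) {
  with_seed(seed, {
    ages <- draw_ages(config)
    simulate_profiles(config, programs, study_id, ages, ages, NULL)
  })
}

#' Simulate a complete multi-study cohort
#'
#' @param config A [sim_config()].
#' @return List of class `"synthetic_cohort"`: `studies` (named list of
#'   [simulate_study()] outputs), `programs`, `config`.
#' @export
simulate_cohort <- function(config) {
  programs <- generate_programs(config)
  seeds <- child_seeds(config$seed, config$n_studies + 1L)[-1L]
  ids <- sprintf("study%d", seq_len(config$n_studies))
  studies <- stats::setNames(
    lapply(seq_along(ids),
           function(i) simulate_study(config, programs, ids[i], seeds[i])),
    ids)
  structure(list(studies = studies, programs = programs, config = config),
            class = "synthetic_cohort")
}

#' Simulate an organoid-like cohort with compressed developmental tempo
#'
#' The latent transcriptomic age that drives expression and composition is an
#' affine map of culture time: latent = offset_weeks + tempo * culture_weeks.
#' With `tempo = 1` and `offset_weeks = 0` the generator is identical to
#' [simulate_study()] under the same seed.
#'
#' @inheritParams simulate_study
#' @param tempo Maturation rate relative to gestational time; must be > 0.
#' @param offset_weeks Latent age at culture time 0 (protocol offset).
#' @return As [simulate_study()]; `cells` carries `culture_age_days`, and
#'   `truth` stores the latent ages and the tempo/offset used.
#' @export
simulate_organoid_cohort <- function(config, programs, tempo, offset_weeks,
                                     seed, study_id = "organoid1") {
  if (!is.numeric(tempo) || tempo <= 0) stop("tempo must be > 0")
  with_seed(seed, {
    latent <- draw_ages(config)
    culture_days <- (latent - offset_weeks) / tempo * 7
    out <- simulate_profiles(config, programs, study_id, latent,
                             culture_days, "culture_age_days")
    out$truth$tempo <- tempo
    out$truth$offset_weeks <- offset_weeks
    out
  })
}

#' Simulate a mouse-like cross-species cohort with an ortholog map
#'
#' Latent transcriptomic age is `tempo * embryonic_day / 7` gestational weeks,
#' emulating the accelerated developmental tempo of the mouse. A random
#' one-to-one ortholog map over `ortholog_fraction` of the universe renames
#' the retained genes; unmapped genes are absent from the foreign matrix.
#'
#' @inheritParams simulate_study
#' @param ortholog_fraction Fraction of the gene universe with a one-to-one
#'   ortholog (0 < fraction <= 1).
#' @param tempo Acceleration factor (weeks of human development per week of
#'   foreign development).
#' @param e_day_range Embryonic-day span sampled (jittered grid).
#' @return List with `counts` (foreign gene names), `cells` (carries
#'   `embryonic_day`), `ortholog_map` (data.frame `source` = reference symbol,
#'   `target` = foreign symbol) and `truth`.
#' @export
simulate_cross_species_cohort <- function(config, programs, ortholog_fraction,
                                          tempo, seed,
                                          e_day_range = c(10.5, 18.5),
                                          study_id = "mouse1") {
  if (!is.numeric(ortholog_fraction) || ortholog_fraction <= 0 ||
      ortholog_fraction > 1) {
    stop("ortholog_fraction must lie in (0, 1]")
  }
  if (!is.numeric(tempo) || tempo <= 0) stop("tempo must be > 0")
  with_seed(seed, {
    grid <- seq(e_day_range[1], e_day_range[2],
                length.out = config$samples_per_study)
    days <- sort(round(grid + stats::rnorm(length(grid), 0, 0.25), 2))
    latent <- tempo * days / 7
    out <- simulate_profiles(config, programs, study_id, latent,
                             days, "embryonic_day")
    n_map <- floor(ortholog_fraction * config$n_genes)
    mapped <- sort(sample(programs$genes, n_map))
    map <- data.frame(source = mapped,
                      target = paste0("mmu-", mapped),
                      stringsAsFactors = FALSE)
    out$counts <- out$counts[map$source, , drop = FALSE]
    rownames(out$counts) <- map$target
    out$ortholog_map <- map
    out$truth$tempo <- tempo
    out
  })
}

#' Write a synthetic cohort to disk (MTX + TSV sidecars + truth JSON)
#'
#' One sub-directory per study containing `counts.mtx`, `genes.tsv`,
#' `cells.tsv` and `truth.json`.
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$studies)) {
    st <- cohort$studies[[id]]
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE)
    Matrix::writeMM(st$counts, file.path(sdir, "counts.mtx"))
    utils::write.table(data.frame(gene = rownames(st$counts)),
                       file.path(sdir, "genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(st$cells, file.path(sdir, "cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(study = st$truth$study,
           latent_ages = st$truth$latent_ages,
           comp_offsets = as.list(st$truth$comp_offsets)),
      file.path(sdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read one study written by [write_cohort()]
#'
#' @param sdir Study directory with `counts.mtx`, `genes.tsv`, `cells.tsv`.
#' @return List with `counts` (sparse gene x cell) and `cells`.
#' @export
read_study <- function(sdir) {
  counts <- methods::as(Matrix::readMM(file.path(sdir, "counts.mtx")),
                        "CsparseMatrix")
  genes <- utils::read.delim(file.path(sdir, "genes.tsv"),
                             stringsAsFactors = FALSE)$gene
  cells <- utils::read.delim(file.path(sdir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in genes.tsv")
  rownames(counts) <- genes
  colnames(counts) <- cells$cell_id
  list(counts = counts, cells = cells)
}
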