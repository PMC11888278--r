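#' Configuration for the synthetic multi-study cohort generator
#'
#' Bundles and validates every knob of the generative model used to emulate a
#' multi-study single-cell cohort of the developing brain: per-study donor
#' samples spanning early to late gestation, seven broad cell classes whose
#' proportions shift with age (progenitors decline, astrocytes rise) with
#' study-specific composition offsets, shared positive/negative age-correlated
#' gene programs expressed in every cell class, study-specific age programs,
#' class marker genes, per-study batch effects, and negative-binomial counts
#' with variable library size.
#'
#' @param n_studies Number of studies in the cohort.
#' @param samples_per_study Donor samples per study; ages are laid out on an
#'   evenly spaced grid over `age_range_weeks` with Gaussian jitter, and at
#'   least 4 distinct ages per study are enforced.
#' @param age_range_weeks Length-2 numeric, gestational-week span of the cohort.
#' @param n_genes Size of the gene universe.
#' @param cell_classes Character vector of 7 (or more) class names. The first
#'   class takes the rising glial trajectory and the second the declining
#'   progenitor trajectory; defaults put Astrocyte and Progenitor there.
#' @param cells_per_sample Cells drawn per donor sample (multinomial over the
#'   class proportions at that sample's age).
#' @param n_shared_pos_genes,n_shared_neg_genes Sizes of the shared age
#'   programs whose log-expression rises (falls) with age in every cell class.
#' @param n_study_specific_age_genes Genes per study that track age only
#'   within that study (alternating sign).
#' @param n_marker_genes_per_class Marker genes per class.
#' @param age_effect_size Log-fold change per gestational week for program
#'   genes (natural log scale).
#' @param batch_sd Standard deviation of the per-study, per-gene log-scale
#'   batch offset.
#' @param composition_offset_sd Standard deviation of the per-study logit
#'   offsets added to each class's composition trajectory.
#' @param composition_slope_scale Multiplier on the age slopes of the class
#'   composition trajectories; 0 gives age-invariant expected composition
#'   (a compositional null).
#' @param conserved_classes Classes whose composition trajectories are
#'   conserved across studies; their study offsets are shrunk by
#'   `conserved_offset_factor`.
#' @param conserved_offset_factor Multiplier (in \[0,1\]) applied to
#'   `composition_offset_sd` for `conserved_classes`.
#' @param marker_baseline Baseline log-mean assigned to marker genes (low, so
#'   markers are near-off outside their class).
#' @param marker_boost In-class additive log-expression boost for markers.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); counts are Gamma-Poisson.
#' @param libsize_lognormal_sd Log-normal s.d. of per-cell library size.
#' @param mean_libsize Mean per-cell library size (total counts).
#' @param age_jitter_sd S.d. of the jitter added to the per-study age grid.
#' @param seed Integer seed; all randomness derives from it through per-study
#'   child seeds, so a fixed seed gives byte-identical cohorts.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_studies = 2, samples_per_study = 4, n_genes = 300,
#'                   cells_per_sample = 50)
sim_config <- function(n_studies = 6,
                       samples_per_study = 8,
                       age_range_weeks = c(5, 40),
                       n_genes = 2000,
                       cell_classes = c("Astrocyte", "Progenitor",
                                        "ExcitatoryNeuron", "InhibitoryNeuron",
                                        "Oligodendrocyte", "Immune", "Vascular"),
                       cells_per_sample = 150,
                       n_shared_pos_genes = 100,
                       n_shared_neg_genes = 100,
                       n_study_specific_age_genes = 30,
                       n_marker_genes_per_class = 10,
                       age_effect_size = 0.05,
                       batch_sd = 0.3,
                       composition_offset_sd = 1.0,
                       composition_slope_scale = 1,
                       conserved_classes = c("Astrocyte", "Progenitor"),
                       conserved_offset_factor = 0.2,
                       marker_baseline = -2,
                       marker_boost = 6,
                       nb_dispersion = 0.5,
                       libsize_lognormal_sd = 0.35,
                       mean_libsize = 2500,
                       age_jitter_sd = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_studies = as.integer(n_studies),
    samples_per_study = as.integer(samples_per_study),
    age_range_weeks = as.numeric(age_range_weeks),
    n_genes = as.integer(n_genes),
    cell_classes = as.character(cell_classes),
    cells_per_sample = as.integer(cells_per_sample),
    n_shared_pos_genes = as.integer(n_shared_pos_genes),
    n_shared_neg_genes = as.integer(n_shared_neg_genes),
    n_study_specific_age_genes = as.integer(n_study_specific_age_genes),
    n_marker_genes_per_class = as.integer(n_marker_genes_per_class),
    age_effect_size = as.numeric(age_effect_size),
    batch_sd = as.numeric(batch_sd),
    composition_offset_sd = as.numeric(composition_offset_sd),
    composition_slope_scale = as.numeric(composition_slope_scale),
    conserved_classes = as.character(conserved_classes),
    conserved_offset_factor = as.numeric(conserved_offset_factor),
    marker_baseline = as.numeric(marker_baseline),
    marker_boost = as.numeric(marker_boost),
    nb_dispersion = as.numeric(nb_dispersion),
    libsize_lognormal_sd = as.numeric(libsize_lognormal_sd),
    mean_libsize = as.numeric(mean_libsize),
    age_jitter_sd = as.numeric(age_jitter_sd),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (length(cfg$age_range_weeks) != 2L ||
      cfg$age_range_weeks[1] >= cfg$age_range_weeks[2]) {
    stop("age_range_weeks must be (min, max) with min < max")
  }
  if (length(cfg$cell_classes) < 2L) {
    stop("at least 2 cell classes are required")
  }
  if (anyDuplicated(cfg$cell_classes)) stop("cell_classes must be unique")
  n_program <- cfg$n_shared_pos_genes + cfg$n_shared_neg_genes +
    cfg$n_studies * cfg$n_study_specific_age_genes +
    length(cfg$cell_classes) * cfg$n_marker_genes_per_class
  if (n_program > cfg$n_genes) {
    stop(sprintf("gene programs need %d genes but n_genes = %d",
                 n_program, cfg$n_genes))
  }
  if (cfg$cells_per_sample < length(cfg$cell_classes)) {
    stop("cells_per_sample must be at least the number of cell classes")
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$conserved_offset_factor < 0 || cfg$conserved_offset_factor > 1) {
    stop("conserved_offset_factor must lie in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d studies x %d samples, %d genes, %d classes, %d cells/sample\n",
    x$n_studies, x$samples_per_study, x$n_genes, length(x$cell_classes),
    x$cells_per_sample))
  cat(sprintf("  ages %.1f-%.1f wk, age effect %.3f/wk, batch sd %.2f, comp offset sd %.2f, seed %d\n",
              x$age_range_weeks[1], x$age_range_weeks[2], x$age_effect_size,
              x$batch_sd, x$composition_offset_sd, x$seed))
  invisible(x)
}

# Per-class composition trajectory parameters (logit scale). The first class
# carries the strictly largest age slope (rising), the second the strictly
# smallest (declining); intermediate classes stay strictly inside, which
# guarantees strict monotonicity of the first two classes' softmax proportions.
trajectory_params <- function(classes) {
  k <- length(classes)
  base_int <- c(-2.0, 2.0, 0.5, 0.2, -1.5, -1.0, -1.2)
  base_slp <- c(0.10, -0.12, 0.02, 0.01, 0.05, 0.00, -0.02)
  intercept <- rep_len(base_int, k)
  slope <- rep_len(base_slp, k)
  if (k > 7L) slope[8:k] <- 0.005  # keep extras strictly interior
  names(intercept) <- names(slope) <- classes
  list(intercept = intercept, slope = slope)
}

#' Noise-free class composition trajectory
#'
#' Expected class proportions at the given ages under the generator's logistic
#' (softmax over linear logit scores) composition model, optionally shifted by
#' per-class study offsets.
#'
#' @param config A [sim_config()].
#' @param ages Numeric vector of ages in weeks.
#' @param offsets Named numeric vector of per-class logit offsets (default 0).
#' @return Matrix `length(ages) x n_classes` of proportions; rows sum to 1.
#' @export
composition_trajectory <- function(config, ages, offsets = NULL) {
  tp <- trajectory_params(config$cell_classes)
  scale <- if (is.null(config$composition_slope_scale)) 1 else
    config$composition_slope_scale
  tp$slope <- tp$slope * scale
  k <- length(config$cell_classes)
  if (is.null(offsets)) offsets <- stats::setNames(numeric(k), config$cell_classes)
  scores <- outer(ages, tp$slope) +
    matrix(tp$intercept + offsets[config$cell_classes],
           nrow = length(ages), ncol = k, byrow = TRUE)
  e <- exp(scores - apply(scores, 1, max))
  p <- e / rowSums(e)
  dimnames(p) <- list(NULL, config$cell_classes)
  p
}
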