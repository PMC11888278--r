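#' Study-specific age-correlated genes
#'
#' Pearson correlation of each gene's normalized expression with age across
#' one study's pseudo-bulk profiles, with the t-distribution p-value (the
#' `cor.test` statistic) and Benjamini-Hochberg FDR within the study.
#' Constant genes are undefined and excluded from the adjustment.
#'
#' @param expr Profiles x genes matrix for one study.
#' @param ages Profile ages (weeks); at least 3 distinct values.
#' @param fdr_threshold Adjusted-p cutoff for the `significant` flag.
#' @return Data.frame: `gene`, `r`, `p`, `p_adj`, `significant`.
#' @export
age_genes <- function(expr, ages, fdr_threshold = 0.05) {
  if (nrow(expr) < 3L) stop("fewer than 3 profiles")
  if (length(unique(ages)) < 3L) stop("fewer than 3 distinct ages")
  n <- nrow(expr)
  r <- suppressWarnings(as.vector(stats::cor(expr, ages)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  defined <- !is.na(r)
  p_adj <- rep(NA_real_, length(r))
  p_adj[defined] <- stats::p.adjust(p[defined], method = "fdr")
  data.frame(gene = colnames(expr), r = r, p = p, p_adj = p_adj,
             significant = !is.na(p_adj) & p_adj < fdr_threshold,
             stringsAsFactors = FALSE)
}

#' Age-correlated genes for every study in an observation table
#'
#' @param obs An `"observation_table"`.
#' @param fdr_threshold Adjusted-p cutoff.
#' @return Named list study -> [age_genes()] table.
#' @export
age_genes_by_study <- function(obs, fdr_threshold = 0.05) {
  studies <- unique(obs$meta$study)
  stats::setNames(lapply(studies, function(s) {
    idx <- obs$meta$study == s
    age_genes(obs$expr[idx, , drop = FALSE], obs$meta$age_weeks[idx],
              fdr_threshold)
  }), studies)
}

#' Rank-standardized co-expression network for one study
#'
#' Spearman correlations between genes over the study's aggregate profiles;
#' the upper-triangle correlations are then jointly ranked (ascending,
#' average ties, diagonal excluded) and divided by the maximum rank, so
#' values lie in (0, 1] and are invariant to any strictly increasing
#' transform of the correlations. The matrix is mirrored to symmetry with
#' unit diagonal.
#'
#' @param expr Profiles x genes matrix (>= 3 profiles, >= 2 genes).
#' @param genes Genes to use (default all columns); constant genes are
#'   dropped with a warning.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
study_network <- function(expr, genes = colnames(expr)) {
  expr <- expr[, genes, drop = FALSE]
  if (nrow(expr) < 3L) stop("fewer than 3 profiles")
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant genes dropped from network: ",
            paste(colnames(expr)[sds == 0], collapse = ", "))
    expr <- expr[, sds > 0, drop = FALSE]
  }
  if (ncol(expr) < 2L) stop("fewer than 2 non-constant genes")
  cors <- stats::cor(expr, method = "spearman")
  ut <- upper.tri(cors)
  v <- cors[ut]
  std <- rank(v, ties.method = "average") / length(v)
  out <- matrix(0, ncol(expr), ncol(expr), dimnames = dimnames(cors))
  out[ut] <- std
  out <- out + t(out)
  diag(out) <- 1
  out
}

#' Aggregate rank-standardized networks across studies
#'
#' @param nets List of [study_network()] matrices over identical gene lists
#'   (same order).
#' @return List of class `"coexpr_network"`: `genes`, `matrix` (elementwise
#'   mean), `n_datasets`, `modules` (NULL until [cluster_modules()]).
#' @export
aggregate_network <- function(nets) {
  stopifnot(length(nets) >= 1L)
  ref <- colnames(nets[[1]])
  for (m in nets) {
    if (!identical(colnames(m), ref) || !identical(rownames(m), ref)) {
      stop("networks have mismatched gene lists")
    }
  }
  agg <- Reduce(`+`, nets) / length(nets)
  structure(list(genes = ref, matrix = agg, n_datasets = length(nets),
                 modules = NULL),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf("coexpr_network: %d genes over %d datasets%s\n",
              length(x$genes), x$n_datasets,
              if (is.null(x$modules)) ""
              else sprintf(", %d modules", length(unique(x$modules)))))
  invisible(x)
}

#' Cut the aggregate network into co-expression modules
#'
#' Rows of the aggregate network matrix are embedded as feature vectors,
#' hierarchically clustered (Euclidean distance, complete linkage) and cut at
#' the given height; module ids are ordered by size, largest first.
#'
#' @param net A `"coexpr_network"`.
#' @param cut_height Non-negative cut height on the dendrogram.
#' @return `net` with `modules` (named integer vector gene -> module id) and
#'   `cut_height` filled.
#' @export
cluster_modules <- function(net, cut_height) {
  stopifnot(inherits(net, "coexpr_network"))
  if (cut_height < 0) stop("cut_height must be non-negative")
  hc <- stats::hclust(stats::dist(net$matrix), method = "complete")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  relabel <- stats::setNames(seq_along(sizes),
                             names(sort(sizes, decreasing = TRUE)))
  net$modules <- stats::setNames(as.integer(relabel[as.character(raw)]),
                                 names(raw))
  net$cut_height <- cut_height
  net
}

#' Enrichment of study age genes within co-expression modules
#'
#' One-sided (greater) Fisher's exact test of each module against each
#' study's significant age-gene set, with BH-FDR across the whole
#' module x study grid.
#'
#' @param modules Named integer vector gene -> module id (from
#'   [cluster_modules()]), or a `"coexpr_network"` with modules assigned.
#' @param age_sets Named list study -> character vector of significant
#'   age-correlated genes (subsets of `universe`).
#' @param universe Character vector, the analysis gene universe.
#' @return Data.frame: `module`, `study`, `overlap`, `module_size`,
#'   `set_size`, `odds_ratio`, `p`, `p_adj`.
#' @export
module_enrichment <- function(modules, age_sets, universe) {
  if (inherits(modules, "coexpr_network")) modules <- modules$modules
  stopifnot(!is.null(names(modules)))
  n_u <- length(universe)
  rows <- list()
  for (mid in sort(unique(modules))) {
    mod <- intersect(names(modules)[modules == mid], universe)
    if (length(mod) == 0L) next
    for (s in names(age_sets)) {
      set <- intersect(age_sets[[s]], universe)
      a <- length(intersect(mod, set))
      tab <- matrix(c(a, length(mod) - a, length(set) - a,
                      n_u - length(mod) - length(set) + a), 2, 2)
      ft <- stats::fisher.test(tab, alternative = "greater")
      rows[[length(rows) + 1L]] <- data.frame(
        module = mid, study = s, overlap = a, module_size = length(mod),
        set_size = length(set), odds_ratio = unname(ft$estimate),
        p = ft$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "fdr")
  out
}

#' AUROC of separating positive- from negative-coefficient model genes by
#' study-specific age correlation
#'
#' For each study, uses that study's per-gene age correlation (signed, or its
#' absolute value under the contrast mode) as a score and asks how well it
#' ranks the clock's positive-coefficient genes above its
#' negative-coefficient genes (Mann-Whitney AUROC).
#'
#' @param model A `"clock_model"` with both positive and negative
#'   coefficients.
#' @param age_tables Named list study -> [age_genes()] table.
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return Named numeric vector of per-study AUROCs.
#' @export
sign_classification_auroc <- function(model, age_tables,
                                      mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  pos <- names(model$coef)[model$coef > 0]
  neg <- names(model$coef)[model$coef < 0]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("model needs both positive- and negative-coefficient genes")
  }
  vapply(age_tables, function(tab) {
    idx <- match(c(pos, neg), tab$gene)
    r <- tab$r[idx]
    if (mode == "absolute") r <- abs(r)
    labels <- c(rep(TRUE, length(pos)), rep(FALSE, length(neg)))
    auroc(r, labels)
  }, numeric(1))
}
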