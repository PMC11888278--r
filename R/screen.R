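#' Filter a gene-set collection by in-universe size
#'
#' Sets are intersected with the analysis universe first; a set is kept iff
#' its post-intersection size lies in \[min_size, max_size\] (the canonical
#' screen uses 50-500, the module-enrichment screen 10-200).
#'
#' @param coll Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of analysis genes.
#' @param min_size,max_size Inclusive size bounds after intersection.
#' @return Named list of the surviving, universe-intersected sets.
#' @export
filter_sets <- function(coll, universe, min_size = 50, max_size = 500) {
  out <- lapply(coll, intersect, y = universe)
  keep <- vapply(out, function(g)
    length(g) >= min_size && length(g) <= max_size, logical(1))
  out <- out[keep]
  if (length(out) == 0L) stop("no gene sets survive the size filter")
  out
}

#' Gene-set restricted clock screen
#'
#' For every gene set and every model flavor (the cell-type-agnostic clock
#' and each per-class clock), refits the clock restricted to the set's genes
#' and records the leave-study-out CV MAE. The fold layout is fixed by the
#' study structure, so results are comparable across sets and invariant to
#' the order of the collection. An all-gene baseline per flavor is attached
#' as the `"baseline"` attribute.
#'
#' @param obs An `"observation_table"`.
#' @param coll Filtered gene-set collection ([filter_sets()]).
#' @param flavors Character vector of flavors: `"agnostic"` and/or broad
#'   class names present in `obs`.
#' @param alphas,nlambda Tuning grid for the restricted fits (lean defaults
#'   for throughput).
#' @param baseline Compute the all-gene baseline per flavor (default TRUE).
#' @param seed Integer seed (interface stability; folds are deterministic).
#' @return Data.frame: `set`, `flavor`, `mae`, `set_size`; attribute
#'   `"baseline"` is a data.frame `flavor`, `mae`.
#' @export
screen_genesets <- function(obs, coll, flavors = "agnostic",
                            alphas = 0.5, nlambda = 30, baseline = TRUE,
                            seed = 1L) {
  flavor_obs <- list()
  for (fl in flavors) {
    if (fl == "agnostic") {
      flavor_obs[[fl]] <- obs
    } else {
      idx <- which(obs$meta$cell_class == fl)
      if (length(idx) == 0L ||
          length(unique(obs$meta$study[idx])) < 2L) {
        warning("flavor ", fl, " absent or single-study; skipped")
        next
      }
      flavor_obs[[fl]] <- subset_obs(obs, idx)
    }
  }
  if (length(flavor_obs) == 0L) stop("no usable flavors")
  restrict <- function(o, genes) {
    keep <- match(genes, o$genes)
    structure(list(expr = o$expr[, keep, drop = FALSE],
                   meta = o$meta, mode = o$mode, genes = genes),
              class = "observation_table")
  }
  rows <- list()
  for (set_name in names(coll)) {
    genes <- intersect(coll[[set_name]], obs$genes)
    for (fl in names(flavor_obs)) {
      rep <- loso_cv(restrict(flavor_obs[[fl]], genes),
                     alphas = alphas, nlambda = nlambda, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, flavor = fl, mae = rep$mae,
        set_size = length(genes), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (baseline) {
    base <- do.call(rbind, lapply(names(flavor_obs), function(fl) {
      rep <- loso_cv(flavor_obs[[fl]], alphas = alphas, nlambda = nlambda,
                     seed = seed)
      data.frame(flavor = fl, mae = rep$mae, stringsAsFactors = FALSE)
    }))
    attr(out, "baseline") <- base
  }
  out
}

#' Spearman correlation of screen performance between model flavors
#'
#' @param res A [screen_genesets()] result with at least 3 sets and 2
#'   flavors.
#' @return Symmetric flavor x flavor matrix of Spearman correlations of the
#'   per-set MAE vectors, unit diagonal.
#' @export
cross_flavor_correlation <- function(res) {
  flavors <- unique(res$flavor)
  if (length(flavors) < 2L) stop("at least 2 flavors required")
  sets <- unique(res$set)
  if (length(sets) < 3L) stop("at least 3 gene sets required")
  mat <- sapply(flavors, function(fl) {
    res$mae[res$flavor == fl][match(sets, res$set[res$flavor == fl])]
  })
  out <- stats::cor(mat, method = "spearman")
  diag(out) <- 1
  dimnames(out) <- list(flavors, flavors)
  out
}

#' Hypergeometric enrichment of gene sets in co-expression modules
#'
#' Upper-tail hypergeometric test of each (size-filtered) set's overlap with
#' each module, given the universe, with BH-FDR across the grid.
#'
#' @param modules Named integer vector gene -> module id, or a
#'   `"coexpr_network"` with modules.
#' @param coll Named list of gene sets.
#' @param universe Analysis gene universe.
#' @param min_size,max_size Inclusive in-universe set-size bounds
#'   (default 10-200).
#' @return Data.frame: `module`, `set`, `overlap`, `module_size`,
#'   `set_size`, `p`, `p_adj`.
#' @export
set_in_module_enrichment <- function(modules, coll, universe,
                                     min_size = 10, max_size = 200) {
  if (inherits(modules, "coexpr_network")) modules <- modules$modules
  if (any(vapply(coll, length, integer(1)) > length(universe))) {
    stop("a gene set is larger than the universe")
  }
  coll <- filter_sets(coll, universe, min_size, max_size)
  n_u <- length(universe)
  rows <- list()
  for (mid in sort(unique(modules))) {
    mod <- intersect(names(modules)[modules == mid], universe)
    if (length(mod) == 0L) next
    for (s in names(coll)) {
      set <- coll[[s]]
      a <- length(intersect(mod, set))
      p <- stats::phyper(a - 1, length(set), n_u - length(set),
                         length(mod), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = mid, set = s, overlap = a, module_size = length(mod),
        set_size = length(set), p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "fdr")
  out
}
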