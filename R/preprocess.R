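#' Map author cell-type labels to broad classes
#'
#' @param cells Cell table with an `author_cell_type` column.
#' @param class_map Named character vector (author label -> broad class) or a
#'   two-column data.frame (`author_cell_type`, `broad_class`).
#' @param strict If `TRUE` (default) any unmapped label is an error naming the
#'   offending labels; if `FALSE` unmapped labels become `"Other"` with a
#'   warning.
#' @return `cells` with `broad_class` filled.
#' @export
harmonize <- function(cells, class_map, strict = TRUE) {
  if (is.data.frame(class_map)) {
    class_map <- stats::setNames(as.character(class_map$broad_class),
                                 class_map$author_cell_type)
  }
  labels <- cells$author_cell_type
  unmapped <- setdiff(unique(labels), names(class_map))
  if (length(unmapped)) {
    if (strict) {
      stop("unmapped author cell types: ", paste(unmapped, collapse = ", "))
    }
    warning("unmapped author cell types set to Other: ",
            paste(unmapped, collapse = ", "))
  }
  cls <- unname(class_map[labels])
  cls[is.na(cls)] <- "Other"
  cells$broad_class <- cls
  cells
}

#' Sorted intersection of gene lists across datasets
#'
#' @param gene_lists List of character vectors (one per dataset).
#' @return Sorted character vector of common genes.
#' @export
intersect_genes <- function(gene_lists) {
  stopifnot(length(gene_lists) >= 1L)
  common <- Reduce(intersect, gene_lists)
  if (length(common) == 0L) stop("gene intersection is empty")
  sort(common)
}

#' Log-normalize counts (library-size scaled, natural log)
#'
#' Each entry c of a profile with total T becomes ln(1 + scale_factor * c / T),
#' the standard LogNormalize transform at scale factor 10,000.
#'
#' @param counts Matrix (genes x profiles), dense or sparse; profiles are
#'   columns (cells or pseudo-bulk aggregates).
#' @param scale_factor Scale factor, default 10000.
#' @param drop_zero_cells Drop zero-total columns with a warning instead of
#'   erroring.
#' @return Matrix of the same shape (sparse in, sparse out).
#' @export
lognormalize <- function(counts, scale_factor = 10000, drop_zero_cells = FALSE) {
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0)) {
    if (!drop_zero_cells) stop("profiles with zero total counts: ",
                               paste(which(totals <= 0), collapse = ", "))
    warning(sum(totals <= 0), " zero-total profiles dropped")
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  if (inherits(counts, "sparseMatrix")) {
    x <- methods::as(counts, "CsparseMatrix")
    j <- rep(seq_len(ncol(x)), diff(x@p))
    x@x <- log1p(scale_factor * x@x / totals[j])
    x
  } else {
    log1p(scale_factor * sweep(counts, 2, totals, "/"))
  }
}

#' Rank-normalize profiles (depth-invariant expression)
#'
#' Within each profile (column), every count is replaced by its average rank
#' among all genes (ties averaged, zeros included in the tie pool) divided by
#' the number of genes, giving values in (0, 1]. Invariant to any strictly
#' increasing transform of a profile's counts, hence to library size.
#'
#' @param counts Matrix (genes x profiles).
#' @return Dense matrix of rank-normalized values.
#' @export
rank_normalize <- function(counts) {
  m <- as.matrix(counts)
  out <- apply(m, 2, function(x) rank(x, ties.method = "average") / length(x))
  dimnames(out) <- dimnames(m)
  out
}

#' Aggregate raw counts to pseudo-bulk profiles
#'
#' Sums raw counts over groups of cells defined by arbitrary metadata keys
#' (e.g. study x sample x cell type). Metadata fields constant within a group
#' are carried; non-constant fields are set to NA with a warning.
#'
#' @param counts Sparse or dense genes x cells matrix.
#' @param cells Cell table aligned with `counts` columns.
#' @param group_keys Character vector of `cells` column names to group by.
#' @param min_cells Groups with fewer cells are dropped (default 1 = keep all).
#' @return List of class `"pseudobulk_table"`: `counts` (genes x groups),
#'   `meta` (one row per group: keys, `n_cells`, carried metadata).
#' @export
pseudobulk <- function(counts, cells, group_keys, min_cells = 1L) {
  missing_keys <- setdiff(group_keys, names(cells))
  if (length(missing_keys)) {
    stop("unknown grouping keys: ", paste(missing_keys, collapse = ", "))
  }
  stopifnot(ncol(counts) == nrow(cells))
  key <- do.call(paste, c(cells[group_keys], sep = "\r"))
  key <- factor(key, levels = unique(key))
  ind <- Matrix::sparseMatrix(i = seq_along(key), j = as.integer(key), x = 1,
                              dims = c(length(key), nlevels(key)))
  agg <- as.matrix(counts %*% ind)
  rownames(agg) <- rownames(counts)
  colnames(agg) <- levels(key)
  n_cells <- as.vector(table(key))

  idx <- split(seq_along(key), key)
  carry_cols <- setdiff(names(cells), c(group_keys, "cell_id"))
  meta <- do.call(rbind, lapply(idx, function(i) cells[i[1], group_keys, drop = FALSE]))
  rownames(meta) <- NULL
  meta$n_cells <- n_cells
  warned <- character(0)
  for (cc in carry_cols) {
    vals <- vapply(idx, function(i) {
      u <- unique(cells[[cc]][i])
      if (length(u) == 1L) as.character(u) else NA_character_
    }, character(1))
    if (anyNA(vals) && !all(is.na(vals))) warned <- c(warned, cc)
    if (all(is.na(vals)) && any(!is.na(cells[[cc]]))) warned <- c(warned, cc)
    if (is.numeric(cells[[cc]])) vals <- as.numeric(vals)
    meta[[cc]] <- vals
  }
  if (length(warned)) {
    warning("metadata not constant within groups, set to NA: ",
            paste(unique(warned), collapse = ", "))
  }
  keep <- meta$n_cells >= min_cells
  structure(list(counts = agg[, keep, drop = FALSE],
                 meta = meta[keep, , drop = FALSE]),
            class = "pseudobulk_table")
}

#' @export
print.pseudobulk_table <- function(x, ...) {
  cat(sprintf("pseudobulk_table: %d genes x %d groups\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Per-sample broad-class composition
#'
#' @param cells Harmonized cell table (`broad_class` populated).
#' @param classes Class columns to report; defaults to the classes present.
#' @return Data.frame, one row per (study, sample): `study`, `sample_id`,
#'   `age_weeks` (if present), `n_cells`, then one proportion column per
#'   class. Proportions sum to 1 across the reported classes.
#' @export
composition <- function(cells, classes = NULL) {
  stopifnot(!is.null(cells$broad_class), !is.null(cells$sample_id))
  if (is.null(classes)) classes <- sort(unique(cells$broad_class))
  key <- paste(cells$study, cells$sample_id, sep = "\r")
  tab <- table(factor(key, levels = unique(key)),
               factor(cells$broad_class, levels = classes))
  n <- rowSums(tab)
  props <- as.matrix(tab / n)
  first <- !duplicated(key)
  out <- data.frame(study = cells$study[first],
                    sample_id = cells$sample_id[first],
                    stringsAsFactors = FALSE)
  if (!is.null(cells$age_weeks)) out$age_weeks <- cells$age_weeks[first]
  out$n_cells <- as.vector(n)
  for (cl in classes) out[[cl]] <- unname(props[, cl])
  attr(out, "classes") <- classes
  out
}

#' Consensus (recurrent) marker genes per broad class
#'
#' For every sample, one-vs-rest log2 fold change
#' log2((mean_in + 1)/(mean_out + 1)) on normalized expression and the
#' in-class expressing fraction (pct.1) are computed per class. A gene is a
#' consensus marker of a class if it passes `log2fc_min` and `pct_min` in
#' every sample where the class is present.
#'
#' @param norm Normalized genes x cells matrix.
#' @param cells Harmonized cell table aligned with `norm` columns.
#' @param log2fc_min Minimum one-vs-rest log2 fold change (default 2).
#' @param pct_min Minimum in-class expressing fraction (default 0.2).
#' @return Named list class -> character vector of consensus marker genes.
#' @export
recurrent_markers <- function(norm, cells, log2fc_min = 2, pct_min = 0.2) {
  stopifnot(ncol(norm) == nrow(cells))
  classes <- sort(unique(cells$broad_class))
  samples <- unique(cells$sample_id)
  pass <- lapply(stats::setNames(classes, classes),
                 function(cl) matrix(NA, nrow(norm), 0))
  for (sm in samples) {
    in_sample <- cells$sample_id == sm
    sub <- norm[, in_sample, drop = FALSE]
    sub_cls <- cells$broad_class[in_sample]
    present <- unique(sub_cls)
    if (length(present) < 2L) {
      warning("sample ", sm, " has a single class; skipped")
      next
    }
    for (cl in classes) {
      if (!(cl %in% present)) {
        warning("class ", cl, " absent from sample ", sm, "; sample skipped")
        next
      }
      inc <- sub_cls == cl
      mean_in <- Matrix::rowMeans(sub[, inc, drop = FALSE])
      mean_out <- Matrix::rowMeans(sub[, !inc, drop = FALSE])
      pct1 <- Matrix::rowMeans(sub[, inc, drop = FALSE] > 0)
      ok <- log2((mean_in + 1) / (mean_out + 1)) > log2fc_min & pct1 > pct_min
      pass[[cl]] <- cbind(pass[[cl]], ok)
    }
  }
  lapply(pass, function(m) {
    if (ncol(m) == 0L) character(0)
    else rownames(norm)[rowSums(m) == ncol(m)]
  })
}
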