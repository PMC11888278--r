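#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then gene symbols.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; descriptions in the
#'   `"descriptions"` attribute. Duplicate set names are an error.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in GMT")
  sets <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), nm)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1)),
    nm)
  sets
}

#' Read a two-column ortholog map TSV (header `source`, `target`)
#'
#' @param path Path to the TSV.
#' @return Data.frame with `source` and `target` columns.
#' @export
read_ortholog_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(map))) {
    stop("ortholog map must have 'source' and 'target' columns")
  }
  map[, c("source", "target")]
}

#' Serialize a fitted model to JSON
#'
#' Clock, compositional and PC models round-trip exactly (numbers are written
#' at full precision).
#'
#' @param model A `"clock_model"`, `"composition_model"` or `"pc_model"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  fields <- lapply(unclass(model), function(f) {
    # named numeric vectors become JSON objects so names survive the trip
    if (is.numeric(f) && !is.null(names(f))) as.list(f) else f
  })
  payload <- list(model_class = class(model)[1], fields = fields)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a model written by [write_model_json()]
#'
#' @param path Path to the JSON file.
#' @return The model with its class restored.
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- payload$fields
  cls <- payload$model_class
  num_named <- function(x) {
    x <- unlist(x)
    if (length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
    stats::setNames(as.numeric(x), names(x))
  }
  if (cls == "clock_model") {
    fields$coef <- num_named(fields$coef)
    fields$genes <- as.character(fields$genes)
  } else if (cls == "composition_model") {
    fields$coefficients <- num_named(fields$coefficients)
  } else if (cls == "pc_model") {
    fields$gene_means <- num_named(fields$gene_means)
    fields$loading <- num_named(fields$loading)
  }
  structure(fields, class = cls)
}

#' Write a pseudobulk table to TSV (one row per group, genes as columns)
#'
#' @param pb A `"pseudobulk_table"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pseudobulk_tsv <- function(pb, path) {
  out <- cbind(pb$meta, as.data.frame(t(pb$counts)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a composition table to TSV
#'
#' @param comp A [composition()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(comp, path) {
  utils::write.table(comp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
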