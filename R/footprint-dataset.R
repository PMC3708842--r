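#' Transposon footprint dataset
#'
#' Container for gene-level transposon footprinting data: a positive matrix
#' of transposon-signal to genomic-DNA-signal ratios (genes x arrays)
#' together with the role of each array. Reference arrays are hybridizations
#' of the mutant library before selection (the f_initial side); selected
#' arrays are post-selection hybridizations, labelled with their growth
#' condition and biological replicate index.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), arrays
#'   in columns (colnames = array ids). All entries must be positive ratios.
#' @param arrays data.frame describing the columns of `values`, with columns
#'   `array` (matching colnames), `role` (`"ref"` or `"sel"`), `condition`
#'   (NA for reference arrays) and `replicate` (integer, NA for reference
#'   arrays).
#' @return an object of class `footprint_dataset`.
#' @export
footprint_dataset <- function(values, arrays) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs gene ids as rownames and array ids as colnames")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("footprint ratios must all be positive and finite")
  req <- c("array", "role", "condition", "replicate")
  if (!is.data.frame(arrays) || !all(req %in% names(arrays)))
    stop("'arrays' must have columns array, role, condition, replicate")
  arrays <- arrays[match(colnames(values), arrays$array), , drop = FALSE]
  if (any(is.na(arrays$array)))
    stop("every column of 'values' must be described in 'arrays'")
  if (!all(arrays$role %in% c("ref", "sel")))
    stop("array roles must be 'ref' or 'sel'")
  if (sum(arrays$role == "ref") < 1L)
    stop("at least one reference (pre-selection) array is required")
  rownames(arrays) <- NULL
  structure(list(values = values, arrays = arrays),
            class = "footprint_dataset")
}

#' @export
print.footprint_dataset <- function(x, ...) {
  nref <- sum(x$arrays$role == "ref")
  sel <- x$arrays[x$arrays$role == "sel", , drop = FALSE]
  conds <- table(sel$condition)
  cat(sprintf("footprint_dataset: %d genes, %d reference array%s\n",
              nrow(x$values), nref, if (nref == 1L) "" else "s"))
  if (length(conds))
    cat("selected conditions:",
        paste(sprintf("%s (%d reps)", names(conds), conds), collapse = ", "),
        "\n")
  invisible(x)
}

#' Conditions present in a footprint dataset
#' @param dataset a [footprint_dataset()].
#' @return character vector of condition labels.
#' @export
footprint_conditions <- function(dataset) {
  unique(dataset$arrays$condition[dataset$arrays$role == "sel"])
}

#' Remove essential genes before significance testing
#'
#' Transposon insertions in essential genes are absent from the library for
#' trivial reasons, so essential genes are dropped before any significance
#' work. The essential list is organism data supplied by the user (e.g. one
#' id per line from a chromosome-profiling database); the package ships
#' none.
#'
#' @param dataset a [footprint_dataset()].
#' @param essential_ids character vector of gene ids to drop. Ids not
#'   present in the dataset are ignored with a warning.
#' @return the dataset restricted to non-essential genes, with attribute
#'   `n_excluded` recording how many genes were removed.
#' @export
exclude_essentials <- function(dataset, essential_ids) {
  stopifnot(inherits(dataset, "footprint_dataset"))
  essential_ids <- as.character(essential_ids)
  unknown <- setdiff(essential_ids, rownames(dataset$values))
  if (length(unknown))
    warning(sprintf("%d essential id(s) not present in the dataset; ignored",
                    length(unknown)))
  keep <- setdiff(rownames(dataset$values), essential_ids)
  if (!length(keep))
    stop("excluding essentials removed every gene")
  out <- footprint_dataset(dataset$values[keep, , drop = FALSE],
                           dataset$arrays)
  attr(out, "n_excluded") <- nrow(dataset$values) - length(keep)
  out
}

#' Read / write footprint datasets as TSV
#'
#' The on-disk format has the gene id in the first column and one column per
#' array with header `role:condition:replicate` (`role` is `ref` or `sel`;
#' condition and replicate are empty for reference arrays, e.g. `ref::1`).
#'
#' @param dataset a [footprint_dataset()].
#' @param path file path.
#' @return `read_footprint_tsv` returns a [footprint_dataset()];
#'   `write_footprint_tsv` returns `path` invisibly.
#' @export
write_footprint_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "footprint_dataset"))
  a <- dataset$arrays
  rep_idx <- a$replicate
  rep_idx[a$role == "ref"] <- seq_len(sum(a$role == "ref"))  # keep unique
  hdr <- sprintf("%s:%s:%s", a$role,
                 ifelse(is.na(a$condition), "", a$condition),
                 ifelse(is.na(rep_idx), "", rep_idx))
  df <- data.frame(gene = rownames(dataset$values), dataset$values,
                   check.names = FALSE)
  names(df) <- c("gene", hdr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_footprint_tsv
#' @export
read_footprint_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first column must be 'gene'")
  hdr <- names(df)[-1]
  parts <- strsplit(hdr, ":", fixed = TRUE)
  bad <- lengths(parts) < 1L
  if (any(bad)) stop("malformed array header: ", hdr[bad][1])
  field <- function(i) vapply(parts, function(p)
    if (length(p) >= i && nzchar(p[i])) p[i] else NA_character_, "")
  arrays <- data.frame(array = hdr, role = field(1), condition = field(2),
                       replicate = suppressWarnings(as.integer(field(3))),
                       stringsAsFactors = FALSE)
  values <- as.matrix(df[-1])
  rownames(values) <- df$gene
  footprint_dataset(values, arrays)
}
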