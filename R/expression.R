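#' Expression matrix with two-group design and optional severity scores
#'
#' Lightweight container for a genes-by-samples real-valued matrix, an
#' optional case/control group assignment and optional per-sample severity
#' scores (e.g. a cognitive score such as MMSE, or a tangle burden such as an
#' NFT count). Row names are gene (or probe) identifiers, column names are
#' sample identifiers.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must have
#'   row and column names.
#' @param group optional character/factor vector of `"case"`/`"control"`
#'   labels, either named by sample or in column order.
#' @param severity optional named list of numeric severity vectors; each
#'   vector named by sample or in column order.
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, group = NULL, severity = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_data("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_data("values must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop_data("duplicate gene/probe identifiers in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop_data("duplicate sample identifiers in expression matrix")
  samples <- colnames(values)
  if (!is.null(group)) {
    group <- as.character(group)
    if (is.null(names(group))) {
      if (length(group) != ncol(values))
        stop_data("group vector length %d does not match %d samples",
                  length(group), ncol(values))
      names(group) <- samples
    }
    missing <- setdiff(samples, names(group))
    if (length(missing) > 0L)
      stop_data("samples without group label: %s",
                paste(utils::head(missing, 5L), collapse = ", "))
    group <- group[samples]
    bad <- setdiff(unique(group), c("case", "control"))
    if (length(bad) > 0L)
      stop_data("group labels must be 'case'/'control', got: %s",
                paste(bad, collapse = ", "))
    group <- factor(group, levels = c("control", "case"))
  }
  if (!is.null(severity)) {
    if (!is.list(severity) || is.null(names(severity)))
      stop_data("severity must be a named list of numeric vectors")
    severity <- lapply(severity, function(v) {
      v <- as.numeric(v) # keep names
      if (is.null(names(v))) {
        if (length(v) != ncol(values))
          stop_data("severity vector length does not match sample count")
        names(v) <- samples
      }
      v[samples]
    })
    for (v in severity) names(v) <- samples
  }
  structure(list(values = values, group = group, severity = severity),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$group))
    cat(sprintf("  design: %d case / %d control\n",
                sum(x$group == "case"), sum(x$group == "control")))
  if (!is.null(x$severity))
    cat(sprintf("  severity scores: %s\n",
                paste(names(x$severity), collapse = ", ")))
  if (anyNA(x$values))
    cat(sprintf("  missing entries: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# replace the value matrix, subsetting design/severity is not needed because
# both are keyed by sample and columns never change here
replace_values <- function(m, values) {
  m$values <- values
  m
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene or
#' probe identifiers. Empty fields and `NA` are read as missing; negative
#' values can additionally be treated as missing (the convention used for
#' series-matrix files whose negative intensities flag unreliable probes).
#'
#' @param path TSV file path.
#' @param group optional named group vector or 2-column TSV path
#'   (sample, case/control).
#' @param severity optional named list of vectors, or named character vector
#'   of 2-column TSV paths (sample, value).
#' @param negative_as_missing logical; treat negative values as missing.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, group = NULL, severity = NULL,
                            negative_as_missing = FALSE) {
  if (!file.exists(path)) stop_data("expression file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, na.strings = c("NA", ""),
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_data("expression TSV needs id column + samples: %s", path)
  ids <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  if (negative_as_missing) values[values < 0] <- NA_real_
  if (is.character(group) && length(group) == 1L && file.exists(group))
    group <- read_two_column(group, what = "group")
  if (is.character(severity))
    severity <- lapply(as.list(severity), read_two_column, what = "severity")
  expression_matrix(values, group = group, severity = severity)
}

read_two_column <- function(path, what = "value") {
  if (!file.exists(path)) stop_data("%s file not found: %s", what, path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_data("%s file must have two columns: %s", what, path)
  stats::setNames(tab[[2L]], as.character(tab[[1L]]))
}

#' Write an expression matrix to TSV
#'
#' @param m an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  tab <- data.frame(gene = rownames(m$values), m$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
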