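#' Expression matrix container
#'
#' The central data structure of the pipeline: a probes-or-genes x samples
#' matrix of log2 expression values together with the sample-to-group design.
#' Probe-level matrices may contain repeated row identifiers (duplicate
#' spots); gene-level matrices must have unique row identifiers.
#'
#' @param values numeric matrix of log2 expression; rownames are probe or
#'   gene identifiers, colnames are sample identifiers.
#' @param design a design `data.frame` as returned by [design_table()], with
#'   one row per column of `values`.
#' @param level `"probe"` or `"gene"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `design`, `level`.
#' @export
expression_matrix <- function(values, design, level = c("probe", "gene")) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values))) {
    if (nrow(values) > 0)
      stop("'values' must carry rownames (features)")
    rownames(values) <- character(0)
  }
  if (is.null(colnames(values)))
    stop("'values' must carry colnames (samples)")
  design <- as_design_table(design)
  if (!setequal(colnames(values), design$sample_id) ||
      ncol(values) != nrow(design))
    stop("columns of 'values' and design sample_ids do not match")
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  if (any(!is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)")
  if (level == "gene" && anyDuplicated(rownames(values)))
    stop("gene-level matrices must have unique row identifiers")
  structure(list(values = values, design = design, level = level),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix (%s level): %d features x %d samples\n",
              x$level, nrow(x$values), ncol(x$values)))
  cat("groups:", paste(sprintf("%s(%d)", names(table(x$design$group)),
                               table(x$design$group)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Sample design table
#'
#' Maps sample (array) identifiers to biological group labels, optionally
#' carrying a dataset-of-origin label for integrated analyses.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group character vector of group labels, same length.
#' @param dataset optional character vector of dataset labels.
#' @return a `data.frame` with columns `sample_id`, `group` (and `dataset`).
#' @export
design_table <- function(sample_id, group, dataset = NULL) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group))
    stop("'sample_id' and 'group' lengths differ")
  if (anyDuplicated(sample_id))
    stop("duplicated sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  d <- data.frame(sample_id = sample_id, group = group,
                  stringsAsFactors = FALSE)
  if (!is.null(dataset)) d$dataset <- as.character(dataset)
  d
}

as_design_table <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("sample_id", "group") %in% names(x)))
      stop("design must have columns 'sample_id' and 'group'")
    x$sample_id <- as.character(x$sample_id)
    x$group <- as.character(x$group)
    if (anyDuplicated(x$sample_id)) stop("duplicated sample_id in design")
    return(x)
  }
  stop("design must be a data.frame")
}

#' Group labels in design order
#'
#' Distinct group labels in order of first appearance in the design table.
#' This order fixes the orientation of U/D/n profile strings.
#'
#' @param design a design `data.frame`.
#' @return character vector of group labels.
#' @export
group_levels <- function(design) unique(as_design_table(design)$group)

# columns of m belonging to one group
group_columns <- function(m, g) which(m$design$group == g)
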