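#' Cycle-threshold table for comparative delta-Ct quantification
#'
#' @param ct samples x genes numeric matrix of Ct values (cycles); rownames
#'   are sample identifiers, colnames gene symbols.
#' @param reference_gene internal-control gene, must be a column of `ct`.
#' @param design design table covering the samples.
#' @param calibrator_group group whose mean expression defines RQ = 1.
#' @return a `CtTable` object.
#' @export
ct_table <- function(ct, reference_gene, design, calibrator_group) {
  stopifnot(is.matrix(ct), is.numeric(ct))
  if (any(!is.finite(ct))) stop("Ct values must be finite")
  design <- as_design_table(design)
  if (!setequal(rownames(ct), design$sample_id))
    stop("Ct rows and design sample_ids do not match")
  ct <- ct[design$sample_id, , drop = FALSE]
  if (!reference_gene %in% colnames(ct))
    stop("reference gene ", reference_gene, " missing from Ct table")
  if (!calibrator_group %in% design$group)
    stop("calibrator group ", calibrator_group, " not in design")
  structure(list(ct = ct, reference_gene = reference_gene, design = design,
                 calibrator_group = calibrator_group),
            class = "CtTable")
}

#' @export
print.CtTable <- function(x, ...) {
  cat(sprintf("CtTable: %d samples x %d genes, reference %s, calibrator %s\n",
              nrow(x$ct), ncol(x$ct), x$reference_gene, x$calibrator_group))
  invisible(x)
}

#' Comparative delta-delta-Ct relative quantification
#'
#' Per sample and gene: `dCt = Ct_gene - Ct_reference`; `ddCt = dCt - mean
#' dCt over the calibrator group's samples`; `RQ = 2^(-ddCt)`. By
#' construction the calibrator group's geometric mean RQ is exactly 1 for
#' every gene, and adding a constant to all Ct values of a sample leaves RQ
#' unchanged (reference-gene cancellation). Amplification efficiency is
#' fixed at 2 (the comparative method's assumption).
#'
#' @param t a `CtTable`.
#' @return samples x genes matrix of RQ values (reference gene excluded).
#' @export
relative_quantification <- function(t) {
  stopifnot(inherits(t, "CtTable"))
  ref <- t$ct[, t$reference_gene]
  if (any(is.na(ref)))
    stop("missing reference Ct for sample(s): ",
         paste(rownames(t$ct)[is.na(ref)], collapse = ", "))
  genes <- setdiff(colnames(t$ct), t$reference_gene)
  dct <- t$ct[, genes, drop = FALSE] - ref
  cal <- t$design$sample_id[t$design$group == t$calibrator_group]
  cal_mean <- colMeans(dct[cal, , drop = FALSE])
  ddct <- sweep(dct, 2, cal_mean)
  2^(-ddct)
}

#' Sign concordance between qPCR and microarray fold changes
#'
#' For the genes shared between an RQ table and a microarray contrast
#' (test group vs calibrator), the fraction whose qPCR direction --
#' `sign(mean log2 RQ over the test group's samples)` -- agrees with the
#' sign of the microarray log2 fold change.
#'
#' @param rq samples x genes RQ matrix from [relative_quantification()].
#' @param design design table for the RQ samples.
#' @param contrast contrast data.frame with `log2fc` oriented as test group
#'   minus calibrator, and gene symbols in a `gene_symbol` column (or
#'   `probe_id` holding symbols).
#' @param group test group label.
#' @return sign-agreement rate in `[0, 1]`.
#' @export
concordance <- function(rq, design, contrast, group) {
  design <- as_design_table(design)
  sym_col <- if (!is.null(contrast$gene_symbol)) "gene_symbol" else "probe_id"
  shared <- intersect(colnames(rq), contrast[[sym_col]])
  if (!length(shared)) stop("no shared genes between RQ table and contrast")
  rows <- design$sample_id[design$group == group]
  if (!length(rows)) stop("no samples in group ", group)
  log_rq <- log2(rq[rows, shared, drop = FALSE])
  qpcr_sign <- sign(colMeans(log_rq))
  arr_sign <- sign(contrast$log2fc[match(shared, contrast[[sym_col]])])
  mean(qpcr_sign == arr_sign)
}
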