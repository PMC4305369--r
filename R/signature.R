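#' FC score of a profile row
#'
#' The summed fold-change score: for one reference cell type, each of the
#' up to `n_groups - 1` pairwise log2 fold changes contributes to the sum
#' only where differential expression was called (`U` or `D`); contrasts
#' called `n` contribute 0. A gene up-regulated against all four other
#' types at log2FC = 2 therefore scores exactly +8 in a five-type design.
#'
#' @param calls character vector (or single string) of U/D/n calls.
#' @param log2fc numeric vector of the matching log2 fold changes.
#' @return the FC score (scalar).
#' @export
fc_score <- function(calls, log2fc) {
  if (length(calls) == 1 && nchar(calls) > 1)
    calls <- strsplit(calls, "")[[1]]
  if (length(calls) != length(log2fc))
    stop("calls and log2fc lengths differ")
  sum(log2fc[calls != "n"])
}

# profile rows restricted to annotated genes
annotated_rows <- function(profile) {
  stopifnot(inherits(profile, "CellTypeProfile"))
  profile$rows[!is.na(profile$rows$gene_symbol), , drop = FALSE]
}

#' Cell-type-specific probes and genes
#'
#' Probes called up-regulated against every other group in the reference
#' profile; the annotated subset is additionally reported as gene symbols.
#'
#' @param profile a `CellTypeProfile` for the cell type of interest.
#' @return list with `probes` (probe identifiers) and `genes` (symbols of
#'   the annotated subset), both ordered by descending FC score.
#' @export
select_specific <- function(profile) {
  stopifnot(inherits(profile, "CellTypeProfile"))
  r <- profile$rows
  all_u <- r$calls == strrep("U", length(profile$others))
  r <- r[all_u, , drop = FALSE]
  r <- r[order(-r$fc_score, r$probe_id), , drop = FALSE]
  list(probes = r$probe_id,
       genes = unique(r$gene_symbol[!is.na(r$gene_symbol)]))
}

#' Shared stem-cell signature by FC-score intersection
#'
#' Genes strongly under-expressed in every somatic reference relative to
#' the remaining cell types: annotated genes whose FC score is at most
#' `-threshold` in each somatic profile; the intersection over somatic
#' references is returned. With the study defaults (score threshold 8,
#' i.e. log2FC >= 2 against each of four other types) this extracts the
#' shared stem/pluripotency set.
#'
#' @param profiles named list of `CellTypeProfile`s (names = reference
#'   groups), containing every somatic reference.
#' @param somatic_refs somatic reference group labels.
#' @param threshold positive FC-score threshold (default 8).
#' @return sorted character vector of gene symbols.
#' @export
select_shared_stem <- function(profiles, somatic_refs, threshold = 8) {
  if (threshold <= 0) stop("threshold must be > 0")
  missing <- setdiff(somatic_refs, names(profiles))
  if (length(missing))
    stop("missing profile(s): ", paste(missing, collapse = ", "))
  sets <- lapply(somatic_refs, function(g) {
    r <- annotated_rows(profiles[[g]])
    unique(r$gene_symbol[r$fc_score <= -threshold])
  })
  sort(Reduce(intersect, sets))
}

#' Germ-cell signature from the germ-analog profile
#'
#' Annotated genes whose FC score in the germ-analog (PGC-like) profile
#' reaches `threshold`, ranked by descending score (ties broken by probe
#' identifier).
#'
#' @param profile the germ-analog `CellTypeProfile`.
#' @param threshold minimum FC score (default 8).
#' @return data.frame with `gene_symbol`, `probe_id`, `fc_score`, ranked.
#' @export
select_germ <- function(profile, threshold = 8) {
  r <- annotated_rows(profile)
  r <- r[r$fc_score >= threshold, c("gene_symbol", "probe_id", "fc_score"),
         drop = FALSE]
  r <- r[order(-r$fc_score, r$probe_id), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Venn partition of differential-expression lists
#'
#' Counts every non-empty membership pattern over the input sets. Region
#' keys are membership bitstrings in the order of the input list ("10" =
#' only in the first of two sets).
#'
#' @param de_lists named list (>= 2) of character vectors.
#' @return named integer vector of region counts; the counts sum to the
#'   size of the union.
#' @export
venn_partition <- function(de_lists) {
  if (length(de_lists) < 2) stop("need at least 2 lists")
  universe <- unique(unlist(de_lists, use.names = FALSE))
  if (!length(universe)) return(stats::setNames(integer(0), character(0)))
  member <- vapply(de_lists, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, 1)
  key <- apply(member, 1, function(b) paste(as.integer(b), collapse = ""))
  tab <- table(key)
  stats::setNames(as.integer(tab), names(tab))
}

#' Assemble a signature report
#'
#' Runs the signature extraction end to end over a set of cell-type
#' profiles: per-type specific lists, the shared stem signature over the
#' somatic references, the germ signature, and the Venn partition of the
#' per-type DE probe lists.
#'
#' @param profiles named list of `CellTypeProfile`s for every group.
#' @param somatic_refs somatic reference group labels.
#' @param germ_ref germ-analog group label.
#' @param score_threshold FC-score threshold (default 8).
#' @return a `SignatureReport` list: `specific` (per group), `shared_stem`,
#'   `germ`, `venn`, `thresholds`.
#' @export
signature_report <- function(profiles, somatic_refs, germ_ref,
                             score_threshold = 8) {
  specific <- lapply(profiles, select_specific)
  de_lists <- lapply(profiles, function(p) p$rows$probe_id)
  structure(list(
    specific = specific,
    shared_stem = select_shared_stem(profiles, somatic_refs, score_threshold),
    germ = select_germ(profiles[[germ_ref]], score_threshold),
    venn = venn_partition(de_lists),
    thresholds = list(score = score_threshold, somatic_refs = somatic_refs,
                      germ_ref = germ_ref)),
    class = "SignatureReport")
}

#' @export
print.SignatureReport <- function(x, ...) {
  cat("SignatureReport\n")
  for (g in names(x$specific))
    cat(sprintf("  specific %-6s: %4d probes (%d genes)\n", g,
                length(x$specific[[g]]$probes), length(x$specific[[g]]$genes)))
  cat(sprintf("  shared stem   : %4d genes (score <= -%g in each of %s)\n",
              length(x$shared_stem), x$thresholds$score,
              paste(x$thresholds$somatic_refs, collapse = ", ")))
  cat(sprintf("  germ          : %4d genes (score >= %g in %s)\n",
              nrow(x$germ), x$thresholds$score, x$thresholds$germ_ref))
  invisible(x)
}
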