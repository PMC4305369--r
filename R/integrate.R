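#' Collapse a probe-level matrix to gene level
#'
#' One row per gene symbol, the mean of its probes' rows; unannotated
#' probes are dropped. Symbols are matched case-insensitively (upper-cased)
#' so cross-species symbol identity works downstream.
#'
#' @param m a probe-level `ExpressionMatrix` with unique probe rows.
#' @param ann an `AnnotationTable`.
#' @return a gene-level `ExpressionMatrix`.
#' @export
collapse_probes_to_genes <- function(m, ann) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  sym <- annotation_symbols(ann, rownames(m$values))
  keep <- !is.na(sym)
  if (!any(keep))
    stop("no overlap between matrix probes and annotated probes")
  v <- m$values[keep, , drop = FALSE]
  sym <- toupper(sym[keep])
  sums <- rowsum(v, group = sym, reorder = FALSE)
  counts <- as.vector(table(factor(sym, levels = unique(sym))))
  expression_matrix(sums / counts, m$design, level = "gene")
}

#' Build a cross-dataset "virtual array"
#'
#' Harmonizes gene-level datasets from different platforms onto one matrix:
#' restrict to the common gene symbols, quantile-normalize all samples to a
#' shared reference distribution, then center each gene within each dataset
#' at its dataset median. The per-dataset centering removes additive
#' platform/batch offsets while preserving within-dataset group structure,
#' so joint clustering reflects biology rather than platform.
#'
#' @param datasets list (>= 2) of gene-level `ExpressionMatrix` objects.
#' @param dataset_labels labels per dataset (default `ds1`, `ds2`, ... or
#'   the design's own `dataset` column where present).
#' @return an integrated gene-level `ExpressionMatrix` whose design carries
#'   a `dataset` column.
#' @export
build_virtual_array <- function(datasets, dataset_labels = NULL) {
  stopifnot(length(datasets) >= 2,
            all(vapply(datasets, inherits, TRUE, "ExpressionMatrix")))
  if (is.null(dataset_labels))
    dataset_labels <- vapply(seq_along(datasets), function(i) {
      d <- datasets[[i]]$design
      if (!is.null(d$dataset) && length(unique(d$dataset)) == 1)
        unique(d$dataset) else paste0("ds", i)
    }, "")
  common <- Reduce(intersect, lapply(datasets, function(d) rownames(d$values)))
  if (!length(common)) stop("no gene symbols common to all datasets")
  vals <- do.call(cbind, lapply(datasets, function(d)
    d$values[common, , drop = FALSE]))
  design <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]$design[, c("sample_id", "group"), drop = FALSE]
    d$dataset <- dataset_labels[i]
    d
  }))
  if (anyDuplicated(design$sample_id))
    stop("sample identifiers collide across datasets")
  m <- expression_matrix(vals, design, level = "gene")
  m <- quantile_between_arrays(m)
  for (lab in unique(design$dataset)) {
    cols <- which(m$design$dataset == lab)
    med <- apply(m$values[, cols, drop = FALSE], 1, stats::median)
    m$values[, cols] <- m$values[, cols] - med
  }
  m
}

#' Rank genes by one-way ANOVA across groups
#'
#' Per-gene one-way F across the biological group labels, vectorized over
#' rows. Genes are ranked by ascending p, ties by descending F, then by
#' symbol. Rows with zero between- and within-group variation get F = 0,
#' p = 1.
#'
#' @param m an `ExpressionMatrix` (gene- or probe-level); groups need >= 2
#'   samples each.
#' @return data.frame `gene`, `F`, `p`, `rank`, sorted by rank.
#' @export
anova_rank <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  grp <- m$design$group
  groups <- unique(grp)
  n_per <- table(factor(grp, levels = groups))
  if (any(n_per < 2))
    stop("group(s) with a single sample: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  k <- length(groups); N <- ncol(v)
  if (k < 2) stop("need at least 2 groups")
  grand <- rowMeans(v)
  ss_between <- numeric(nrow(v)); ss_within <- numeric(nrow(v))
  for (g in groups) {
    cols <- which(grp == g)
    mg <- rowMeans(v[, cols, drop = FALSE])
    ss_between <- ss_between + length(cols) * (mg - grand)^2
    ss_within <- ss_within + rowSums((v[, cols, drop = FALSE] - mg)^2)
  }
  Fstat <- (ss_between / (k - 1)) / (ss_within / (N - k))
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  zero <- ss_within == 0
  Fstat[zero & ss_between == 0] <- 0
  p[zero & ss_between == 0] <- 1
  Fstat[zero & ss_between > 0] <- Inf
  p[zero & ss_between > 0] <- 0
  out <- data.frame(gene = rownames(v), F = unname(Fstat), p = unname(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, -out$F, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Top ANOVA-ranked submatrix
#'
#' @param m an `ExpressionMatrix`.
#' @param k number of top-ranked genes to keep (default 1000, truncated to
#'   the available rows).
#' @param ranking optional precomputed [anova_rank()] result.
#' @return an `ExpressionMatrix` restricted to the top `k` genes.
#' @export
top_ranked <- function(m, k = 1000, ranking = NULL) {
  if (is.null(ranking)) ranking <- anova_rank(m)
  keep <- ranking$gene[seq_len(min(k, nrow(ranking)))]
  m$values <- m$values[keep, , drop = FALSE]
  m
}

#' PCA sample scores with replicate barycenters
#'
#' Row-centered principal component analysis over samples. Each group's
#' barycenter is the mean score of its replicates; variance fractions are
#' per-component shares of the total variance. A constant matrix yields
#' all-zero scores.
#'
#' @param m an `ExpressionMatrix` (or plain features x samples matrix with
#'   a `design` argument).
#' @param design design table when `m` is a plain matrix.
#' @return list with `scores` (samples x components), `barycenters`
#'   (groups x components), `variance_fraction`.
#' @export
pca_scores <- function(m, design = NULL) {
  if (inherits(m, "ExpressionMatrix")) {
    v <- m$values; design <- m$design
  } else { v <- m; design <- as_design_table(design) }
  if (ncol(v) < 2) stop("need at least 2 samples")
  centered <- v - rowMeans(v)
  if (all(centered == 0)) {
    k <- min(dim(v)) - 1
    scores <- matrix(0, ncol(v), max(k, 1),
                     dimnames = list(colnames(v), paste0("PC", seq_len(max(k, 1)))))
    bary <- rowsum(scores, design$group) / as.vector(table(design$group)[unique(design$group)])
    return(list(scores = scores, barycenters = bary,
                variance_fraction = rep(0, ncol(scores))))
  }
  pc <- stats::prcomp(t(centered), center = TRUE, scale. = FALSE)
  scores <- pc$x
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  groups <- unique(design$group)
  bary <- t(vapply(groups, function(g)
    colMeans(scores[design$group == g, , drop = FALSE]),
    numeric(ncol(scores))))
  rownames(bary) <- groups
  list(scores = scores, barycenters = bary, variance_fraction = vf)
}

#' Hierarchical clustering of samples with newick export
#'
#' Agglomerative clustering of sample columns. Default distance is
#' 1 - Pearson correlation across genes; average linkage. Samples are
#' processed in sorted sample-id order so merge order is deterministic
#' under ties.
#'
#' @param m an `ExpressionMatrix` or plain features x samples matrix.
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return a `ClusterTree`: list with `hclust`, `merge_heights`, `newick`.
#' @export
hierarchical_tree <- function(m, distance = c("correlation", "euclidean"),
                              linkage = "average") {
  distance <- match.arg(distance)
  v <- if (inherits(m, "ExpressionMatrix")) m$values else m
  if (ncol(v) < 2) stop("need at least 2 samples")
  v <- v[, order(colnames(v)), drop = FALSE]
  if (distance == "correlation") {
    sds <- apply(v, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance sample(s) under correlation distance: ",
           paste(colnames(v)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(v))
  } else {
    d <- stats::dist(t(v))
  }
  hc <- stats::hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, merge_heights = hc$height,
                 newick = ape::write.tree(phy)),
            class = "ClusterTree")
}

#' @export
print.ClusterTree <- function(x, ...) {
  cat(sprintf("ClusterTree: %d leaves, %d merges, max height %.4g\n",
              length(x$hclust$labels), length(x$merge_heights),
              max(x$merge_heights)))
  invisible(x)
}

#' Cophenetic distances of a ClusterTree
#' @param tree a `ClusterTree`.
#' @return a full symmetric matrix of cophenetic distances.
#' @export
tree_cophenetic <- function(tree) {
  stopifnot(inherits(tree, "ClusterTree"))
  as.matrix(stats::cophenetic(tree$hclust))
}
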