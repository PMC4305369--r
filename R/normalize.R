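#' Within-array lowess normalization against a pseudo-reference
#'
#' Single-channel analog of MA-plot lowess: for each array, the deviation
#' M from the per-probe mean across arrays (the pseudo-reference) is
#' smoothed against the pseudo-reference itself (the probe's mean
#' log-intensity A) with a robust lowess curve, and the fitted
#' intensity-dependent trend is subtracted. Using the across-array mean as
#' the abscissa keeps genuinely differential probes spread over the A axis
#' instead of clustering at the extreme of their own array's range, so the
#' robust smoother is not dragged by them. For two arrays this reduces to
#' classic MA-plot lowess up to the factor one-half in M.
#'
#' Because correcting the arrays changes the pseudo-reference, the
#' correction is iterated (as in cyclic loess); two passes suffice for the
#' residual trend to drop well below the smoother's own tolerance.
#'
#' @param m a log2-scale probe-level `ExpressionMatrix` with >= 2 arrays.
#' @param span lowess smoother span, in (0, 1].
#' @param iter robustifying iterations of the smoother.
#' @param passes correction passes over the array set.
#' @return the normalized `ExpressionMatrix`.
#' @export
lowess_within_array <- function(m, span = 0.3, iter = 3, passes = 2) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  v <- m$values
  if (ncol(v) < 2) stop("need at least 2 arrays")
  for (p in seq_len(passes)) {
    ref <- rowMeans(v)
    for (j in seq_len(ncol(v))) {
      M <- v[, j] - ref
      fit <- stats::lowess(ref, M, f = span, iter = iter)
      trend <- stats::approx(fit$x, fit$y, xout = ref, rule = 2, ties = mean)$y
      v[, j] <- v[, j] - trend
    }
  }
  m$values <- v
  m
}

#' Average-quantile normalization between arrays
#'
#' Forces every array onto the common reference distribution defined by the
#' across-array mean of order statistics: the value of rank k in each column
#' becomes the mean over columns of the rank-k values. Tied values receive
#' the mean of the reference values their rank span covers, so the map is
#' well defined and idempotent.
#'
#' @param m an `ExpressionMatrix` with no missing values.
#' @return the quantile-normalized `ExpressionMatrix`.
#' @export
quantile_between_arrays <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  if (ncol(v) < 2) {
    warning("single array: quantile normalization is the identity")
    return(m)
  }
  if (nrow(v) == 0) return(m)
  ref <- rowMeans(apply(v, 2L, sort))
  for (j in seq_len(ncol(v))) {
    out <- numeric(nrow(v))
    out[order(v[, j])] <- ref
    # ties span several ranks: assign the mean of the reference values spanned
    v[, j] <- stats::ave(out, v[, j], FUN = mean)
  }
  m$values <- v
  m
}

#' Average duplicate spots
#'
#' Rows sharing a probe identifier are replaced by their arithmetic mean per
#' sample; the order of first occurrence is preserved.
#'
#' @param m a probe-level `ExpressionMatrix`.
#' @return an `ExpressionMatrix` with unique probe rows.
#' @export
average_duplicates <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  ids <- rownames(v)
  if (!anyDuplicated(ids)) return(m)
  first <- !duplicated(ids)
  sums <- rowsum(v, group = ids, reorder = FALSE)
  counts <- as.vector(table(factor(ids, levels = ids[first])))
  m$values <- sums / counts
  m
}

#' Run the full preprocessing chain on a set of array scans
#'
#' normexp background correction (per array, parameters fitted by maximum
#' likelihood from that array's intensities) -> log2 -> within-array lowess
#' against the pseudo-reference -> between-array average-quantile
#' normalization -> duplicate-spot averaging.
#'
#' @param scans list of `ArrayScan` objects sharing an identical ordered
#'   probe list.
#' @param design design table mapping the scan `array_id`s to groups.
#' @param span lowess span.
#' @param log_offset constant added before log2 (default 0).
#' @param use_local_background subtract the scanner's local background
#'   column before model-based correction (default FALSE: model-only
#'   correction of the foreground).
#' @param exclude_flagged drop spots flagged (< 0) on any array.
#' @return list with `matrix` (normalized probe-level `ExpressionMatrix`,
#'   one row per unique probe) and `normexp_params` (per-array fitted
#'   `NormexpParams`).
#' @export
preprocess_experiment <- function(scans, design, span = 0.3, log_offset = 0,
                                  use_local_background = FALSE,
                                  exclude_flagged = FALSE) {
  stopifnot(length(scans) >= 2, all(vapply(scans, inherits, TRUE, "ArrayScan")))
  ids <- scans[[1]]$probes$probe_id
  for (s in scans[-1])
    if (!identical(s$probes$probe_id, ids))
      stop("arrays do not share an identical ordered probe list (",
           s$array_id, ")")
  keep <- rep(TRUE, length(ids))
  if (exclude_flagged)
    for (s in scans) keep <- keep & s$probes$flag >= 0
  arr_ids <- vapply(scans, function(s) s$array_id, "")
  v <- matrix(NA_real_, sum(keep), length(scans),
              dimnames = list(ids[keep], arr_ids))
  params <- vector("list", length(scans))
  names(params) <- arr_ids
  for (j in seq_along(scans)) {
    x <- scans[[j]]$probes$foreground
    if (use_local_background)
      x <- x - scans[[j]]$probes$background
    x <- x[keep]
    p <- estimate_normexp(x)
    params[[j]] <- p
    v[, j] <- log2(normexp_correct(x, p) + log_offset)
  }
  m <- expression_matrix(v, design, level = "probe")
  m <- lowess_within_array(m, span = span)
  m <- quantile_between_arrays(m)
  m <- average_duplicates(m)
  list(matrix = m, normexp_params = params)
}
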