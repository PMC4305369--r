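#' Fit the per-probe group-means model
#'
#' Computes per-row group means and the pooled within-group residual
#' variance with `N - k` degrees of freedom, the sufficient statistics for
#' all pairwise moderated-t contrasts.
#'
#' @param m an `ExpressionMatrix` (unique row identifiers).
#' @param design optional design override (defaults to `m$design`); every
#'   group needs >= 2 replicates.
#' @return a `GeneFit`: list with `means` (rows x groups), `s2` (pooled
#'   variance per row), `df` (residual degrees of freedom, scalar),
#'   `n_per_group`, `groups`.
#' @export
fit_group_model <- function(m, design = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  design <- if (is.null(design)) m$design else as_design_table(design)
  v <- m$values
  groups <- group_levels(design)
  n_per <- table(factor(design$group, levels = groups))
  small <- names(n_per)[n_per < 2]
  if (length(small))
    stop("group(s) with fewer than 2 replicates: ",
         paste(small, collapse = ", "))
  k <- length(groups)
  N <- nrow(design)
  means <- matrix(NA_real_, nrow(v), k, dimnames = list(rownames(v), groups))
  rss <- numeric(nrow(v))
  for (g in groups) {
    cols <- design$sample_id[design$group == g]
    sub <- v[, cols, drop = FALSE]
    mg <- rowMeans(sub)
    means[, g] <- mg
    rss <- rss + rowSums((sub - mg)^2)
  }
  structure(list(means = means, s2 = rss / (N - k), df = N - k,
                 n_per_group = stats::setNames(as.integer(n_per), groups),
                 groups = groups),
            class = "GeneFit")
}

#' @export
print.GeneFit <- function(x, ...) {
  cat(sprintf("GeneFit: %d rows, groups %s, residual df %d\n",
              nrow(x$means), paste(x$groups, collapse = "/"), x$df))
  invisible(x)
}

# Newton solve of trigamma(y) = x, vectorized (decreasing convex function)
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior of the moderated t-statistic by
#' matching the first two moments of `log(s^2)` to the theoretical
#' log-F/log-chi-square law (trigamma matching). If the observed variances
#' show no excess dispersion beyond the sampling law, the prior degrees of
#' freedom are infinite and `s0_sq` is the common variance.
#'
#' @param fit a `GeneFit` with at least 10 rows of positive `s2`.
#' @param d0_cap cap treated as the infinity sentinel.
#' @return a `ModerationPrior`: list with `d0` (prior df, possibly `Inf`)
#'   and `s0_sq` (prior variance).
#' @export
estimate_prior <- function(fit, d0_cap = 1e6) {
  stopifnot(inherits(fit, "GeneFit"))
  s2 <- fit$s2[is.finite(fit$s2) & fit$s2 > 0]
  if (length(s2) < 10)
    stop("need at least 10 rows with positive residual variance, got ",
         length(s2))
  df <- fit$df
  # e is an unbiased estimate of log(sigma_g^2) per row
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    if (d0 >= d0_cap) d0 <- Inf
  } else d0 <- Inf
  s0_sq <- if (is.finite(d0))
    exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  else if (stats::var(log(s2)) == 0)
    s2[1]          # literally constant variances: the common value itself
  else exp(mean(e))
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ModerationPrior")
}

#' @export
print.ModerationPrior <- function(x, ...) {
  cat(sprintf("ModerationPrior: d0 = %s, s0_sq = %.4g\n",
              if (is.finite(x$d0)) sprintf("%.3f", x$d0) else "Inf", x$s0_sq))
  invisible(x)
}

#' Moderated t-statistics for one pairwise contrast
#'
#' Shrinks each row's residual variance toward the prior,
#' `s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and tests
#' `log2FC = mean_a - mean_b` with `t = log2FC / (s_tilde sqrt(1/n_a +
#' 1/n_b))` on `d0 + d_g` degrees of freedom (normal when `d0` is
#' infinite). With `d0 = 0` this is the ordinary pooled two-sample t.
#'
#' @param fit a `GeneFit`.
#' @param prior a `ModerationPrior` (or `list(d0 =, s0_sq =)`).
#' @param pair character vector `c(a, b)` of group labels; positive log2FC
#'   means higher in `a`.
#' @return data.frame with `probe_id`, `log2fc`, `t_mod`, `p_raw`.
#' @export
moderated_t <- function(fit, prior, pair) {
  stopifnot(inherits(fit, "GeneFit"), length(pair) == 2)
  if (!all(pair %in% fit$groups))
    stop("unknown group(s): ", paste(setdiff(pair, fit$groups), collapse = ", "))
  d0 <- prior$d0; s0 <- prior$s0_sq
  if (is.null(d0) || is.null(s0) || d0 < 0 || s0 <= 0)
    stop("invalid moderation prior")
  lfc <- fit$means[, pair[1]] - fit$means[, pair[2]]
  dg <- fit$df
  s2t <- if (is.finite(d0)) (d0 * s0 + dg * fit$s2) / (d0 + dg) else rep(s0, length(lfc))
  se <- sqrt(s2t * (1 / fit$n_per_group[pair[1]] + 1 / fit$n_per_group[pair[2]]))
  t <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_tot <- d0 + dg
  p <- if (is.finite(df_tot)) 2 * stats::pt(abs(t), df = df_tot, lower.tail = FALSE)
       else 2 * stats::pnorm(abs(t), lower.tail = FALSE)
  p[is.infinite(t)] <- 0
  p[t == 0 & se == 0] <- 1
  data.frame(probe_id = rownames(fit$means), log2fc = unname(lfc),
             t_mod = unname(t), p_raw = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, monotone in raw-p rank
#' order and capped at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential expression with dual thresholds
#'
#' A probe is up-regulated (`U`) when the adjusted p-value passes `alpha`
#' and `log2fc` exceeds `lfc`, down-regulated (`D`) for the mirror case,
#' otherwise not differential (`n`). Defaults use strict inequalities
#' (adjusted p < 0.05, |log2FC| > 2); set `strict = FALSE` for the
#' inclusive variant (<=, >=).
#'
#' @param ct a contrast data.frame containing `log2fc` and `p_adj` (or
#'   `p_raw`, which is then adjusted).
#' @param alpha adjusted-p significance level.
#' @param lfc absolute log2 fold-change threshold.
#' @param strict use strict inequalities.
#' @return `ct` with columns `p_adj` and `call`.
#' @export
call_de <- function(ct, alpha = 0.05, lfc = 2, strict = TRUE) {
  stopifnot(is.data.frame(ct), "log2fc" %in% names(ct))
  if (is.null(ct$p_adj)) ct$p_adj <- bh_adjust(ct$p_raw)
  sig <- if (strict) ct$p_adj < alpha else ct$p_adj <= alpha
  up <- if (strict) ct$log2fc > lfc else ct$log2fc >= lfc
  dn <- if (strict) ct$log2fc < -lfc else ct$log2fc <= -lfc
  ct$call <- ifelse(sig & up, "U", ifelse(sig & dn, "D", "n"))
  ct
}

#' All pairwise contrasts with calls
#'
#' Runs [moderated_t()], [bh_adjust()] (per contrast) and [call_de()] for
#' every unordered pair of groups. The returned list is keyed `"a|b"` in
#' design group order; each element carries attributes `group_a`,
#' `group_b`.
#'
#' @param fit a `GeneFit`.
#' @param prior a `ModerationPrior`.
#' @param alpha,lfc,strict thresholds passed to [call_de()].
#' @param pool_bh adjust p-values pooled across all contrasts instead of
#'   per contrast.
#' @return named list of contrast data.frames.
#' @export
all_contrasts <- function(fit, prior, alpha = 0.05, lfc = 2, strict = TRUE,
                          pool_bh = FALSE) {
  g <- fit$groups
  pairs <- utils::combn(g, 2, simplify = FALSE)
  tabs <- lapply(pairs, function(p) {
    ct <- moderated_t(fit, prior, p)
    attr(ct, "group_a") <- p[1]; attr(ct, "group_b") <- p[2]
    ct
  })
  names(tabs) <- vapply(pairs, paste, "", collapse = "|")
  if (pool_bh) {
    all_p <- unlist(lapply(tabs, `[[`, "p_raw"), use.names = FALSE)
    adj <- bh_adjust(all_p)
    off <- 0L
    for (i in seq_along(tabs)) {
      n <- nrow(tabs[[i]])
      tabs[[i]]$p_adj <- adj[(off + 1L):(off + n)]
      off <- off + n
    }
  } else {
    tabs <- lapply(tabs, function(ct) { ct$p_adj <- bh_adjust(ct$p_raw); ct })
  }
  lapply(tabs, call_de, alpha = alpha, lfc = lfc, strict = strict)
}

# fetch the contrast (a, b) from a contrast list, flipping sign if stored
# as (b, a); flipping negates log2fc and t and preserves p and mirrors calls
get_contrast <- function(tables, a, b) {
  key <- paste(a, b, sep = "|"); rkey <- paste(b, a, sep = "|")
  if (!is.null(tables[[key]])) return(tables[[key]])
  if (!is.null(tables[[rkey]])) {
    ct <- tables[[rkey]]
    ct$log2fc <- -ct$log2fc
    ct$t_mod <- -ct$t_mod
    if (!is.null(ct$call))
      ct$call <- c(U = "D", D = "U", n = "n")[ct$call]
    attr(ct, "group_a") <- a; attr(ct, "group_b") <- b
    return(ct)
  }
  stop("missing contrast: ", a, " vs ", b)
}

#' Build a cell-type profile of U/D/n calls and fold changes
#'
#' For one reference group, orients every contrast as reference minus other
#' (other groups in design order), keeps the probes with at least one
#' non-`n` call, and records the ordered call string and log2 fold
#' changes. The FC score (sum of log2FC over non-`n` calls) is attached by
#' [fc_score()].
#'
#' @param reference reference group label.
#' @param tables contrast list from [all_contrasts()].
#' @param groups all group labels in design order.
#' @param annotation optional `AnnotationTable` to attach gene symbols.
#' @return a `CellTypeProfile`: list with `reference`, `others` (ordered
#'   non-reference groups) and `rows` (data.frame: `probe_id`,
#'   `gene_symbol`, `calls` string, `log2fc_<other>` columns, `fc_score`).
#' @export
build_profile <- function(reference, tables, groups, annotation = NULL) {
  if (!reference %in% groups) stop("unknown reference group: ", reference)
  others <- setdiff(groups, reference)
  cts <- lapply(others, function(o) get_contrast(tables, reference, o))
  ids <- cts[[1]]$probe_id
  calls <- vapply(cts, `[[`, character(length(ids)), "call")
  lfcs <- vapply(cts, `[[`, numeric(length(ids)), "log2fc")
  if (length(ids) == 1) { calls <- matrix(calls, 1); lfcs <- matrix(lfcs, 1) }
  keep <- rowSums(calls != "n") >= 1
  rows <- data.frame(probe_id = ids[keep],
                     gene_symbol = if (is.null(annotation)) NA_character_
                                   else annotation_symbols(annotation, ids[keep]),
                     calls = apply(calls[keep, , drop = FALSE], 1, paste, collapse = ""),
                     stringsAsFactors = FALSE)
  lf <- lfcs[keep, , drop = FALSE]
  colnames(lf) <- paste0("log2fc_", others)
  rows <- cbind(rows, as.data.frame(lf))
  rows$fc_score <- rowSums(lf * (calls[keep, , drop = FALSE] != "n"))
  structure(list(reference = reference, others = others, rows = rows),
            class = "CellTypeProfile")
}

#' @export
print.CellTypeProfile <- function(x, ...) {
  cat(sprintf("CellTypeProfile '%s' vs %s: %d probes with >= 1 call\n",
              x$reference, paste(x$others, collapse = "/"), nrow(x$rows)))
  invisible(x)
}

#' Count differentially expressed probes in one contrast
#'
#' @param tables contrast list from [all_contrasts()].
#' @param a,b group labels; `a == b` returns 0.
#' @return number of probes called `U` or `D` in the (a, b) contrast.
#' @export
pairwise_de_count <- function(tables, a, b) {
  if (a == b) return(0L)
  ct <- get_contrast(tables, a, b)
  sum(ct$call != "n")
}

#' Pairwise DE-count matrix over all groups
#'
#' @param tables contrast list from [all_contrasts()].
#' @param groups group labels in display order.
#' @return symmetric integer matrix of DE counts.
#' @export
pairwise_de_matrix <- function(tables, groups) {
  k <- length(groups)
  out <- matrix(0L, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    out[i, j] <- pairwise_de_count(tables, groups[i], groups[j])
  out
}
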