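two_group_fit <- function(rows, groups = c("A", "A", "A", "B", "B", "B")) {
  v <- do.call(rbind, rows)
  rownames(v) <- sprintf("g%d", seq_len(nrow(v)))
  colnames(v) <- sprintf("s%d", seq_len(ncol(v)))
  fit_group_model(expression_matrix(v, design_table(colnames(v), groups)))
}

test_that("group model pools within-group variance with N - k df", {
  f <- two_group_fit(list(c(1, 1, 1, 3, 3, 3)))
  expect_equal(unname(f$means[1, ]), c(1, 3))
  expect_equal(unname(f$s2[1]), 0)
  expect_equal(f$df, 4)

  f2 <- two_group_fit(list(c(1, 2, 3, 4, 6, 8)))
  expect_equal(unname(f2$means[1, ]), c(2, 6))
  expect_equal(unname(f2$s2[1]), 2.5)   # (2 + 8) / 4

  v <- matrix(stats::rnorm(8), 2, 4,
              dimnames = list(c("a", "b"), sprintf("s%d", 1:4)))
  expect_error(
    fit_group_model(expression_matrix(
      v, design_table(colnames(v), c("A", "A", "A", "B")))),
    "B")
})

test_that("variance prior recovers a planted scaled-inverse-chi-square law", {
  set.seed(201)
  d0 <- 4; s02 <- 0.04; dg <- 4; n <- 20000
  sigma2 <- d0 * s02 / stats::rchisq(n, d0)
  s2 <- sigma2 * stats::rchisq(n, dg) / dg
  fit <- structure(list(s2 = s2, df = dg,
                        means = matrix(0, n, 2,
                                       dimnames = list(sprintf("g%d", 1:n),
                                                       c("A", "B"))),
                        n_per_group = c(A = 3L, B = 3L),
                        groups = c("A", "B")),
                   class = "GeneFit")
  pr <- estimate_prior(fit)
  expect_lt(abs(pr$d0 - d0) / d0, 0.10)
  expect_lt(abs(pr$s0_sq - s02) / s02, 0.05)
})

test_that("prior estimation agrees with the independent reference implementation", {
  set.seed(202)
  s2 <- 0.05 * stats::rchisq(5000, 4) / 4 * (6 / stats::rchisq(5000, 6))
  fit <- structure(list(s2 = s2, df = 4,
                        means = matrix(0, 5000, 2),
                        n_per_group = c(A = 3L, B = 3L),
                        groups = c("A", "B")),
                   class = "GeneFit")
  pr <- estimate_prior(fit)
  ref <- limma::fitFDist(s2, df1 = 4)
  expect_equal(pr$d0, ref$df2, tolerance = 0.02)
  expect_equal(pr$s0_sq, ref$scale, tolerance = 0.02)
})

test_that("identical variances give the infinite-d0 sentinel", {
  fit <- structure(list(s2 = rep(0.25, 50), df = 4,
                        means = matrix(0, 50, 2),
                        n_per_group = c(A = 3L, B = 3L),
                        groups = c("A", "B")),
                   class = "GeneFit")
  pr <- estimate_prior(fit)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 0.25, tolerance = 1e-10)
  expect_error(estimate_prior(structure(
    list(s2 = rep(1, 5), df = 4), class = "GeneFit")), "at least 10")
})

test_that("moderated t with d0 = 0 equals an independently coded pooled t", {
  set.seed(203)
  v <- matrix(stats::rnorm(50 * 6, 8, 1), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
  fit <- fit_group_model(expression_matrix(
    v, design_table(colnames(v), rep(c("A", "B"), each = 3))))
  ct <- moderated_t(fit, list(d0 = 0, s0_sq = 1), c("A", "B"))
  for (i in 1:50) {
    a <- v[i, 1:3]; b <- v[i, 4:6]
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 4
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
    expect_equal(ct$t_mod[i], tt, tolerance = 1e-10)
    expect_equal(ct$p_raw[i], 2 * stats::pt(abs(tt), 4, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("moderated t limits and hand-worked shrinkage example hold", {
  fit <- structure(list(
    s2 = 3, df = 4,
    means = matrix(c(2, 0), 1, 2, dimnames = list("g1", c("A", "B"))),
    n_per_group = c(A = 3L, B = 3L), groups = c("A", "B")),
    class = "GeneFit")
  # d0 = 4, s0^2 = 1: s~^2 = (4*1 + 4*3)/8 = 2; t = 2/sqrt(2*(2/3))
  ct <- moderated_t(fit, list(d0 = 4, s0_sq = 1), c("A", "B"))
  expect_equal(ct$t_mod, 2 / sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(ct$t_mod, 1.7320508, tolerance = 1e-6)
  expect_equal(ct$p_raw, 2 * stats::pt(ct$t_mod, 8, lower.tail = FALSE))
  # infinite d0: s~^2 = s0^2, normal reference
  ct2 <- moderated_t(fit, list(d0 = Inf, s0_sq = 4), c("A", "B"))
  expect_equal(ct2$t_mod, 2 / sqrt(4 * (2 / 3)))
  expect_equal(ct2$p_raw, 2 * stats::pnorm(abs(ct2$t_mod), lower.tail = FALSE))
})

test_that("zero-variance rows produce the documented sentinels", {
  fit <- structure(list(
    s2 = c(0, 0), df = 4,
    means = matrix(c(1, 1, 1, 2), 2, 2,
                   dimnames = list(c("g1", "g2"), c("A", "B"))),
    n_per_group = c(A = 3L, B = 3L), groups = c("A", "B")),
    class = "GeneFit")
  ct <- moderated_t(fit, list(d0 = 0, s0_sq = 1), c("A", "B"))
  expect_equal(ct$t_mod[1], 0); expect_equal(ct$p_raw[1], 1)
  expect_equal(ct$t_mod[2], -Inf); expect_equal(ct$p_raw[2], 0)
})

test_that("contrast reversal negates log2FC and t everywhere", {
  p <- cached_pipeline()
  ab <- moderated_t(p$fit, p$prior, c("cES", "CEF"))
  ba <- moderated_t(p$fit, p$prior, c("CEF", "cES"))
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$t_mod, -ba$t_mod)
  expect_equal(ab$p_raw, ba$p_raw)
})

test_that("BH adjustment matches hand computations and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.5, 0.01)), c(0.5, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) {
      r <- which(o == i)  # rank of p[i]
      adj[i] <- min(1, min(m * p[o[r:m]] / (r:m)))
    }
    adj
  }
  set.seed(204)
  for (i in 1:10) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-14)
  }
})

test_that("U/D/n calls follow the dual-threshold rule", {
  ct <- data.frame(log2fc = c(2.5, 1.9, 5.0, -2.5, -3),
                   p_adj = c(0.04, 0.04, 0.06, 0.04, 0.05))
  out <- call_de(ct, alpha = 0.05, lfc = 2)
  expect_identical(out$call, c("U", "n", "n", "D", "n"))
  # inclusive variant admits the boundary
  out2 <- call_de(data.frame(log2fc = 2, p_adj = 0.05), strict = FALSE)
  expect_identical(out2$call, "U")
})

test_that("profiles keep only rows with at least one call, in design group order", {
  p <- cached_pipeline()
  prof <- build_profile("cES", p$tabs, p$cfg$groups, p$ex$annotation)
  expect_identical(prof$others, c("CEF", "BM2", "PGC", "cBC"))
  expect_true(all(nchar(prof$rows$calls) == 4))
  expect_true(all(grepl("[UD]", prof$rows$calls)))

  # a planted cES-specific probe is U against all four other types
  spec <- p$ex$truth$probe_id[p$ex$truth$class == "specific_cES"]
  got <- prof$rows$calls[match(spec, prof$rows$probe_id)]
  expect_gt(mean(got == "UUUU", na.rm = TRUE), 0.8)
  expect_error(build_profile("nope", p$tabs, p$cfg$groups), "unknown reference")
})

test_that("pairwise DE counts saturate for strong effects and vanish on the diagonal", {
  set.seed(205)
  sim <- simulate_two_group(n_probes = 300, n_de = 30, effect_log2 = 6,
                            sd_log2 = 0.1, seed = 205)
  fit <- fit_group_model(sim$matrix)
  pr <- estimate_prior(fit)
  tabs <- all_contrasts(fit, pr, alpha = 0.05, lfc = 2)
  expect_equal(pairwise_de_count(tabs, "A", "B"), 30)
  expect_equal(pairwise_de_count(tabs, "A", "A"), 0L)
  pm <- pairwise_de_matrix(tabs, c("A", "B"))
  expect_equal(unname(pm), matrix(c(0L, 30L, 30L, 0L), 2))
})

test_that("moderated t matches the reference empirical-Bayes pipeline", {
  set.seed(206)
  sim <- simulate_two_group(n_probes = 400, n_de = 40, effect_log2 = 2,
                            sd_log2 = 0.3, seed = 206)
  v <- sim$matrix$values
  fit <- fit_group_model(sim$matrix)
  pr <- estimate_prior(fit)
  ours <- moderated_t(fit, pr, c("B", "A"))
  design <- stats::model.matrix(~ 0 + factor(rep(c("A", "B"), each = 3),
                                             levels = c("A", "B")))
  colnames(design) <- c("A", "B")
  lfit <- limma::lmFit(v, design)
  lfit <- limma::contrasts.fit(lfit, limma::makeContrasts(B - A,
                                                          levels = design))
  eb <- limma::eBayes(lfit)
  expect_equal(unname(ours$t_mod), unname(eb$t[, 1]), tolerance = 1e-4)
  expect_equal(unname(ours$p_raw), unname(eb$p.value[, 1]), tolerance = 1e-4)
})
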