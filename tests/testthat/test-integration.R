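gene_matrix <- function(v, groups, dataset = NULL) {
  if (is.null(colnames(v))) colnames(v) <- sprintf("s%d", seq_len(ncol(v)))
  expression_matrix(v, design_table(colnames(v), groups, dataset = dataset),
                    level = "gene")
}

test_that("probe-to-gene collapsing averages probes and drops unannotated", {
  v <- matrix(c(2, 4, 1, 4, 6, 1), 3, 2,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  m <- expression_matrix(v, design_table(c("s1", "s2"), c("A", "B")))
  ann <- annotation_table(c("p1", "p2", "p3"), c("gx", "GX", ""))
  out <- collapse_probes_to_genes(m, ann)
  expect_identical(rownames(out$values), "GX")
  expect_equal(unname(out$values[1, ]), c(3, 5))
  expect_identical(out$level, "gene")

  ann2 <- annotation_table(c("p1", "p2", "p3"), c("", "", ""))
  expect_error(collapse_probes_to_genes(m, ann2), "no overlap")
})

test_that("virtual array restricts to common symbols and removes constant batches", {
  set.seed(401)
  g <- sprintf("G%03d", 1:120)
  v1 <- matrix(stats::rnorm(120 * 4, 8), 120, 4, dimnames = list(g, NULL))
  colnames(v1) <- paste0("a", 1:4)
  v2 <- v1[1:100, ] + 5     # global batch shift, subset of symbols
  colnames(v2) <- paste0("b", 1:4)
  d1 <- gene_matrix(v1, c("X", "X", "Y", "Y"), dataset = "one")
  d2 <- gene_matrix(v2, c("X", "X", "Y", "Y"), dataset = "two")
  im <- build_virtual_array(list(d1, d2))
  expect_equal(nrow(im$values), 100)
  expect_identical(unique(im$design$dataset), c("one", "two"))
  meds <- apply(im$values, 1, function(r)
    stats::median(r[im$design$dataset == "one"]) -
      stats::median(r[im$design$dataset == "two"]))
  expect_lt(max(abs(meds)), 1e-10)
  expect_error(build_virtual_array(list(
    d1, gene_matrix(matrix(0, 2, 2, dimnames = list(c("ZZ1", "ZZ2"), NULL)),
                    c("X", "Y")))), "common")
})

test_that("adding a constant to one dataset leaves the integrated tree unchanged", {
  cfg <- small_config(n_probes = 700, seed = 41)
  ex <- generate_experiment(cfg)
  pp <- preprocess_experiment(ex$scans, ex$design)
  gm <- collapse_probes_to_genes(pp$matrix, ex$annotation)
  comp <- generate_companion_dataset(cfg, ex$truth, shared_symbol_count = 150)
  t1 <- hierarchical_tree(build_virtual_array(list(gm, comp$matrix)))
  shifted <- comp$matrix
  shifted$values <- shifted$values + 7
  t2 <- hierarchical_tree(build_virtual_array(list(gm, shifted)))
  expect_identical(t1$newick, t2$newick)
})

test_that("ANOVA F matches hand computation and flags degenerate inputs", {
  v <- rbind(g1 = c(1, 2, 3, 4, 5, 6), g2 = c(1, 1, 1, 1, 1, 1))
  colnames(v) <- sprintf("s%d", 1:6)
  m <- expression_matrix(v, design_table(colnames(v),
                                         rep(c("A", "B"), each = 3)))
  out <- anova_rank(m)
  # between SS = 13.5 on 1 df, within SS = 4 on 4 df -> F = 13.5
  expect_equal(out$F[out$gene == "g1"], 13.5)
  expect_equal(out$F[out$gene == "g2"], 0)
  expect_equal(out$p[out$gene == "g2"], 1)
  expect_identical(out$gene[1], "g1")

  expect_error(anova_rank(expression_matrix(
    v[, 1:4], design_table(colnames(v)[1:4], c("A", "A", "A", "B")))),
    "single sample")
})

test_that("ANOVA F equals the sums-of-squares oracle on random matrices", {
  set.seed(402)
  groups <- rep(c("A", "B", "C"), each = 3)
  v <- matrix(stats::rnorm(30 * 9), 30, 9,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:9)))
  out <- anova_rank(expression_matrix(v, design_table(colnames(v), groups)))
  for (i in sample(30, 10)) {
    ref <- summary(stats::aov(v[i, ] ~ factor(groups)))[[1]]
    expect_equal(out$F[out$gene == rownames(v)[i]], ref[1, "F value"],
                 tolerance = 1e-10)
    expect_equal(out$p[out$gene == rownames(v)[i]], ref[1, "Pr(>F)"],
                 tolerance = 1e-10)
  }
})

test_that("a planted differential gene outranks all null genes", {
  set.seed(403)
  v <- matrix(stats::rnorm(50 * 6, 8, 0.3), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
  v[7, 4:6] <- v[7, 4:6] + 5
  m <- expression_matrix(v, design_table(colnames(v),
                                         rep(c("A", "B"), each = 3)))
  rk <- anova_rank(m)
  expect_identical(rk$gene[1], "g07")
  top <- top_ranked(m, k = 10, ranking = rk)
  expect_equal(nrow(top$values), 10)
  expect_true("g07" %in% rownames(top$values))
})

test_that("PCA separates planted structure and reports exact variance fractions", {
  v <- rbind(f1 = c(0, 0, 10, 10), f2 = c(0, 2, 0, 2))
  colnames(v) <- sprintf("s%d", 1:4)
  m <- expression_matrix(v, design_table(colnames(v), c("A", "A", "B", "B")))
  out <- pca_scores(m)
  # PC1 carries the 10-unit split; barycenters sit at the group midpoints
  expect_gt(abs(diff(out$barycenters[, 1])), 9.9)
  expect_equal(sum(out$variance_fraction), 1)
  expect_equal(abs(diff(range(out$scores[c(1, 2), 1]))), 0, tolerance = 1e-8)

  # identical samples score identically
  v2 <- matrix(stats::rnorm(20), 10, 2, dimnames = list(NULL, c("x", "y")))
  v2[, 2] <- v2[, 1]
  rownames(v2) <- sprintf("f%02d", 1:10)
  out2 <- pca_scores(expression_matrix(v2, design_table(c("x", "y"),
                                                        c("A", "A"))))
  expect_equal(out2$scores["x", ], out2$scores["y", ], tolerance = 1e-10)
})

test_that("PCA scores reproduce pairwise distances of centered data", {
  set.seed(404)
  v <- matrix(stats::rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("f%02d", 1:40), sprintf("s%d", 1:6)))
  m <- expression_matrix(v, design_table(colnames(v),
                                         rep(c("A", "B", "C"), each = 2)))
  out <- pca_scores(m)
  centered <- v - rowMeans(v)
  centered <- t(scale(t(v) - colMeans(t(v)), center = TRUE, scale = FALSE))
  d_data <- stats::dist(t(v - rowMeans(v)))
  d_score <- stats::dist(out$scores)
  expect_equal(as.numeric(d_score), as.numeric(d_data), tolerance = 1e-8)
})

test_that("constant matrices give all-zero PCA scores", {
  v <- matrix(3, 5, 3, dimnames = list(sprintf("f%d", 1:5),
                                       sprintf("s%d", 1:3)))
  out <- pca_scores(expression_matrix(v, design_table(colnames(v),
                                                      c("A", "A", "B"))))
  expect_true(all(out$scores == 0))
  expect_true(all(out$variance_fraction == 0))
})

test_that("hierarchical trees have n - 1 merges, zero height for clones, valid newick", {
  set.seed(405)
  v <- matrix(stats::rnorm(60), 20, 3,
              dimnames = list(sprintf("f%02d", 1:20), c("s1", "s2", "s3")))
  v[, 2] <- v[, 1]
  tree <- hierarchical_tree(expression_matrix(
    v, design_table(colnames(v), c("A", "A", "B"))))
  expect_length(tree$merge_heights, 2)
  expect_equal(min(tree$merge_heights), 0, tolerance = 1e-12)
  expect_false(is.unsorted(tree$merge_heights))
  phy <- ape::read.tree(text = tree$newick)
  expect_setequal(phy$tip.label, c("s1", "s2", "s3"))

  v[, 3] <- 5  # zero variance
  expect_error(hierarchical_tree(expression_matrix(
    v, design_table(colnames(v), c("A", "A", "B")))), "s3")
})

test_that("a planted two-block design splits at the root", {
  set.seed(406)
  base <- stats::rnorm(200, 8, 2)          # shared expression structure
  v <- matrix(base, 200, 6,
              dimnames = list(sprintf("f%03d", 1:200),
                              c("st1", "st2", "st3", "so1", "so2", "so3"))) +
    matrix(stats::rnorm(200 * 6, 0, 0.3), 200, 6)
  v[1:50, 1:3] <- v[1:50, 1:3] + 3
  tree <- hierarchical_tree(expression_matrix(
    v, design_table(colnames(v), rep(c("stem", "soma"), each = 3))))
  d <- tree_cophenetic(tree)
  within <- c(d[1:3, 1:3][upper.tri(diag(3))], d[4:6, 4:6][upper.tri(diag(3))])
  across <- d[1:3, 4:6]
  expect_gt(min(across), max(within))
})
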