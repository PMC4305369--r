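#' Simulation configuration
#'
#' Parameters of the synthetic probe-level experiment generator. Defaults
#' emulate a five-cell-type, triplicate, 44k-probe single-channel microarray
#' study of chicken stem and somatic cells: three stem-like groups (cES-,
#' PGC- and cBC-analogs), two somatic references (CEF-, BM2-analogs), about
#' 58% of probes carrying a gene symbol, exponential-signal-plus-normal-
#' background intensities and a smooth array-specific intensity-dependent
#' bias. Planted classes give every downstream stage a ground truth:
#' `specific_<group>` probes are elevated in one group only, `shared_stem`
#' probes are elevated in all stem groups, `germ` probes are elevated in the
#' germ-analog group only (the germ signature is by construction the
#' germ-analog group's specific profile), and the rest are `null`.
#'
#' @param n_probes number of distinct probes on the array.
#' @param duplicate_fraction fraction of probes printed as two spots.
#' @param groups group labels; first elements of `somatic_groups` /
#'   `stem_groups` partition them.
#' @param replicates_per_group arrays per group.
#' @param fraction_annotated target overall fraction of probes carrying a
#'   gene symbol. Planted probes are always annotated; the null-probe
#'   annotation rate is adjusted so the overall fraction matches.
#' @param somatic_groups,stem_groups partition of `groups`; `germ_group`
#'   must be one of `stem_groups`.
#' @param germ_group the germ-analog group.
#' @param planted_counts named integer vector over classes
#'   `specific_<group>` (for non-germ groups), `shared_stem`, `germ`.
#' @param effect_size_log2 planted elevation, log2 units.
#' @param residual_sd_log2 per-spot log2 residual standard deviation.
#' @param signal_alpha mean of the exponential distribution of per-probe
#'   baseline signal (arbitrary intensity units).
#' @param background_mu,background_sd normal background parameters (a.u.).
#' @param array_bias_amplitude amplitude (log2 units) of the smooth
#'   array-specific intensity-dependent distortion; 0 disables.
#' @param batch_offset_log2 additive platform offset used by
#'   [generate_companion_dataset()].
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_probes = 44000,
                              duplicate_fraction = 0.10,
                              groups = c("CEF", "BM2", "cES", "PGC", "cBC"),
                              replicates_per_group = 3,
                              fraction_annotated = 0.578,
                              somatic_groups = c("CEF", "BM2"),
                              stem_groups = c("cES", "PGC", "cBC"),
                              germ_group = "PGC",
                              planted_counts = NULL,
                              effect_size_log2 = 3,
                              residual_sd_log2 = 0.3,
                              signal_alpha = 800,
                              background_mu = 100,
                              background_sd = 15,
                              array_bias_amplitude = 0.2,
                              batch_offset_log2 = 2,
                              seed = 1L) {
  if (!setequal(groups, c(somatic_groups, stem_groups)))
    stop("'groups' must be the union of somatic_groups and stem_groups")
  if (!germ_group %in% stem_groups) stop("germ_group must be a stem group")
  if (is.null(planted_counts)) {
    specific <- setdiff(groups, germ_group)
    planted_counts <- stats::setNames(rep(40L, length(specific)),
                                      paste0("specific_", specific))
    planted_counts <- c(planted_counts, shared_stem = 88L, germ = 60L)
    # at full array scale, mirror the study's per-type list sizes
    if (n_probes >= 20000) {
      big <- c(specific_CEF = 511L, specific_BM2 = 666L, specific_cES = 37L,
               specific_cBC = 110L, germ = 182L, shared_stem = 88L)
      planted_counts[names(big)[names(big) %in% names(planted_counts)]] <-
        big[names(big) %in% names(planted_counts)]
    }
  }
  cfg <- list(n_probes = as.integer(n_probes),
              duplicate_fraction = duplicate_fraction,
              groups = groups,
              replicates_per_group = as.integer(replicates_per_group),
              fraction_annotated = fraction_annotated,
              somatic_groups = somatic_groups, stem_groups = stem_groups,
              germ_group = germ_group,
              planted_counts = planted_counts,
              effect_size_log2 = effect_size_log2,
              residual_sd_log2 = residual_sd_log2,
              signal_alpha = signal_alpha,
              background_mu = background_mu, background_sd = background_sd,
              array_bias_amplitude = array_bias_amplitude,
              batch_offset_log2 = batch_offset_log2,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_probes < 1) stop("n_probes must be positive")
    if (duplicate_fraction < 0 || duplicate_fraction > 1 ||
        fraction_annotated < 0 || fraction_annotated > 1)
      stop("proportions must lie in [0, 1]")
    if (residual_sd_log2 <= 0 || background_sd <= 0 || signal_alpha <= 0)
      stop("signal_alpha and standard deviations must be > 0")
    if (replicates_per_group < 1) stop("replicates_per_group must be >= 1")
    if (sum(planted_counts) > n_probes)
      stop("planted counts (", sum(planted_counts),
           ") exceed n_probes (", n_probes, ")")
    known <- c(paste0("specific_", groups), "shared_stem", "germ")
    bad <- setdiff(names(planted_counts), known)
    if (length(bad)) stop("unknown planted class: ", paste(bad, collapse = ", "))
  })
  invisible(cfg)
}

# true log2 group-mean matrix (probes x groups) from baseline + class
planted_means <- function(cfg, class, baseline_log2) {
  k <- length(cfg$groups)
  mu <- matrix(baseline_log2, length(class), k)
  colnames(mu) <- cfg$groups
  eff <- cfg$effect_size_log2
  for (g in cfg$groups) {
    up <- class == paste0("specific_", g)
    if (g == cfg$germ_group) up <- up | class == "germ"
    if (g %in% cfg$stem_groups) up <- up | class == "shared_stem"
    mu[up, g] <- mu[up, g] + eff
  }
  mu
}

#' Generate a synthetic probe-level experiment
#'
#' Produces one `ArrayScan` per sample plus the annotation, design and
#' ground truth. Each probe draws a baseline signal from an exponential
#' distribution with mean `signal_alpha`, so the across-probe signal
#' marginal matches the normexp generative model; planted fold effects and
#' per-spot N(0, `residual_sd_log2`) noise act on the log2 scale, a smooth
#' array-specific polynomial bias in log-intensity distorts each array, and
#' a N(`background_mu`, `background_sd`) background is added on the
#' intensity scale. A `duplicate_fraction` of probes appear as two spots
#' (appended after the main block, identical order on every array).
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a `SimulationConfig`.
#' @return list with `scans` (list of `ArrayScan`), `annotation`
#'   (`AnnotationTable`), `design` (design `data.frame`) and `truth`
#'   (`SyntheticTruth` data.frame: `probe_id`, `class`, `gene_symbol`,
#'   `duplicated_spot`, one `mean_<group>` column per group).
#' @export
generate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  validate_sim_config(cfg)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  n <- cfg$n_probes
  probe_id <- sprintf("TID%06d", seq_len(n))

  class <- rep("null", n)
  pool <- sample.int(n)  # random placement of planted probes
  off <- 0L
  for (cl in names(cfg$planted_counts)) {
    cnt <- cfg$planted_counts[[cl]]
    if (cnt > 0) {
      class[pool[(off + 1L):(off + cnt)]] <- cl
      off <- off + cnt
    }
  }

  baseline <- log2(stats::rexp(n, rate = 1 / cfg$signal_alpha))
  # planted signature genes sit above the background detection floor: a
  # fold change on a probe whose signal is buried in background noise is
  # not identifiable by any method (memoryless shift keeps the marginal
  # exponential in shape)
  planted <- class != "null"
  floor_au <- 4 * cfg$background_sd
  baseline[planted] <- log2(floor_au +
    stats::rexp(sum(planted), rate = 1 / cfg$signal_alpha))
  mu <- planted_means(cfg, class, baseline)

  # annotation: planted probes always carry a symbol; null probes at an
  # adjusted rate so the overall annotated fraction targets the config value
  n_pl <- sum(planted)
  p_null <- max(0, min(1, (cfg$fraction_annotated * n - n_pl) / max(1, n - n_pl)))
  annotated <- planted
  annotated[!planted] <- stats::runif(n - n_pl) < p_null
  symbol <- rep(NA_character_, n)
  symbol[annotated] <- sprintf("GENE%05d", which(annotated))

  n_dup <- round(cfg$duplicate_fraction * n)
  dup_idx <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
  spot_idx <- c(seq_len(n), dup_idx)  # identical layout on every array

  design <- design_table(
    sample_id = paste(rep(cfg$groups, each = cfg$replicates_per_group),
                      seq_len(cfg$replicates_per_group), sep = "_"),
    group = rep(cfg$groups, each = cfg$replicates_per_group))

  z_center <- mean(baseline); z_scale <- max(stats::sd(baseline), 1e-8)
  scans <- vector("list", nrow(design))
  for (s in seq_len(nrow(design))) {
    g <- design$group[s]
    true_log2 <- mu[spot_idx, g] +
      stats::rnorm(length(spot_idx), 0, cfg$residual_sd_log2)
    if (cfg$array_bias_amplitude != 0) {
      cf <- stats::rnorm(2)
      cf <- cf / sqrt(sum(cf^2)) * cfg$array_bias_amplitude
      # clamp the standardized log-intensity so the smooth distortion stays
      # bounded at the intensity extremes (a scanner bias, not a blow-up)
      z <- pmin(pmax((true_log2 - z_center) / z_scale, -2), 2)
      true_log2 <- true_log2 + cf[1] * z + cf[2] * (z^2 - 1)
    }
    fg <- 2^true_log2 +
      stats::rnorm(length(spot_idx), cfg$background_mu, cfg$background_sd)
    bg <- stats::rnorm(length(spot_idx), cfg$background_mu, cfg$background_sd)
    scans[[s]] <- array_scan(design$sample_id[s], data.frame(
      probe_id = probe_id[spot_idx],
      gene_symbol = symbol[spot_idx],
      foreground = fg, background = pmax(bg, 0), flag = 0L,
      stringsAsFactors = FALSE))
  }

  truth <- data.frame(probe_id = probe_id, class = class,
                      gene_symbol = symbol,
                      duplicated_spot = seq_len(n) %in% dup_idx,
                      stringsAsFactors = FALSE)
  mu_df <- as.data.frame(mu)
  names(mu_df) <- paste0("mean_", cfg$groups)
  truth <- cbind(truth, mu_df)
  class(truth) <- c("SyntheticTruth", class(truth))
  list(scans = scans, annotation = annotation_table(probe_id, symbol),
       design = design, truth = truth)
}

#' Simulate a normalized expression matrix directly from planted truth
#'
#' Expression-level counterpart of [generate_experiment()]: the same planted
#' class structure and truth table, but values are drawn directly as
#' `true log2 group mean + N(0, residual_sd_log2)` per sample, with no
#' array-level intensity layer (no background, scanner bias or duplicate
#' spots). Suitable for exercising the statistical stages in isolation from
#' preprocessing.
#'
#' @param cfg a `SimulationConfig` (duplicate and intensity-layer fields are
#'   ignored).
#' @return list with `matrix` (probe-level `ExpressionMatrix` with unique
#'   rows), `annotation`, `design`, `truth`.
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  validate_sim_config(cfg)
  ex <- generate_experiment(cfg)  # reuse truth/annotation/design layout
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed + 7L)
  truth <- ex$truth
  mu <- as.matrix(truth[, paste0("mean_", cfg$groups), drop = FALSE])
  colnames(mu) <- cfg$groups
  design <- ex$design
  vals <- matrix(NA_real_, nrow(truth), nrow(design),
                 dimnames = list(truth$probe_id, design$sample_id))
  for (s in seq_len(nrow(design)))
    vals[, s] <- mu[, design$group[s]] +
      stats::rnorm(nrow(truth), 0, cfg$residual_sd_log2)
  list(matrix = expression_matrix(vals, design, level = "probe"),
       annotation = ex$annotation, design = design, truth = truth)
}

#' Generate a companion "foreign platform" gene-level dataset
#'
#' Builds a second, gene-level dataset (e.g. a mouse-analog platform) whose
#' symbol universe overlaps the truth's annotated symbols at exactly
#' `shared_symbol_count`. One foreign group (`stem_like`, default the first)
#' reuses the truth's stem-reference expression profile so that its samples
#' should co-cluster with the stem-analog groups after integration; the
#' remaining foreign groups reuse a somatic reference profile. An additive
#' `batch_offset_log2` and independent noise distinguish the platform.
#'
#' @param cfg the `SimulationConfig` used for the main experiment.
#' @param truth the `SyntheticTruth` of the main experiment.
#' @param shared_symbol_count number of symbols shared with the truth.
#' @param foreign_groups labels of the companion dataset's groups.
#' @param stem_like the foreign group that carries the stem profile.
#' @param stem_reference,somatic_reference truth groups whose mean profiles
#'   are reused.
#' @param replicates samples per foreign group.
#' @param foreign_only_count additional symbols unique to the platform.
#' @param seed RNG seed (defaults to `cfg$seed + 1`).
#' @return list with `matrix` (gene-level `ExpressionMatrix`, design carries
#'   `dataset = "companion"`) and `truth` (per-symbol class and foreign
#'   group means).
#' @export
generate_companion_dataset <- function(cfg, truth, shared_symbol_count,
                                       foreign_groups = c("mES", "EpiSC", "mEF"),
                                       stem_like = foreign_groups[1],
                                       stem_reference = cfg$stem_groups[1],
                                       somatic_reference = cfg$somatic_groups[1],
                                       replicates = cfg$replicates_per_group,
                                       foreign_only_count = max(20L, round(shared_symbol_count / 4)),
                                       seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "SimulationConfig"), stem_like %in% foreign_groups)
  ann <- truth[!is.na(truth$gene_symbol), ]
  if (shared_symbol_count > nrow(ann))
    stop("shared_symbol_count (", shared_symbol_count,
         ") exceeds available annotated symbols (", nrow(ann), ")")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  # planted symbols first so the cross-platform structure survives the cut
  ord <- order(ann$class == "null", ann$probe_id)
  shared <- ann[ord[seq_len(shared_symbol_count)], ]

  mean_cols <- paste0("mean_", cfg$groups)
  prof_stem <- shared[[paste0("mean_", stem_reference)]]
  prof_som <- shared[[paste0("mean_", somatic_reference)]]

  sym_foreign <- sprintf("MGENE%05d", seq_len(foreign_only_count))
  base_foreign <- log2(stats::rexp(foreign_only_count, rate = 1 / cfg$signal_alpha))

  genes <- c(shared$gene_symbol, sym_foreign)
  design <- design_table(
    sample_id = paste(rep(foreign_groups, each = replicates),
                      seq_len(replicates), "c", sep = "_"),
    group = rep(foreign_groups, each = replicates),
    dataset = "companion")
  vals <- matrix(NA_real_, length(genes), nrow(design),
                 dimnames = list(genes, design$sample_id))
  for (s in seq_len(nrow(design))) {
    mu <- c(if (design$group[s] == stem_like) prof_stem else prof_som,
            base_foreign)
    vals[, s] <- mu + cfg$batch_offset_log2 +
      stats::rnorm(length(mu), 0, cfg$residual_sd_log2)
  }
  ctruth <- data.frame(
    gene_symbol = genes,
    class = c(shared$class, rep("foreign_null", foreign_only_count)),
    stringsAsFactors = FALSE)
  list(matrix = expression_matrix(vals, design, level = "gene"),
       truth = ctruth)
}

#' Generate a synthetic qPCR Ct table
#'
#' Emits cycle-threshold values for selected genes over the experiment's
#' samples: `Ct = ct0 - true log2 expression + N(0, noise_sd)`. The
#' reference (internal control) gene must have equal planted expression in
#' all groups, i.e. belong to the `null` class.
#'
#' @param truth a `SyntheticTruth`.
#' @param design the experiment design table.
#' @param genes gene symbols to assay (must be annotated in `truth`).
#' @param reference_gene internal-control symbol (null class).
#' @param calibrator_group group whose mean expression defines RQ = 1.
#' @param ct0 baseline cycle offset.
#' @param noise_sd Ct noise standard deviation (cycles); 0 gives the exact
#'   generator round trip.
#' @param seed RNG seed.
#' @return a `CtTable` (see [ct_table()]).
#' @export
generate_ct_table <- function(truth, design, genes, reference_gene,
                              calibrator_group, ct0 = 30, noise_sd = 0.2,
                              seed = 1L) {
  design <- as_design_table(design)
  all_genes <- unique(c(genes, reference_gene))
  idx <- match(all_genes, truth$gene_symbol)
  if (anyNA(idx))
    stop("unknown gene symbol(s): ",
         paste(all_genes[is.na(idx)], collapse = ", "))
  ref_row <- truth[match(reference_gene, truth$gene_symbol), ]
  if (ref_row$class != "null")
    stop("reference_gene must have equal expression in all groups (class 'null')")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  mean_cols <- grep("^mean_", names(truth), value = TRUE)
  groups <- sub("^mean_", "", mean_cols)
  ct <- matrix(NA_real_, nrow(design), length(all_genes),
               dimnames = list(design$sample_id, all_genes))
  for (s in seq_len(nrow(design))) {
    g <- design$group[s]
    if (!g %in% groups) stop("design group not in truth: ", g)
    mu <- as.numeric(truth[idx, paste0("mean_", g)])
    ct[s, ] <- ct0 - mu + stats::rnorm(length(mu), 0, noise_sd)
  }
  ct_table(ct, reference_gene = reference_gene, design = design,
           calibrator_group = calibrator_group)
}

#' Simulate a two-group log2 expression matrix with planted effects
#'
#' A direct expression-scale simulation used for calibration studies of the
#' differential-expression stage (e.g. false-discovery-proportion runs):
#' `n_de` probes carry a log2 effect of `effect_log2` (random sign) in the
#' second group, residual noise is N(0, `sd_log2`).
#'
#' @param n_probes number of probes.
#' @param n_de number of truly differential probes.
#' @param effect_log2 absolute planted log2 effect.
#' @param sd_log2 residual standard deviation (log2).
#' @param replicates samples per group.
#' @param groups two group labels.
#' @param baseline_log2 mean baseline expression.
#' @param seed RNG seed.
#' @return list with `matrix` (probe-level `ExpressionMatrix`) and
#'   `de_index` (integer indices of planted probes).
#' @export
simulate_two_group <- function(n_probes = 2000, n_de = 200, effect_log2 = 2,
                               sd_log2 = 0.3, replicates = 3,
                               groups = c("A", "B"), baseline_log2 = 8,
                               seed = 1L) {
  stopifnot(length(groups) == 2, n_de <= n_probes)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  design <- design_table(
    sample_id = paste(rep(groups, each = replicates),
                      seq_len(replicates), sep = "_"),
    group = rep(groups, each = replicates))
  base <- stats::rnorm(n_probes, baseline_log2, 1.5)
  de_index <- if (n_de > 0) sort(sample.int(n_probes, n_de)) else integer(0)
  eff <- numeric(n_probes)
  eff[de_index] <- effect_log2 * sample(c(-1, 1), n_de, replace = TRUE)
  mu <- cbind(base, base + eff)
  vals <- matrix(NA_real_, n_probes, nrow(design),
                 dimnames = list(sprintf("P%05d", seq_len(n_probes)),
                                 design$sample_id))
  for (s in seq_len(nrow(design)))
    vals[, s] <- mu[, match(design$group[s], groups)] +
      stats::rnorm(n_probes, 0, sd_log2)
  list(matrix = expression_matrix(vals, design, level = "probe"),
       de_index = de_index)
}

# save/restore .Random.seed so generators do not disturb the caller's RNG
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
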