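# shared fixtures: all built in code, cached per test run

# write a GPR-style file from a data.frame of spots; returns the path
write_gpr_fixture <- function(rows, path = tempfile(fileext = ".gpr"),
                              atf_header = TRUE, columns = NULL) {
  if (is.null(columns))
    columns <- c("ID", "Name", "F532 Median", "B532 Median", "Flags")
  lines <- character(0)
  if (atf_header)
    lines <- c("ATF\t1.0", "2\t5", "\"Type=GenePix Results 3\"",
               "\"Wavelengths=532\"")
  lines <- c(lines, paste(columns, collapse = "\t"))
  for (i in seq_len(nrow(rows)))
    lines <- c(lines, paste(unlist(rows[i, seq_along(columns)]), collapse = "\t"))
  writeLines(lines, path)
  path
}

# a small config with feasible planted counts for tiny arrays
small_config <- function(n_probes = 600, seed = 7, ...) {
  simulation_config(
    n_probes = n_probes, seed = seed,
    planted_counts = c(specific_CEF = 15L, specific_BM2 = 15L,
                       specific_cES = 15L, specific_cBC = 15L,
                       shared_stem = 20L, germ = 15L),
    ...)
}

# cache one mid-size preprocessed experiment shared by several tests
.fixture_env <- new.env(parent = emptyenv())
cached_pipeline <- function() {
  if (is.null(.fixture_env$pipe)) {
    cfg <- small_config(n_probes = 1500, seed = 7)
    ex <- generate_experiment(cfg)
    pp <- preprocess_experiment(ex$scans, ex$design)
    fit <- fit_group_model(pp$matrix)
    prior <- estimate_prior(fit)
    tabs <- all_contrasts(fit, prior)
    .fixture_env$pipe <- list(cfg = cfg, ex = ex, pp = pp, fit = fit,
                              prior = prior, tabs = tabs)
  }
  .fixture_env$pipe
}

# profiles + report for the cached pipeline
cached_profiles <- function() {
  if (is.null(.fixture_env$profs)) {
    p <- cached_pipeline()
    profs <- lapply(p$cfg$groups, build_profile, tables = p$tabs,
                    groups = p$cfg$groups, annotation = p$ex$annotation)
    names(profs) <- p$cfg$groups
    .fixture_env$profs <- profs
  }
  .fixture_env$profs
}

# a tiny hand-made CellTypeProfile for rule-level signature tests
manual_profile <- function(reference, others, probe_id, gene_symbol,
                           calls, lfcs) {
  rows <- data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                     calls = calls, stringsAsFactors = FALSE)
  lf <- matrix(unlist(lfcs), nrow = length(probe_id), byrow = TRUE)
  colnames(lf) <- paste0("log2fc_", others)
  rows <- cbind(rows, as.data.frame(lf))
  cm <- do.call(rbind, strsplit(calls, ""))
  rows$fc_score <- rowSums(lf * (cm != "n"))
  structure(list(reference = reference, others = others, rows = rows),
            class = "CellTypeProfile")
}
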