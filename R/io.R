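#' Read a GenePix-style GPR scan file
#'
#' Parses a single-channel tab-delimited GenePix results file into an
#' `ArrayScan`: one row per spot, in file order, with foreground and
#' background median intensities. An optional ATF-style header block (any
#' lines preceding the column-name row) is skipped. Required columns are
#' `ID`, `Name`, `F532 Median` and `B532 Median`; `Flags` is optional and
#' defaults to 0. Duplicate spot IDs are retained — downstream preprocessing
#' averages them. A `Name` of `""` or `"---"` records the gene symbol as
#' absent (`NA`).
#'
#' @param path path to the .gpr file.
#' @param array_id identifier for the array; defaults to the file name
#'   without extension.
#' @return An `ArrayScan`: list with `array_id` and a data.frame `probes`
#'   with columns `probe_id`, `gene_symbol`, `foreground`, `background`,
#'   `flag`.
#' @export
read_gpr <- function(path, array_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- find_column_header(lines, required = "ID")
  if (is.na(hdr)) stop("no column header row found in ", path)
  cols <- strip_quotes(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  required <- c("ID", "Name", "F532 Median", "B532 Median")
  missing <- setdiff(required, cols)
  if (length(missing))
    stop("missing column ", paste(shQuote(missing), collapse = ", "),
         " in ", path)
  body <- lines[seq.int(hdr + 1L, length(lines))]
  body <- body[nzchar(body)]
  rows <- lapply(body, function(l) strip_quotes(strsplit(l, "\t", fixed = TRUE)[[1]]))
  idx <- match(c(required, "Flags"), cols)
  get <- function(r, j) if (is.na(j) || j > length(r)) "" else r[j]
  n <- length(rows)
  probe_id <- character(n); symbol <- character(n)
  fg <- numeric(n); bg <- numeric(n); flag <- integer(n)
  for (i in seq_len(n)) {
    r <- rows[[i]]
    probe_id[i] <- get(r, idx[1])
    symbol[i] <- get(r, idx[2])
    fgi <- suppressWarnings(as.numeric(get(r, idx[3])))
    bgi <- suppressWarnings(as.numeric(get(r, idx[4])))
    if (is.na(fgi) || is.na(bgi))
      stop("non-numeric intensity at line ", hdr + i, " of ", path)
    fg[i] <- fgi; bg[i] <- bgi
    fl <- get(r, idx[5])
    flag[i] <- if (nzchar(fl)) suppressWarnings(as.integer(as.numeric(fl))) else 0L
  }
  if (any(!nzchar(probe_id))) stop("empty probe ID at line ",
                                   hdr + which(!nzchar(probe_id))[1], " of ", path)
  symbol[symbol %in% c("", "---")] <- NA_character_
  if (is.null(array_id)) array_id <- sub("\\.[^.]*$", "", basename(path))
  array_scan(array_id, data.frame(
    probe_id = probe_id, gene_symbol = symbol,
    foreground = fg, background = bg, flag = flag,
    stringsAsFactors = FALSE))
}

#' Construct an ArrayScan
#'
#' @param array_id array identifier.
#' @param probes data.frame with columns `probe_id`, `gene_symbol`,
#'   `foreground`, `background`, `flag`.
#' @return An `ArrayScan` object.
#' @export
array_scan <- function(array_id, probes) {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "foreground", "background") %in% names(probes)))
  if (is.null(probes$gene_symbol)) probes$gene_symbol <- NA_character_
  if (is.null(probes$flag)) probes$flag <- 0L
  if (any(!nzchar(probes$probe_id))) stop("probe_id must be non-empty")
  if (any(!is.finite(probes$foreground)) || any(!is.finite(probes$background)))
    stop("intensities must be finite")
  structure(list(array_id = as.character(array_id), probes = probes),
            class = "ArrayScan")
}

#' @export
print.ArrayScan <- function(x, ...) {
  cat(sprintf("ArrayScan '%s': %d spots (%d annotated, %d flagged)\n",
              x$array_id, nrow(x$probes), sum(!is.na(x$probes$gene_symbol)),
              sum(x$probes$flag < 0)))
  invisible(x)
}

#' Write an ArrayScan as a GPR-style file
#'
#' Inverse of [read_gpr()]; writes a minimal ATF header block followed by
#' the spot table.
#'
#' @param scan an `ArrayScan`.
#' @param path output file path.
#' @export
write_gpr <- function(scan, path) {
  stopifnot(inherits(scan, "ArrayScan"))
  p <- scan$probes
  name <- ifelse(is.na(p$gene_symbol), "", p$gene_symbol)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ATF\t1.0", "2\t5",
               sprintf("\"ArrayID=%s\"", scan$array_id),
               "\"Wavelengths=532\"",
               "ID\tName\tF532 Median\tB532 Median\tFlags"), con)
  writeLines(paste(p$probe_id, name,
                   format(p$foreground, digits = 15, trim = TRUE, scientific = FALSE),
                   format(p$background, digits = 15, trim = TRUE, scientific = FALSE),
                   p$flag, sep = "\t"), con)
  invisible(path)
}

#' Read a GAL-style probe annotation table
#'
#' Maps probe identifiers to gene symbols. Accepts an optional ATF header
#' block, then either a header row containing `ID` and `Name` columns or a
#' bare two-column probe/symbol table. Symbols are upper-cased; empty
#' symbols (or `"---"`) are recorded as absent. A probe mapped to two
#' different symbols is an error.
#'
#' @param path path to the annotation file.
#' @param version_tag optional free-text annotation version.
#' @return An `AnnotationTable`: list with `map` (data.frame `probe_id`,
#'   `gene_symbol`) and `version_tag`.
#' @export
read_annotation <- function(path, version_tag = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- find_column_header(lines, required = "ID")
  if (!is.na(hdr)) {
    cols <- strip_quotes(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
    ii <- match(c("ID", "Name"), cols)
    if (any(is.na(ii))) stop("annotation header must name ID and Name columns")
    body <- lines[seq.int(hdr + 1L, length(lines))]
  } else {
    ii <- c(1L, 2L)
    body <- lines
  }
  rows <- lapply(body, function(l) strip_quotes(strsplit(l, "\t", fixed = TRUE)[[1]]))
  pid <- vapply(rows, function(r) if (ii[1] <= length(r)) r[ii[1]] else "", "")
  sym <- vapply(rows, function(r) if (ii[2] <= length(r)) r[ii[2]] else "", "")
  annotation_table(pid, sym, version_tag = version_tag)
}

#' Construct an AnnotationTable from probe/symbol vectors
#'
#' @param probe_id character vector of probe identifiers.
#' @param gene_symbol character vector of symbols; `""`, `"---"` or `NA`
#'   mean unannotated.
#' @param version_tag free-text version label.
#' @return An `AnnotationTable`.
#' @export
annotation_table <- function(probe_id, gene_symbol, version_tag = "") {
  probe_id <- as.character(probe_id)
  gene_symbol <- toupper(as.character(gene_symbol))
  gene_symbol[gene_symbol %in% c("", "---") | is.na(gene_symbol)] <- NA_character_
  keep <- !duplicated(paste(probe_id, gene_symbol))
  pid <- probe_id[keep]; sym <- gene_symbol[keep]
  dup <- unique(pid[duplicated(pid)])
  if (length(dup))
    stop("probe(s) mapped to conflicting symbols: ",
         paste(dup, collapse = ", "))
  structure(list(map = data.frame(probe_id = pid, gene_symbol = sym,
                                  stringsAsFactors = FALSE),
                 version_tag = version_tag),
            class = "AnnotationTable")
}

#' @export
print.AnnotationTable <- function(x, ...) {
  cat(sprintf("AnnotationTable: %d probes, %d with symbol%s\n",
              nrow(x$map), sum(!is.na(x$map$gene_symbol)),
              if (nzchar(x$version_tag)) paste0(" (", x$version_tag, ")") else ""))
  invisible(x)
}

#' Look up gene symbols for probe identifiers
#'
#' @param ann an `AnnotationTable`.
#' @param probe_id character vector.
#' @return character vector of upper-cased symbols, `NA` where unannotated.
#' @export
annotation_symbols <- function(ann, probe_id) {
  stopifnot(inherits(ann, "AnnotationTable"))
  ann$map$gene_symbol[match(probe_id, ann$map$probe_id)]
}

#' Write an annotation table (GAL-style TSV)
#' @param ann an `AnnotationTable`.
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "AnnotationTable"))
  sym <- ifelse(is.na(ann$map$gene_symbol), "", ann$map$gene_symbol)
  writeLines(c("ID\tName",
               paste(ann$map$probe_id, sym, sep = "\t")), path)
  invisible(path)
}

#' Read / write a sample design table
#'
#' TSV with header columns `sample_id` and `group` (optionally `dataset`).
#'
#' @param path file path.
#' @return for `read_design`, a design `data.frame`.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  design_table(d$sample_id, d$group, dataset = d$dataset)
}

#' @rdname read_design
#' @param design a design `data.frame`.
#' @export
write_design <- function(design, path) {
  utils::write.table(as_design_table(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an expression matrix as TSV
#'
#' Values are serialized at full precision so that
#' `read_matrix(write_matrix(m))` reproduces `m` exactly. Row identifiers go
#' in the first column (header `feature_id`), sample identifiers in the
#' header row. The design is not stored in the file; supply it on read.
#'
#' @param m an `ExpressionMatrix`.
#' @param path output file path.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  if (any(!is.finite(v))) stop("refusing to write non-finite values")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(v)), collapse = "\t"), con)
  if (nrow(v)) {
    txt <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(paste(rownames(v), txt, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @param design design table for the samples in the file (required to
#'   rebuild the `ExpressionMatrix`).
#' @param level `"probe"` or `"gene"`.
#' @export
read_matrix <- function(path, design, level = "probe") {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- hdr[-1]
  n <- length(lines) - 1L
  vals <- matrix(NA_real_, n, length(samples))
  ids <- character(n)
  if (n) for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop("ragged row at data row ", i, " of ", path)
    ids[i] <- f[1]
    vals[i, ] <- as.numeric(f[-1])
  }
  rownames(vals) <- ids
  colnames(vals) <- samples
  expression_matrix(vals, design, level = level)
}

# -- internal helpers ---------------------------------------------------------

strip_quotes <- function(x) gsub('^"|"$', "", x)

# index of the first line whose tab fields include `required`
find_column_header <- function(lines, required) {
  for (i in seq_along(lines)) {
    f <- strip_quotes(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (required %in% f) return(i)
  }
  NA_integer_
}
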