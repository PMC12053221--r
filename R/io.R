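#' Read a sparse count matrix in Matrix Market + TSV triplet layout
#'
#' Reads the conventional `matrix.mtx` / `genes.tsv` / `barcodes.tsv` trio and
#' returns a validated [SingleCellExperiment::SingleCellExperiment] with a
#' `counts` assay. Matrix Market coordinates are 1-based on disk; everything
#' internal is ordinary R indexing.
#'
#' @param matrixPath path to the Matrix Market coordinate file (genes x nuclei).
#' @param genesPath path to a TSV with one gene id per line (first field used).
#' @param barcodesPath path to a TSV with one nucleus id per line.
#' @return A `SingleCellExperiment` with assay `counts`.
#' @export
readCounts <- function(matrixPath, genesPath, barcodesPath) {
  m <- Matrix::readMM(matrixPath)
  genes <- .readIdColumn(genesPath, "gene")
  barcodes <- .readIdColumn(barcodesPath, "nucleus")
  if (length(barcodes) == 0L)
    stop(sprintf("0 nuclei in '%s'", barcodesPath), call. = FALSE)
  if (length(genes) == 0L)
    stop(sprintf("0 genes in '%s'", genesPath), call. = FALSE)
  if (nrow(m) != length(genes))
    stop(sprintf("dimension mismatch: '%s' declares %d rows but '%s' has %d ids",
                 matrixPath, nrow(m), genesPath, length(genes)), call. = FALSE)
  if (ncol(m) != length(barcodes))
    stop(sprintf("dimension mismatch: '%s' declares %d columns but '%s' has %d ids",
                 matrixPath, ncol(m), barcodesPath, length(barcodes)), call. = FALSE)
  x <- if (is(m, "dMatrix")) m@x else as.numeric(m@x)
  if (length(x) && (any(x < 0) || any(x != floor(x))))
    stop(sprintf("'%s' contains negative or non-integer entries", matrixPath),
         call. = FALSE)
  m <- methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
  dimnames(m) <- list(genes, barcodes)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

.readIdColumn <- function(path, what) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  ids <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate %s ids in '%s': %s", what, path,
                 paste(unique(dup)[seq_len(min(3, length(unique(dup))))],
                       collapse = ", ")), call. = FALSE)
  ids
}

#' Write a count matrix as Matrix Market + TSV triplet
#'
#' Inverse of [readCounts()]; coordinates are emitted in canonical
#' column-major order so the round trip is byte-stable.
#'
#' @param x `SingleCellExperiment` or gene x nucleus matrix with dimnames.
#' @param dir output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
writeCounts <- function(x, dir) {
  counts <- .getCounts(x)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry gene and nucleus identifiers", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(methods::as(counts, "dMatrix"), "CsparseMatrix"),
                  paths[1])
  writeLines(rownames(counts), paths[2])
  writeLines(colnames(counts), paths[3])
  invisible(paths)
}

#' Read a GMT gene-set collection
#'
#' Each line is `set_name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Descriptions are discarded; duplicate set names are an error.
#'
#' @param path GMT file path.
#' @param source optional tag recording where the collection came from.
#' @return Named list of character vectors with attribute `source`.
#' @export
readGmt <- function(path, source = "unknown") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("'%s' line %d has fewer than 3 fields", path, short[1]),
         call. = FALSE)
  names <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names))
    stop(sprintf("duplicate set name '%s' in '%s'",
                 names[duplicated(names)][1], path), call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- names
  if (any(lengths(sets) == 0L))
    stop("empty gene set after deduplication", call. = FALSE)
  attr(sets, "source") <- source
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a typed delimited table with schema validation
#'
#' Reads a TSV/CSV with header and validates it against a schema: required
#' columns, column types, and enum vocabularies. The delimiter is inferred
#' from the file extension (`.csv` means comma, anything else tab) unless
#' given explicitly.
#'
#' @param path file path.
#' @param schema list with `columns` (named character vector of types among
#'   `"character"`, `"numeric"`, `"integer"`, `"logical"`) and optional
#'   `enums` (named list of allowed values per column).
#' @param delim optional explicit delimiter.
#' @return data.frame with validated, typed columns.
#' @export
readTableTyped <- function(path, schema, delim = NULL) {
  if (is.null(delim))
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = delim, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(names(schema$columns), names(df))
  if (length(missing))
    stop(sprintf("'%s' is missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in names(schema$columns)) {
    type <- schema$columns[[col]]
    if (type %in% c("numeric", "integer")) {
      suppressWarnings(v <- as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(trimws(df[[col]])))
      if (length(bad))
        stop(sprintf("'%s' column '%s' row %d: cannot parse '%s' as %s",
                     path, col, bad[1], df[[col]][bad[1]], type), call. = FALSE)
      df[[col]] <- if (type == "integer") as.integer(round(v)) else v
    } else if (type == "logical") {
      df[[col]] <- as.logical(df[[col]])
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  for (col in names(schema$enums %||% list())) {
    allowed <- schema$enums[[col]]
    bad <- setdiff(unique(df[[col]][!is.na(df[[col]])]), allowed)
    if (length(bad))
      stop(sprintf("'%s' column '%s': unknown value '%s' (allowed: %s)",
                   path, col, bad[1], paste(allowed, collapse = ", ")),
           call. = FALSE)
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Built-in table schemas
#'
#' Schemas for the tables the pipeline exchanges: per-nucleus metadata,
#' spatial cell tables, histology ROI tables, and GSEA result tables.
#'
#' @param name one of `"nucleusMeta"`, `"spatialCells"`, `"roiTable"`,
#'   `"gseaResults"`, `"rankedList"`.
#' @return A schema list consumable by [readTableTyped()].
#' @export
tableSchema <- function(name = c("nucleusMeta", "spatialCells", "roiTable",
                                 "gseaResults", "rankedList")) {
  name <- match.arg(name)
  switch(name,
    nucleusMeta = list(
      columns = c(nucleus_id = "character", sample_id = "character",
                  condition = "character", region = "character",
                  sex = "character", n_umi = "numeric", n_genes = "numeric",
                  mito_frac = "numeric"),
      enums = list(condition = c("Control", "PD"), region = c("CN", "Pu"),
                   sex = c("M", "F", "NA"))),
    spatialCells = list(
      columns = c(cell_id = "character", x = "numeric", y = "numeric",
                  sample_id = "character", condition = "character",
                  label = "character"),
      enums = list(condition = c("Control", "PD"))),
    roiTable = list(
      columns = c(donor_id = "character", region = "character",
                  condition = "character", marker = "character",
                  measurement_type = "character", value = "numeric"),
      enums = list(region = c("CN", "Pu"), condition = c("Control", "PD"),
                   measurement_type = c("mean_dab_intensity",
                                        "positive_area_um2",
                                        "total_area_um2"))),
    gseaResults = list(
      columns = c(contrast = "character", pathway = "character",
                  ES = "numeric", NES = "numeric", p = "numeric",
                  q = "numeric")),
    rankedList = list(
      columns = c(gene = "character", score = "numeric",
                  contrast = "character")))
}
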