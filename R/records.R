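# Molecule record table ingest and count-matrix output.
#
# A record table is a tibble with one row per observed (cell barcode, UMI,
# gene) triple:
#   cb         cell barcode, ACGT string
#   umi        UMI sequence, fixed length within a dataset
#   gene       gene identifier (intergenic reads carry a pseudo-gene label)
#   reads      read count for the triple, >= 1
#   quals      list-column: numeric vector of per-position mean Phred scores
#   intergenic logical flag
# The tibble carries the UMI length redundantly through nchar(umi).

#' Read a molecule record table
#'
#' Reads the tab-separated tag-level format: header line, columns
#' `cb`, `umi`, `gene`, `reads`, `quals` (comma-separated Phred values, one
#' per UMI position) and optional `intergenic` (0/1). Duplicate
#' (cb, umi, gene) rows are aggregated: reads are summed and quality vectors
#' combined as read-weighted means.
#'
#' @param path Path to the TSV file.
#' @param umi_length Expected UMI length; inferred from the first row when
#'   `NULL`.
#' @return A tibble of molecule records (possibly empty, with a warning).
#' @export
read_records <- function(path, umi_length = NULL) {
  if (!file.exists(path)) abort(sprintf("record file not found: %s", path))
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    warn(sprintf("record file is empty: %s", path))
    return(empty_records())
  }
  required <- c("cb", "umi", "gene", "reads", "quals")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("record file lacks columns: %s", paste(missing, collapse = ", ")))
  }
  records <- tibble(
    cb = raw$cb,
    umi = raw$umi,
    gene = raw$gene,
    reads = as.numeric(raw$reads),
    quals = lapply(strsplit(raw$quals, ",", fixed = TRUE), as.numeric),
    intergenic = if ("intergenic" %in% names(raw)) raw$intergenic %in% c("1", "TRUE", "true") else FALSE
  )
  validate_records(records, umi_length = umi_length)
  aggregate_records(records)
}

empty_records <- function() {
  tibble(
    cb = character(), umi = character(), gene = character(),
    reads = numeric(), quals = list(), intergenic = logical()
  )
}

validate_records <- function(records, umi_length = NULL) {
  if (nrow(records) == 0) return(invisible(records))
  assert_acgt(records$cb, "cell barcode")
  assert_acgt(records$umi, "UMI")
  lens <- nchar(records$umi)
  L <- umi_length %||% lens[1]
  if (any(lens != L)) {
    abort(sprintf(
      "ragged UMI lengths: expected %d, row %d has length %d ('%s')",
      L, which(lens != L)[1], lens[which(lens != L)[1]],
      records$umi[which(lens != L)[1]]
    ))
  }
  if (any(is.na(records$reads)) || any(records$reads < 1)) {
    abort(sprintf("read counts must be >= 1 (row %d)",
                  which(is.na(records$reads) | records$reads < 1)[1]))
  }
  qlen <- lengths(records$quals)
  if (any(qlen != L)) {
    abort(sprintf("quality vector length mismatch at row %d (expected %d, got %d)",
                  which(qlen != L)[1], L, qlen[which(qlen != L)[1]]))
  }
  invisible(records)
}

#' Aggregate duplicate molecule records
#'
#' Collapses rows sharing (cb, umi, gene): reads are summed and quality
#' vectors combined as read-weighted means, so total reads are conserved.
#'
#' @param records A molecule record tibble.
#' @return A tibble with unique (cb, umi, gene) keys.
#' @export
aggregate_records <- function(records) {
  if (nrow(records) == 0) return(records)
  key <- paste(records$cb, records$umi, records$gene, sep = "\r")
  if (!anyDuplicated(key)) return(records)
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(i) {
    if (length(i) == 1) return(records[i, ])
    r <- records$reads[i]
    q <- Reduce(`+`, Map(`*`, records$quals[i], r)) / sum(r)
    out <- records[i[1], ]
    out$reads <- sum(r)
    out$quals <- list(q)
    out
  })
  out <- bind_rows(rows)
  out[order(out$cb, out$gene, out$umi), ]
}

# UMI length of a record table.
umi_length <- function(records) {
  if (nrow(records) == 0) abort("cannot infer UMI length from empty records")
  nchar(records$umi[1])
}

#' Build a gene-by-cell molecular count matrix
#'
#' Counts distinct (umi, gene) molecules per cell. Intergenic pseudo-genes
#' are excluded.
#'
#' @param records A molecule record tibble.
#' @return A sparse `dgCMatrix` (genes in rows, cells in columns); cells are
#'   ordered by descending molecule count then lexicographically, genes
#'   lexicographically.
#' @export
count_matrix <- function(records) {
  records <- records[!records$intergenic, , drop = FALSE]
  if (nrow(records) == 0) {
    return(Matrix::sparseMatrix(
      i = integer(), j = integer(), x = numeric(), dims = c(0L, 0L),
      dimnames = list(character(), character())
    ))
  }
  counts <- records %>%
    count(.data$cb, .data$gene, name = "molecules")
  genes <- sort(unique(counts$gene))
  cell_order <- counts %>%
    group_by(.data$cb) %>%
    summarise(total = sum(.data$molecules), .groups = "drop") %>%
    arrange(desc(.data$total), .data$cb)
  cells <- cell_order$cb
  Matrix::sparseMatrix(
    i = match(counts$gene, genes),
    j = match(counts$cb, cells),
    x = as.numeric(counts$molecules),
    dims = c(length(genes), length(cells)),
    dimnames = list(genes, cells)
  )
}

#' Write a count matrix as Matrix Market plus sidecars
#'
#' Writes `<prefix>matrix.mtx`, `<prefix>barcodes.tsv` (cell barcodes, one
#' per line) and `<prefix>features.tsv` (gene identifiers) in the
#' conventional triplet layout with 1-based coordinates.
#'
#' @param matrix A genes-by-cells `dgCMatrix` with dimnames.
#' @param out_prefix Path prefix (directory must exist or be creatable).
#' @return Invisibly, the three file paths.
#' @export
write_count_matrix <- function(matrix, out_prefix) {
  dir <- dirname(paste0(out_prefix, "x"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- paste0(out_prefix, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  Matrix::writeMM(methods::as(matrix, "CsparseMatrix"), paths[1])
  writeLines(as.character(colnames(matrix) %||% character()), paths[2])
  writeLines(as.character(rownames(matrix) %||% character()), paths[3])
  invisible(paths)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param out_prefix The prefix passed to [write_count_matrix()].
#' @return A sparse `dgCMatrix` with dimnames restored.
#' @export
read_count_matrix <- function(out_prefix) {
  paths <- paste0(out_prefix, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  m <- Matrix::readMM(paths[1])
  # pattern/logical variants (e.g. an empty matrix) coerce through dMatrix
  m <- methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
  dimnames(m) <- list(readLines(paths[3]), readLines(paths[2]))
  m
}

#' Read a cellular barcode whitelist
#'
#' @param path Plain-text file, one barcode per line.
#' @return Character vector of barcodes.
#' @export
read_whitelist <- function(path) {
  cbs <- readLines(path)
  cbs <- cbs[nzchar(cbs)]
  assert_acgt(cbs, "whitelist barcode")
  cbs
}
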