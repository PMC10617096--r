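#' Screen count container
#'
#' A `screen_matrix` wraps a sparse cell-by-gene UMI count matrix together
#' with a per-cell metadata tibble. Cells are rows, genes are columns,
#' matching the orientation used by the downstream scoring functions. The
#' per-cell tibble always carries `barcode`, `total_umi`, `n_genes_detected`
#' and `mito_fraction`; later pipeline stages append `sgrna_id`,
#' `target_gene` and `condition`.
#'
#' @param counts sparse (or dense) non-negative integer matrix, cells x genes,
#'   with barcodes as rownames and gene symbols as colnames.
#' @param cells optional tibble of per-cell metadata; must contain `barcode`
#'   matching the rownames of `counts`. QC columns are (re)computed.
#' @param mito_prefix prefix identifying mitochondrial gene symbols
#'   (case-insensitive, default `"mt-"`), used for `mito_fraction`.
#'
#' @return an object of class `screen_matrix` with elements `counts`,
#'   `cells`, `genes` and `normalized` (initially `NULL`).
#' @export
screen_matrix <- function(counts, cells = NULL, mito_prefix = "mt-") {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("gene", seq_len(ncol(counts)))

  qc <- cell_qc_stats(counts, mito_prefix = mito_prefix)
  if (is.null(cells)) {
    cells <- qc
  } else {
    cells <- tibble::as_tibble(cells)
    if (!"barcode" %in% names(cells))
      stop("`cells` must contain a `barcode` column", call. = FALSE)
    if (!identical(cells$barcode, rownames(counts)))
      stop("`cells$barcode` must match rownames(counts) in order", call. = FALSE)
    cells <- dplyr::bind_cols(
      qc, dplyr::select(cells, -dplyr::any_of(names(qc)))
    )
  }

  structure(
    list(counts = counts, cells = cells, genes = colnames(counts),
         normalized = NULL),
    class = "screen_matrix"
  )
}

cell_qc_stats <- function(counts, mito_prefix = "mt-") {
  is_mito <- startsWith(tolower(colnames(counts)), tolower(mito_prefix))
  total <- Matrix::rowSums(counts)
  mito <- if (any(is_mito)) Matrix::rowSums(counts[, is_mito, drop = FALSE]) else 0
  tibble::tibble(
    barcode = rownames(counts),
    total_umi = as.numeric(total),
    n_genes_detected = as.integer(Matrix::rowSums(counts > 0)),
    mito_fraction = ifelse(total > 0, as.numeric(mito) / total, 0)
  )
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat("<screen_matrix> ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes", if (!is.null(x$normalized)) " (normalized)", "\n", sep = "")
  extra <- setdiff(names(x$cells),
                   c("barcode", "total_umi", "n_genes_detected", "mito_fraction"))
  if (length(extra))
    cat("  cell metadata: ", paste(extra, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.screen_matrix <- function(x) dim(x$counts)

#' Subset a screen to a set of barcodes (order preserved as given)
#' @param m a `screen_matrix`
#' @param barcodes character vector of barcodes to keep
#' @return the subset `screen_matrix`
#' @export
subset_cells <- function(m, barcodes) {
  stopifnot(inherits(m, "screen_matrix"))
  keep <- match(barcodes, m$cells$barcode)
  if (anyNA(keep)) stop("unknown barcodes in subset_cells()", call. = FALSE)
  m$counts <- m$counts[keep, , drop = FALSE]
  m$cells <- m$cells[keep, ]
  if (!is.null(m$normalized)) m$normalized <- m$normalized[keep, , drop = FALSE]
  m
}

#' Read a CellRanger-style sparse count matrix
#'
#' Reads a MatrixMarket triplet file plus features and barcodes tables (the
#' CellRanger v3 dialect: the features file may have 2 or 3 columns, with
#' the gene symbol in column 2 when 3 columns are present) and returns a
#' cell-by-gene `screen_matrix` regardless of the on-disk orientation.
#' Duplicated gene symbols are deduplicated deterministically by appending
#' `.1`, `.2`, ... in file order.
#'
#' @param matrix_path path to the `.mtx` file (integer coordinate format).
#' @param features_path path to `features.tsv` / `genes.tsv` (optionally gz).
#' @param barcodes_path path to `barcodes.tsv` (optionally gz).
#' @param mito_prefix passed to [screen_matrix()].
#' @return a `screen_matrix`
#' @export
read_counts_mtx <- function(matrix_path, features_path, barcodes_path,
                            mito_prefix = "mt-") {
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)

  mm <- Matrix::readMM(matrix_path)
  if (methods::is(mm, "nMatrix")) # pattern MTX: all stored entries are 1
    mm <- methods::as(mm, "dMatrix")
  if (any(mm@x != round(mm@x)))
    stop("non-integer values in ", matrix_path, call. = FALSE)

  feat <- utils::read.table(features_path, sep = "\t", header = FALSE,
                            quote = "", comment.char = "",
                            stringsAsFactors = FALSE)
  symbols <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
  barcodes <- readLines(barcodes_path)

  # On disk CellRanger stores genes x cells; accept either orientation.
  if (nrow(mm) == length(symbols) && ncol(mm) == length(barcodes)) {
    mm <- Matrix::t(mm)
  } else if (!(nrow(mm) == length(barcodes) && ncol(mm) == length(symbols))) {
    stop("dimension mismatch between ", matrix_path, " (", nrow(mm), " x ",
         ncol(mm), "), ", features_path, " (", length(symbols), ") and ",
         barcodes_path, " (", length(barcodes), ")", call. = FALSE)
  }
  rownames(mm) <- barcodes
  colnames(mm) <- make_unique_symbols(symbols)
  screen_matrix(mm, mito_prefix = mito_prefix)
}

# "Alb","Alb" -> "Alb","Alb.1" (suffix counts occurrences seen so far)
make_unique_symbols <- function(x) {
  seen <- new.env(parent = emptyenv())
  vapply(x, function(s) {
    n <- if (is.null(seen[[s]])) 0L else seen[[s]]
    seen[[s]] <- n + 1L
    if (n == 0L) s else paste0(s, ".", n)
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a guide library table
#'
#' @param sgrna_id character, unique guide identifiers.
#' @param target_gene character, target gene symbol; `NA` (or the value of
#'   `nt_label`) for non-targeting controls.
#' @param is_nt optional logical; derived from `target_gene` when missing.
#' @param nt_label sentinel used for non-targeting entries in input tables.
#' @return tibble with columns `sgrna_id`, `target_gene` (`NA` for NT) and
#'   `is_nt`.
#' @export
guide_library <- function(sgrna_id, target_gene, is_nt = NULL,
                          nt_label = "NT") {
  target_gene <- as.character(target_gene)
  target_gene[!is.na(target_gene) & target_gene == nt_label] <- NA_character_
  if (is.null(is_nt)) is_nt <- is.na(target_gene)
  lib <- tibble::tibble(sgrna_id = as.character(sgrna_id),
                        target_gene = target_gene, is_nt = is_nt)
  if (anyDuplicated(lib$sgrna_id))
    stop("duplicated sgrna_id in guide library", call. = FALSE)
  bad <- !lib$is_nt & (is.na(lib$target_gene) | lib$target_gene == "")
  if (any(bad))
    stop("targeting guides without a target gene: ",
         paste(lib$sgrna_id[bad], collapse = ", "), call. = FALSE)
  lib$target_gene[lib$is_nt] <- NA_character_
  lib
}

#' Read a guide library TSV (columns sgrna_id, target_gene[, is_nt])
#' @param path tab-separated file with a header.
#' @param nt_label sentinel marking non-targeting rows in `target_gene`.
#' @return a guide library tibble (see [guide_library()]).
#' @export
read_guide_library <- function(path, nt_label = "NT") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  if (!all(c("sgrna_id", "target_gene") %in% names(tab)))
    stop("guide library needs columns sgrna_id, target_gene", call. = FALSE)
  guide_library(tab$sgrna_id, tab$target_gene, nt_label = nt_label)
}

#' Read per-cell sgRNA assignments
#'
#' @param table_path TSV with header and columns `barcode`, `sgrna_id`
#'   (additional columns such as UMI support are carried through).
#' @param library guide library tibble; every `sgrna_id` must appear in it.
#' @return tibble `barcode`, `sgrna_id` (one row per assignment, preserving
#'   multiplicity) plus any extra columns from the file.
#' @export
read_guide_assignments <- function(table_path, library) {
  tab <- utils::read.table(table_path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  if (!all(c("barcode", "sgrna_id") %in% names(tab)))
    stop("assignment table needs columns barcode, sgrna_id", call. = FALSE)
  unknown <- setdiff(tab$sgrna_id, library$sgrna_id)
  if (length(unknown))
    stop("sgrna_id not in guide library: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  tibble::as_tibble(tab) |>
    dplyr::mutate(barcode = as.character(.data$barcode),
                  sgrna_id = as.character(.data$sgrna_id))
}

#' Quality-control filter on cells
#'
#' Retains cells with strictly more than `min_genes` and strictly fewer than
#' `max_genes` detected genes, and a mitochondrial UMI fraction strictly
#' below `max_mito`. Cell order is preserved.
#'
#' @param m a `screen_matrix`
#' @param min_genes,max_genes exclusive bounds on detected genes (defaults
#'   200 and 6000).
#' @param max_mito exclusive upper bound on mitochondrial fraction (0.10).
#' @return filtered `screen_matrix` (empty, with a warning, if nothing passes)
#' @export
qc_filter_cells <- function(m, min_genes = 200, max_genes = 6000,
                            max_mito = 0.10) {
  stopifnot(inherits(m, "screen_matrix"))
  keep <- m$cells$n_genes_detected > min_genes &
    m$cells$n_genes_detected < max_genes &
    m$cells$mito_fraction < max_mito
  if (!any(keep)) warning("qc_filter_cells: no cells pass QC", call. = FALSE)
  subset_cells(m, m$cells$barcode[keep])
}

#' Keep cells carrying exactly one sgRNA
#'
#' Cells whose assignment list contains exactly one distinct guide are
#' retained and annotated with `sgrna_id` and `target_gene`; all other cells
#' (zero or multiple guides) are dropped.
#'
#' @param m a `screen_matrix`
#' @param assignments tibble `barcode`, `sgrna_id` (rows may repeat for UMI
#'   multiplicity; multiplicity of the same guide does not disqualify a cell).
#' @param library guide library tibble used to annotate the target gene.
#' @return annotated `screen_matrix` restricted to unique-guide cells.
#' @export
select_unique_sgrna_cells <- function(m, assignments, library) {
  stopifnot(inherits(m, "screen_matrix"))
  per_cell <- assignments |>
    dplyr::distinct(.data$barcode, .data$sgrna_id) |>
    dplyr::count(.data$barcode, name = "n_guides")
  uniq <- assignments |>
    dplyr::distinct(.data$barcode, .data$sgrna_id) |>
    dplyr::inner_join(dplyr::filter(per_cell, .data$n_guides == 1L),
                      by = "barcode") |>
    dplyr::left_join(library, by = "sgrna_id")
  keep <- m$cells$barcode[m$cells$barcode %in% uniq$barcode]
  out <- subset_cells(m, keep)
  ann <- uniq[match(keep, uniq$barcode), c("sgrna_id", "target_gene", "is_nt")]
  out$cells <- dplyr::bind_cols(
    dplyr::select(out$cells, -dplyr::any_of(c("sgrna_id", "target_gene", "is_nt"))),
    ann
  )
  out
}

#' Log-normalize counts (counts-per-`scale`, natural log1p)
#'
#' `normalized[c, g] = log(1 + counts[c, g] * scale / total_umi[c])`.
#'
#' @param m a `screen_matrix` (QC-filtered; zero-total cells are an error).
#' @param scale library-size scale factor (default 1e4, i.e. CP10K).
#' @param base logarithm base (default natural log).
#' @return the `screen_matrix` with `$normalized` filled in.
#' @export
normalize_log <- function(m, scale = 1e4, base = exp(1)) {
  stopifnot(inherits(m, "screen_matrix"))
  tot <- m$cells$total_umi
  if (any(tot <= 0))
    stop("cells with zero total UMI present; run qc_filter_cells() first",
         call. = FALSE)
  # dgCMatrix is column-compressed: @i holds 0-based row indices per entry.
  norm <- m$counts
  norm@x <- norm@x * scale / tot[norm@i + 1L]
  norm@x <- log1p(norm@x) / log(base)
  m$normalized <- norm
  m
}

#' Summarize a guide library
#' @param library a guide library tibble.
#' @return one-row tibble: `n_targeting`, `n_nt`, `n_total`, `n_genes`.
#' @export
summarize_library <- function(library) {
  tibble::tibble(
    n_targeting = sum(!library$is_nt),
    n_nt = sum(library$is_nt),
    n_total = nrow(library),
    n_genes = dplyr::n_distinct(library$target_gene[!library$is_nt])
  )
}
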