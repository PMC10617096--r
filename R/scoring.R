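#' Marker fold changes per perturbation
#'
#' `FC[i, j]` = (mean normalized expression of marker j in target group i +
#' pseudocount) / (mean in the reference cells + pseudocount). Group means
#' are taken on the linear normalized (counts-per-scale) scale; the
#' pseudocount stabilizes markers with zero expression in a group.
#'
#' @param m a `screen_matrix` with `$normalized`.
#' @param groups tibble `barcode`, `target_gene`, `is_nt` — typically
#'   [target_groups()] after removing GMM-labelled unperturbed cells.
#' @param markers marker gene panel (default [hepatocyte_markers]); markers
#'   absent from the matrix are dropped with a message.
#' @param reference_cells barcodes of the reference set; defaults to the
#'   non-targeting cells in `groups`.
#' @param pseudocount added to both group means (default 1e-2).
#' @return numeric matrix of fold changes, targets x markers.
#' @export
compute_fold_changes <- function(m, groups, markers = hepatocyte_markers,
                                 reference_cells = NULL,
                                 pseudocount = 1e-2) {
  stopifnot(inherits(m, "screen_matrix"))
  if (is.null(m$normalized))
    stop("normalized expression missing; run normalize_log() first",
         call. = FALSE)
  missing <- setdiff(markers, m$genes)
  if (length(missing))
    message("compute_fold_changes: dropping markers absent from matrix: ",
            paste(missing, collapse = ", "))
  markers <- intersect(markers, m$genes)
  if (!length(markers)) stop("no marker genes in matrix", call. = FALSE)
  if (is.null(reference_cells))
    reference_cells <- groups$barcode[groups$is_nt]
  if (!length(reference_cells)) stop("empty reference group", call. = FALSE)

  expr <- m$normalized[, markers, drop = FALSE]
  # linear CP-scale means: back-transform the log-normalized values
  expr@x <- expm1(expr@x)
  ref_mean <- Matrix::colMeans(expr[reference_cells, , drop = FALSE])

  targets <- sort(unique(groups$target_gene[!groups$is_nt]))
  fc <- matrix(NA_real_, length(targets), length(markers),
               dimnames = list(targets, markers))
  for (t in targets) {
    cells <- groups$barcode[!groups$is_nt & groups$target_gene == t]
    if (!length(cells)) stop("empty group for target ", t, call. = FALSE)
    g_mean <- Matrix::colMeans(expr[cells, , drop = FALSE])
    fc[t, ] <- (g_mean + pseudocount) / (ref_mean + pseudocount)
  }
  fc
}

#' Composite regulator score over a marker panel
#'
#' `Score_i = sum_j log2(FC_ij) / k` over the `k` panel markers: the mean
#' log2 fold change of the marker panel under perturbation i. A positive
#' score means the perturbation increases marker expression (a candidate
#' negative regulator of the marker-defined fate when knocked out).
#'
#' @param fc fold-change matrix from [compute_fold_changes()] (all > 0).
#' @return tibble sorted by decreasing score: `target`, one `log2fc_<marker>`
#'   column per marker, `score`, `rank`.
#' @export
regulator_score <- function(fc) {
  stopifnot(is.matrix(fc))
  if (any(fc <= 0)) stop("fold changes must be positive", call. = FALSE)
  l2 <- log2(fc)
  score <- rowMeans(l2)
  out <- tibble::as_tibble(l2, rownames = "target") |>
    dplyr::rename_with(~ paste0("log2fc_", .x), -"target") |>
    dplyr::mutate(score = unname(score)) |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::mutate(rank = dplyr::row_number())
  out
}
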