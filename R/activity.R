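#' Read regulon gene sets from a GMT file
#'
#' One regulon per line: name, description, then member genes. Duplicate
#' genes within a line are removed with a warning. Member genes absent from
#' a particular count matrix are kept here and dropped at scoring time.
#'
#' @param path GMT file.
#' @return named list of character vectors (member genes per regulon TF).
#' @export
read_regulons_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(list(), character()))
  regs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in regulon '", f[1], "' deduplicated",
              call. = FALSE)
      genes <- unique(genes)
    }
    stats::setNames(list(genes), f[1])
  })
  unlist(regs, recursive = FALSE)
}

#' Write regulons to GMT
#' @param regulons named list of character vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regulons_gmt <- function(regulons, path) {
  lines <- vapply(names(regulons), function(tf)
    paste(c(tf, "na", regulons[[tf]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter low-information genes before activity scoring
#'
#' Keeps genes with at least `min_total_umi` UMIs summed over all cells and
#' detected (count > 0) in at least `min_cell_frac` of cells.
#'
#' @param m a `screen_matrix`.
#' @param min_total_umi minimum total UMI count (default 6).
#' @param min_cell_frac minimum detected fraction of cells (default 0.01).
#' @return the gene-filtered `screen_matrix`.
#' @export
filter_genes_for_activity <- function(m, min_total_umi = 6,
                                      min_cell_frac = 0.01) {
  stopifnot(inherits(m, "screen_matrix"))
  tot <- Matrix::colSums(m$counts)
  frac <- Matrix::colSums(m$counts > 0) / nrow(m$counts)
  keep <- tot >= min_total_umi & frac >= min_cell_frac
  m$counts <- m$counts[, keep, drop = FALSE]
  m$genes <- colnames(m$counts)
  if (!is.null(m$normalized)) m$normalized <- m$normalized[, keep, drop = FALSE]
  m
}

#' Per-cell regulon activity by recovery-curve AUC
#'
#' For each cell, all genes are ranked by decreasing raw count (ties by
#' `tie_rule`). With `T = floor(top_frac * G)` genes in the top set, the
#' recovery curve counts regulon members among the top `x` ranks for
#' `x = 1..T`; the activity is the area under this step curve divided by the
#' maximal achievable area (all members ranked first). Values lie in [0, 1].
#' Ranking raw counts makes the score invariant to per-cell scaling.
#'
#' @param m a gene-filtered `screen_matrix`.
#' @param regulons named list of member gene vectors; members absent from
#'   the matrix are dropped (logged once); a regulon with empty intersection
#'   scores 0 with a warning.
#' @param top_frac fraction of genes in the top set (default 0.05).
#' @param tie_rule "average" (deterministic, default) or "random" (seeded).
#' @param seed seed for `tie_rule = "random"`.
#' @return numeric matrix, cells x regulons, rownames barcodes.
#' @export
score_aucell <- function(m, regulons, top_frac = 0.05,
                         tie_rule = c("average", "random"), seed = 1L) {
  stopifnot(inherits(m, "screen_matrix"))
  tie_rule <- match.arg(tie_rule)
  if (!(top_frac > 0 && top_frac <= 1))
    stop("top_frac must be in (0, 1]", call. = FALSE)
  genes <- m$genes
  G <- length(genes)
  T_top <- max(1L, floor(top_frac * G))

  dropped <- sum(vapply(regulons, function(g) sum(!g %in% genes), 0L))
  if (dropped > 0)
    message("score_aucell: ", dropped,
            " regulon member genes absent from matrix were dropped")
  members <- lapply(regulons, function(g) match(intersect(g, genes), genes))
  empty <- vapply(members, length, 0L) == 0L
  if (any(empty))
    warning("regulons with no genes in matrix score 0: ",
            paste(names(regulons)[empty], collapse = ", "), call. = FALSE)

  x <- as.matrix(m$counts)
  act <- matrix(0, nrow(x), length(regulons),
                dimnames = list(rownames(x), names(regulons)))
  compute <- function() {
    for (c_i in seq_len(nrow(x))) {
      r <- rank(-x[c_i, ], ties.method = tie_rule)
      for (j in seq_along(members)) {
        idx <- members[[j]]
        if (!length(idx)) next
        mr <- ceiling(r[idx])
        auc <- sum(pmax(0, T_top - mr + 1))
        m_sz <- length(idx)
        xs <- seq_len(T_top)
        max_auc <- sum(pmin(xs, m_sz))
        act[c_i, j] <<- auc / max_auc
      }
    }
  }
  if (tie_rule == "random") with_seed(seed, compute()) else compute()
  act
}

#' Order regulons by variability
#'
#' For a cell-by-regulon activity matrix the criterion is variance across
#' cells; for an `effect_matrix` it is variance across targets. Ties are
#' broken alphabetically for determinism.
#'
#' @param source an activity matrix (cells x regulons) or [effect_matrix].
#' @param n number of regulons to return (default 20).
#' @return character vector of regulon names, most variable first.
#' @export
select_variable_regulons <- function(source, n = 20) {
  vals <- if (inherits(source, "effect_matrix")) source$effect else source
  stopifnot(is.matrix(vals), n <= ncol(vals))
  v <- apply(vals, 2, stats::var)
  ord <- order(-v, colnames(vals))
  colnames(vals)[ord][seq_len(n)]
}
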