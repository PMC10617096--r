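# small in-code fixtures shared across test files

toy_screen <- function(counts, genes = NULL, barcodes = NULL, ...) {
  counts <- as.matrix(counts)
  if (!is.null(genes)) colnames(counts) <- genes
  if (!is.null(barcodes)) rownames(counts) <- barcodes
  screen_matrix(Matrix::Matrix(counts, sparse = TRUE), ...)
}

# write a CellRanger-style triplet (genes x cells on disk) and return paths
write_mtx_fixture <- function(counts_cells_by_genes, genes, barcodes,
                              dir = withr::local_tempdir(.local_envir =
                                                           parent.frame())) {
  m <- Matrix::Matrix(t(as.matrix(counts_cells_by_genes)), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(id = paste0("ENS", seq_along(genes)), symbol = genes,
               type = "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  list(mtx = file.path(dir, "matrix.mtx"),
       features = file.path(dir, "features.tsv"),
       barcodes = file.path(dir, "barcodes.tsv"))
}

# pilot-style library: 6 genes x 3 guides + 4 NT
pilot_library <- function() {
  genes <- c("Hnf4a", "Onecut1", "Hdac3", "Esrp2", "Cebpd", "Hmga2")
  guide_library(
    sgrna_id = c(paste0(rep(genes, each = 3), "_g", 1:3),
                 paste0("NT_g", 1:4)),
    target_gene = c(rep(genes, each = 3), rep(NA, 4))
  )
}

# independent recovery-curve AUC: explicit loop over the step curve
aucell_oracle <- function(counts_cell, member_idx, top_frac = 0.05) {
  G <- length(counts_cell)
  T_top <- max(1L, floor(top_frac * G))
  r <- rank(-counts_cell, ties.method = "average")
  hits <- vapply(seq_len(T_top), function(x) sum(r[member_idx] <= x), 0L)
  max_hits <- vapply(seq_len(T_top), function(x)
    min(x, length(member_idx)), 0L)
  sum(hits) / sum(max_hits)
}

# exhaustive hypergeometric enumeration over all K_R-subsets of N items,
# K_P of which are marked
hypergeom_enum <- function(N, K_P, K_R, k, tail = "upper") {
  if (K_R == 0) return(as.numeric(k == 0 || tail == "upper" && k <= 0))
  subs <- utils::combn(N, K_R)
  overlap <- colSums(subs <= K_P) # items 1..K_P are the marked ones
  if (tail == "pmf") mean(overlap == k) else mean(overlap >= k)
}
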