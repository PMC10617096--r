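test_that("read_counts_mtx transcribes a toy matrix and orients cell x gene", {
  counts <- rbind(c1 = c(5, 0, 0), c2 = c(0, 0, 1))
  colnames(counts) <- c("g1", "g2", "g3")
  paths <- write_mtx_fixture(counts, c("g1", "g2", "g3"), c("c1", "c2"))
  m <- read_counts_mtx(paths$mtx, paths$features, paths$barcodes)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(unname(Matrix::rowSums(m$counts)), c(5, 1))
  expect_equal(as.numeric(m$counts["c1", "g1"]), 5)
  expect_equal(as.numeric(m$counts["c2", "g3"]), 1)
})

test_that("empty MTX body gives an all-zero matrix of declared shape", {
  counts <- matrix(0, 2, 3, dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
  paths <- write_mtx_fixture(counts, c("g1", "g2", "g3"), c("c1", "c2"))
  m <- read_counts_mtx(paths$mtx, paths$features, paths$barcodes)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(sum(m$counts), 0)
})

test_that("duplicate gene symbols are suffixed deterministically in file order", {
  counts <- matrix(1, 2, 3, dimnames = list(c("c1", "c2"), NULL))
  paths <- write_mtx_fixture(counts, c("Alb", "Alb", "Ttr"), c("c1", "c2"))
  m <- read_counts_mtx(paths$mtx, paths$features, paths$barcodes)
  expect_equal(m$genes, c("Alb", "Alb.1", "Ttr"))
})

test_that("reader rejects dimension mismatches naming the offending files", {
  counts <- matrix(1, 2, 3, dimnames = list(c("c1", "c2"), NULL))
  paths <- write_mtx_fixture(counts, c("g1", "g2", "g3"), c("c1", "c2"))
  writeLines(c("c1", "c2", "c3"), paths$barcodes)
  expect_error(read_counts_mtx(paths$mtx, paths$features, paths$barcodes),
               "mismatch")
  expect_error(read_counts_mtx("/nonexistent.mtx", paths$features,
                               paths$barcodes), "not found")
})

test_that("reader rejects non-integer matrix values", {
  dir <- withr::local_tempdir()
  m <- Matrix::Matrix(matrix(c(0.5, 0, 0, 0, 0, 0), 3, 2), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(paste0("g", 1:3), paste0("g", 1:3)),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  expect_error(read_counts_mtx(file.path(dir, "matrix.mtx"),
                               file.path(dir, "features.tsv"),
                               file.path(dir, "barcodes.tsv")),
               "non-integer")
})

test_that("guide assignments map barcodes to guides and reject unknown guides", {
  lib <- guide_library(c("g1", "g2"), c("A", "B"))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "asg.tsv")
  utils::write.table(
    data.frame(barcode = c("c1", "c1", "c2"), sgrna_id = c("g1", "g2", "g1")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  asg <- read_guide_assignments(path, lib)
  expect_equal(sort(asg$sgrna_id[asg$barcode == "c1"]), c("g1", "g2"))
  expect_equal(asg$sgrna_id[asg$barcode == "c2"], "g1")

  utils::write.table(
    data.frame(barcode = "c1", sgrna_id = "gX"), path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_guide_assignments(path, lib), "gX")

  utils::write.table(
    data.frame(barcode = character(), sgrna_id = character()), path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_guide_assignments(path, lib)), 0L)
})

test_that("qc_filter_cells applies strict bounds on genes and mito fraction", {
  # 1000-gene universe with a mito block so fractions are controllable;
  # every expressed gene gets 5 UMI, so the mito UMI fraction equals the
  # fraction of expressed genes that are mitochondrial
  genes <- c(paste0("g", 1:900), paste0("mt-", 1:100))
  mk_cell <- function(n_genes, mito_frac) {
    x <- numeric(1000)
    n_mito <- round(n_genes * mito_frac)
    if (n_mito > 0) x[901:(900 + n_mito)] <- 5
    x[seq_len(n_genes - n_mito)] <- 5
    x
  }
  counts <- rbind(a = mk_cell(150, 0.05), b = mk_cell(300, 0.12),
                  c = mk_cell(300, 0.05), d = mk_cell(900, 0.01))
  m <- toy_screen(counts, genes = genes)
  kept <- qc_filter_cells(m, min_genes = 200, max_genes = 600,
                          max_mito = 0.10)
  expect_equal(kept$cells$barcode, "c")
})

test_that("qc boundary cells are removed (strict inequality) and QC is idempotent", {
  genes <- paste0("g", 1:500)
  counts <- matrix(0, 3, 500, dimnames = list(c("a", "b", "c"), genes))
  counts[1, 1:200] <- 1  # exactly 200 genes -> removed
  counts[2, 1:201] <- 1  # 201 genes -> kept
  counts[3, 1:350] <- 1
  m <- toy_screen(counts)
  kept <- qc_filter_cells(m, min_genes = 200, max_genes = 350, max_mito = 0.1)
  expect_equal(kept$cells$barcode, "b") # 350 is also a strict bound
  twice <- qc_filter_cells(kept, min_genes = 200, max_genes = 350,
                           max_mito = 0.1)
  expect_identical(as.matrix(twice$counts), as.matrix(kept$counts))
})

test_that("qc filtering matches per-cell predicate evaluation on random data", {
  withr::local_seed(42)
  genes <- c(paste0("g", 1:90), paste0("mt-", 1:10))
  counts <- matrix(rpois(100 * 100, 1.2), 100, 100,
                   dimnames = list(sprintf("c%03d", 1:100), genes))
  m <- toy_screen(counts)
  kept <- qc_filter_cells(m, min_genes = 50, max_genes = 75, max_mito = 0.08)
  oracle <- vapply(seq_len(100), function(i) {
    x <- counts[i, ]
    ng <- sum(x > 0)
    mito <- sum(x[91:100]) / sum(x)
    ng > 50 && ng < 75 && mito < 0.08
  }, logical(1))
  expect_equal(kept$cells$barcode, rownames(counts)[oracle])
})

test_that("unique-sgRNA selection keeps single-guide cells and annotates them", {
  lib <- guide_library(c("g1", "g2", "nt1"), c("A", "B", NA))
  counts <- matrix(1, 3, 4, dimnames = list(c("c1", "c2", "c3"), NULL))
  m <- toy_screen(counts)
  asg <- tibble::tibble(barcode = c("c1", "c2", "c2", "c1"),
                        sgrna_id = c("g1", "g1", "g2", "g1"))
  out <- select_unique_sgrna_cells(m, asg, lib)
  expect_equal(out$cells$barcode, "c1") # c2 has two guides, c3 none
  expect_equal(out$cells$sgrna_id, "g1")
  expect_equal(out$cells$target_gene, "A")

  all_uniq <- tibble::tibble(barcode = c("c1", "c2", "c3"),
                             sgrna_id = c("g1", "g2", "nt1"))
  expect_equal(select_unique_sgrna_cells(m, all_uniq, lib)$cells$barcode,
               c("c1", "c2", "c3"))
})

test_that("unique-guide retention matches the simulator's multiplicity truth", {
  cfg <- sim_config(n_cells_per_guide = 30, moi = 0.5, seed = 9)
  sim <- simulate_screen(cfg)
  distinct_asg <- dplyr::distinct(sim$assignments)
  n_per_cell <- table(factor(distinct_asg$barcode,
                             levels = sim$screen$cells$barcode))
  expected <- names(n_per_cell)[n_per_cell == 1]
  out <- select_unique_sgrna_cells(sim$screen, sim$assignments, sim$library)
  expect_setequal(out$cells$barcode, expected)
})

test_that("normalize_log reproduces the per-entry formula and preserves ranks", {
  m <- toy_screen(rbind(c1 = c(1, 0)), genes = c("g1", "g2"))
  out <- normalize_log(m, scale = 10)
  expect_equal(as.numeric(out$normalized["c1", ]), c(log(11), 0))

  withr::local_seed(7)
  counts <- matrix(rpois(30 * 20, 3) + 1, 30, 20)
  m2 <- normalize_log(toy_screen(counts))
  brute <- log1p(counts * 1e4 / rowSums(counts))
  expect_equal(unname(as.matrix(m2$normalized)), brute, tolerance = 1e-12)
  for (i in c(1, 15, 30))
    expect_equal(rank(as.numeric(m2$normalized[i, ])), rank(counts[i, ]))

  zero <- toy_screen(rbind(c1 = c(0, 0)))
  expect_error(normalize_log(zero), "QC|zero")
})

test_that("all-equal counts normalize to equal values within a cell", {
  m <- normalize_log(toy_screen(rbind(c1 = c(4, 4, 4))))
  expect_equal(length(unique(as.numeric(m$normalized[1, ]))), 1L)
})

test_that("summarize_library reproduces pilot and main screen compositions", {
  expect_equal(summarize_library(pilot_library()),
               tibble::tibble(n_targeting = 18L, n_nt = 4L, n_total = 22L,
                              n_genes = 6L))

  genes <- paste0("G", 1:78)
  main <- guide_library(
    sgrna_id = c(paste0("G1_g", 1:5),
                 paste0(rep(genes[-1], each = 3), "_g", 1:3),
                 paste0("NT_g", 1:10)),
    target_gene = c(rep("G1", 5), rep(genes[-1], each = 3), rep(NA, 10))
  )
  s <- summarize_library(main)
  expect_equal(s$n_targeting, 236L)
  expect_equal(s$n_total, 246L)
  expect_equal(s$n_genes, 78L)
  expect_equal(s$n_total, s$n_targeting + s$n_nt)
  expect_equal(s$n_total, nrow(main))

  empty <- guide_library(character(), character())
  expect_equal(unlist(summarize_library(empty)),
               c(n_targeting = 0L, n_nt = 0L, n_total = 0L, n_genes = 0L))
})

test_that("guide_library enforces its invariants", {
  expect_error(guide_library(c("a", "a"), c("X", "Y")), "duplicated")
  expect_error(guide_library("a", NA, is_nt = FALSE), "target gene")
  lib <- guide_library(c("a", "n"), c("X", "NT"))
  expect_true(lib$is_nt[2])
  expect_true(is.na(lib$target_gene[2]))
})
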