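random_effect_matrix <- function(n_t = 5, n_f = 8, seed = 1) {
  withr::with_seed(seed, structure(list(
    effect = matrix(rnorm(n_t * n_f), n_t, n_f,
                    dimnames = list(paste0("T", seq_len(n_t)),
                                    paste0("R", seq_len(n_f)))),
    pvalue = matrix(runif(n_t * n_f), n_t, n_f),
    feature_kind = "regulon", reference = "nt"), class = "effect_matrix"))
}

test_that("Spearman correlation matches rank-then-Pearson and handles edge rows", {
  e <- random_effect_matrix(5, 8, seed = 2)
  cm <- correlate_spearman(e, "targets")
  brute <- cor(apply(t(e$effect), 2, rank))
  expect_equal(unname(cm), unname(brute), tolerance = 1e-12)
  expect_true(isSymmetric(cm))
  expect_equal(unname(diag(cm)), rep(1, 5))

  e$effect[2, ] <- e$effect[1, ]
  expect_equal(correlate_spearman(e, "targets")[1, 2], 1)
  e$effect[3, ] <- -e$effect[1, ]
  expect_equal(correlate_spearman(e, "targets")[1, 3], -1)
  e$effect[4, ] <- 7
  expect_warning(cm2 <- correlate_spearman(e, "targets"), "constant")
  expect_equal(unname(cm2[4, 1]), 0)
})

test_that("k-means recovers block structure and degenerates gracefully", {
  withr::local_seed(4)
  base <- c(rep(1, 5), rep(-1, 5))
  cm <- outer(base, base) + matrix(rnorm(100, sd = 0.05), 10)
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  dimnames(cm) <- list(paste0("L", 1:10), paste0("L", 1:10))
  mod <- kmeans_modules(cm, k = 2, seed = 1)
  expect_length(unique(mod$module[1:5]), 1)
  expect_length(unique(mod$module[6:10]), 1)
  expect_false(mod$module[1] == mod$module[6])

  singletons <- kmeans_modules(cm, k = 10, seed = 1)
  expect_equal(sort(unique(singletons$module)), 1:10)
  expect_equal(attr(singletons, "inertia"), 0, tolerance = 1e-12)
})

test_that("planted perturbation programs are recovered across seeds", {
  hits <- vapply(1:20, function(s) {
    withr::local_seed(400 + s)
    prog <- rep(c(0, 1), each = 6)
    eff <- matrix(rnorm(12 * 20, sd = 0.3), 12, 20)
    eff[prog == 0, 1:10] <- eff[prog == 0, 1:10] + 2
    eff[prog == 1, 11:20] <- eff[prog == 1, 11:20] + 2
    dimnames(eff) <- list(paste0("T", 1:12), paste0("R", 1:20))
    e <- structure(list(effect = eff, pvalue = eff * 0 + 1,
                        feature_kind = "regulon", reference = "nt"),
                   class = "effect_matrix")
    mod <- kmeans_modules(correlate_spearman(e, "targets"), k = 2,
                          seed = s)
    agreement <- max(mean((mod$module == 1) == (prog == 1)),
                     mean((mod$module == 2) == (prog == 1)))
    agreement == 1
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("hypergeometric pmf and tail match stats and exhaustive enumeration", {
  # forced draws
  expect_equal(hypergeom_pvalue(10, 10, 4, 4, tail = "pmf"), 1)
  expect_equal(hypergeom_pvalue(10, 0, 4, 0, tail = "pmf"), 1)

  expect_equal(hypergeom_enum(20, 8, 5, 4, "upper"),
               hypergeom_pvalue(20, 8, 5, 4, tail = "upper"),
               tolerance = 1e-12)

  withr::local_seed(19)
  for (i in 1:25) {
    N <- sample(5:20, 1)
    K_P <- sample(0:N, 1)
    K_R <- sample(0:min(8, N), 1)
    k <- sample(max(0, K_P + K_R - N):min(K_P, K_R), 1)
    expect_equal(hypergeom_pvalue(N, K_P, K_R, k, tail = "pmf"),
                 dhyper(k, K_P, N - K_P, K_R), tolerance = 1e-12)
    expect_equal(hypergeom_pvalue(N, K_P, K_R, k, tail = "upper"),
                 phyper(k - 1, K_P, N - K_P, K_R, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_pvalue(10, 5, 5, 6), "invalid")
})

test_that("the pmf sums to one over its support", {
  withr::local_seed(29)
  for (i in 1:100) {
    N <- sample(2:200, 1)
    K_P <- sample(0:N, 1)
    K_R <- sample(0:N, 1)
    ks <- max(0, K_P + K_R - N):min(K_P, K_R)
    expect_equal(sum(hypergeom_pvalue(N, K_P, K_R, ks, tail = "pmf")), 1,
                 tolerance = 1e-9)
  }
})

test_that("module map concentrates all regulations into the expected edge", {
  pairs <- tibble::tibble(
    target = paste0("T", 1:6), feature = paste0("R", 1:6),
    sign = "activating", effect = 0.5, pvalue = 0.01)
  pm <- tibble::tibble(label = paste0("T", 1:6), module = rep(1:2, each = 3))
  rm_ <- tibble::tibble(label = paste0("R", 1:6), module = rep(1:2, each = 3))
  edges <- build_module_map(pairs, pm, rm_, tail = "pmf")
  all_tests <- attr(edges, "all_tests")
  # P1 -> R1 holds 3 of 6 regulations with K_P = K_R = 3
  p11 <- all_tests[all_tests$from_module == "P1" &
                     all_tests$to_module == "R1", ]
  expect_equal(p11$pvalue, hypergeom_enum(6, 3, 3, 3, "pmf"),
               tolerance = 1e-12)
  expect_true(all(edges$adj_pvalue < 0.05))
  expect_equal(edges$weight, -log10(edges$adj_pvalue))
})

test_that("BH adjustment is monotone and empty pair lists yield empty maps", {
  pairs <- tibble::tibble(target = character(), feature = character(),
                          sign = character(), effect = numeric(),
                          pvalue = numeric())
  pm <- tibble::tibble(label = character(), module = integer())
  expect_equal(nrow(build_module_map(pairs, pm, pm)), 0)

  withr::local_seed(41)
  pairs2 <- tibble::tibble(
    target = sample(paste0("T", 1:8), 60, TRUE),
    feature = sample(paste0("R", 1:8), 60, TRUE),
    sign = sample(c("activating", "repressive"), 60, TRUE),
    effect = rnorm(60), pvalue = runif(60, 0, 0.05))
  pairs2$effect <- abs(pairs2$effect) *
    ifelse(pairs2$sign == "activating", 1, -1)
  pm2 <- tibble::tibble(label = paste0("T", 1:8), module = rep(1:2, 4))
  rm2 <- tibble::tibble(label = paste0("R", 1:8), module = rep(1:2, 4))
  edges <- build_module_map(pairs2, pm2, rm2)
  tests <- attr(edges, "all_tests")
  ord <- order(tests$pvalue)
  expect_true(all(diff(tests$adj_pvalue[ord]) >= -1e-12))
  expect_gte(min(tests$adj_pvalue), min(tests$pvalue))
})

test_that("edge export round-trips TSV and writes deterministic SIF", {
  edges <- tibble::tibble(
    from_module = c("P2", "P1"), to_module = c("R1", "R3"),
    sign_class = c("repressive", "activating"), k = c(3L, 5L),
    K_P = c(4L, 6L), K_R = c(5L, 7L), N = c(20L, 20L),
    pvalue = c(0.001, 0.002), adj_pvalue = c(0.004, 0.004),
    weight = -log10(c(0.004, 0.004)))
  dir <- withr::local_tempdir()
  export_edges(edges, file.path(dir, "e.tsv"), "tsv")
  back <- readr::read_tsv(file.path(dir, "e.tsv"), show_col_types = FALSE)
  expect_equal(dplyr::arrange(as.data.frame(back), from_module),
               dplyr::arrange(as.data.frame(edges), from_module))

  export_edges(edges, file.path(dir, "e.sif"), "sif")
  expect_equal(readLines(file.path(dir, "e.sif")),
               c("P1 activating R3", "P2 repressive R1"))
})
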