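#' Spearman correlation across targets or features of an effect matrix
#'
#' @param e an [effect_matrix].
#' @param axis `"targets"` (correlate perturbations over their feature
#'   effect profiles) or `"features"` (correlate regulons over targets).
#' @return symmetric correlation matrix with unit diagonal; constant effect
#'   vectors get correlation 0 with a warning.
#' @export
correlate_spearman <- function(e, axis = c("targets", "features")) {
  stopifnot(inherits(e, "effect_matrix"))
  axis <- match.arg(axis)
  vals <- if (axis == "targets") t(e$effect) else e$effect
  if (ncol(vals) < 3) stop("need at least 3 labels on axis '", axis, "'",
                           call. = FALSE)
  cm <- suppressWarnings(stats::cor(vals, method = "spearman"))
  if (anyNA(cm)) {
    warning("constant effect vectors set to correlation 0", call. = FALSE)
    cm[is.na(cm)] <- 0
  }
  diag(cm) <- 1
  cm
}

#' k-means modules from a correlation matrix
#'
#' Each label's correlation profile (its row) is the feature vector; modules
#' are the best of `n_init` k-means restarts by within-cluster sum of
#' squares, deterministic under `seed`.
#'
#' @param cm square correlation matrix with dimnames.
#' @param k number of modules (>= 2).
#' @param seed integer seed.
#' @param n_init number of restarts (default 50).
#' @return tibble `label`, `module` (ids 1..k) with attributes `k`, `seed`
#'   and `inertia` (total within-cluster sum of squares).
#' @export
kmeans_modules <- function(cm, k, seed = 1L, n_init = 50) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), k >= 2, k <= nrow(cm))
  if (k == nrow(cm)) { # singleton clusters: no search needed
    out <- tibble::tibble(label = rownames(cm), module = seq_len(k))
    attr(out, "k") <- k
    attr(out, "seed") <- seed
    attr(out, "inertia") <- 0
    return(out)
  }
  fit <- NULL
  for (attempt in 0:9) {
    fit <- try(with_seed(seed + attempt,
                         stats::kmeans(cm, centers = k, nstart = n_init,
                                       iter.max = 100)),
               silent = TRUE)
    if (!inherits(fit, "try-error")) break
  }
  if (inherits(fit, "try-error"))
    stop("k-means failed after 10 re-seeded restarts", call. = FALSE)
  out <- tibble::tibble(label = rownames(cm),
                        module = as.integer(fit$cluster))
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  attr(out, "inertia") <- fit$tot.withinss
  out
}

#' Hypergeometric probability / tail for module enrichment
#'
#' With `N` total regulations, `K_P` from perturbation module Pi, `K_R` into
#' regulon module Rj and `k` in both, the point probability is
#' `C(K_P, k) C(N - K_P, K_R - k) / C(N, K_R)`; the upper tail sums the
#' point probabilities for `x >= k`. Computed in log space.
#'
#' @param N,K_P,K_R,k hypergeometric counts (vectorized).
#' @param tail `"upper"` (default, P(X >= k)) or `"pmf"` (point probability).
#' @return numeric vector of probabilities.
#' @export
hypergeom_pvalue <- function(N, K_P, K_R, k, tail = c("upper", "pmf")) {
  tail <- match.arg(tail)
  n <- max(length(N), length(K_P), length(K_R), length(k))
  N <- rep_len(N, n); K_P <- rep_len(K_P, n)
  K_R <- rep_len(K_R, n); k <- rep_len(k, n)
  ok <- k >= 0 & K_P >= 0 & K_R >= 0 & K_P <= N & K_R <= N &
    k <= pmin(K_P, K_R)
  if (!all(ok))
    stop("invalid hypergeometric counts: need 0 <= k <= min(K_P, K_R) and ",
         "K_P, K_R <= N", call. = FALSE)
  pmf1 <- function(N, K_P, K_R, x) {
    lp <- lchoose(K_P, x) + lchoose(N - K_P, K_R - x) - lchoose(N, K_R)
    exp(lp)
  }
  vapply(seq_len(n), function(i) {
    if (tail == "pmf") return(pmf1(N[i], K_P[i], K_R[i], k[i]))
    xs <- k[i]:min(K_P[i], K_R[i])
    min(1, sum(pmf1(N[i], K_P[i], K_R[i], xs)))
  }, numeric(1))
}

#' Infer the module-to-module regulatory map
#'
#' Regulation pairs are split into activating and repressive classes; within
#' each class, every perturbation-module / regulon-module combination (Pi,
#' Rj) is tested hypergeometrically (`N` = class regulations, `K_P` = from
#' Pi, `K_R` = into Rj, `k` = both). P-values are Benjamini-Hochberg
#' adjusted (jointly over all tests by default) and edges with adjusted
#' p < `alpha` are retained with weight `-log10(adj_pvalue)`.
#'
#' @param pairs regulation pairs from [test_regulations()].
#' @param pm,rm module assignments from [kmeans_modules()] for targets
#'   (perturbations) and features (regulons).
#' @param alpha retention threshold on adjusted p-values (default 0.05).
#' @param tail hypergeometric tail, `"upper"` (default) or `"pmf"`.
#' @param bh_pool `"joint"` (default): BH over all Pi x Rj x sign tests;
#'   `"per_class"`: BH within each sign class.
#' @return tibble of retained edges: `from_module`, `to_module`,
#'   `sign_class`, `k`, `K_P`, `K_R`, `N`, `pvalue`, `adj_pvalue`, `weight`.
#'   The attribute `"all_tests"` holds the full test table before retention.
#' @export
build_module_map <- function(pairs, pm, rm, alpha = 0.05,
                             tail = c("upper", "pmf"),
                             bh_pool = c("joint", "per_class")) {
  tail <- match.arg(tail)
  bh_pool <- match.arg(bh_pool)
  empty <- tibble::tibble(
    from_module = character(), to_module = character(),
    sign_class = character(), k = integer(), K_P = integer(),
    K_R = integer(), N = integer(), pvalue = numeric(),
    adj_pvalue = numeric(), weight = numeric())
  if (!nrow(pairs)) return(empty)
  miss_t <- setdiff(pairs$target, pm$label)
  miss_f <- setdiff(pairs$feature, rm$label)
  if (length(miss_t) || length(miss_f))
    stop("pairs reference labels missing from module assignments: ",
         paste(c(miss_t, miss_f), collapse = ", "), call. = FALSE)

  pairs <- pairs |>
    dplyr::left_join(stats::setNames(pm, c("target", "p_module")),
                     by = "target") |>
    dplyr::left_join(stats::setNames(rm, c("feature", "r_module")),
                     by = "feature")

  tests <- purrr::map_dfr(unique(pairs$sign), function(cl) {
    sub <- dplyr::filter(pairs, .data$sign == cl)
    N <- nrow(sub)
    grid <- tidyr::expand_grid(p_module = sort(unique(pm$module)),
                               r_module = sort(unique(rm$module)))
    grid |>
      dplyr::mutate(
        sign_class = cl,
        K_P = vapply(.data$p_module, function(i)
          sum(sub$p_module == i), 0L),
        K_R = vapply(.data$r_module, function(j)
          sum(sub$r_module == j), 0L),
        k = purrr::map2_int(.data$p_module, .data$r_module, function(i, j)
          sum(sub$p_module == i & sub$r_module == j)),
        N = N
      )
  })
  tests$pvalue <- hypergeom_pvalue(tests$N, tests$K_P, tests$K_R, tests$k,
                                   tail = tail)
  tests$adj_pvalue <- if (bh_pool == "joint") {
    stats::p.adjust(tests$pvalue, method = "BH")
  } else {
    stats::ave(tests$pvalue, tests$sign_class,
               FUN = function(p) stats::p.adjust(p, method = "BH"))
  }
  tests <- tests |>
    dplyr::mutate(from_module = paste0("P", .data$p_module),
                  to_module = paste0("R", .data$r_module),
                  weight = -log10(.data$adj_pvalue)) |>
    dplyr::select("from_module", "to_module", "sign_class", "k", "K_P",
                  "K_R", "N", "pvalue", "adj_pvalue", "weight") |>
    dplyr::arrange(.data$sign_class, .data$from_module, .data$to_module)
  edges <- dplyr::filter(tests, .data$adj_pvalue < alpha)
  attr(edges, "all_tests") <- tests
  edges
}

#' Export module-map edges
#'
#' @param edges tibble from [build_module_map()].
#' @param path output file.
#' @param format `"tsv"` (all columns, lossless) or `"sif"` (from, sign,
#'   to triples for network viewers).
#' @return `path`, invisibly.
#' @export
export_edges <- function(edges, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  edges <- dplyr::arrange(edges, .data$sign_class, .data$from_module,
                          .data$to_module)
  if (format == "tsv") {
    readr::write_tsv(edges, path)
  } else {
    writeLines(paste(edges$from_module, edges$sign_class, edges$to_module),
               path)
  }
  invisible(path)
}
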