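#' Mean-difference effect estimator (benchmark default)
#'
#' For each group label, the coefficient of feature i is the mean of feature
#' i over the group's cells minus its mean over all other cells.
#'
#' @param M numeric matrix, cells x features.
#' @param labels per-cell group labels (length `nrow(M)`).
#' @return numeric matrix, features x groups.
#' @export
mean_diff_estimator <- function(M, labels) {
  groups <- sort(unique(labels))
  out <- vapply(groups, function(g) {
    ing <- labels == g
    colMeans(M[ing, , drop = FALSE]) - colMeans(M[!ing, , drop = FALSE])
  }, numeric(ncol(M)))
  rownames(out) <- colnames(M)
  out
}

#' Z-score features of a cell-by-feature matrix
#' @param M numeric matrix, cells x features; constant features are left at 0.
#' @return the standardized matrix.
#' @export
standardize_features <- function(M) {
  s <- apply(M, 2, stats::sd)
  s[s == 0] <- 1
  scale(M, scale = s)
}

#' Top highly variable genes
#' @param m a `screen_matrix` with `$normalized`.
#' @param n number of genes (default 4000, capped at the gene count).
#' @return character vector of gene symbols, most variable first.
#' @export
hvg_genes <- function(m, n = 4000) {
  stopifnot(inherits(m, "screen_matrix"), !is.null(m$normalized))
  v <- apply(m$normalized, 2, stats::var)
  names(sort(v, decreasing = TRUE))[seq_len(min(n, length(v)))]
}

#' Cross-method consistency of relative perturbation effects
#'
#' Per method, each target's relative effect is the Spearman correlation of
#' its effect vector with the reference target's, restricted to that
#' method's `n_features` most variable features. The cross-method
#' consistency is the Spearman correlation of the two per-target profiles
#' (the reference itself, trivially 1, is excluded).
#'
#' @param eA,eB [effect_matrix] objects sharing targets.
#' @param reference_target target used as the anchor of relative effects.
#' @param n_features number of most-variable features per method (default
#'   200, capped at the feature count).
#' @return list: `per_target` tibble (`target`, `rho_a`, `rho_b`) and
#'   `consistency` (Spearman of the two columns).
#' @export
consistency_profile <- function(eA, eB, reference_target, n_features = 200) {
  stopifnot(inherits(eA, "effect_matrix"), inherits(eB, "effect_matrix"))
  targets <- intersect(rownames(eA$effect), rownames(eB$effect))
  if (!reference_target %in% targets)
    stop("reference target '", reference_target,
         "' missing from both effect matrices", call. = FALSE)
  rel <- function(e) {
    feats <- select_variable_regulons(e, min(n_features, ncol(e$effect)))
    vapply(targets, function(t)
      stats::cor(e$effect[t, feats], e$effect[reference_target, feats],
                 method = "spearman"), numeric(1))
  }
  per_target <- tibble::tibble(target = targets,
                               rho_a = unname(rel(eA)),
                               rho_b = unname(rel(eB)))
  rest <- dplyr::filter(per_target, .data$target != reference_target)
  list(per_target = per_target,
       consistency = stats::cor(rest$rho_a, rest$rho_b,
                                method = "spearman"))
}

#' Co-directionality of effect signs under downsampling
#'
#' The estimator is run on the full data and on `n_downsample` subsamples of
#' `cells_per_group` cells per group (without replacement); `D[i, j]` is the
#' fraction of subsamples in which the sign of feature i's coefficient for
#' target j agrees with the full-data sign.
#'
#' @param M0 numeric matrix, cells x features (rownames required).
#' @param P0 per-cell group labels.
#' @param cells_per_group subsample size per group (at most the smallest
#'   group size).
#' @param estimator function(M, labels) -> features x groups coefficient
#'   matrix (default [mean_diff_estimator()]).
#' @param n_downsample number of subsamples (default 100).
#' @param seed integer seed.
#' @return list: `C0_sign` (features x groups sign matrix) and `D`
#'   (features x groups co-directionality matrix in [0, 1]).
#' @export
codirectionality <- function(M0, P0, cells_per_group,
                             estimator = mean_diff_estimator,
                             n_downsample = 100, seed = 1L) {
  stopifnot(nrow(M0) == length(P0))
  sizes <- table(P0)
  if (cells_per_group > min(sizes))
    stop("cells_per_group exceeds the smallest group (", min(sizes), ")",
         call. = FALSE)
  C0s <- sign(estimator(M0, P0))
  agree <- matrix(0, nrow(C0s), ncol(C0s), dimnames = dimnames(C0s))
  idx_by_group <- split(seq_along(P0), P0)
  with_seed(seed, {
    for (t in seq_len(n_downsample)) {
      idx <- unlist(lapply(idx_by_group, function(ix)
        ix[sample.int(length(ix), cells_per_group)]), use.names = FALSE)
      Cts <- sign(estimator(M0[idx, , drop = FALSE], P0[idx]))
      agree <- agree + (Cts == C0s)
    }
  })
  list(C0_sign = C0s, D = agree / n_downsample)
}

#' Robustness score per target
#'
#' `RS_j = || D[, j] - 1 ||_2`: the Euclidean distance of target j's
#' co-directionality column from the all-ones vector. 0 means every
#' subsample reproduced every sign; `sqrt(n_features)` is total
#' disagreement. Lower is more robust.
#'
#' @param D co-directionality matrix from [codirectionality()].
#' @return tibble `target`, `rs`.
#' @export
robustness_score <- function(D) {
  tibble::tibble(
    target = colnames(D) %||% as.character(seq_len(ncol(D))),
    rs = unname(sqrt(colSums((1 - D)^2)))
  )
}

#' Subsample-size sweep of readout stability
#'
#' For each subsample size `n`, draws `n_iter` random subsets of the cells
#' (without replacement) and computes the Spearman correlation between the
#' per-feature means in the subset and in the full set of cells; reports the
#' median correlation per `n`.
#'
#' @param features numeric matrix, cells x features, for one cell group
#'   (regulon activities or gene expression).
#' @param n_grid subsample sizes to evaluate (each <= `nrow(features)`).
#' @param n_iter subsamples per size (default 1000).
#' @param seed integer seed.
#' @param feature_mode label recorded in the output ("regulon" or "gene").
#' @return tibble `n`, `median_rho`, `feature_mode`.
#' @export
cell_number_sweep <- function(features, n_grid, n_iter = 1000, seed = 1L,
                              feature_mode = "regulon") {
  stopifnot(is.matrix(features), all(n_grid >= 1),
            all(n_grid <= nrow(features)))
  full_means <- colMeans(features)
  med <- with_seed(seed, vapply(n_grid, function(n) {
    rho <- vapply(seq_len(n_iter), function(i) {
      sub <- features[sample.int(nrow(features), n), , drop = FALSE]
      stats::cor(colMeans(sub), full_means, method = "spearman")
    }, numeric(1))
    stats::median(rho)
  }, numeric(1)))
  tibble::tibble(n = n_grid, median_rho = med, feature_mode = feature_mode)
}

#' Smallest subsample size whose median correlation reaches a threshold
#' @param sweep tibble from [cell_number_sweep()].
#' @param threshold median Spearman threshold (default 0.9).
#' @return the smallest `n` with `median_rho >= threshold` (`NA` if none).
#' @export
min_cells_at <- function(sweep, threshold = 0.9) {
  hit <- sweep$n[sweep$median_rho >= threshold]
  if (length(hit)) min(hit) else NA_integer_
}

`%||%` <- function(a, b) if (is.null(a)) b else a
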