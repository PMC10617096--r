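#' Extract target groups from annotated screen cells
#'
#' @param m a `screen_matrix` after [select_unique_sgrna_cells()].
#' @return tibble `barcode`, `sgrna_id`, `target_gene`, `is_nt` (plus
#'   `condition` when present).
#' @export
target_groups <- function(m) {
  stopifnot(inherits(m, "screen_matrix"),
            all(c("sgrna_id", "target_gene") %in% names(m$cells)))
  dplyr::select(m$cells, dplyr::any_of(
    c("barcode", "sgrna_id", "target_gene", "is_nt", "condition")))
}

#' Drop under-supported sgRNAs
#'
#' Removes cells of sgRNAs supported by fewer than `min_cells` cells. A
#' target gene survives as long as at least one of its guides survives.
#'
#' @param groups tibble from [target_groups()].
#' @param min_cells minimum cells per sgRNA (default 40).
#' @return filtered tibble; attribute `"removed"` holds the per-guide
#'   removal report.
#' @export
filter_min_cells <- function(groups, min_cells = 40) {
  counts <- dplyr::count(groups, .data$sgrna_id, name = "n_cells")
  drop <- dplyr::filter(counts, .data$n_cells < min_cells)
  if (nrow(drop))
    message("filter_min_cells: dropping ", nrow(drop), " sgRNA(s) with < ",
            min_cells, " cells: ",
            paste(drop$sgrna_id, collapse = ", "))
  out <- dplyr::filter(groups, !.data$sgrna_id %in% drop$sgrna_id)
  attr(out, "removed") <- drop
  out
}

#' Perturbation effect sizes on regulon activities (or genes)
#'
#' The effect of perturbing target `t` on feature `r` is the mean activity
#' of `t`'s cells minus the mean activity of the reference cells; the
#' p-value is a two-sided Wilcoxon rank-sum test of the two samples.
#'
#' @param activity numeric matrix, cells x features (regulon activities from
#'   [score_aucell()] or normalized gene expression), rownames barcodes.
#' @param groups tibble from [target_groups()] (after [filter_min_cells()]).
#' @param reference `"nt"` (default): non-targeting control cells;
#'   `"other"`: for each target, all cells not in that target's group.
#' @param condition optional condition label; when given, only cells of that
#'   condition enter the computation (requires a `condition` column).
#' @param feature_kind label recorded in the result ("regulon" or "gene").
#' @return an `effect_matrix`: list with `effect` and `pvalue` matrices
#'   (targets x features), `feature_kind`, `reference`, and per-group sizes.
#' @export
compute_effect_matrix <- function(activity, groups,
                                  reference = c("nt", "other"),
                                  condition = NULL,
                                  feature_kind = "regulon") {
  reference <- match.arg(reference)
  if (!is.null(condition)) {
    stopifnot("condition" %in% names(groups))
    groups <- dplyr::filter(groups, .data$condition == !!condition)
  }
  groups <- dplyr::filter(groups, .data$barcode %in% rownames(activity))
  targets <- sort(unique(groups$target_gene[!groups$is_nt]))
  if (!length(targets)) stop("no target groups survive", call. = FALSE)
  nt_cells <- groups$barcode[groups$is_nt]
  if (reference == "nt" && length(nt_cells) < 2)
    stop("reference = 'nt' needs at least 2 non-targeting cells",
         call. = FALSE)

  feats <- colnames(activity)
  eff <- pval <- matrix(NA_real_, length(targets), length(feats),
                        dimnames = list(targets, feats))
  n_group <- stats::setNames(integer(length(targets)), targets)
  for (t in targets) {
    g_cells <- groups$barcode[!groups$is_nt & groups$target_gene == t]
    if (length(g_cells) < 2)
      stop("target group '", t, "' has < 2 cells; run filter_min_cells()",
           call. = FALSE)
    r_cells <- if (reference == "nt") nt_cells
               else setdiff(groups$barcode, g_cells)
    n_group[t] <- length(g_cells)
    a_g <- activity[g_cells, , drop = FALSE]
    a_r <- activity[r_cells, , drop = FALSE]
    eff[t, ] <- colMeans(a_g) - colMeans(a_r)
    pval[t, ] <- vapply(seq_along(feats), function(j)
      stats::wilcox.test(a_g[, j], a_r[, j], exact = FALSE)$p.value,
      numeric(1))
  }
  structure(list(effect = eff, pvalue = pval, feature_kind = feature_kind,
                 reference = reference, condition = condition,
                 n_group = n_group,
                 n_reference = if (reference == "nt") length(nt_cells)
                               else NA_integer_),
            class = "effect_matrix")
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat("<effect_matrix> ", nrow(x$effect), " targets x ", ncol(x$effect), " ",
      x$feature_kind, " features (reference: ", x$reference, ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy effect_matrix
#' @export
tidy.effect_matrix <- function(x, ...) {
  tibble::tibble(
    target = rep(rownames(x$effect), times = ncol(x$effect)),
    feature = rep(colnames(x$effect), each = nrow(x$effect)),
    effect = as.vector(x$effect),
    pvalue = as.vector(x$pvalue)
  )
}

#' @method glance effect_matrix
#' @export
glance.effect_matrix <- function(x, ...) {
  tibble::tibble(
    n_targets = nrow(x$effect), n_features = ncol(x$effect),
    feature_kind = x$feature_kind, reference = x$reference,
    n_significant_05 = sum(x$pvalue < 0.05)
  )
}

#' Significant regulation pairs
#'
#' Retains target-feature pairs with Wilcoxon `pvalue < alpha` and labels
#' them activating (effect > 0) or repressive (effect < 0). Significant
#' pairs with exactly zero effect are discarded with a warning.
#'
#' @param e an [effect_matrix].
#' @param alpha significance threshold (default 0.05, strict `<`).
#' @return tibble `target`, `feature`, `sign` ("activating"/"repressive"),
#'   `effect`, `pvalue`.
#' @export
test_regulations <- function(e, alpha = 0.05) {
  stopifnot(inherits(e, "effect_matrix"))
  tab <- tidy(e) |> dplyr::filter(.data$pvalue < alpha)
  zero <- tab$effect == 0
  if (any(zero)) {
    warning(sum(zero), " significant pair(s) with zero effect discarded",
            call. = FALSE)
    tab <- tab[!zero, ]
  }
  tab |>
    dplyr::mutate(sign = ifelse(.data$effect > 0, "activating", "repressive")) |>
    dplyr::select("target", "feature", "sign", "effect", "pvalue") |>
    dplyr::arrange(.data$target, .data$feature)
}
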