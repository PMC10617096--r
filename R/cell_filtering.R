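#' Guide indicator design matrix
#'
#' @param groups tibble `barcode`, `sgrna_id` (unique-guide cells).
#' @return sparse 0/1 matrix, cells x guides, one indicator per row.
#' @export
guide_design <- function(groups) {
  stopifnot(all(c("barcode", "sgrna_id") %in% names(groups)),
            !anyDuplicated(groups$barcode))
  guides <- sort(unique(groups$sgrna_id))
  Matrix::sparseMatrix(
    i = seq_len(nrow(groups)),
    j = match(groups$sgrna_id, guides),
    x = 1,
    dims = c(nrow(groups), length(guides)),
    dimnames = list(groups$barcode, guides)
  )
}

#' Per-cell perturbation probability from an elastic-net linear model
#'
#' Standardized expression of the most variable genes is regressed on guide
#' indicators with a multi-response elastic net (`l1_ratio` mixes lasso and
#' ridge as in glmnet's `alpha`). For a cell carrying guide g, let `r1` be
#' its residual sum of squares under the full fit and `r0` the RSS with
#' guide g's coefficient row zeroed; the perturbation probability is the
#' equal-prior Gaussian posterior
#' `exp(-r1 / 2s2) / (exp(-r1 / 2s2) + exp(-r0 / 2s2))` with `s2` the pooled
#' residual variance. Cells of guides with a zero coefficient row score
#' exactly 0.5; cells expressing their guide's signature score above 0.5 and
#' editing-escape cells below, giving the bimodal distribution the mixture
#' filter consumes.
#'
#' @param m a `screen_matrix` with `$normalized` (run [normalize_log()]).
#' @param groups tibble `barcode`, `sgrna_id` of unique-guide cells.
#' @param n_hvg number of high-variance genes used (default 2000, capped at
#'   the number of genes).
#' @param l1_ratio elastic-net mixing parameter (glmnet `alpha`, default 0.5).
#' @param penalty fixed lambda; `NULL` (default) selects it by 5-fold
#'   cross-validation.
#' @param cross_fit evaluate each cell's contrast with coefficients fitted
#'   on the other folds (default `TRUE`). This keeps the posterior honest:
#'   without it, coefficients fitted on the cell itself inflate every
#'   probability above 0.5.
#' @param nfolds folds for cross-validation and cross-fitting (default 5).
#' @param seed seed for fold assignment.
#' @return list: `prob` tibble (`barcode`, `sgrna_id`, `prob`),
#'   `coefficients` (guide x gene matrix, full-data fit), `lambda`,
#'   `sigma2`, `genes`.
#' @export
fit_perturbation_model <- function(m, groups, n_hvg = 2000, l1_ratio = 0.5,
                                   penalty = NULL, cross_fit = TRUE,
                                   nfolds = 5, seed = 1L) {
  stopifnot(inherits(m, "screen_matrix"))
  if (is.null(m$normalized))
    stop("normalized expression missing; run normalize_log() first",
         call. = FALSE)
  groups <- dplyr::filter(groups, .data$barcode %in% m$cells$barcode)
  X <- guide_design(groups)
  norm <- m$normalized[groups$barcode, , drop = FALSE]

  v <- apply(norm, 2, stats::var)
  hvg <- names(sort(v, decreasing = TRUE))[seq_len(min(n_hvg, sum(v > 0)))]
  Y <- scale(as.matrix(norm[, hvg, drop = FALSE]))

  coef_matrix <- function(idx) {
    fit <- glmnet::glmnet(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                          family = "mgaussian", alpha = l1_ratio,
                          intercept = FALSE, standardize = FALSE,
                          lambda = fit_lambda)
    B <- do.call(cbind, lapply(stats::coef(fit),
                               function(co) as.matrix(co)[-1, 1]))
    colnames(B) <- hvg
    B
  }

  fit_lambda <- penalty
  if (is.null(fit_lambda)) {
    cv <- with_seed(seed, glmnet::cv.glmnet(
      X, Y, family = "mgaussian", alpha = l1_ratio, intercept = FALSE,
      standardize = FALSE, nfolds = nfolds))
    fit_lambda <- cv$lambda.min
  }
  B_full <- coef_matrix(seq_len(nrow(Y)))

  # per-cell contrast: fitted row b of the cell's guide, r0 - r1 =
  # sum(2*y*b - b^2); with cross_fit, b comes from the other folds.
  contrast <- numeric(nrow(Y))
  g_idx <- match(groups$sgrna_id, rownames(B_full))
  rss1 <- 0
  if (cross_fit) {
    folds <- with_seed(seed, {
      f <- integer(nrow(Y))
      for (ix in split(seq_len(nrow(Y)), groups$sgrna_id))
        f[ix] <- sample(rep_len(seq_len(min(nfolds, length(ix))),
                                length(ix)))
      f
    })
    for (f in sort(unique(folds))) {
      hold <- folds == f
      B_f <- coef_matrix(which(!hold))
      pred <- B_f[g_idx[hold], , drop = FALSE]
      yh <- Y[hold, , drop = FALSE]
      contrast[hold] <- rowSums(2 * yh * pred - pred^2)
      rss1 <- rss1 + sum((yh - pred)^2)
    }
  } else {
    pred <- B_full[g_idx, , drop = FALSE]
    contrast <- rowSums(2 * Y * pred - pred^2)
    rss1 <- sum((Y - pred)^2)
  }
  sigma2 <- rss1 / length(Y)
  prob <- stats::plogis(contrast / (2 * sigma2))

  list(
    prob = tibble::tibble(barcode = groups$barcode,
                          sgrna_id = groups$sgrna_id, prob = prob),
    coefficients = B_full,
    lambda = fit_lambda,
    sigma2 = sigma2,
    genes = hvg
  )
}

# EM for a univariate two-component Gaussian mixture; components ordered by
# mean. Restarts use a k-means++-style draw of the two initial means.
em_gmm2 <- function(x, seed = 1L, tol = 1e-6, max_iter = 1000,
                    n_restart = 10) {
  n <- length(x)
  sd_floor <- max(stats::sd(x), .Machine$double.eps) * 1e-3
  run_em <- function(m1, m2) {
    w <- c(0.5, 0.5); mu <- c(m1, m2)
    s <- rep(max(stats::sd(x) / 2, sd_floor), 2)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * stats::dnorm(x, mu[1], s[1])
      d2 <- w[2] * stats::dnorm(x, mu[2], s[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      ll_trace <- c(ll_trace, ll)
      g2 <- d2 / tot
      g1 <- 1 - g2
      w <- c(mean(g1), mean(g2))
      mu <- c(sum(g1 * x) / sum(g1), sum(g2 * x) / sum(g2))
      s <- c(sqrt(sum(g1 * (x - mu[1])^2) / sum(g1)),
             sqrt(sum(g2 * (x - mu[2])^2) / sum(g2)))
      s <- pmax(s, sd_floor)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol)
        return(list(mu = mu, s = s, w = w, loglik = ll, n_iter = it,
                    converged = TRUE, ll_trace = ll_trace, resp2 = g2))
      ll_old <- ll
    }
    list(mu = mu, s = s, w = w, loglik = ll_old, n_iter = max_iter,
         converged = FALSE, ll_trace = ll_trace, resp2 = g2)
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restart)) {
      m1 <- x[sample.int(n, 1)]
      d2w <- (x - m1)^2
      m2 <- if (all(d2w == 0)) m1 else x[sample.int(n, 1, prob = d2w)]
      cand <- run_em(m1, m2)
      if (is.null(best) || cand$loglik > best$loglik) best <- cand
    }
    best
  })
}

#' Two-component Gaussian mixtures on perturbation probabilities
#'
#' Fits a k = 2 Gaussian mixture by EM to the perturbation probabilities of
#' each group (per sgRNA by default, per target gene optionally). The
#' higher-mean component is the "perturbed" one; its per-cell posterior
#' feeds [classify_unperturbed()]. Groups that are too small, constant, or
#' non-convergent are flagged and passed through unfiltered.
#'
#' @param prob tibble from [fit_perturbation_model()] (`barcode`,
#'   `sgrna_id`, `prob`; plus `target_gene` for `group_by = "target"`).
#' @param group_by `"sgrna"` (default) or `"target"`.
#' @param seed,tol,max_iter EM controls (10 restarts, best log-likelihood).
#' @param min_cells minimum group size to attempt a fit (default 10).
#' @return named list of `gmm2` fits, one per group: `means`, `sds`,
#'   `weights` (ordered by mean), `posterior` (named per-cell posterior of
#'   the higher-mean component), `converged`, `flagged`, `n_iter`,
#'   `loglik`, `loglik_trace`.
#' @export
fit_gmm2 <- function(prob, group_by = c("sgrna", "target"), seed = 1L,
                     tol = 1e-6, max_iter = 1000, min_cells = 10) {
  group_by <- match.arg(group_by)
  key <- if (group_by == "sgrna") "sgrna_id" else "target_gene"
  stopifnot(key %in% names(prob))
  groups <- split(prob, prob[[key]])
  fits <- lapply(groups, function(g) {
    x <- g$prob
    names(x) <- g$barcode
    if (length(x) < min_cells || stats::sd(x) == 0) {
      warning("gmm2: group '", g[[key]][1],
              "' degenerate or too small; passed through unfiltered",
              call. = FALSE)
      return(structure(list(
        means = rep(mean(x), 2), sds = c(0, 0), weights = c(0.5, 0.5),
        posterior = stats::setNames(rep(1, length(x)), names(x)),
        converged = FALSE, flagged = TRUE, n_iter = 0L, loglik = NA_real_,
        loglik_trace = numeric(0)), class = "gmm2"))
    }
    f <- em_gmm2(unname(x), seed = seed, tol = tol, max_iter = max_iter)
    ord <- order(f$mu)
    post_hi <- if (ord[2] == 2) f$resp2 else 1 - f$resp2
    if (!f$converged)
      warning("gmm2: group '", g[[key]][1],
              "' did not converge; passed through unfiltered", call. = FALSE)
    structure(list(
      means = f$mu[ord], sds = f$s[ord], weights = f$w[ord],
      posterior = stats::setNames(post_hi, names(x)),
      converged = f$converged, flagged = !f$converged,
      n_iter = f$n_iter, loglik = f$loglik, loglik_trace = f$ll_trace),
      class = "gmm2")
  })
  fits
}

#' @export
print.gmm2 <- function(x, ...) {
  cat(sprintf(
    "<gmm2> means %.3f/%.3f sds %.3f/%.3f weights %.2f/%.2f (%s)\n",
    x$means[1], x$means[2], x$sds[1], x$sds[2], x$weights[1], x$weights[2],
    if (x$converged) "converged" else "flagged"))
  invisible(x)
}

#' @method tidy gmm2
#' @export
tidy.gmm2 <- function(x, ...) {
  tibble::tibble(component = c("low", "high"), mean = x$means, sd = x$sds,
                 weight = x$weights)
}

#' @method glance gmm2
#' @export
glance.gmm2 <- function(x, ...) {
  tibble::tibble(converged = x$converged, flagged = x$flagged,
                 n_iter = x$n_iter, loglik = x$loglik,
                 n_cells = length(x$posterior))
}

#' Label unperturbed cells from the mixture posteriors
#'
#' A cell is unperturbed iff its posterior probability of belonging to the
#' higher-mean ("perturbed") component is strictly below `threshold`. Cells
#' of flagged (degenerate or non-convergent) fits are all labelled
#' perturbed, i.e. passed through.
#'
#' @param fits list from [fit_gmm2()].
#' @param threshold posterior cutoff (default 0.05, strict `<`).
#' @return tibble `barcode`, `group`, `posterior`, `label` ("perturbed" /
#'   "unperturbed").
#' @export
classify_unperturbed <- function(fits, threshold = 0.05) {
  purrr::imap_dfr(fits, function(f, grp) {
    tibble::tibble(
      barcode = names(f$posterior),
      group = grp,
      posterior = unname(f$posterior),
      label = unname(ifelse(!f$flagged & f$posterior < threshold,
                            "unperturbed", "perturbed"))
    )
  })
}
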