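#' Default hepatocyte marker panel
#'
#' Nine hepatocyte-specific marker genes used by the regulator score.
#' @export
hepatocyte_markers <- c("Alb", "Ttr", "Mup20", "Sult1a1", "Cyp3a13",
                        "Abcc3", "Tff3", "Trf", "Fga")

# run expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic CROP-seq screen
#'
#' The defaults emulate the pilot-screen design: 6 target genes with 3
#' guides each plus 4 non-targeting controls, low-MOI unique assignment,
#' negative-binomial counts with mild logistic dropout, regulon-driven
#' co-expression, and an editing-escape fraction that makes the perturbation
#' status of targeted cells bimodal.
#'
#' @param n_cells_per_guide cells per sgRNA (default 100).
#' @param n_genes size of the gene universe (default 300).
#' @param n_tfs number of disjoint regulons (default 10).
#' @param regulon_size inclusive size range for each regulon (default 8..12).
#' @param effects named list: one entry per target gene, each a named numeric
#'   vector of log2-scale shifts applied to regulon member genes (names are
#'   regulon TFs). Targets default to `Tgt1`..`Tgt6` with effects on the
#'   first six regulons (the first regulon carries the marker panel).
#' @param n_guides_per_target guides per target (default 3).
#' @param n_nt number of non-targeting control guides (default 4).
#' @param escape_rate fraction of guide-carrying cells whose target escapes
#'   editing and which therefore stay transcriptionally unperturbed
#'   (default 0.2).
#' @param nb_mean,nb_dispersion negative-binomial baseline mean and size
#'   (defaults 2 and 2).
#' @param dropout_midpoint logistic dropout midpoint on the log-mean scale;
#'   entry dropout probability is `plogis(dropout_midpoint - log(mu))`
#'   (default -3, i.e. mild extra dropout on top of NB zeros).
#' @param marker_names gene names grafted onto the first members of regulon 1
#'   so that the marker panel is regulon-linked (default
#'   [hepatocyte_markers]).
#' @param moi `NULL` for strict one-guide-per-cell; a positive rate (e.g.
#'   0.3) draws per-cell guide multiplicity from a zero-truncated Poisson to
#'   exercise the unique-sgRNA filter.
#' @param condition condition label stamped on all cells (default "DM").
#' @param seed integer seed; the simulator is byte-deterministic given the
#'   full configuration.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cells_per_guide = 100, n_genes = 300, n_tfs = 10,
                       regulon_size = c(8, 12), effects = NULL,
                       n_guides_per_target = 3, n_nt = 4,
                       escape_rate = 0.2, nb_mean = 2, nb_dispersion = 2,
                       dropout_midpoint = -3,
                       marker_names = hepatocyte_markers,
                       moi = NULL, condition = "DM", seed = 1L) {
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  if (is.null(effects)) {
    effects <- list(
      Tgt1 = c(TF01 = 1.5), Tgt2 = c(TF02 = -1), Tgt3 = c(TF03 = 1),
      Tgt4 = c(TF04 = -1), Tgt5 = c(TF05 = 1), Tgt6 = c(TF01 = -0.5)
    )
    effects <- lapply(effects, function(e) e[names(e) %in% tfs])
  }
  stopifnot(escape_rate >= 0, escape_rate <= 1, nb_mean > 0,
            nb_dispersion > 0, length(regulon_size) == 2,
            regulon_size[1] <= regulon_size[2])
  if (n_tfs * regulon_size[2] > n_genes)
    stop("regulons cannot be disjoint: n_tfs * max regulon size > n_genes",
         call. = FALSE)
  bad <- setdiff(unlist(lapply(effects, names)), tfs)
  if (length(bad))
    stop("effects refer to unknown regulons: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(
    n_cells_per_guide = n_cells_per_guide, n_genes = n_genes, n_tfs = n_tfs,
    regulon_size = regulon_size, effects = effects,
    n_guides_per_target = n_guides_per_target, n_nt = n_nt,
    escape_rate = escape_rate, nb_mean = nb_mean,
    nb_dispersion = nb_dispersion, dropout_midpoint = dropout_midpoint,
    marker_names = marker_names, moi = moi, condition = condition,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Draw disjoint synthetic regulons
#'
#' @param cfg a [sim_config()].
#' @return named list of character vectors (regulon member genes), one per
#'   synthetic TF; disjoint, deterministic under the config seed. The first
#'   members of the first regulon carry the marker panel names.
#' @export
simulate_regulons <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    size_choices <- seq(cfg$regulon_size[1], cfg$regulon_size[2])
    sizes <- if (length(size_choices) == 1) rep(size_choices, cfg$n_tfs)
             else sample(size_choices, cfg$n_tfs, replace = TRUE)
    pool <- sample(genes, sum(sizes))
    regs <- split(pool, rep(seq_len(cfg$n_tfs), times = sizes))
    names(regs) <- sprintf("TF%02d", seq_len(cfg$n_tfs))
    # graft marker names onto the head of the designated (first) regulon
    nm <- min(length(cfg$marker_names), length(regs[[1]]))
    if (nm > 0) regs[[1]][seq_len(nm)] <- cfg$marker_names[seq_len(nm)]
    regs
  })
}

#' Simulate a CROP-seq-like screen with full ground truth
#'
#' Baseline expression of every gene is negative binomial; cells truly
#' perturbed by target `t` have the member genes of each affected regulon
#' scaled by `2^effect` before logistic dropout. Non-targeting and
#' editing-escape cells draw from the baseline distribution exactly.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `screen` (a [screen_matrix()] with `condition`
#'   in the cell metadata), `library` (guide library tibble), `assignments`
#'   (barcode/sgrna_id tibble) and `truth` (list: `regulons`, `cell_status`
#'   tibble with `barcode`, `sgrna_id`, `target_gene`, `perturbed`,
#'   `true_effects` target x regulon matrix, `config`).
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  regulons <- simulate_regulons(cfg)
  targets <- names(cfg$effects)
  tfs <- names(regulons)
  genes <- unique(c(unlist(regulons, use.names = FALSE),
                    sprintf("g%04d", seq_len(cfg$n_genes))))
  genes <- genes[seq_len(cfg$n_genes)]

  lib <- guide_library(
    sgrna_id = c(unlist(lapply(targets, function(t)
      paste0(t, "_g", seq_len(cfg$n_guides_per_target)))),
      paste0("NT_g", seq_len(cfg$n_nt))),
    target_gene = c(rep(targets, each = cfg$n_guides_per_target),
                    rep(NA_character_, cfg$n_nt))
  )

  true_effects <- matrix(0, length(targets), length(tfs),
                         dimnames = list(targets, tfs))
  for (t in targets) true_effects[t, names(cfg$effects[[t]])] <- cfg$effects[[t]]

  with_seed(cfg$seed + 1L, {
    cell_guide <- rep(lib$sgrna_id, each = cfg$n_cells_per_guide)
    n_cells <- length(cell_guide)
    barcodes <- sprintf("cell%06d", seq_len(n_cells))
    is_nt <- lib$is_nt[match(cell_guide, lib$sgrna_id)]
    target_of <- lib$target_gene[match(cell_guide, lib$sgrna_id)]
    perturbed <- !is_nt & stats::runif(n_cells) >= cfg$escape_rate

    # per-cell mean profile class: baseline, or perturbed-by-target-t
    mu_base <- rep(cfg$nb_mean, cfg$n_genes)
    names(mu_base) <- genes
    counts <- matrix(0L, n_cells, cfg$n_genes,
                     dimnames = list(barcodes, genes))
    classes <- ifelse(perturbed, target_of, ".baseline")
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      mu <- mu_base
      if (cl != ".baseline") {
        eff <- true_effects[cl, ]
        for (tf in tfs[eff != 0]) {
          mem <- intersect(regulons[[tf]], genes)
          mu[mem] <- mu[mem] * 2^eff[tf]
        }
      }
      n <- length(idx)
      x <- matrix(stats::rnbinom(n * cfg$n_genes, mu = rep(mu, each = n),
                                 size = cfg$nb_dispersion), n, cfg$n_genes)
      p_drop <- stats::plogis(cfg$dropout_midpoint - log(mu))
      drop <- matrix(stats::runif(n * cfg$n_genes) <
                       rep(p_drop, each = n), n, cfg$n_genes)
      x[drop] <- 0L
      counts[idx, ] <- x
    }

    assignments <- tibble::tibble(barcode = barcodes, sgrna_id = cell_guide)
    if (!is.null(cfg$moi)) {
      extra_n <- pmax(stats::rpois(n_cells, cfg$moi), 0L)
      add <- rep(seq_len(n_cells), extra_n)
      if (length(add))
        assignments <- dplyr::bind_rows(assignments, tibble::tibble(
          barcode = barcodes[add],
          sgrna_id = sample(lib$sgrna_id, length(add), replace = TRUE)
        )) |> dplyr::arrange(.data$barcode)
    }

    scr <- screen_matrix(counts)
    scr$cells$condition <- cfg$condition

    list(
      screen = scr,
      library = lib,
      assignments = assignments,
      truth = list(
        regulons = regulons,
        cell_status = tibble::tibble(
          barcode = barcodes, sgrna_id = cell_guide,
          target_gene = target_of, perturbed = perturbed
        ),
        true_effects = true_effects,
        config = cfg
      )
    )
  })
}

#' Write a simulated screen to disk in the formats the readers consume
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv`, `guides.tsv`,
#' `assignments.tsv`, `regulons.gmt` and `truth.json` under `dir`.
#'
#' @param sim output of [simulate_screen()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # CellRanger orientation on disk: genes x cells
  Matrix::writeMM(Matrix::t(sim$screen$counts), file.path(dir, "matrix.mtx"))
  feats <- data.frame(id = sim$screen$genes, symbol = sim$screen$genes,
                      type = "Gene Expression")
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(sim$screen$cells$barcode, file.path(dir, "barcodes.tsv"))
  lib <- sim$library
  lib$target_gene[lib$is_nt] <- "NT"
  utils::write.table(lib, file.path(dir, "guides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$assignments, file.path(dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_regulons_gmt(sim$truth$regulons, file.path(dir, "regulons.gmt"))
  truth <- sim$truth
  jsonlite::write_json(
    list(cell_status = truth$cell_status,
         true_effects = as.data.frame(truth$true_effects),
         regulons = truth$regulons),
    file.path(dir, "truth.json")
  )
  invisible(dir)
}
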