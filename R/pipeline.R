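#' Pipeline configuration
#'
#' Collects the input paths and every tunable threshold of the end-to-end
#' run. Unknown keys are rejected so that a config file always matches what
#' the pipeline actually does; the config is serialized verbatim into the
#' output directory of every run.
#'
#' @param counts_mtx,features,barcodes paths of the sparse count matrix
#'   triplet.
#' @param guides,assignments,regulons paths of the guide library TSV, the
#'   per-cell assignment TSV, and the regulon GMT.
#' @param out_dir output directory.
#' @param seed integer seed routed to every stochastic stage.
#' @param condition condition label analyzed (default "DM").
#' @param min_genes,max_genes,max_mito,mito_prefix cell QC bounds.
#' @param min_total_umi,min_cell_frac gene filter thresholds.
#' @param top_frac activity-scoring top fraction.
#' @param min_cells minimum cells per sgRNA (default 40).
#' @param alpha significance threshold for regulation pairs and map edges.
#' @param k_perturbation,k_regulon module counts (defaults 4 and 5; capped
#'   at the available labels with a warning).
#' @param tail hypergeometric tail ("upper" or "pmf").
#' @param l1_ratio,n_hvg perturbation-probability model controls.
#' @param gmm_threshold posterior cutoff for unperturbed cells.
#' @param pseudocount fold-change pseudocount.
#' @param markers marker panel for the regulator score.
#' @param normalize_scale library-size scale factor.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(counts_mtx, features, barcodes, guides,
                            assignments, regulons, out_dir,
                            seed = 1L, condition = "DM",
                            min_genes = 200, max_genes = 6000,
                            max_mito = 0.10, mito_prefix = "mt-",
                            min_total_umi = 6, min_cell_frac = 0.01,
                            top_frac = 0.05, min_cells = 40, alpha = 0.05,
                            k_perturbation = 4, k_regulon = 5,
                            tail = "upper", l1_ratio = 0.5, n_hvg = 2000,
                            gmm_threshold = 0.05, pseudocount = 1e-2,
                            markers = hepatocyte_markers,
                            normalize_scale = 1e4) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline config from YAML (or JSON)
#' @param path YAML (or JSON) file whose keys match [pipeline_config()]
#'   arguments; unknown keys are an error.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- tryCatch(yaml::read_yaml(path),
                   error = function(e) jsonlite::read_json(path,
                                                           simplifyVector = TRUE))
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

cap_k <- function(k, n_labels, what) {
  if (n_labels < 2) stop("cannot cluster ", what, ": fewer than 2 labels",
                         call. = FALSE)
  if (k > n_labels) {
    warning("k for ", what, " capped at ", n_labels, call. = FALSE)
    k <- n_labels
  }
  max(2L, as.integer(k))
}

#' Run the full screen analysis pipeline
#'
#' Executes: cell QC, unique-sgRNA selection, gene filter, log
#' normalization, regulon activity scoring, minimum-cell filter, effect
#' matrix with Wilcoxon tests, regulation pairs, Spearman/k-means modules,
#' hypergeometric module map, perturbation-probability cell filtering, and
#' marker-based regulator scores. Every stage artifact is written as TSV
#' under the output directory, together with the verbatim config
#' (`config.yaml`), a log of defaults applied (`log.txt`), and MD5 checksums
#' of all artifacts (`checksums.tsv`). Runs are byte-deterministic given
#' config + seed.
#'
#' @param cfg a [pipeline_config()] (or path to a YAML config).
#' @return the output directory, invisibly; stage results are also returned
#'   as the attribute `"results"`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  note("stage qc: bounds genes (", cfg$min_genes, ", ", cfg$max_genes,
       "), mito < ", cfg$max_mito)
  m <- read_counts_mtx(cfg$counts_mtx, cfg$features, cfg$barcodes,
                       mito_prefix = cfg$mito_prefix)
  lib <- read_guide_library(cfg$guides)
  asg <- read_guide_assignments(cfg$assignments, lib)
  regs <- read_regulons_gmt(cfg$regulons)

  m <- qc_filter_cells(m, cfg$min_genes, cfg$max_genes, cfg$max_mito)
  m <- select_unique_sgrna_cells(m, asg, lib)
  if (!"condition" %in% names(m$cells)) m$cells$condition <- cfg$condition
  m <- filter_genes_for_activity(m, cfg$min_total_umi, cfg$min_cell_frac)
  m <- normalize_log(m, scale = cfg$normalize_scale)
  note("cells after QC/unique-guide: ", nrow(m$counts),
       "; genes after filter: ", ncol(m$counts))

  act <- score_aucell(m, regs, top_frac = cfg$top_frac)
  write_matrix_tsv(act, file.path(cfg$out_dir, "activity.tsv"), "barcode")

  groups <- filter_min_cells(target_groups(m), cfg$min_cells)
  if (!nrow(groups) || !any(!groups$is_nt))
    stop("pipeline stage 'effects': no groups survive the min-cell filter",
         call. = FALSE)
  eff <- compute_effect_matrix(act, groups, reference = "nt",
                               condition = cfg$condition)
  write_matrix_tsv(eff$effect, file.path(cfg$out_dir, "effects.tsv"), "target")
  write_matrix_tsv(eff$pvalue, file.path(cfg$out_dir, "effect_pvalues.tsv"),
                   "target")

  pairs <- test_regulations(eff, alpha = cfg$alpha)
  readr::write_tsv(pairs, file.path(cfg$out_dir, "regulation_pairs.tsv"))

  kp <- cap_k(cfg$k_perturbation, nrow(eff$effect), "perturbations")
  kr <- cap_k(cfg$k_regulon, ncol(eff$effect), "regulons")
  pm <- kmeans_modules(correlate_spearman(eff, "targets"), kp,
                       seed = cfg$seed)
  rm_ <- kmeans_modules(correlate_spearman(eff, "features"), kr,
                        seed = cfg$seed)
  readr::write_tsv(dplyr::bind_rows(
    dplyr::mutate(pm, axis = "perturbation"),
    dplyr::mutate(rm_, axis = "regulon")),
    file.path(cfg$out_dir, "modules.tsv"))

  edges <- build_module_map(pairs, pm, rm_, alpha = cfg$alpha,
                            tail = cfg$tail)
  export_edges(edges, file.path(cfg$out_dir, "module_map.tsv"), "tsv")

  fitp <- fit_perturbation_model(m, groups, n_hvg = cfg$n_hvg,
                                 l1_ratio = cfg$l1_ratio, seed = cfg$seed)
  prob <- dplyr::left_join(
    fitp$prob,
    dplyr::select(groups, "barcode", "target_gene", "is_nt"),
    by = "barcode")
  fits <- suppressWarnings(
    fit_gmm2(dplyr::filter(prob, !.data$is_nt), group_by = "sgrna",
             seed = cfg$seed))
  labels <- classify_unperturbed(fits, threshold = cfg$gmm_threshold)
  cell_table <- prob |>
    dplyr::left_join(dplyr::select(labels, "barcode", "posterior", "label"),
                     by = "barcode") |>
    dplyr::mutate(label = dplyr::coalesce(
      .data$label, ifelse(.data$is_nt, "nt_control", "perturbed")))
  readr::write_tsv(cell_table, file.path(cfg$out_dir, "cell_filter.tsv"))

  kept <- dplyr::filter(groups,
                        !.data$barcode %in%
                          labels$barcode[labels$label == "unperturbed"])
  fc <- compute_fold_changes(m, kept, markers = cfg$markers,
                             pseudocount = cfg$pseudocount)
  scores <- regulator_score(fc)
  readr::write_tsv(scores, file.path(cfg$out_dir, "regulator_scores.tsv"))

  cfg_out <- cfg
  cfg_out$markers <- as.list(cfg_out$markers)
  yaml::write_yaml(unclass(cfg_out), file.path(cfg$out_dir, "config.yaml"))
  writeLines(log_lines, file.path(cfg$out_dir, "log.txt"))

  artifacts <- sort(setdiff(list.files(cfg$out_dir), "checksums.tsv"))
  sums <- tools::md5sum(file.path(cfg$out_dir, artifacts))
  readr::write_tsv(tibble::tibble(file = artifacts, md5 = unname(sums)),
                   file.path(cfg$out_dir, "checksums.tsv"))

  res <- list(screen = m, activity = act, groups = groups, effects = eff,
              pairs = pairs, perturbation_modules = pm,
              regulon_modules = rm_, edges = edges, cell_table = cell_table,
              scores = scores)
  out <- cfg$out_dir
  attr(out, "results") <- res
  invisible(out)
}

write_matrix_tsv <- function(x, path, rowname_col) {
  df <- tibble::as_tibble(as.data.frame(x), rownames = rowname_col)
  readr::write_tsv(df, path)
}
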