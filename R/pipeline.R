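#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end flow: (optionally) simulate the three data
#' layers, call translational regulation from the fraction pools, fit the
#' proteome time course, and integrate (mRNA direction calls, discordance
#' classes, cross-level correlations, optional gene-set enrichment, and
#' Spearman-distance clustering of regulated genes). All result tables are
#' written as TSV under `outdir`, together with a plain-text run manifest
#' (configuration, seed, md5 checksum of every file) sufficient to
#' re-execute the run; identical inputs and seed give byte-identical
#' outputs. Stages whose input layer is absent are skipped with a log line.
#'
#' @param config A [sim_config()] used to simulate any layer not supplied
#'   in `datasets`.
#' @param outdir Output directory (created if needed).
#' @param datasets Optional named list overriding simulated layers:
#'   `pools`, `mrna`, `counts` (long tibbles as produced by the
#'   [read_matrix()] family). Set a layer to `NA` to skip its stage.
#' @param thresholds [calling_thresholds()] for the translation stage.
#' @param mode Curation mode for [call_translation()].
#' @param alpha,pseudocount Proteome-stage settings (see [fit_proteome()],
#'   [log2_trajectories()]).
#' @param fold_cutoff,min_timepoints mRNA-call settings (see
#'   [call_mrna_direction()]).
#' @param gene_sets Optional named list of gene sets for enrichment; the
#'   query is the set of genes regulated at any level.
#' @return Invisibly, a list with every intermediate and final table plus
#'   `manifest`, the manifest file path.
#' @examples
#' \donttest{
#' res <- run_pipeline(sim_config(n_genes = 60, seed = 1),
#'                     outdir = tempfile())
#' names(res)
#' }
#' @export
run_pipeline <- function(config = sim_config(),
                         outdir,
                         datasets = list(),
                         thresholds = calling_thresholds(),
                         mode = "lenient",
                         alpha = 0.05,
                         pseudocount = 0.5,
                         fold_cutoff = 1.5,
                         min_timepoints = 4,
                         gene_sets = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) inform(paste0("[polystress] ", sprintf(...)))
  res <- list(config = config)

  supplied <- function(nm) !is.null(datasets[[nm]]) &&
    !identical(datasets[[nm]], NA)
  skipped <- function(nm) identical(datasets[[nm]], NA)

  need_sim <- !all(c("pools", "mrna", "counts") %in% names(datasets))
  sim <- NULL
  if (need_sim) {
    log_line("simulating layers not supplied (seed %d)", config$seed)
    sim <- simulate_stress_study(config)
    res$truth <- sim$truth
    readr::write_tsv(sim$truth, file.path(outdir, "ground_truth.tsv"),
                     progress = FALSE)
    writeLines(yaml::as.yaml(unclass(config)),
               file.path(outdir, "config.yaml"))
  }
  layer <- function(nm) {
    if (supplied(nm)) datasets[[nm]] else if (skipped(nm)) NULL else sim[[nm]]
  }
  pools <- layer("pools"); mrna <- layer("mrna"); counts <- layer("counts")

  # translation stage
  trans_calls <- NULL
  if (!is.null(pools)) {
    write_matrix(pools, file.path(outdir, "fraction_pools.tsv"), "fractions")
    profiles <- normalize_profiles(pools)
    trans_calls <- call_translation(profiles, thresholds, mode = mode)
    readr::write_tsv(trans_calls, file.path(outdir, "translation_calls.tsv"),
                     progress = FALSE)
    log_line("translation: %d genes, %d (gene, time) calls != none",
             length(unique(trans_calls$gene_id)),
             sum(trans_calls$direction != "none"))
    res$profiles <- profiles
    res$translation_calls <- trans_calls
  } else log_line("translation stage skipped: no fraction pools")

  # proteome stage
  fits <- NULL
  if (!is.null(counts)) {
    if (!"unique_peptides" %in% names(counts)) counts$unique_peptides <- Inf
    write_matrix(counts, file.path(outdir, "spectrum_counts.tsv"), "counts")
    kept <- filter_detected(counts)
    ret <- attr(kept, "retained")
    log_line("proteome: %d of %d proteins pass detection filters",
             ret[["kept"]], ret[["total"]])
    if (ret[["kept"]] > 0) {
      cal <- calibrate_samples(kept)
      traj <- log2_trajectories(cal, pseudocount)
      fits <- fit_proteome(traj, alpha)
      readr::write_tsv(cal$scale_factors,
                       file.path(outdir, "calibration_factors.tsv"),
                       progress = FALSE)
      readr::write_tsv(fits, file.path(outdir, "temporal_fits.tsv"),
                       progress = FALSE)
      log_line("proteome: %d of %d proteins significant at alpha=%g",
               sum(fits$significant), nrow(fits), alpha)
      res$calibration <- cal
      res$trajectories <- traj
      res$temporal_fits <- fits
    }
  } else log_line("proteome stage skipped: no spectrum counts")

  # integrate stage
  if (!is.null(mrna)) {
    write_matrix(mrna, file.path(outdir, "mrna_ratios.tsv"), "mrna")
    mrna_calls <- call_mrna_direction(mrna, fold_cutoff, min_timepoints)
    readr::write_tsv(mrna_calls, file.path(outdir, "mrna_calls.tsv"),
                     progress = FALSE)
    log_line("mRNA: %d up, %d down of %d genes",
             sum(mrna_calls$direction == "up"),
             sum(mrna_calls$direction == "down"), nrow(mrna_calls))
    res$mrna_calls <- mrna_calls

    if (!is.null(trans_calls) && !is.null(fits)) {
      disc <- classify_discordance(mrna_calls, trans_calls, fits)
      readr::write_tsv(disc, file.path(outdir, "discordance.tsv"),
                       progress = FALSE)
      res$discordance <- disc
    }

    # cross-level correlations on per-gene summary changes
    mrna_max <- dplyr::summarise(
      dplyr::group_by(mrna, .data$gene_id),
      mrna_max_log2 = max_change(.data$log2_ratio), .groups = "drop")
    cors <- list()
    if (!is.null(trans_calls)) {
      tr <- dplyr::summarise(dplyr::group_by(trans_calls, .data$gene_id),
                             mean_log2_R = mean(log2(.data$R)),
                             .groups = "drop")
      j <- dplyr::inner_join(mrna_max, tr, by = "gene_id")
      cors$mrna_vs_translation <- correlate_changes(j$mrna_max_log2,
                                                    j$mean_log2_R)
    }
    if (!is.null(fits)) {
      pr <- tibble::tibble(gene_id = fits$protein_id,
                           protein_max_log2 = fits$fitted_max_change)
      j <- dplyr::inner_join(mrna_max, pr, by = "gene_id")
      if (nrow(j) >= 3) {
        cors$mrna_vs_protein <- correlate_changes(j$mrna_max_log2,
                                                  j$protein_max_log2)
      }
      if (!is.null(trans_calls)) {
        tr <- dplyr::summarise(dplyr::group_by(trans_calls, .data$gene_id),
                               mean_R = mean(.data$R), .groups = "drop")
        j2 <- dplyr::inner_join(dplyr::inner_join(mrna_max, tr, by = "gene_id"),
                                pr, by = "gene_id")
        if (nrow(j2) >= 3) {
          combined <- combine_mrna_translation(2^j2$mrna_max_log2, j2$mean_R)
          cors$combined_vs_protein <-
            correlate_changes(log2(combined), j2$protein_max_log2)
        }
      }
    }
    if (length(cors)) {
      cor_tbl <- dplyr::bind_rows(cors, .id = "comparison")
      readr::write_tsv(cor_tbl, file.path(outdir, "correlations.tsv"),
                       progress = FALSE)
      res$correlations <- cor_tbl
    }

    # enrichment of regulated genes
    if (!is.null(gene_sets)) {
      regulated <- unique(c(
        mrna_calls$gene_id[mrna_calls$direction != "none"],
        if (!is.null(trans_calls))
          trans_calls$gene_id[trans_calls$direction != "none"]))
      enr <- hypergeom_enrichment(regulated, gene_sets,
                                  universe = unique(mrna_calls$gene_id))
      readr::write_tsv(enr, file.path(outdir, "enrichment.tsv"),
                       progress = FALSE)
      res$enrichment <- enr
    }

    # cluster regulated genes on the wider mRNA experiment
    reg <- mrna_calls$gene_id[mrna_calls$direction != "none"]
    if (!is.null(trans_calls)) {
      reg <- unique(c(reg,
                      trans_calls$gene_id[trans_calls$direction != "none"]))
    }
    wide <- tidyr::pivot_wider(
      dplyr::filter(mrna, .data$gene_id %in% reg),
      id_cols = "gene_id",
      names_from = c("experiment", "time_min"),
      values_from = "log2_ratio")
    if (nrow(wide) >= 2 && ncol(wide) >= 3) {
      tree <- withCallingHandlers(
        cluster_genes(wide),
        warning = function(w) invokeRestart("muffleWarning"))
      write_tree_newick(tree, file.path(outdir, "regulated_genes.nwk"))
      res$tree <- tree
      log_line("clustered %d regulated genes", length(tree$leaf_order))
    }
  } else log_line("integrate stage skipped: no mRNA tables")

  # manifest
  files <- setdiff(list.files(outdir, full.names = TRUE),
                   file.path(outdir, "manifest.txt"))
  sums <- tools::md5sum(files)
  manifest <- c(
    "polystress run manifest",
    sprintf("seed: %d", config$seed),
    sprintf("mode: %s | alpha: %g | pseudocount: %g | fold_cutoff: %g | min_timepoints: %d",
            mode, alpha, pseudocount, fold_cutoff, as.integer(min_timepoints)),
    sprintf("thresholds: D>=%g, R>=%g, R<=%g, min_delta=%g",
            thresholds$D_cutoff, thresholds$R_cutoff, thresholds$down_cutoff,
            thresholds$min_fraction_delta),
    "files:",
    sprintf("  %s  %s", unname(sums), basename(names(sums))))
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  res$manifest <- file.path(outdir, "manifest.txt")
  invisible(res)
}
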