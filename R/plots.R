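#' Plot translation profiles for selected genes
#'
#' Line plot of the percentage of each gene's signal per pooled fraction,
#' coloured by condition/time with one line per replicate — the standard
#' way single-gene polysome shifts are displayed.
#'
#' @param profiles Normalized profiles from [normalize_profiles()].
#' @param genes Character vector of gene ids to show.
#' @return A ggplot object.
#' @examples
#' cfg <- sim_config(n_genes = 4, seed = 1)
#' profs <- normalize_profiles(simulate_fraction_pools(cfg)$pools)
#' plot_translation_profile(profs, genes = profs$gene_id[1])
#' @export
plot_translation_profile <- function(profiles, genes) {
  df <- dplyr::filter(profiles, .data$gene_id %in% genes)
  if (nrow(df) == 0L) abort("none of the requested genes have profiles")
  long <- tidyr::pivot_longer(df, dplyr::all_of(c("p1", "p2", "p3", "p4")),
                              names_to = "pool", values_to = "percent")
  long$pool <- as.integer(sub("^p", "", long$pool))
  long$sample <- ifelse(long$condition == "control", "control",
                        paste0("stress ", long$time_min, " min"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$pool, y = .data$percent,
                               colour = .data$sample,
                               group = interaction(.data$sample,
                                                   .data$replicate))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~gene_id) +
    ggplot2::labs(x = "pooled fraction (1 = sub-polysomal, 4 = heavy polysomes)",
                  y = "% of mRNA signal", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn call_translation Scatter of the two shift statistics with the
#'   calling cutoffs; points coloured by called direction.
#' @param object A `polystress_translation_calls` tibble.
#' @param ... Unused.
#' @method autoplot polystress_translation_calls
#' @export
autoplot.polystress_translation_calls <- function(object, ...) {
  th <- attr(object, "thresholds")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$D, y = log2(.data$R),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_vline(xintercept = th$D_cutoff, linetype = 2) +
    ggplot2::geom_hline(yintercept = log2(c(th$R_cutoff, th$down_cutoff)),
                        linetype = 3) +
    ggplot2::facet_wrap(~time_min, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(up = "#d55e00",
                                            down = "#0072b2",
                                            none = "grey70")) +
    ggplot2::labs(x = "sum of profile differences (D)",
                  y = "log2 translation ratio") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_proteome Temporal-category overview; with
#'   `trajectories` supplied, observed and fitted log2 trajectories of the
#'   significant proteins are drawn per category.
#' @param object A `polystress_temporal_fits` tibble.
#' @param trajectories Optional trajectory tibble from
#'   [log2_trajectories()].
#' @param ... Unused.
#' @method autoplot polystress_temporal_fits
#' @export
autoplot.polystress_temporal_fits <- function(object, trajectories = NULL,
                                              ...) {
  if (is.null(trajectories)) {
    cnt <- dplyr::count(tibble::as_tibble(object), .data$category)
    return(
      ggplot2::ggplot(cnt, ggplot2::aes(x = .data$category, y = .data$n)) +
        ggplot2::geom_col(fill = "#0072b2") +
        ggplot2::labs(x = NULL, y = "proteins") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                           hjust = 1)))
  }
  sig <- tibble::as_tibble(object)[object$significant, ]
  df <- dplyr::inner_join(trajectories,
                          sig[, c("protein_id", "category")],
                          by = "protein_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$log2_ratio,
                                   group = .data$protein_id)) +
    ggplot2::geom_line(alpha = 0.25, colour = "#0072b2") +
    ggplot2::facet_wrap(~category) +
    ggplot2::labs(x = "time after stress (min)",
                  y = "log2 ratio vs 0 min") +
    ggplot2::theme_minimal()
}

#' Plot discordance-class counts
#'
#' @param labels Output of [classify_discordance()].
#' @return A ggplot object.
#' @examples
#' labs <- tibble::tibble(gene_id = c("a", "b"), mrna = c("up", "none"),
#'                        translation = c("up", "none"),
#'                        protein = c("up", "up"),
#'                        class = c("concordant", "protein_up_mRNA_flat"),
#'                        incomplete = FALSE)
#' plot_discordance(labs)
#' @export
plot_discordance <- function(labels) {
  cnt <- dplyr::count(labels, .data$class)
  ggplot2::ggplot(cnt, ggplot2::aes(x = stats::reorder(.data$class, .data$n),
                                    y = .data$n)) +
    ggplot2::geom_col(fill = "#d55e00") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' @method glance polystress_translation_calls
#' @export
glance.polystress_translation_calls <- function(x, ...) {
  tibble::tibble(
    n_calls = nrow(x),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    n_candidates = sum(x$passed_D | x$passed_R),
    mode = attr(x, "mode"))
}
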