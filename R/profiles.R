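#' Convert raw four-pool abundances to profile percentages
#'
#' A translation profile is the percentage of a gene's total signal found in
#' each of the four pooled gradient fractions, so every valid profile sums
#' to 100. Defined only when all four pools carry data: vectors with a
#' missing or negative pool, or with zero total signal, are rejected.
#'
#' @param x Numeric vector of 4 nonnegative pool abundances.
#' @return Numeric vector of 4 percentages summing to 100.
#' @examples
#' profile_percentages(c(1, 1, 1, 1))
#' profile_percentages(c(2, 3, 5, 10))
#' @export
profile_percentages <- function(x) {
  if (length(x) != 4L) abort("a translation profile needs exactly 4 pools")
  if (anyNA(x)) abort("missing pool value: profile undefined")
  if (any(x < 0)) abort("negative pool value: profile undefined")
  s <- sum(x)
  if (s <= 0) abort("all-zero pools: profile undefined")
  100 * x / s
}

#' Normalize a pool table to translation profiles
#'
#' Applies [profile_percentages()] gene-wise to a long pool table. Genes
#' lacking any pool in a sample, or with nonpositive total signal there, are
#' excluded from that sample (never imputed); exclusions are reported via a
#' warning and the `"excluded"` attribute.
#'
#' @param pools Long tibble with columns `gene_id`, `condition`, `time_min`,
#'   `replicate`, `pool` (1-4) and `abundance` (as produced by
#'   [simulate_fraction_pools()] or [read_matrix()] on a fractions file).
#' @return Wide tibble: `gene_id`, `condition`, `time_min`, `replicate`,
#'   `p1`..`p4` (percentages summing to 100).
#' @examples
#' cfg <- sim_config(n_genes = 5, noise_sd_log = 0, seed = 1)
#' profiles <- normalize_profiles(simulate_fraction_pools(cfg)$pools)
#' rowSums(profiles[, c("p1", "p2", "p3", "p4")])
#' @export
normalize_profiles <- function(pools) {
  need <- c("gene_id", "condition", "time_min", "replicate", "pool",
            "abundance")
  if (!all(need %in% names(pools))) {
    abort(paste("`pools` must have columns:", paste(need, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(pools, names_from = "pool",
                             values_from = "abundance", names_prefix = "p")
  if (!all(c("p1", "p2", "p3", "p4") %in% names(wide))) {
    abort("`pools` must contain pools 1 to 4")
  }
  pm <- as.matrix(wide[, c("p1", "p2", "p3", "p4")])
  tot <- rowSums(pm)
  bad <- apply(pm, 1L, anyNA) | apply(pm, 1L, function(r) any(r < 0, na.rm = TRUE)) |
    is.na(tot) | tot <= 0
  if (any(bad)) {
    warn(sprintf("%d profile(s) excluded (missing, negative or all-zero pools)",
                 sum(bad)))
  }
  out <- wide[!bad, , drop = FALSE]
  pm <- pm[!bad, , drop = FALSE]
  out[, c("p1", "p2", "p3", "p4")] <- as.data.frame(100 * pm / rowSums(pm))
  attr(out, "excluded") <- wide[bad, c("gene_id", "condition", "time_min",
                                       "replicate")]
  out
}

#' Sum of absolute profile differences
#'
#' The total difference D between a stress and a control translation
#' profile: the sum over the four pools of the absolute percentage
#' differences. D is 0 for identical profiles and at most 200 (all mass in
#' disjoint pools). A small D reflects similar translational efficiency in
#' stressed and unstressed cells; a large D reflects a profile change.
#'
#' @param stress,control Numeric vectors of 4 percentages (each summing
#'   to 100).
#' @return The total difference, in percentage points.
#' @examples
#' sum_of_differences(c(30, 30, 20, 20), c(20, 20, 30, 30))
#' @export
sum_of_differences <- function(stress, control) {
  check_profile(stress); check_profile(control)
  sum(abs(stress - control))
}

check_profile <- function(p) {
  if (length(p) != 4L || anyNA(p) || any(p < 0) ||
      abs(sum(p) - 100) > 1e-6) {
    abort("not a valid translation profile (4 nonnegative percentages summing to 100)")
  }
  invisible(p)
}

#' Weighted translation score
#'
#' Multiplies the percentage in each fraction by an increasing weight
#' (default 0.1, 0.2, 0.3, 0.4 for fractions 1 to 4) and sums, giving more
#' weight to mRNAs sitting in fractions with more ribosomes. With the
#' default weights scores range from 10 (all mass sub-polysomal) to 40 (all
#' mass in the heaviest fraction).
#'
#' @param p Numeric vector of 4 percentages summing to 100.
#' @param weights Strictly increasing positive weights, one per fraction.
#' @return The score S.
#' @examples
#' weighted_score(c(25, 25, 25, 25))
#' weighted_score(c(0, 0, 0, 100))
#' @export
weighted_score <- function(p, weights = c(0.1, 0.2, 0.3, 0.4)) {
  check_profile(p)
  if (length(weights) != 4L || any(weights <= 0) || any(diff(weights) <= 0)) {
    abort("`weights` must be 4 positive, strictly increasing factors")
  }
  sum(weights * p)
}

#' Translation ratio
#'
#' Ratio of the weighted score under stress to the weighted score in the
#' matched control. A ratio above 1 reflects translational up-regulation
#' (mass moved into heavier fractions), below 1 down-regulation.
#'
#' @param s_stress,s_control Weighted scores of the same gene in stress and
#'   control.
#' @return The translation ratio R.
#' @examples
#' translation_ratio(23, 20)
#' @export
translation_ratio <- function(s_stress, s_control) {
  if (any(s_control <= 0)) abort("`s_control` must be > 0")
  s_stress / s_control
}

#' Compare stress and control profiles per replicate pair
#'
#' Pairs each stress profile with its round's control (stress replicate r
#' against control replicate r, reflecting one separate control per
#' profiling round). If the control and stress replicate sets differ, every
#' stress x control pair is used instead (documented fallback). For each
#' gene, stress time and pair it computes the sum of differences D, the
#' weighted scores and the translation ratio R. Genes missing a valid
#' profile on either side of a pair are dropped for that pair.
#'
#' @param profiles Normalized profile tibble from [normalize_profiles()].
#' @param weights Fraction weights, see [weighted_score()].
#' @return Tibble: `gene_id`, `time_min`, `control_replicate`,
#'   `stress_replicate`, `D`, `S_control`, `S_stress`, `R`.
#' @examples
#' cfg <- sim_config(n_genes = 5, seed = 1)
#' comps <- compare_profiles(normalize_profiles(simulate_fraction_pools(cfg)$pools))
#' head(comps)
#' @export
compare_profiles <- function(profiles, weights = c(0.1, 0.2, 0.3, 0.4)) {
  ctrl <- dplyr::filter(profiles, .data$condition == "control")
  strs <- dplyr::filter(profiles, .data$condition != "control")
  if (nrow(ctrl) == 0L) abort("no control profiles found")
  if (nrow(strs) == 0L) abort("no stress profiles found")

  paired <- setequal(unique(ctrl$replicate), unique(strs$replicate))
  if (paired) {
    joined <- dplyr::inner_join(
      strs, ctrl,
      by = c("gene_id", "replicate"), suffix = c("_s", "_c"),
      relationship = "many-to-many")
    joined$control_replicate <- joined$replicate
    joined$stress_replicate <- joined$replicate
  } else {
    joined <- dplyr::inner_join(
      strs, ctrl,
      by = "gene_id", suffix = c("_s", "_c"),
      relationship = "many-to-many")
    joined$control_replicate <- joined$replicate_c
    joined$stress_replicate <- joined$replicate_s
  }

  ps <- as.matrix(joined[, c("p1_s", "p2_s", "p3_s", "p4_s")])
  pc <- as.matrix(joined[, c("p1_c", "p2_c", "p3_c", "p4_c")])
  D <- rowSums(abs(ps - pc))
  S_s <- as.vector(ps %*% weights)
  S_c <- as.vector(pc %*% weights)
  tibble::tibble(gene_id = joined$gene_id,
                 time_min = joined$time_min_s,
                 control_replicate = joined$control_replicate,
                 stress_replicate = joined$stress_replicate,
                 D = D, S_control = S_c, S_stress = S_s,
                 R = S_s / S_c)
}

#' Average shift statistics over replicate pairs
#'
#' The sum of differences and the translation ratio are averaged separately
#' across the replicate pairs of each gene and stress time, recording how
#' many pairs contributed.
#'
#' @param comparisons Output of [compare_profiles()].
#' @return Tibble: `gene_id`, `time_min`, `D`, `R`, `n_pairs`.
#' @examples
#' average_replicates(tibble::tibble(
#'   gene_id = "g1", time_min = 15, control_replicate = 1:2,
#'   stress_replicate = 1:2, D = c(20, 40), S_control = 25, S_stress = 25,
#'   R = c(1.0, 1.3)))
#' @export
average_replicates <- function(comparisons) {
  if (nrow(comparisons) == 0L) abort("no replicate comparisons to average")
  dplyr::summarise(
    dplyr::group_by(comparisons, .data$gene_id, .data$time_min),
    D = mean(.data$D), R = mean(.data$R),
    S_control = mean(.data$S_control), S_stress = mean(.data$S_stress),
    n_pairs = dplyr::n(), .groups = "drop")
}

#' Call translationally regulated genes
#'
#' Implements the two automated criteria plus the codified curation rule.
#' A gene is a candidate at a stress time if its replicate-averaged D meets
#' `D_cutoff` or its replicate-averaged R meets the up (`R_cutoff`) or down
#' (`down_cutoff`) ratio cutoff — the union of the two approaches, with
#' inclusive comparisons. A direction is then assigned only if the curation
#' rule holds on the replicate-mean profiles: translational down-regulation
#' requires an increase of the gene in fractions 1-2 together with a
#' concomitant decrease in fractions 3-4 (by more than `min_fraction_delta`
#' points each), up-regulation the inverse trend. `replicate_consistent`
#' records whether every replicate pair individually shows the same sign
#' pattern; in `"strict"` mode a direction is only kept when it does.
#'
#' @param profiles Normalized profiles from [normalize_profiles()].
#' @param thresholds A [calling_thresholds()] object.
#' @param mode `"lenient"` (direction from replicate-mean profiles) or
#'   `"strict"` (additionally require per-replicate consistency).
#' @param weights Fraction weights, see [weighted_score()].
#' @return Tibble with one row per gene and stress time: averaged `D`, `R`,
#'   `S_control`, `S_stress`, `n_pairs`, flags `passed_D`, `passed_R`,
#'   `passed_curation`, `replicate_consistent`, and `direction`
#'   (up/down/none).
#' @examples
#' cfg <- sim_config(n_genes = 40, seed = 5)
#' profiles <- normalize_profiles(simulate_fraction_pools(cfg)$pools)
#' calls <- call_translation(profiles)
#' dplyr::count(calls, direction)
#' @export
call_translation <- function(profiles, thresholds = calling_thresholds(),
                             mode = c("lenient", "strict"),
                             weights = c(0.1, 0.2, 0.3, 0.4)) {
  mode <- match.arg(mode)
  stopifnot(inherits(thresholds, "polystress_thresholds"))
  comps <- compare_profiles(profiles, weights)
  avg <- average_replicates(comps)

  ctrl <- dplyr::filter(profiles, .data$condition == "control")
  strs <- dplyr::filter(profiles, .data$condition != "control")
  mean_prof <- function(df, by) {
    dplyr::summarise(dplyr::group_by(df, !!!rlang::syms(by)),
                     dplyr::across(dplyr::all_of(c("p1", "p2", "p3", "p4")),
                                   mean),
                     .groups = "drop")
  }
  mc <- mean_prof(ctrl, "gene_id")
  ms <- mean_prof(strs, c("gene_id", "time_min"))
  mm <- dplyr::inner_join(ms, mc, by = "gene_id", suffix = c("_s", "_c"))
  delta <- thresholds$min_fraction_delta
  d_low <- (mm$p1_s + mm$p2_s) - (mm$p1_c + mm$p2_c)
  d_high <- (mm$p3_s + mm$p4_s) - (mm$p3_c + mm$p4_c)
  mm$curated_direction <- dplyr::case_when(
    d_low > delta & d_high < -delta ~ "down",
    d_low < -delta & d_high > delta ~ "up",
    TRUE ~ "none")

  # per-pair sign pattern, for the replicate-consistency flag
  if (setequal(unique(ctrl$replicate), unique(strs$replicate))) {
    pairs <- dplyr::inner_join(strs, ctrl, by = c("gene_id", "replicate"),
                               suffix = c("_s", "_c"),
                               relationship = "many-to-many")
  } else {
    pairs <- dplyr::inner_join(strs, ctrl, by = "gene_id",
                               suffix = c("_s", "_c"),
                               relationship = "many-to-many")
  }
  pl <- (pairs$p1_s + pairs$p2_s) - (pairs$p1_c + pairs$p2_c)
  ph <- (pairs$p3_s + pairs$p4_s) - (pairs$p3_c + pairs$p4_c)
  pairs$pair_dir <- dplyr::case_when(
    pl > delta & ph < -delta ~ "down",
    pl < -delta & ph > delta ~ "up",
    TRUE ~ "none")
  consist <- dplyr::summarise(
    dplyr::group_by(pairs, .data$gene_id, time_min = .data$time_min_s),
    all_down = all(.data$pair_dir == "down"),
    all_up = all(.data$pair_dir == "up"), .groups = "drop")

  out <- dplyr::left_join(avg,
                          mm[, c("gene_id", "time_min", "curated_direction")],
                          by = c("gene_id", "time_min"))
  out <- dplyr::left_join(out, consist, by = c("gene_id", "time_min"))
  out$passed_D <- out$D >= thresholds$D_cutoff
  out$passed_R <- out$R >= thresholds$R_cutoff |
    out$R <= thresholds$down_cutoff
  candidate <- out$passed_D | out$passed_R
  out$passed_curation <- out$curated_direction != "none"
  out$replicate_consistent <- (out$curated_direction == "down" & out$all_down) |
    (out$curated_direction == "up" & out$all_up)
  keep <- candidate & out$passed_curation
  if (mode == "strict") keep <- keep & out$replicate_consistent
  out$direction <- ifelse(keep, out$curated_direction, "none")
  out <- dplyr::select(out, -"all_down", -"all_up", -"curated_direction")
  class(out) <- c("polystress_translation_calls", class(out))
  attr(out, "thresholds") <- thresholds
  attr(out, "mode") <- mode
  out
}
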