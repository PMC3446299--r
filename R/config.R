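#' Simulation configuration for the synthetic stress study
#'
#' Builds and validates the configuration object consumed by
#' [simulate_fraction_pools()], [simulate_mrna_table()] and
#' [simulate_spectrum_counts()]. Defaults describe a fission-yeast-style
#' oxidative-stress study: four polysome pools with paired control/stress
#' rounds at 15 and 60 minutes, two mRNA expression experiments, and a
#' duplicated six-time-point spectrum-count proteome time course
#' (2 replicates x 6 times = 12 samples).
#'
#' @param n_genes Number of genes (= proteins) in the simulated universe.
#' @param n_replicates_control,n_replicates_stress Biological repeats for the
#'   polysome fractionation; each stress round has its own matched control,
#'   so the two usually agree.
#' @param stress_timepoints_min Stress exposure times (minutes) profiled on
#'   the translation layer.
#' @param proteome_timepoints_min Time grid (minutes) of the proteome time
#'   course; must include 0 (the untreated reference).
#' @param n_replicates_proteome Repeats of the proteome time course.
#' @param fraction_count Number of pooled gradient fractions; the analysis is
#'   defined for four pools.
#' @param planted Named numeric vector of planted-effect proportions. Names
#'   among `translation_up`, `translation_down`, `mrna_up`, `mrna_down`,
#'   `protein_linear_up`, `protein_linear_down`, `protein_convex`,
#'   `protein_concave`. Proportions within one layer must sum to <= 1.
#' @param effect_size_shift Percentage points of profile mass moved between
#'   the sub-polysomal (pools 1-2) and polysomal (pools 3-4) halves for
#'   planted translational regulation.
#' @param mrna_log2_effect Mean peak log2 change planted for mRNA-regulated
#'   genes.
#' @param mrna_effect_cv Coefficient of variation of the per-gene lognormal
#'   multiplier on `mrna_log2_effect` (0 = all planted genes share the same
#'   effect size).
#' @param count_depth Expected spectrum count per protein per sample at
#'   baseline (before the lognormal abundance spread).
#' @param baseline_sdlog Log-sd of the per-protein baseline abundance spread.
#' @param protein_log2_span Total log2 change over the time course for planted
#'   linear proteins.
#' @param protein_quad_amplitude Peak absolute log2 deviation for planted
#'   quadratic (convex/concave) proteins.
#' @param scale_factor_sdlog Log-sd of the per-sample true scale factors the
#'   calibration step has to recover (0 = all factors 1).
#' @param dropout_fraction Proportion of proteins zeroed out in at least one
#'   sample, to exercise the detected-in-all-samples filter.
#' @param noise_sd_log Standard deviation of the multiplicative log-normal
#'   noise on polysome-pool and mRNA array ratios.
#' @param protein_model `"planted"` gives proteins their own planted temporal
#'   categories; `"mrna_coupled"` derives protein trajectories from each
#'   gene's mRNA fold change through a first-order synthesis-degradation
#'   response (see [simulate_spectrum_counts()]).
#' @param protein_halflife_min Protein half-life (minutes) used by the
#'   coupled model for up-regulated genes; down-regulated genes are treated
#'   as effectively stable (infinite half-life), decoupling protein loss from
#'   mRNA loss.
#' @param concordant_layers If `TRUE` (default) planted up (resp. down)
#'   labels occupy the same gene blocks across layers, so regulation is
#'   concordant by construction; if `FALSE` labels are assigned independently
#'   at random per layer.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A list of class `polystress_config`.
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 1)
#' cfg$planted
#' @export
sim_config <- function(n_genes = 2000,
                       n_replicates_control = 3,
                       n_replicates_stress = 3,
                       stress_timepoints_min = c(15, 60),
                       proteome_timepoints_min = c(0, 15, 30, 60, 120, 180),
                       n_replicates_proteome = 2,
                       fraction_count = 4,
                       planted = c(translation_up = 0.05,
                                   translation_down = 0.05,
                                   mrna_up = 0.05,
                                   mrna_down = 0.05,
                                   protein_linear_up = 0.025,
                                   protein_linear_down = 0.025,
                                   protein_convex = 0.025,
                                   protein_concave = 0.025),
                       effect_size_shift = 30,
                       mrna_log2_effect = 1,
                       mrna_effect_cv = 0,
                       count_depth = 200,
                       baseline_sdlog = 0.5,
                       protein_log2_span = 1,
                       protein_quad_amplitude = 0.75,
                       scale_factor_sdlog = 0.15,
                       dropout_fraction = 0,
                       noise_sd_log = 0.1,
                       protein_model = c("planted", "mrna_coupled"),
                       protein_halflife_min = 180,
                       concordant_layers = TRUE,
                       seed = 1L) {
  protein_model <- match.arg(protein_model)

  known <- c("translation_up", "translation_down", "mrna_up", "mrna_down",
             "protein_linear_up", "protein_linear_down",
             "protein_convex", "protein_concave")
  full <- setNames(numeric(length(known)), known)
  if (length(planted)) {
    if (is.null(names(planted)) || !all(names(planted) %in% known)) {
      abort(paste0("`planted` names must be among: ",
                   paste(known, collapse = ", ")))
    }
    full[names(planted)] <- planted
  }
  planted <- full

  if (any(planted < 0) || any(planted > 1)) {
    abort("planted proportions must lie in [0, 1]")
  }
  layer_sums <- c(
    translation = planted[["translation_up"]] + planted[["translation_down"]],
    mrna = planted[["mrna_up"]] + planted[["mrna_down"]],
    protein = sum(planted[c("protein_linear_up", "protein_linear_down",
                            "protein_convex", "protein_concave")])
  )
  if (any(layer_sums > 1 + 1e-12)) {
    abort("planted proportions must sum to <= 1 within each layer")
  }
  if (!is.numeric(effect_size_shift) || effect_size_shift <= 0 ||
      effect_size_shift >= 100) {
    abort("`effect_size_shift` must lie in (0, 100) percentage points")
  }
  if (count_depth <= 0) abort("`count_depth` must be > 0")
  if (noise_sd_log < 0) abort("`noise_sd_log` must be >= 0")
  if (dropout_fraction < 0 || dropout_fraction >= 1) {
    abort("`dropout_fraction` must lie in [0, 1)")
  }
  if (fraction_count != 4L) {
    abort("the translation-profile analysis is defined for 4 pooled fractions")
  }
  if (n_genes < 0) abort("`n_genes` must be >= 0")
  if (!0 %in% proteome_timepoints_min) {
    abort("`proteome_timepoints_min` must include the untreated reference 0")
  }
  if (n_replicates_control < 1 || n_replicates_stress < 1 ||
      n_replicates_proteome < 1) {
    abort("replicate counts must be >= 1")
  }

  structure(
    list(n_genes = as.integer(n_genes),
         n_replicates_control = as.integer(n_replicates_control),
         n_replicates_stress = as.integer(n_replicates_stress),
         stress_timepoints_min = sort(unique(stress_timepoints_min)),
         proteome_timepoints_min = sort(unique(proteome_timepoints_min)),
         n_replicates_proteome = as.integer(n_replicates_proteome),
         fraction_count = 4L,
         planted = planted,
         effect_size_shift = effect_size_shift,
         mrna_log2_effect = mrna_log2_effect,
         mrna_effect_cv = mrna_effect_cv,
         count_depth = count_depth,
         baseline_sdlog = baseline_sdlog,
         protein_log2_span = protein_log2_span,
         protein_quad_amplitude = protein_quad_amplitude,
         scale_factor_sdlog = scale_factor_sdlog,
         dropout_fraction = dropout_fraction,
         noise_sd_log = noise_sd_log,
         protein_model = protein_model,
         protein_halflife_min = protein_halflife_min,
         concordant_layers = isTRUE(concordant_layers),
         seed = as.integer(seed)),
    class = "polystress_config"
  )
}

#' @export
print.polystress_config <- function(x, ...) {
  cat("<polystress_config>\n")
  cat("  genes:", x$n_genes,
      "| fraction replicates:", x$n_replicates_stress,
      "| proteome samples:",
      length(x$proteome_timepoints_min) * x$n_replicates_proteome, "\n")
  cat("  stress times (min):", paste(x$stress_timepoints_min, collapse = ", "),
      "| proteome grid:", paste(x$proteome_timepoints_min, collapse = ", "),
      "\n")
  planted <- x$planted[x$planted > 0]
  if (length(planted)) {
    cat("  planted:", paste(sprintf("%s=%g", names(planted), planted),
                            collapse = ", "), "\n")
  } else {
    cat("  planted: none (all null)\n")
  }
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Thresholds for calling translational regulation
#'
#' The two automated criteria use a cutoff of 30 on the sum of profile
#' differences and 1.15 on the translation ratio; genes passing either are
#' candidates. The down-side ratio cutoff is applied reciprocally
#' (R <= 1/`R_cutoff`) by default. `min_fraction_delta` is the minimum
#' co-directional shift (percentage points) between the pooled low (1-2) and
#' high (3-4) fraction halves demanded by the codified curation rule.
#'
#' @param D_cutoff Cutoff on the replicate-averaged sum of differences.
#' @param R_cutoff Cutoff on the replicate-averaged translation ratio
#'   (> 1; applied as R >= `R_cutoff` for up, R <= `down_cutoff` for down).
#' @param down_cutoff Down-side ratio cutoff; default the reciprocal
#'   `1 / R_cutoff`.
#' @param min_fraction_delta Minimum shift (percentage points) per pooled
#'   half required by the curation direction rule.
#' @return A list of class `polystress_thresholds`.
#' @examples
#' calling_thresholds()
#' calling_thresholds(down_cutoff = 0.85) # fixed rather than reciprocal
#' @export
calling_thresholds <- function(D_cutoff = 30, R_cutoff = 1.15,
                               down_cutoff = 1 / R_cutoff,
                               min_fraction_delta = 0) {
  if (D_cutoff <= 0) abort("`D_cutoff` must be > 0")
  if (R_cutoff <= 1) abort("`R_cutoff` must be > 1")
  if (down_cutoff >= 1 || down_cutoff <= 0) {
    abort("`down_cutoff` must lie in (0, 1)")
  }
  if (min_fraction_delta < 0) abort("`min_fraction_delta` must be >= 0")
  structure(list(D_cutoff = D_cutoff, R_cutoff = R_cutoff,
                 down_cutoff = down_cutoff,
                 min_fraction_delta = min_fraction_delta),
            class = "polystress_thresholds")
}

#' @export
print.polystress_thresholds <- function(x, ...) {
  cat(sprintf(
    "<polystress_thresholds> D >= %g | R >= %g (up) | R <= %g (down) | min half-shift %g\n",
    x$D_cutoff, x$R_cutoff, x$down_cutoff, x$min_fraction_delta))
  invisible(x)
}
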