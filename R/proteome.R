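#' Filter proteins by detection criteria
#'
#' Keeps proteins identified with at least `min_unique_peptides` unique
#' peptides in at least one sample and, when `require_all_samples` is set,
#' detected (count > 0) in every sample — the subset used for quantitative
#' comparison. Reports retained/total counts.
#'
#' @param counts Long count tibble: `protein_id`, `time_min`, `replicate`,
#'   `count`, `unique_peptides`.
#' @param min_unique_peptides Minimum unique peptides in at least one
#'   sample.
#' @param require_all_samples Require a nonzero count in every sample.
#' @return The filtered tibble, with attribute `"retained"` =
#'   `c(kept, total)`.
#' @examples
#' sim <- simulate_spectrum_counts(sim_config(n_genes = 30, seed = 1,
#'                                            dropout_fraction = 0.2))
#' kept <- filter_detected(sim$counts)
#' attr(kept, "retained")
#' @export
filter_detected <- function(counts, min_unique_peptides = 2,
                            require_all_samples = TRUE) {
  if (nrow(counts) == 0L) {
    warn("empty count matrix: nothing to filter")
    attr(counts, "retained") <- c(kept = 0L, total = 0L)
    return(counts)
  }
  per <- dplyr::summarise(
    dplyr::group_by(counts, .data$protein_id),
    max_upep = max(.data$unique_peptides),
    all_detected = all(.data$count > 0), .groups = "drop")
  keep <- per$max_upep >= min_unique_peptides &
    (!require_all_samples | per$all_detected)
  kept_ids <- per$protein_id[keep]
  out <- dplyr::filter(counts, .data$protein_id %in% kept_ids)
  inform(sprintf("retained %d of %d proteins", length(kept_ids), nrow(per)))
  attr(out, "retained") <- c(kept = length(kept_ids), total = nrow(per))
  out
}

#' Calibrate samples against the average-count control
#'
#' A control profile is formed by averaging each protein's spectrum count
#' over all samples. Every sample is then compared with this control in a
#' linear least-squares fit through the origin, whose slope
#' `a_s = sum(x_is * control_i) / sum(x_is^2)` is the calibration (gain)
#' factor applied to that sample's counts. An intercept can be included but
#' calibration is a pure rescaling by default.
#'
#' @param counts Filtered long count tibble (see [filter_detected()]).
#' @param intercept Include an intercept in the fit (default `FALSE`).
#' @param control Optional per-protein reference tibble (`protein_id`,
#'   `control`); by default the mean count of each protein over all
#'   samples.
#' @return A list of class `polystress_calibration`: `calibrated` (the
#'   input with a `calibrated` column), `scale_factors` (per-sample tibble
#'   with `a`), `control` (per-protein control means).
#' @examples
#' sim <- simulate_spectrum_counts(sim_config(n_genes = 40, seed = 2))
#' cal <- calibrate_samples(sim$counts)
#' cal$scale_factors
#' @export
calibrate_samples <- function(counts, intercept = FALSE, control = NULL) {
  if (nrow(counts) == 0L) abort("empty count matrix: cannot calibrate")
  if (is.null(control)) {
    control <- dplyr::summarise(dplyr::group_by(counts, .data$protein_id),
                                control = mean(.data$count),
                                .groups = "drop")
  } else if (!all(c("protein_id", "control") %in% names(control))) {
    abort("`control` needs columns protein_id and control")
  }
  x <- dplyr::left_join(counts, control, by = "protein_id")
  fit_one <- function(df) {
    if (all(df$count == 0)) {
      abort("all-zero sample column: calibration factor undefined")
    }
    if (intercept) {
      cf <- stats::coef(stats::lm(control ~ count, data = df))
      tibble::tibble(a = cf[[2]], b = cf[[1]])
    } else {
      tibble::tibble(a = sum(df$count * df$control) / sum(df$count^2), b = 0)
    }
  }
  sf <- dplyr::reframe(dplyr::group_by(x, .data$time_min, .data$replicate),
                       fit_one(dplyr::pick(dplyr::everything())))
  out <- dplyr::left_join(x, sf, by = c("time_min", "replicate"))
  out$calibrated <- out$a * out$count + out$b
  out <- dplyr::select(out, -"a", -"b", -"control")
  structure(list(calibrated = out,
                 scale_factors = sf,
                 control = control),
            class = "polystress_calibration")
}

#' @export
print.polystress_calibration <- function(x, ...) {
  cat("<polystress_calibration>",
      nrow(x$control), "proteins,",
      nrow(x$scale_factors), "samples\n")
  print(x$scale_factors, n = 6)
  invisible(x)
}

#' @method tidy polystress_calibration
#' @export
tidy.polystress_calibration <- function(x, ...) x$scale_factors

#' Log2 trajectories versus the untreated reference
#'
#' Computes, per replicate, `log2((x + pseudocount) / (x0 + pseudocount))`
#' of the calibrated value against that replicate's 0-minute sample, then
#' averages the replicate values at each time point to give a single log2
#' trajectory per protein. The ratio at time 0 is 0 by construction.
#'
#' @param calibration A `polystress_calibration` object, or a tibble with
#'   columns `protein_id`, `time_min`, `replicate`, `calibrated`.
#' @param pseudocount Added to numerator and denominator before the ratio;
#'   with the detected-in-all filter counts are positive, so the default
#'   0.5 only matters under lenient filtering.
#' @return Tibble: `protein_id`, `time_min`, `log2_ratio`, `n_reps`.
#' @examples
#' sim <- simulate_spectrum_counts(sim_config(n_genes = 20, seed = 3))
#' traj <- log2_trajectories(calibrate_samples(sim$counts))
#' head(traj)
#' @export
log2_trajectories <- function(calibration, pseudocount = 0.5) {
  df <- if (inherits(calibration, "polystress_calibration")) {
    calibration$calibrated
  } else calibration
  if (!"calibrated" %in% names(df)) {
    abort("`calibration` must carry a `calibrated` column")
  }
  ref <- dplyr::filter(df, .data$time_min == 0)
  if (nrow(ref) == 0L) abort("no 0-minute reference sample present")
  ref <- dplyr::select(ref, "protein_id", "replicate", ref = "calibrated")
  x <- dplyr::inner_join(df, ref, by = c("protein_id", "replicate"))
  x$log2_ratio <- log2((x$calibrated + pseudocount) / (x$ref + pseudocount))
  dplyr::summarise(
    dplyr::group_by(x, .data$protein_id, .data$time_min),
    log2_ratio = mean(.data$log2_ratio), n_reps = dplyr::n(),
    .groups = "drop")
}

# Quadratic least squares on a standardized time axis; shared by
# fit_temporal() and fit_proteome(). Y: matrix proteins x timepoints.
quad_fit_matrix <- function(Y, timepoints, alpha) {
  n <- length(timepoints)
  if (n < 4L) {
    abort("need at least 4 time points to fit the quadratic-linear model")
  }
  z <- (timepoints - mean(timepoints)) / sd(timepoints)
  X <- cbind(1, z, z^2)
  XtXi <- solve(crossprod(X))
  H <- XtXi %*% t(X)                 # coefficient hat matrix
  B <- Y %*% t(H)                    # proteins x 3
  fitted <- B %*% t(X)
  res <- Y - fitted
  rss <- rowSums(res^2)
  rss0 <- rowSums((Y - rowMeans(Y))^2)
  df_res <- n - 3L
  sigma2 <- rss / df_res
  Fstat <- ((rss0 - rss) / 2) / sigma2
  pval <- pf(Fstat, 2, df_res, lower.tail = FALSE)
  se2 <- sqrt(sigma2 * XtXi[3, 3])
  t2 <- B[, 3] / se2
  p2 <- 2 * pt(abs(t2), df_res, lower.tail = FALSE)

  tol <- 1e-12
  flat <- rss0 < tol * pmax(1, rowSums(Y^2)) | rss0 == 0
  exact <- !flat & rss < tol * pmax(rss0, 1)
  if (any(exact)) {
    # noiseless input: zero residual variance, the trend is unambiguous
    warn(sprintf(
      "%d trajectory(ies) fit with zero residual variance; p reported as 0",
      sum(exact)))
    Fstat[exact] <- Inf
    pval[exact] <- 0
    # classify curvature by the exact coefficient instead of its t statistic
    p2[exact] <- ifelse(abs(B[exact, 3]) > 1e-8 * pmax(1, abs(B[exact, 2])),
                        0, 1)
  }
  Fstat[flat] <- 0
  pval[flat] <- 1

  significant <- pval < alpha
  category <- rep("unchanged", nrow(Y))
  quad <- significant & p2 < alpha
  lin <- significant & !quad
  category[quad & B[, 3] > 0] <- "quadratic_convex"
  category[quad & B[, 3] < 0] <- "quadratic_concave"
  category[lin & B[, 2] > 0] <- "linear_up"
  category[lin & B[, 2] < 0] <- "linear_down"
  category[significant & category == "unchanged"] <-
    ifelse(B[significant & category == "unchanged", 2] >= 0,
           "linear_up", "linear_down")

  idx_max <- max.col(abs(fitted), ties.method = "first")
  fitted_max <- fitted[cbind(seq_len(nrow(Y)), idx_max)]

  tibble::tibble(
    beta0 = B[, 1], beta1 = B[, 2], beta2 = B[, 3],
    se_beta2 = se2, F_statistic = Fstat, p_value = pval,
    p_beta2 = p2, significant = significant, category = category,
    fitted_max_change = fitted_max)
}

#' Fit the quadratic-linear temporal model to one trajectory
#'
#' Least-squares fit of `y(t) = b0 + b1 z + b2 z^2`, with `z` the time axis
#' centered and scaled to unit variance. Temporal change is assessed by the
#' overall F test of the linear and quadratic terms against the
#' intercept-only model; significant trajectories (p < `alpha`) are
#' classified by a t test on the quadratic coefficient at the same level:
#' quadratic convex (b2 > 0) or concave (b2 < 0) when curvature is
#' significant, otherwise linear up (b1 > 0) or down (b1 < 0). Noiseless
#' input (zero residual variance) is reported significant with p = 0 and a
#' warning; constant trajectories get F = 0 and category `"unchanged"`.
#'
#' @param trajectory Numeric vector of log2 ratios, one per time point.
#' @param timepoints Numeric vector of times (minutes), length >= 4.
#' @param alpha Significance level for both tests.
#' @return One-row tibble: `beta0`, `beta1`, `beta2`, `F_statistic`,
#'   `p_value`, `p_beta2`, `significant`, `category`, `fitted_max_change`
#'   (signed largest-magnitude fitted value, used to collapse categories to
#'   a direction).
#' @examples
#' fit_temporal(c(0, 0.15, 0.3, 0.6, 1.2, 1.8) + rnorm(6, 0, 0.05),
#'              c(0, 15, 30, 60, 120, 180))
#' @export
fit_temporal <- function(trajectory, timepoints, alpha = 0.05) {
  if (length(trajectory) != length(timepoints)) {
    abort("`trajectory` and `timepoints` must have the same length")
  }
  quad_fit_matrix(matrix(trajectory, nrow = 1), timepoints, alpha)
}

#' Fit temporal models to every protein
#'
#' Applies the quadratic-linear fit of [fit_temporal()] to each protein's
#' replicate-averaged log2 trajectory (all proteins share the time grid, so
#' the fit is vectorized).
#'
#' @param trajectories Tibble from [log2_trajectories()].
#' @param alpha Significance level.
#' @return A tibble of class `polystress_temporal_fits`, one row per
#'   protein, with the columns of [fit_temporal()] plus `protein_id`.
#' @examples
#' sim <- simulate_spectrum_counts(sim_config(n_genes = 25, seed = 4))
#' fits <- fit_proteome(log2_trajectories(calibrate_samples(sim$counts)))
#' dplyr::count(fits, category)
#' @export
fit_proteome <- function(trajectories, alpha = 0.05) {
  wide <- tidyr::pivot_wider(
    trajectories[, c("protein_id", "time_min", "log2_ratio")],
    names_from = "time_min", values_from = "log2_ratio")
  times <- as.numeric(names(wide)[-1])
  o <- order(times)
  Y <- as.matrix(wide[, -1, drop = FALSE])[, o, drop = FALSE]
  if (anyNA(Y)) abort("trajectories contain missing time points")
  fits <- quad_fit_matrix(Y, times[o], alpha)
  out <- dplyr::bind_cols(tibble::tibble(protein_id = wide$protein_id), fits)
  class(out) <- c("polystress_temporal_fits", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "timepoints") <- times[o]
  out
}

#' @method tidy polystress_temporal_fits
#' @export
tidy.polystress_temporal_fits <- function(x, ...) {
  df <- tibble::as_tibble(x)
  tidyr::pivot_longer(df[, c("protein_id", "beta0", "beta1", "beta2")],
                      -"protein_id", names_to = "term",
                      values_to = "estimate")
}

#' @method glance polystress_temporal_fits
#' @export
glance.polystress_temporal_fits <- function(x, ...) {
  tibble::tibble(n_proteins = nrow(x),
                 n_significant = sum(x$significant),
                 prop_significant = mean(x$significant),
                 alpha = attr(x, "alpha"))
}
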