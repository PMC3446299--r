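times6 <- c(0, 15, 30, 60, 120, 180)

test_that("detection filters drop undetected and low-evidence proteins", {
  mat <- rbind(a = rep(10, 12), b = c(0, rep(10, 11)), c = rep(10, 12))
  counts <- make_counts(mat)
  counts$unique_peptides[counts$protein_id == "c"] <- 1L
  kept <- suppressMessages(filter_detected(counts))
  expect_setequal(unique(kept$protein_id), "a")
  expect_equal(attr(kept, "retained"), c(kept = 1L, total = 3L))
  # without the all-samples requirement, b comes back
  kept2 <- suppressMessages(filter_detected(counts,
                                            require_all_samples = FALSE))
  expect_setequal(unique(kept2$protein_id), c("a", "b"))
  expect_warning(filter_detected(counts[0, ]), "empty")
})

test_that("retained count is monotone in filter strictness", {
  cfg <- sim_config(n_genes = 80, seed = 30, dropout_fraction = 0.2)
  counts <- simulate_spectrum_counts(cfg)$counts
  kept_of <- function(...) {
    attr(suppressMessages(filter_detected(counts, ...)), "retained")[["kept"]]
  }
  expect_gte(kept_of(min_unique_peptides = 2, require_all_samples = FALSE),
             kept_of(min_unique_peptides = 2, require_all_samples = TRUE))
  expect_gte(kept_of(min_unique_peptides = 2),
             kept_of(min_unique_peptides = 6))
})

test_that("calibration slope follows the closed form", {
  set.seed(31)
  base <- rpois(50, 100) + 1
  mat <- cbind(base, base, base, base)
  rownames(mat) <- sprintf("p%03d", 1:50)
  counts <- make_counts(mat, times = c(0, 60), reps = 1:2)
  cal <- calibrate_samples(counts)
  expect_equal(cal$scale_factors$a, rep(1, 4))          # identity fixed point
  expect_equal(cal$calibrated$calibrated, cal$calibrated$count)

  # sample equal to 2x a fixed control has slope exactly 0.5
  ctrl <- tibble::tibble(protein_id = rownames(mat), control = base)
  counts2 <- make_counts(cbind(2 * base, base, base, base),
                         times = c(0, 60), reps = 1:2)
  cal2 <- calibrate_samples(counts2, control = ctrl)
  a_first <- cal2$scale_factors$a[cal2$scale_factors$time_min == 0 &
                                    cal2$scale_factors$replicate == 1]
  expect_equal(a_first, 0.5)

  expect_error(calibrate_samples(make_counts(cbind(base, 0 * base),
                                             times = c(0, 60), reps = 1)),
               "all-zero")
})

test_that("calibration is scale-equivariant and self-consistent", {
  set.seed(32)
  base <- rpois(80, 150) + 1
  mat <- sapply(1:4, function(i) rpois(80, base))
  rownames(mat) <- sprintf("p%03d", 1:80)
  counts <- make_counts(mat, times = c(0, 60), reps = 1:2)
  ctrl <- tibble::tibble(protein_id = rownames(mat), control = base)
  cal <- calibrate_samples(counts, control = ctrl)
  # multiplying one sample by c divides its slope by c, exactly
  counts_scaled <- counts
  idx <- counts_scaled$time_min == 60 & counts_scaled$replicate == 2
  counts_scaled$count[idx] <- counts_scaled$count[idx] * 3
  cal_s <- calibrate_samples(counts_scaled, control = ctrl)
  pick <- function(x) x$scale_factors$a[x$scale_factors$time_min == 60 &
                                          x$scale_factors$replicate == 2]
  expect_equal(pick(cal_s), pick(cal) / 3)

  # recalibrating calibrated data leaves all factors at 1
  recal_in <- dplyr::mutate(cal$calibrated, count = .data$calibrated)
  recal <- calibrate_samples(recal_in)
  # approximate fixed point: residual deviation is second order in noise
  expect_equal(recal$scale_factors$a, rep(1, 4), tolerance = 0.01)
  expect_lt(max(abs(recal$scale_factors$a - 1)),
            max(abs(cal$scale_factors$a - 1)))
})

test_that("log2 trajectories are replicate-referenced then averaged", {
  # constant protein -> all-zero trajectory
  mat <- rbind(a = rep(8, 12))
  cal <- calibrate_samples(make_counts(mat))
  traj <- log2_trajectories(cal, pseudocount = 0)
  expect_equal(traj$log2_ratio, rep(0, 6))
  # doubling from t0, pseudocount 0 -> ratio exactly 1
  # (samples are time-major: both replicates of t = 0 come first)
  mat2 <- rbind(a = c(10, 10, rep(20, 10)))
  df2 <- make_counts(mat2)
  df2$calibrated <- df2$count
  traj2 <- log2_trajectories(df2, pseudocount = 0)
  expect_equal(traj2$log2_ratio[traj2$time_min == 15], 1)
  # replicate ratios {0.8, 1.2} average to 1.0
  df3 <- tibble::tibble(protein_id = "a",
                        time_min = c(0, 60, 0, 60),
                        replicate = c(1, 1, 2, 2),
                        calibrated = c(10, 10 * 2^0.8, 10, 10 * 2^1.2))
  traj3 <- log2_trajectories(df3, pseudocount = 0)
  expect_equal(traj3$log2_ratio[traj3$time_min == 60], 1)
  # missing 0-min reference is an error
  expect_error(log2_trajectories(df3[df3$time_min != 0, ], 0), "0-minute")
})

test_that("the temporal fit classifies noiseless trends exactly", {
  expect_warning(lin <- fit_temporal(0.01 * times6, times6), "zero residual")
  expect_equal(lin$category, "linear_up")
  expect_equal(lin$p_value, 0)
  expect_equal(lin$fitted_max_change, 0.01 * 180, tolerance = 1e-8)
  expect_warning(dn <- fit_temporal(-0.01 * times6, times6), "zero residual")
  expect_equal(dn$category, "linear_down")
  m <- 90
  expect_warning(cx <- fit_temporal(0.75 * (((times6 - m)^2) / m^2 - 1),
                                    times6), "zero residual")
  expect_equal(cx$category, "quadratic_convex")
  expect_warning(cc <- fit_temporal(-0.75 * (((times6 - m)^2) / m^2 - 1),
                                    times6), "zero residual")
  expect_equal(cc$category, "quadratic_concave")
})

test_that("degenerate trajectories are unchanged and short input errors", {
  flat <- fit_temporal(rep(0, 6), times6)
  expect_equal(flat$F_statistic, 0)
  expect_equal(flat$category, "unchanged")
  expect_false(flat$significant)
  expect_error(fit_temporal(c(0, 1, 2), c(0, 15, 30)), "4 time points")
  expect_error(fit_temporal(c(0, 1), times6), "same length")
})

test_that("the overall F statistic matches lm's on random trajectories", {
  set.seed(33)
  z <- (times6 - mean(times6)) / sd(times6)
  for (i in 1:100) {
    y <- rnorm(6, sd = runif(1, 0.5, 2))
    mine <- fit_temporal(y, times6)
    ref <- summary(stats::lm(y ~ z + I(z^2)))
    expect_equal(mine$F_statistic, unname(ref$fstatistic[1]),
                 tolerance = 1e-8)
    expect_equal(unname(c(mine$beta0, mine$beta1, mine$beta2)),
                 unname(ref$coefficients[, 1]), tolerance = 1e-8)
    pref <- stats::pf(ref$fstatistic[1], 2, 3, lower.tail = FALSE)
    expect_equal(mine$p_value, unname(pref), tolerance = 1e-8)
  }
})

test_that("fit_proteome vectorizes fit_temporal over proteins", {
  set.seed(34)
  traj <- tidyr::expand_grid(protein_id = sprintf("p%02d", 1:15),
                             time_min = times6)
  traj$log2_ratio <- rnorm(nrow(traj), sd = 0.5)
  fits <- fit_proteome(traj)
  expect_s3_class(fits, "polystress_temporal_fits")
  one <- dplyr::filter(traj, .data$protein_id == "p07")
  single <- fit_temporal(one$log2_ratio[order(one$time_min)], times6)
  row <- tibble::as_tibble(fits)[fits$protein_id == "p07", ]
  expect_equal(row$F_statistic, single$F_statistic)
  expect_equal(row$category, single$category)
  gl <- glance(fits)
  expect_equal(gl$n_proteins, 15L)
  td <- tidy(fits)
  expect_equal(nrow(td), 45L)
})
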