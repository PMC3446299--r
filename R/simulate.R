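#' Plant ground-truth regulation labels
#'
#' Assigns each simulated gene one label per layer (translation, mRNA,
#' protein; `"null"` when unregulated) according to the planted proportions
#' in the configuration. With `concordant_layers = TRUE` the up-regulated
#' blocks of all layers share the same leading gene indices and the
#' down-regulated blocks share a block in the second half of the universe,
#' so cross-layer regulation is concordant by construction; otherwise labels
#' are drawn independently per layer.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per gene: `gene_id`, `translation_label`
#'   (null/up/down), `mrna_label` (null/up/down), `protein_label`
#'   (null/linear_up/linear_down/convex/concave) and `mrna_effect`, the
#'   signed per-gene peak log2 effect.
#' @examples
#' table(plant_truth(sim_config(n_genes = 100, seed = 1))$translation_label)
#' @export
plant_truth <- function(config) {
  stopifnot(inherits(config, "polystress_config"))
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  if (n == 0L) {
    return(tibble::tibble(gene_id = character(),
                          translation_label = character(),
                          mrna_label = character(),
                          protein_label = character(),
                          mrna_effect = numeric()))
  }
  set.seed(config$seed)
  p <- config$planted
  n_of <- function(key) as.integer(round(p[[key]] * n))

  assign_block <- function(labels, idx, value) {
    labels[idx] <- value
    labels
  }

  tl <- ml <- rep("null", n)
  pl <- rep("null", n)
  if (config$concordant_layers) {
    h <- n %/% 2L
    up_ids <- function(k) seq_len(min(k, h))
    down_ids <- function(k) h + seq_len(min(k, n - h))
    tl <- assign_block(tl, up_ids(n_of("translation_up")), "up")
    tl <- assign_block(tl, down_ids(n_of("translation_down")), "down")
    ml <- assign_block(ml, up_ids(n_of("mrna_up")), "up")
    ml <- assign_block(ml, down_ids(n_of("mrna_down")), "down")
    npu <- n_of("protein_linear_up"); ncx <- n_of("protein_convex")
    npd <- n_of("protein_linear_down"); ncc <- n_of("protein_concave")
    pl <- assign_block(pl, up_ids(npu), "linear_up")
    pl <- assign_block(pl, npu + seq_len(min(ncx, max(0L, h - npu))), "convex")
    pl <- assign_block(pl, down_ids(npd), "linear_down")
    cc_ids <- h + npd + seq_len(min(ncc, max(0L, n - h - npd)))
    pl <- assign_block(pl, cc_ids, "concave")
  } else {
    draw <- function(labels, sizes) {
      free <- which(labels == "null")
      for (nm in names(sizes)) {
        k <- min(sizes[[nm]], length(free))
        pick <- sample(free, k)
        labels[pick] <- nm
        free <- setdiff(free, pick)
      }
      labels
    }
    tl <- draw(tl, c(up = n_of("translation_up"),
                     down = n_of("translation_down")))
    ml <- draw(ml, c(up = n_of("mrna_up"), down = n_of("mrna_down")))
    pl <- draw(pl, c(linear_up = n_of("protein_linear_up"),
                     linear_down = n_of("protein_linear_down"),
                     convex = n_of("protein_convex"),
                     concave = n_of("protein_concave")))
  }

  cv <- config$mrna_effect_cv
  if (cv > 0) {
    sdl <- sqrt(log(1 + cv^2))
    mult <- exp(rnorm(n, -sdl^2 / 2, sdl))
  } else {
    mult <- rep(1, n)
  }
  sign_m <- ifelse(ml == "up", 1, ifelse(ml == "down", -1, 0))
  tibble::tibble(gene_id = gene_id,
                 translation_label = tl,
                 mrna_label = ml,
                 protein_label = pl,
                 mrna_effect = sign_m * config$mrna_log2_effect * mult)
}

# Move `shift` percentage points between the (1,2) and (3,4) halves of a
# control percentage vector; positive direction = into the polysomal half.
shift_profile <- function(p, shift, direction) {
  low <- p[1] + p[2]; high <- p[3] + p[4]
  split2 <- function(pair, total) {
    s <- pair[1] + pair[2]
    if (s <= 0) c(total / 2, total / 2) else pair / s * total
  }
  if (direction == "down") {
    out <- c(split2(p[1:2], low + shift), split2(p[3:4], high - shift))
  } else {
    out <- c(split2(p[1:2], low - shift), split2(p[3:4], high + shift))
  }
  out
}

#' Simulate four-pool polysome-fraction abundances
#'
#' Generates raw pool abundances for paired control/stress rounds. Every
#' gene has a latent control profile (percent of its signal per pool, drawn
#' from a Dirichlet distribution). Genes planted as translationally
#' down-regulated move `effect_size_shift` percentage points of mass from
#' the polysomal half (pools 3-4) into the sub-polysomal half (pools 1-2)
#' under stress; up-regulated genes the inverse; null genes keep their
#' control profile. Observed abundances are the latent percentages under
#' multiplicative log-normal noise, drawn independently per pool, replicate
#' and condition.
#'
#' @param config A [sim_config()] object.
#' @param truth Optional truth table from [plant_truth()]; generated from
#'   `config` when missing.
#' @return A list with `pools`, a long tibble
#'   (`gene_id`, `condition`, `time_min`, `replicate`, `pool`, `abundance`),
#'   and `truth`.
#' @examples
#' sim <- simulate_fraction_pools(sim_config(n_genes = 20, seed = 7))
#' head(sim$pools)
#' @export
simulate_fraction_pools <- function(config, truth = plant_truth(config)) {
  stopifnot(inherits(config, "polystress_config"))
  if (nrow(truth) != config$n_genes) {
    abort("`truth` does not match `config`: different gene universe")
  }
  n <- config$n_genes
  set.seed(config$seed + 11L)
  if (n == 0L) {
    empty <- tibble::tibble(gene_id = character(), condition = character(),
                            time_min = numeric(), replicate = integer(),
                            pool = integer(), abundance = numeric())
    return(list(pools = empty, truth = truth))
  }

  planted <- truth$translation_label != "null"
  need_high <- truth$translation_label == "down"
  need_low <- truth$translation_label == "up"
  margin <- config$effect_size_shift + 2
  if (margin > 95) abort("`effect_size_shift` leaves no feasible profile")

  base <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    for (try in seq_len(1000L)) {
      g <- stats::rgamma(4, shape = 8)
      p <- 100 * g / sum(g)
      ok <- if (need_high[i]) p[3] + p[4] >= margin
            else if (need_low[i]) p[1] + p[2] >= margin else TRUE
      if (ok) break
    }
    if (!ok) { # deterministic feasible fallback for extreme shifts
      d <- margin + 1
      p <- if (need_high[i]) c((100 - d) / 2, (100 - d) / 2, d / 2, d / 2)
           else c(d / 2, d / 2, (100 - d) / 2, (100 - d) / 2)
    }
    base[i, ] <- p
  }

  stress_mean <- base
  for (i in which(planted)) {
    stress_mean[i, ] <- shift_profile(base[i, ], config$effect_size_shift,
                                      truth$translation_label[i])
  }

  noisy <- function(mean_mat) {
    if (config$noise_sd_log == 0) return(mean_mat)
    mean_mat * exp(matrix(rnorm(length(mean_mat), 0, config$noise_sd_log),
                          nrow(mean_mat)))
  }
  one_block <- function(mean_mat, condition, time_min, replicate) {
    m <- noisy(mean_mat)
    tibble::tibble(gene_id = rep(truth$gene_id, times = 4),
                   condition = condition, time_min = time_min,
                   replicate = replicate,
                   pool = rep(1:4, each = max(n, 0L)),
                   abundance = as.vector(m))
  }

  blocks <- list()
  for (r in seq_len(config$n_replicates_control)) {
    blocks[[length(blocks) + 1L]] <- one_block(base, "control", 0, r)
  }
  for (t in config$stress_timepoints_min) {
    for (r in seq_len(config$n_replicates_stress)) {
      blocks[[length(blocks) + 1L]] <- one_block(stress_mean, "stress", t, r)
    }
  }
  pools <- dplyr::bind_rows(blocks)
  list(pools = pools, truth = truth)
}

# Transient-peak shape: fast rise to 1 at `peak`, partial linear decay after.
mrna_shape <- function(t, peak, t_max) {
  s <- numeric(length(t))
  rise <- t <= peak
  s[rise] <- (t[rise] / peak)^0.3
  if (t_max > peak) {
    s[!rise] <- 1 - 0.4 * (t[!rise] - peak) / (t_max - peak)
  } else {
    s[!rise] <- 1
  }
  s
}

#' Simulate mRNA log2-ratio expression tables
#'
#' Produces per-gene log2 expression ratios (stress vs unstressed) for two
#' experiments: `mrna1` on the translation-layer stress times and `mrna2` on
#' the proteome stress times. Planted mRNA-regulated genes follow a
#' transient-peak trajectory — rapid induction, peak of `mrna_effect` log2
#' units at `peak_time_min`, then partial decay to 60% of the peak — so most
#' regulated transcripts peak at 60 minutes; null genes are flat. Gaussian
#' noise (`noise_sd_log`, log2 units) is added per measurement.
#'
#' @param config A [sim_config()] object.
#' @param truth Truth table from [plant_truth()] (same config).
#' @param peak_time_min Peak time of the planted trajectory (minutes).
#' @return A long tibble: `gene_id`, `experiment`, `time_min`, `log2_ratio`.
#' @examples
#' cfg <- sim_config(n_genes = 10, noise_sd_log = 0, seed = 2)
#' simulate_mrna_table(cfg, plant_truth(cfg))
#' @export
simulate_mrna_table <- function(config, truth = plant_truth(config),
                                peak_time_min = 60) {
  stopifnot(inherits(config, "polystress_config"))
  if (nrow(truth) != config$n_genes ||
      (config$n_genes > 0 &&
       !identical(truth$gene_id, sprintf("g%05d", seq_len(config$n_genes))))) {
    abort("`truth` does not match `config`: different gene universe")
  }
  set.seed(config$seed + 22L)
  grids <- list(mrna1 = config$stress_timepoints_min,
                mrna2 = setdiff(config$proteome_timepoints_min, 0))
  if (config$n_genes == 0L) {
    return(tibble::tibble(gene_id = character(), experiment = character(),
                          time_min = numeric(), log2_ratio = numeric()))
  }
  out <- purrr::imap(grids, function(times, exp_name) {
    if (!length(times)) return(NULL)
    t_max <- max(times, peak_time_min)
    s <- mrna_shape(times, peak_time_min, t_max)
    mu <- outer(truth$mrna_effect, s) # genes x times
    eps <- if (config$noise_sd_log == 0) 0 else
      matrix(rnorm(length(mu), 0, config$noise_sd_log), nrow(mu))
    tibble::tibble(
      gene_id = rep(truth$gene_id, times = length(times)),
      experiment = exp_name,
      time_min = rep(times, each = nrow(truth)),
      log2_ratio = as.vector(mu + eps))
  })
  dplyr::bind_rows(out)
}

# Relative protein level for a first-order synthesis-degradation response to
# an mRNA fold-change trajectory; exact exponential stepping on a 1-min grid.
lowpass_response <- function(times, mrel_fun, kd) {
  t_max <- max(times)
  if (kd <= 0) return(rep(1, length(times)))
  grid <- seq(0, t_max, by = 1)
  p <- numeric(length(grid)); p[1] <- 1
  for (i in seq_along(grid)[-1]) {
    m <- mrel_fun(grid[i - 1])
    p[i] <- m + (p[i - 1] - m) * exp(-kd)
  }
  p[match(times, grid)]
}

#' Simulate a spectrum-count proteome time course
#'
#' Draws Poisson spectrum counts for every protein over the proteome time
#' grid with the configured number of replicate time courses (default 2 x 6
#' = 12 samples). Each protein has a log-normal baseline abundance around
#' `count_depth`; planted proteins follow linear or quadratic log2 mean
#' trajectories (`protein_model = "planted"`), or trajectories derived from
#' the gene's mRNA fold change through a first-order synthesis-degradation
#' response (`protein_model = "mrna_coupled"`, where mRNA-down genes have
#' effectively stable proteins and so stay flat). Per-sample true scale
#' factors multiply all counts in a sample and are what the calibration step
#' must recover. A configured dropout fraction zeroes some proteins in one
#' or more samples so the detected-in-all-samples filter has work to do.
#'
#' @param config A [sim_config()] object.
#' @param truth Truth table from [plant_truth()].
#' @return A list with `counts` (long tibble: `protein_id`, `time_min`,
#'   `replicate`, `count`, `unique_peptides`), `scale_factors` (per-sample
#'   `true_scale`), and `truth` augmented with a `dropout` flag.
#' @examples
#' sim <- simulate_spectrum_counts(sim_config(n_genes = 15, seed = 3))
#' dplyr::count(sim$counts, time_min, replicate)
#' @export
simulate_spectrum_counts <- function(config, truth = plant_truth(config)) {
  stopifnot(inherits(config, "polystress_config"))
  if (nrow(truth) != config$n_genes) {
    abort("`truth` does not match `config`: different gene universe")
  }
  set.seed(config$seed + 33L)
  n <- config$n_genes
  times <- config$proteome_timepoints_min
  reps <- seq_len(config$n_replicates_proteome)
  t_max <- max(times)
  samples <- tidyr::expand_grid(time_min = times, replicate = reps)
  ns <- nrow(samples)

  sf <- if (config$scale_factor_sdlog > 0) {
    s <- exp(rnorm(ns, 0, config$scale_factor_sdlog))
    s / exp(mean(log(s)))
  } else rep(1, ns)
  scale_factors <- dplyr::mutate(samples, true_scale = sf)

  baseline <- config$count_depth *
    exp(rnorm(n, -config$baseline_sdlog^2 / 2, config$baseline_sdlog))

  # per-protein log2 trajectory over `times`
  traj <- matrix(0, nrow = n, ncol = length(times))
  if (n > 0 && config$protein_model == "planted") {
    m <- t_max / 2
    for (i in seq_len(n)) {
      traj[i, ] <- switch(truth$protein_label[i],
        linear_up = config$protein_log2_span * times / t_max,
        linear_down = -config$protein_log2_span * times / t_max,
        convex = config$protein_quad_amplitude * (((times - m)^2) / m^2 - 1),
        concave = -config$protein_quad_amplitude * (((times - m)^2) / m^2 - 1),
        numeric(length(times)))
    }
  } else if (n > 0) {
    kd_up <- log(2) / config$protein_halflife_min
    peak <- 60
    for (i in seq_len(n)) {
      eff <- truth$mrna_effect[i]
      if (eff == 0) next
      kd <- if (eff > 0) kd_up else 0 # stable proteins decouple mRNA loss
      mfun <- function(t) 2^(eff * mrna_shape(t, peak, max(t_max, peak)))
      traj[i, ] <- log2(lowpass_response(times, mfun, kd))
    }
  }

  # mean count matrix, proteins x samples
  mu <- matrix(0, n, ns)
  for (j in seq_len(ns)) {
    ti <- match(samples$time_min[j], times)
    mu[, j] <- baseline * 2^traj[, ti] * sf[j]
  }
  counts <- matrix(rpois(n * ns, as.vector(mu)), n, ns)
  upep <- matrix(rpois(n * ns, 2 + sqrt(pmax(counts, 0)) / 3) + 2L, n, ns)

  dropout <- rep(FALSE, n)
  if (config$dropout_fraction > 0 && n > 0) {
    k <- max(1L, floor(config$dropout_fraction * n))
    drop_idx <- sample(n, k)
    dropout[drop_idx] <- TRUE
    for (i in drop_idx) {
      cols <- sample(ns, sample(1:3, 1))
      counts[i, cols] <- 0L
      upep[i, cols] <- 0L
    }
  }

  counts_tbl <- tibble::tibble(
    protein_id = rep(truth$gene_id, times = ns),
    time_min = rep(samples$time_min, each = max(n, 0L)),
    replicate = rep(samples$replicate, each = max(n, 0L)),
    count = as.integer(counts),
    unique_peptides = as.integer(upep))

  list(counts = counts_tbl, scale_factors = scale_factors,
       truth = dplyr::mutate(truth, dropout = dropout))
}

#' Simulate all three data layers of a stress study
#'
#' Convenience wrapper running [plant_truth()], [simulate_fraction_pools()],
#' [simulate_mrna_table()] and [simulate_spectrum_counts()] with one
#' configuration.
#'
#' @param config A [sim_config()] object.
#' @return A list: `pools`, `mrna`, `counts`, `scale_factors`, `truth`,
#'   `config`.
#' @examples
#' study <- simulate_stress_study(sim_config(n_genes = 12, seed = 4))
#' names(study)
#' @export
simulate_stress_study <- function(config) {
  truth <- plant_truth(config)
  fr <- simulate_fraction_pools(config, truth)
  mrna <- simulate_mrna_table(config, truth)
  pc <- simulate_spectrum_counts(config, truth)
  list(pools = fr$pools, mrna = mrna, counts = pc$counts,
       scale_factors = pc$scale_factors, truth = pc$truth, config = config)
}
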