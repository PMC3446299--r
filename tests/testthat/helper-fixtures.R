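# in-code fixtures shared across test files

# long pool tibble from explicit percentage profiles:
# control / stress are lists of 4-vectors, one per replicate
make_pools <- function(gene = "gX", control, stress, time_min = 15) {
  one <- function(p, cond, t, r) {
    tibble::tibble(gene_id = gene, condition = cond, time_min = t,
                   replicate = r, pool = 1:4, abundance = p)
  }
  dplyr::bind_rows(
    purrr::imap(control, ~one(.x, "control", 0, .y)),
    purrr::imap(stress, ~one(.x, "stress", time_min, .y)))
}

# random valid profile (percentages summing to 100)
random_profile <- function() {
  x <- stats::rgamma(4, shape = 2)
  100 * x / sum(x)
}

# long count tibble from a proteins x samples matrix
make_counts <- function(mat, times = c(0, 15, 30, 60, 120, 180), reps = 1:2,
                        unique_peptides = 3L) {
  samples <- tidyr::expand_grid(time_min = times, replicate = reps)
  stopifnot(ncol(mat) == nrow(samples))
  ids <- rownames(mat) %||% sprintf("p%03d", seq_len(nrow(mat)))
  tibble::tibble(
    protein_id = rep(ids, times = nrow(samples)),
    time_min = rep(samples$time_min, each = nrow(mat)),
    replicate = rep(samples$replicate, each = nrow(mat)),
    count = as.vector(mat),
    unique_peptides = unique_peptides)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
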