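#' Read a tab-delimited study matrix
#'
#' All interchange files are plain TSV with identifiers in the first column
#' and one sample per remaining column. Header fields are colon-separated
#' and carry the design, so no separate design file is needed:
#' * `fractions`: `condition:time:replicate:pool` (pool 1-4);
#' * `mrna`: `experiment:time`;
#' * `counts`: `condition:time:replicate`.
#'
#' Duplicate identifiers, malformed headers and non-numeric cells give
#' descriptive errors.
#'
#' @param path File path.
#' @param layer One of `"fractions"`, `"mrna"`, `"counts"`.
#' @return A long tibble in the layout the analysis functions expect
#'   ([normalize_profiles()], [call_mrna_direction()],
#'   [filter_detected()]).
#' @examples
#' cfg <- sim_config(n_genes = 3, seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' write_matrix(simulate_fraction_pools(cfg)$pools, f, layer = "fractions")
#' head(read_matrix(f, layer = "fractions"))
#' @export
read_matrix <- function(path, layer = c("fractions", "mrna", "counts")) {
  layer <- match.arg(layer)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (ncol(raw) < 1L) abort(sprintf("%s: no columns found", path))
  id_col <- names(raw)[1]
  ids <- raw[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    line <- which(duplicated(ids))[1] + 1L
    abort(sprintf("%s: duplicated identifier '%s' (line %d)",
                  path, dup[1], line))
  }
  if (ncol(raw) == 1L) {
    warn(sprintf("%s: empty data section", path))
  }
  n_fields <- switch(layer, fractions = 4L, mrna = 2L, counts = 3L)
  heads <- strsplit(names(raw)[-1], ":", fixed = TRUE)
  bad <- which(lengths(heads) != n_fields)
  if (length(bad)) {
    abort(sprintf(
      "%s: malformed header '%s' (expected %d colon-separated fields for layer '%s')",
      path, names(raw)[-1][bad[1]], n_fields, layer))
  }
  vals <- raw[, -1, drop = FALSE]
  num <- suppressWarnings(
    lapply(vals, function(v) as.numeric(v)))
  for (j in seq_along(num)) {
    miss <- !is.na(vals[[j]]) & is.na(num[[j]])
    if (any(miss)) {
      abort(sprintf("%s: non-numeric value '%s' in column '%s' (line %d)",
                    path, vals[[j]][which(miss)[1]], names(vals)[j],
                    which(miss)[1] + 1L))
    }
  }
  long <- tibble::tibble(
    id = rep(ids, times = max(ncol(vals), 0L)),
    header = rep(names(vals), each = length(ids)),
    value = unlist(num, use.names = FALSE) %||% numeric(0))
  hf <- function(i) vapply(heads, `[[`, "", i)
  meta <- tibble::tibble(header = names(vals))
  out <- switch(layer,
    fractions = {
      meta$condition <- hf(1); meta$time_min <- as.numeric(hf(2))
      meta$replicate <- as.integer(hf(3)); meta$pool <- as.integer(hf(4))
      x <- dplyr::left_join(long, meta, by = "header")
      tibble::tibble(gene_id = x$id, condition = x$condition,
                     time_min = x$time_min, replicate = x$replicate,
                     pool = x$pool, abundance = x$value)
    },
    mrna = {
      meta$experiment <- hf(1); meta$time_min <- as.numeric(hf(2))
      x <- dplyr::left_join(long, meta, by = "header")
      tibble::tibble(gene_id = x$id, experiment = x$experiment,
                     time_min = x$time_min, log2_ratio = x$value)
    },
    counts = {
      meta$condition <- hf(1); meta$time_min <- as.numeric(hf(2))
      meta$replicate <- as.integer(hf(3))
      x <- dplyr::left_join(long, meta, by = "header")
      tibble::tibble(protein_id = x$id, time_min = x$time_min,
                     replicate = x$replicate, count = x$value)
    })
  if (anyNA(out$time_min)) {
    abort(sprintf("%s: non-numeric time field in a column header", path))
  }
  out
}

#' Write a study matrix as TSV
#'
#' Inverse of [read_matrix()]: writes the wide tab-delimited form with
#' colon-separated design headers. Values round-trip at full double
#' precision.
#'
#' @param data Long tibble for the given layer (see [read_matrix()]).
#' @param path Output path.
#' @param layer One of `"fractions"`, `"mrna"`, `"counts"`.
#' @param value Column to write for the `counts` layer (`"count"` or
#'   `"unique_peptides"`).
#' @return `path`, invisibly.
#' @examples
#' cfg <- sim_config(n_genes = 3, seed = 1)
#' write_matrix(simulate_fraction_pools(cfg)$pools, tempfile(), "fractions")
#' @export
write_matrix <- function(data, path,
                         layer = c("fractions", "mrna", "counts"),
                         value = "count") {
  layer <- match.arg(layer)
  wide <- switch(layer,
    fractions = {
      d <- dplyr::mutate(data, header = paste(.data$condition,
                                              .data$time_min,
                                              .data$replicate, .data$pool,
                                              sep = ":"))
      tidyr::pivot_wider(d[, c("gene_id", "header", "abundance")],
                         names_from = "header", values_from = "abundance")
    },
    mrna = {
      d <- dplyr::mutate(data, header = paste(.data$experiment,
                                              .data$time_min, sep = ":"))
      tidyr::pivot_wider(d[, c("gene_id", "header", "log2_ratio")],
                         names_from = "header", values_from = "log2_ratio")
    },
    counts = {
      d <- dplyr::mutate(data, header = paste("stress", .data$time_min,
                                              .data$replicate, sep = ":"))
      d$.value <- d[[value]]
      tidyr::pivot_wider(d[, c("protein_id", "header", ".value")],
                         names_from = "header", values_from = ".value")
    })
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read spectrum counts plus unique-peptide counts
#'
#' Reads a counts matrix and, when given, a parallel unique-peptide matrix
#' of identical layout; without one, every protein is assumed to meet the
#' peptide criterion (with a message).
#'
#' @param counts_path TSV of spectrum counts (`counts` layer).
#' @param peptides_path Optional TSV of unique-peptide counts.
#' @return Long tibble: `protein_id`, `time_min`, `replicate`, `count`,
#'   `unique_peptides`.
#' @examples
#' sim <- simulate_spectrum_counts(sim_config(n_genes = 3, seed = 1))
#' f <- tempfile(); p <- tempfile()
#' write_matrix(sim$counts, f, "counts", value = "count")
#' write_matrix(sim$counts, p, "counts", value = "unique_peptides")
#' head(read_counts(f, p))
#' @export
read_counts <- function(counts_path, peptides_path = NULL) {
  counts <- read_matrix(counts_path, layer = "counts")
  if (is.null(peptides_path)) {
    inform("no unique-peptide file given: peptide filter treated as passed")
    counts$unique_peptides <- Inf
    return(counts)
  }
  pep <- read_matrix(peptides_path, layer = "counts")
  pep <- dplyr::rename(pep, unique_peptides = "count")
  out <- dplyr::left_join(counts, pep,
                          by = c("protein_id", "time_min", "replicate"))
  if (anyNA(out$unique_peptides)) {
    abort("unique-peptide file does not cover every count cell")
  }
  out
}

#' Read gene sets for enrichment
#'
#' One set per line: set name, a tab, then comma-separated gene ids.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @examples
#' f <- tempfile()
#' writeLines("setA\tg1,g2,g3", f)
#' read_gene_sets(f)
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    abort(sprintf("%s: line %d is not 'name<TAB>gene,gene,...'",
                  path, bad[1]))
  }
  sets <- lapply(parts, function(p) {
    unique(trimws(strsplit(p[2], ",", fixed = TRUE)[[1]]))
  })
  names(sets) <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(names(sets))) abort(sprintf("%s: duplicated set name", path))
  sets
}

#' Write gene sets
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @examples
#' write_gene_sets(list(setA = c("g1", "g2")), tempfile())
#' @export
write_gene_sets <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste0(nm, "\t", paste(sets[[nm]], collapse = ","))
  }, ""), path)
  invisible(path)
}
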