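#' Call mRNA regulation direction from fold-change tables
#'
#' A gene is called up-regulated when its expression exceeds `fold_cutoff`
#' (strictly, on the linear scale) at `min_timepoints` or more of the
#' pooled stress time points across the supplied experiments; down-regulated
#' symmetrically for repression below `1 / fold_cutoff`. With the default
#' two-experiment design (two stress times in the first, five in the
#' second) the pooled set has seven stress time points. Missing values count
#' as non-passing; if both directions reach the threshold across different
#' time points the larger count wins and ties give `"none"`.
#'
#' @param mrna Long tibble: `gene_id`, `experiment`, `time_min`,
#'   `log2_ratio` (stress vs unstressed).
#' @param fold_cutoff Linear fold-change cutoff (> 1).
#' @param min_timepoints Minimum number of passing pooled time points.
#' @return Tibble: `gene_id`, `direction` (up/down/none),
#'   `n_timepoints_passing`, `n_timepoints_total`.
#' @examples
#' mrna <- tibble::tibble(gene_id = "gA", experiment = "mrna2",
#'                        time_min = c(15, 30, 60, 120, 180),
#'                        log2_ratio = c(1, 1, 1, 1, 0))
#' call_mrna_direction(mrna)
#' @export
call_mrna_direction <- function(mrna, fold_cutoff = 1.5, min_timepoints = 4) {
  if (fold_cutoff <= 1) abort("`fold_cutoff` must be > 1")
  lc <- log2(fold_cutoff)
  per <- dplyr::summarise(
    dplyr::group_by(mrna, .data$gene_id),
    n_up = sum(.data$log2_ratio > lc, na.rm = TRUE),
    n_down = sum(.data$log2_ratio < -lc, na.rm = TRUE),
    n_total = dplyr::n(), .groups = "drop")
  all_na <- dplyr::summarise(dplyr::group_by(mrna, .data$gene_id),
                             all_na = all(is.na(.data$log2_ratio)),
                             .groups = "drop")
  if (any(all_na$all_na)) {
    warn(sprintf("%d gene(s) with no mRNA data: called none",
                 sum(all_na$all_na)))
  }
  per$direction <- dplyr::case_when(
    per$n_up >= min_timepoints & per$n_up > per$n_down ~ "up",
    per$n_down >= min_timepoints & per$n_down > per$n_up ~ "down",
    TRUE ~ "none")
  tibble::tibble(gene_id = per$gene_id, direction = per$direction,
                 n_timepoints_passing = pmax(per$n_up, per$n_down),
                 n_timepoints_total = per$n_total)
}

collapse_protein_category <- function(category, fitted_max_change) {
  dplyr::case_when(
    category == "linear_up" ~ "up",
    category == "linear_down" ~ "down",
    category %in% c("quadratic_convex", "quadratic_concave") &
      fitted_max_change > 0 ~ "up",
    category %in% c("quadratic_convex", "quadratic_concave") &
      fitted_max_change < 0 ~ "down",
    TRUE ~ "none")
}

#' Classify cross-level discordance
#'
#' Maps each gene's (mRNA, translation, protein) direction triple to one
#' discordance class by a fixed, ordered rule table. Protein temporal
#' categories are first collapsed to a direction: linear up/down directly,
#' quadratic categories by the sign of the largest-magnitude fitted value
#' (a convex profile with a net rise counts as up, a concave profile with a
#' net fall as down). Rules, first match wins:
#' 1. mRNA down & translation up -> `mRNA_down_translation_up`
#' 2. mRNA up & translation down -> `mRNA_up_translation_down`
#' 3. protein up & mRNA none -> `protein_up_mRNA_flat`
#' 4. protein down & mRNA none -> `protein_down_mRNA_flat`
#' 5. protein up & mRNA down -> `protein_up_mRNA_down`
#' 6. protein down & mRNA up -> `protein_down_mRNA_up`
#' 7. at least one level changed and all changed levels agree ->
#'    `concordant`
#' 8. otherwise (including genes flat at every level) -> `unclassified`
#'
#' Genes absent at a level are treated as `"none"` there and flagged.
#'
#' @param mrna_calls Tibble with `gene_id`, `direction` (from
#'   [call_mrna_direction()]).
#' @param translation_calls Tibble with `gene_id`, `direction` (from
#'   [call_translation()]; multiple stress times are collapsed to the
#'   majority non-none direction, ties -> none).
#' @param protein_fits A `polystress_temporal_fits` tibble (or any tibble
#'   with `protein_id`, `category`, `fitted_max_change`).
#' @return Tibble: `gene_id`, `mrna`, `translation`, `protein` (directions)
#'   `class`, and `incomplete` (TRUE when a level was missing).
#' @examples
#' classify_discordance(
#'   tibble::tibble(gene_id = "g1", direction = "down"),
#'   tibble::tibble(gene_id = "g1", direction = "up"),
#'   tibble::tibble(protein_id = "g1", category = "unchanged",
#'                  fitted_max_change = 0))
#' @export
classify_discordance <- function(mrna_calls, translation_calls,
                                 protein_fits) {
  collapse_calls <- function(df) {
    dplyr::summarise(
      dplyr::group_by(df, .data$gene_id),
      direction = {
        d <- .data$direction[.data$direction != "none"]
        if (!length(d)) "none"
        else if (sum(d == "up") > sum(d == "down")) "up"
        else if (sum(d == "down") > sum(d == "up")) "down"
        else "none"
      }, .groups = "drop")
  }
  m <- collapse_calls(mrna_calls)
  t <- collapse_calls(translation_calls)
  p <- tibble::tibble(
    gene_id = protein_fits$protein_id,
    direction = collapse_protein_category(protein_fits$category,
                                          protein_fits$fitted_max_change))
  universe <- unique(c(m$gene_id, t$gene_id, p$gene_id))
  lk <- function(df) {
    d <- df$direction[match(universe, df$gene_id)]
    ifelse(is.na(d), "none", d)
  }
  md <- lk(m); td <- lk(t); pd <- lk(p)
  incomplete <- !(universe %in% m$gene_id) | !(universe %in% t$gene_id) |
    !(universe %in% p$gene_id)

  concord <- vapply(seq_along(universe), function(i) {
    ds <- c(md[i], td[i], pd[i])
    ds <- ds[ds != "none"]
    length(ds) > 0 && length(unique(ds)) == 1L
  }, logical(1))

  cls <- dplyr::case_when(
    md == "down" & td == "up" ~ "mRNA_down_translation_up",
    md == "up" & td == "down" ~ "mRNA_up_translation_down",
    pd == "up" & md == "none" ~ "protein_up_mRNA_flat",
    pd == "down" & md == "none" ~ "protein_down_mRNA_flat",
    pd == "up" & md == "down" ~ "protein_up_mRNA_down",
    pd == "down" & md == "up" ~ "protein_down_mRNA_up",
    concord ~ "concordant",
    TRUE ~ "unclassified")

  tibble::tibble(gene_id = universe, mrna = md, translation = td,
                 protein = pd, class = cls, incomplete = incomplete)
}

#' Correlate paired per-gene changes
#'
#' Pearson (with the two-tailed t approximation) or Spearman rank
#' correlation of two paired per-gene vectors, as used to compare changes
#' across regulatory levels.
#'
#' @param x,y Paired numeric vectors (pairs with a missing value are
#'   dropped).
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row tibble: `r`, `p_value`, `n`, `method`.
#' @examples
#' correlate_changes(1:10, 2 * (1:10) + rnorm(10, 0, 0.1))
#' @export
correlate_changes <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance: correlation undefined")
  }
  ct <- suppressWarnings(cor.test(x, y, method = method,
                                  alternative = "two.sided"))
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), method = method)
}

#' Combine mRNA and translation changes
#'
#' The product of linear-scale mRNA fold change and translation ratio per
#' gene, an estimate of the combined change in protein synthesis input.
#'
#' @param mrna_fold Linear-scale mRNA fold changes (> 0).
#' @param translation_ratio Translation ratios (> 0).
#' @return Numeric vector of combined fold changes.
#' @examples
#' combine_mrna_translation(2, 1.5)
#' @export
combine_mrna_translation <- function(mrna_fold, translation_ratio) {
  if (any(!is.finite(mrna_fold)) || any(!is.finite(translation_ratio)) ||
      any(mrna_fold <= 0) || any(translation_ratio <= 0)) {
    abort("fold changes and ratios must be positive and finite")
  }
  mrna_fold * translation_ratio
}

#' Signed maximum change of a trajectory
#'
#' The value with the largest absolute magnitude across the time course,
#' keeping its sign (ties: first occurrence).
#'
#' @param trajectory Numeric vector of (log2) changes.
#' @return A single signed value.
#' @examples
#' max_change(c(-1.2, 0.8))
#' @export
max_change <- function(trajectory) {
  trajectory <- trajectory[!is.na(trajectory)]
  if (!length(trajectory)) abort("empty trajectory")
  trajectory[which.max(abs(trajectory))]
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric probability P(X >= k) of drawing `k` or more
#' genes of a set of size `K` when sampling `n` genes from a universe of
#' size `N` without replacement — the classical over-representation test
#' for functional lists or ontology terms. Raw p-values are reported by
#' default; Benjamini-Hochberg adjustment across sets is optional.
#'
#' @param query Character vector of query gene ids (deduplicated; ids
#'   outside the universe are dropped with a warning).
#' @param sets Named list of character vectors (each intersected with the
#'   universe).
#' @param universe Character vector of all testable gene ids.
#' @param adjust Apply Benjamini-Hochberg adjustment across sets.
#' @return Tibble: `set_name`, `k`, `K`, `n`, `N`, `p_value` (and
#'   `p_adjusted` if requested), ordered by `p_value`.
#' @examples
#' hypergeom_enrichment(c("a", "b"), list(s = c("a", "b", "c")),
#'                      universe = letters[1:10])
#' @export
hypergeom_enrichment <- function(query, sets, universe, adjust = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) abort("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn(sprintf("%d query id(s) outside the universe dropped",
                 length(outside)))
    query <- intersect(query, universe)
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be a named list")
  }
  N <- length(universe); n <- length(query)
  res <- purrr::imap(sets, function(genes, nm) {
    g <- intersect(unique(genes), universe)
    K <- length(g)
    k <- length(intersect(query, g))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set_name = nm, k = k, K = K, n = n, N = N, p_value = p)
  })
  out <- dplyr::bind_rows(res)
  if (adjust) out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_value)
}

#' Cluster genes by Spearman-correlation distance
#'
#' Average-linkage hierarchical clustering of gene rows with distance
#' `1 - Spearman correlation`, so the tree is invariant to monotone
#' transformations of each row. Rows are put in a canonical order (by
#' `gene_id`) before clustering, making the result independent of input row
#' order; constant rows have undefined rank correlation and are dropped
#' with a warning.
#'
#' @param mat A tibble whose first column is `gene_id` and remaining
#'   columns are numeric ratios, or a numeric matrix with rownames.
#' @return A list of class `polystress_tree`: `hclust` (the tree),
#'   `leaf_order` (gene ids in dendrogram order), `dropped` (constant-row
#'   ids).
#' @examples
#' m <- tibble::tibble(gene_id = c("a", "b", "c"),
#'                     t1 = c(1, 1, 3), t2 = c(2, 2, 2), t3 = c(3, 3, 1))
#' cluster_genes(m)$leaf_order
#' @export
cluster_genes <- function(mat) {
  if (is.data.frame(mat)) {
    ids <- as.character(mat[[1]])
    m <- as.matrix(mat[, -1, drop = FALSE])
    rownames(m) <- ids
  } else {
    m <- as.matrix(mat)
    if (is.null(rownames(m))) abort("matrix input needs rownames")
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort("need at least 2 genes and 2 columns to cluster")
  }
  m <- m[order(rownames(m)), , drop = FALSE]
  const <- apply(m, 1L, function(r) sd(r, na.rm = TRUE) == 0 || all(is.na(r)))
  const[is.na(const)] <- TRUE
  dropped <- rownames(m)[const]
  if (any(const)) {
    warn(sprintf("%d constant row(s) dropped before clustering", sum(const)))
    m <- m[!const, , drop = FALSE]
  }
  if (nrow(m) < 2L) abort("fewer than 2 non-constant rows left")
  d <- as.dist(1 - cor(t(m), method = "spearman", use = "pairwise.complete.obs"))
  hc <- hclust(d, method = "average")
  structure(list(hclust = hc,
                 leaf_order = hc$labels[hc$order],
                 dropped = dropped),
            class = "polystress_tree")
}

#' @export
print.polystress_tree <- function(x, ...) {
  cat("<polystress_tree>", length(x$leaf_order), "leaves;",
      length(x$dropped), "constant row(s) dropped\n")
  invisible(x)
}

#' Write a clustering tree in newick format
#'
#' @param tree A `polystress_tree` from [cluster_genes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' m <- tibble::tibble(gene_id = c("a", "b", "c"),
#'                     t1 = c(1, 1, 3), t2 = c(2, 2, 2), t3 = c(3, 3, 1))
#' f <- tempfile(fileext = ".nwk")
#' write_tree_newick(cluster_genes(m), f)
#' readLines(f)
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "polystress_tree"))
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
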