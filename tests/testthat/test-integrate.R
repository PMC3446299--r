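test_that("mRNA direction calls use a strict fold cutoff over pooled times", {
  seven <- tibble::tibble(
    gene_id = "gA", experiment = c("mrna1", "mrna1", rep("mrna2", 5)),
    time_min = c(15, 60, 15, 30, 60, 120, 180),
    log2_ratio = c(1, 1, 1, 1, 0, 0, 0))
  expect_equal(call_mrna_direction(seven)$direction, "up")
  # exactly 1.5-fold everywhere fails the strict > rule
  boundary <- dplyr::mutate(seven, log2_ratio = log2(1.5))
  expect_equal(call_mrna_direction(boundary)$direction, "none")
  flat <- dplyr::mutate(seven, log2_ratio = 0)
  expect_equal(call_mrna_direction(flat)$direction, "none")
  three <- dplyr::mutate(seven, log2_ratio = c(-1, -1, -1, 0, 0, 0, 0))
  expect_equal(call_mrna_direction(three)$direction, "none")
  four <- dplyr::mutate(seven, log2_ratio = c(-1, -1, -1, -1, 0, 0, 0))
  expect_equal(call_mrna_direction(four)$direction, "down")
})

test_that("raising the cutoffs never adds called genes", {
  set.seed(41)
  mrna <- tidyr::expand_grid(gene_id = sprintf("g%03d", 1:60),
                             experiment = "mrna2",
                             time_min = c(15, 30, 60, 120, 180))
  mrna$log2_ratio <- rnorm(nrow(mrna), 0, 1)
  called <- function(fc, mt) {
    calls <- call_mrna_direction(mrna, fold_cutoff = fc, min_timepoints = mt)
    calls$gene_id[calls$direction != "none"]
  }
  expect_true(all(called(2, 3) %in% called(1.5, 3)))
  expect_true(all(called(1.5, 4) %in% called(1.5, 3)))
})

test_that("missing values never count as passing", {
  x <- tibble::tibble(gene_id = "g1", experiment = "e",
                      time_min = c(15, 30, 60, 120),
                      log2_ratio = c(2, 2, 2, NA))
  expect_equal(call_mrna_direction(x, min_timepoints = 4)$direction, "none")
  allna <- dplyr::mutate(x, log2_ratio = NA_real_)
  expect_warning(out <- call_mrna_direction(allna), "missing|no mRNA")
  expect_equal(out$direction, "none")
})

test_that("the discordance rule table reproduces the documented classes", {
  mk <- function(m, t, p_cat, p_max = if (p_cat == "unchanged") 0 else 1) {
    classify_discordance(
      tibble::tibble(gene_id = "g", direction = m),
      tibble::tibble(gene_id = "g", direction = t),
      tibble::tibble(protein_id = "g", category = p_cat,
                     fitted_max_change = p_max))$class
  }
  expect_equal(mk("down", "up", "unchanged"), "mRNA_down_translation_up")
  expect_equal(mk("up", "down", "unchanged"), "mRNA_up_translation_down")
  expect_equal(mk("none", "none", "linear_up"), "protein_up_mRNA_flat")
  expect_equal(mk("none", "none", "linear_down", -1), "protein_down_mRNA_flat")
  expect_equal(mk("down", "none", "linear_up"), "protein_up_mRNA_down")
  expect_equal(mk("up", "none", "linear_down", -1), "protein_down_mRNA_up")
  expect_equal(mk("up", "up", "linear_up"), "concordant")
  expect_equal(mk("up", "none", "unchanged"), "concordant")
  expect_equal(mk("none", "none", "unchanged"), "unclassified")
  # quadratic categories collapse by the sign of the fitted extreme
  expect_equal(mk("none", "none", "quadratic_concave", 1.2),
               "protein_up_mRNA_flat")
  expect_equal(mk("none", "none", "quadratic_convex", -0.9),
               "protein_down_mRNA_flat")
})

test_that("discordance classes partition the shared gene universe", {
  set.seed(42)
  genes <- sprintf("g%03d", 1:80)
  dirs <- c("up", "down", "none")
  cats <- c("linear_up", "linear_down", "quadratic_convex",
            "quadratic_concave", "unchanged")
  m <- tibble::tibble(gene_id = genes, direction = sample(dirs, 80, TRUE))
  t <- tibble::tibble(gene_id = sample(genes, 70),
                      direction = sample(dirs, 70, TRUE))
  cat_p <- sample(cats, 75, TRUE)
  p <- tibble::tibble(protein_id = sample(genes, 75), category = cat_p,
                      fitted_max_change =
                        ifelse(cat_p == "unchanged", 0,
                               sample(c(-1, 1), 75, TRUE)))
  out <- classify_discordance(m, t, p)
  expect_setequal(out$gene_id, genes)
  expect_equal(anyDuplicated(out$gene_id), 0L)
  expect_true(all(!is.na(out$class)))
  expect_true(any(out$incomplete))
})

test_that("correlations match their textbook cases", {
  x <- 1:10
  expect_equal(correlate_changes(x, 2 * x + 1)$r, 1)
  sp <- correlate_changes(x, rev(x), method = "spearman")
  expect_equal(sp$r, -1)
  expect_error(correlate_changes(x, rep(1, 10)), "zero variance")
  expect_error(correlate_changes(1:2, 1:2), "3 complete pairs")
})

test_that("combined change is the product of linear-scale changes", {
  expect_equal(combine_mrna_translation(2, 1), 2)
  expect_equal(combine_mrna_translation(2, 1.5), 3)
  expect_equal(combine_mrna_translation(c(2, 4), c(0.5, 1)), c(1, 4))
  expect_error(combine_mrna_translation(-2, 1), "positive")
  expect_error(combine_mrna_translation(2, 0), "positive")
})

test_that("max_change keeps the sign of the largest magnitude", {
  expect_equal(max_change(c(0.2, 1.0, 0.5)), 1.0)
  expect_equal(max_change(c(-1.2, 0.8)), -1.2)
  expect_equal(max_change(c(0, 0, 0)), 0)
  expect_equal(max_change(c(NA, -2, 1)), -2)
  expect_error(max_change(numeric(0)), "empty")
})

test_that("hypergeometric tail matches exhaustive draw enumeration", {
  # all C(10,5) query draws from a 10-gene universe against a 5-gene set
  universe <- letters[1:10]
  set5 <- letters[1:5]
  draws <- utils::combn(universe, 5)
  k_obs <- apply(draws, 2, function(d) length(intersect(d, set5)))
  for (k in 0:5) {
    enum_p <- mean(k_obs >= k)
    # package p for a query achieving exactly k overlap
    q <- c(set5[seq_len(k)], setdiff(universe, set5)[seq_len(5 - k)])
    got <- hypergeom_enrichment(q, list(s = set5), universe)$p_value
    expect_equal(got, enum_p, tolerance = 1e-12)
  }
  # the fully-overlapping draw: 1 of choose(10,5) = 1/252
  got <- hypergeom_enrichment(set5, list(s = set5), universe)$p_value
  expect_equal(got, 1 / 252, tolerance = 1e-12)
})

test_that("enrichment edge cases behave", {
  u <- letters[1:10]
  expect_equal(hypergeom_enrichment(u, list(s = u), u)$p_value, 1)
  expect_equal(hypergeom_enrichment(character(0), list(s = u[1:3]),
                                    u)$p_value, 1)
  expect_error(hypergeom_enrichment("a", list(s = "a"), character(0)),
               "empty universe")
  expect_warning(hypergeom_enrichment(c("a", "zz"), list(s = u[1:3]), u),
                 "outside")
  adj <- hypergeom_enrichment(u[1:4], list(s1 = u[1:4], s2 = u[5:8]), u,
                              adjust = TRUE)
  expect_true("p_adjusted" %in% names(adj))
  expect_equal(adj$p_adjusted,
               stats::p.adjust(adj$p_value, method = "BH"))
})

test_that("clustering groups rank-identical rows first", {
  m <- tibble::tibble(gene_id = c("a", "b", "c"),
                      t1 = c(1, 10, 3), t2 = c(2, 20, 2), t3 = c(3, 30, 1))
  tree <- cluster_genes(m)
  # a and b are rank-identical (distance 0) and must merge first
  first_merge <- tree$hclust$merge[1, ]
  merged <- tree$hclust$labels[-first_merge]
  expect_setequal(merged, c("a", "b"))
  expect_equal(tree$hclust$height[1], 0)
})

test_that("clustering is invariant to row order and monotone transforms", {
  set.seed(44)
  m <- tibble::tibble(gene_id = sprintf("g%02d", 1:12))
  vals <- matrix(rnorm(12 * 5), 12, 5)
  m <- dplyr::bind_cols(m, tibble::as_tibble(vals, .name_repair = "minimal"))
  names(m)[-1] <- paste0("t", 1:5)
  t1 <- cluster_genes(m)
  t2 <- cluster_genes(m[sample(12), ])
  expect_identical(t1$hclust$merge, t2$hclust$merge)
  expect_identical(t1$leaf_order, t2$leaf_order)
  # monotone transform of every row leaves Spearman distances unchanged
  m3 <- m
  m3[, -1] <- exp(m3[, -1])
  t3 <- cluster_genes(m3)
  expect_identical(t1$hclust$merge, t3$hclust$merge)
  expect_equal(t1$hclust$height, t3$hclust$height)
})

test_that("constant rows are dropped with a warning and trees export to newick", {
  m <- tibble::tibble(gene_id = c("a", "b", "c"),
                      t1 = c(1, 1, 3), t2 = c(2, 1, 2), t3 = c(3, 1, 1))
  expect_warning(tree <- cluster_genes(m), "constant")
  expect_equal(tree$dropped, "b")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tree, f)
  nwk <- readLines(f)
  expect_match(nwk, "^\\(")
  expect_true(all(c("a", "c") %in%
                    ape::read.tree(text = nwk)$tip.label))
  expect_error(cluster_genes(m[1, ]), "at least 2")
})
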