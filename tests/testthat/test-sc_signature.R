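test_that("filter_cells applies both QC rules and is idempotent", {
  genes <- c(sprintf("G%03d", 1:300), "MT-A", "MT-B")
  set.seed(5)
  counts <- matrix(rpois(302 * 4, 3), 302, 4,
                   dimnames = list(genes, paste0("c", 1:4)))
  # c1: only 150 detected genes; c2: 35% mito; c3: healthy; c4: healthy
  counts[151:302, 1] <- 0                      # c1 detects at most 150 genes
  counts["MT-A", 2] <- round(sum(counts[, 2]) * 0.6)
  cd <- cell_data(counts)
  expect_true(all(cd$gene_meta$mito == grepl("^MT-", genes)))
  kept <- filter_cells(cd, min_genes = 200, max_mito_frac = 0.30)
  expect_false("c1" %in% colnames(kept$counts))
  expect_false("c2" %in% colnames(kept$counts))
  expect_true(all(c("c3", "c4") %in% colnames(kept$counts)))
  rep1 <- attr(kept, "filter_report")
  expect_equal(rep1$kept, 2)
  # idempotence
  again <- filter_cells(kept, min_genes = 200, max_mito_frac = 0.30)
  expect_equal(again$counts, kept$counts)
  expect_error(filter_cells(cd, min_genes = 1e5), "all .* cells dropped|all 4 cells")
})

test_that("lognormalize equalizes library sizes", {
  counts <- matrix(c(10, 0, 0,   5, 5, 0,  2, 2, 2), 3, 3,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3")))
  cd <- lognormalize(cell_data(counts), scale = 1e4)
  # all counts in one gene -> log(1 + 1e4)
  expect_equal(cd$lognorm["g1", "c1"], log(1 + 1e4))
  # proportional cells get identical columns
  prop <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2,
                 dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  cdp <- lognormalize(cell_data(prop))
  expect_equal(cdp$lognorm[, "a"], cdp$lognorm[, "b"])
  # conservation: column sums of exp(lognorm) - 1 all equal scale
  expect_equal(unname(colSums(exp(cd$lognorm) - 1)), rep(1e4, 3))
  zero <- counts; zero[, 2] <- 0
  expect_error(lognormalize(cell_data(zero)), "zero-total")
})

test_that("module_score is zero on constant data and detects spiked modules", {
  genes <- sprintf("G%03d", 1:200)
  const <- matrix(2, 200, 50, dimnames = list(genes, paste0("c", 1:50)))
  cd <- cell_data(const)
  cd$lognorm <- const
  sc <- module_score(cd, genes[1:10], seed = 1)
  expect_equal(max(abs(sc)), 0)

  # spike signature genes +2 log-units in half the cells
  cells <- make_null_cells(n_genes = 300, n_cells = 400, seed = 2)
  cells <- lognormalize(cells)
  sig_genes <- rownames(cells$lognorm)[1:10]
  spiked <- cells
  spiked$lognorm[sig_genes, 201:400] <- spiked$lognorm[sig_genes, 201:400] + 2
  sc2 <- module_score(spiked, sig_genes, seed = 3)
  mw <- group_compare(sc2, factor(rep(c("lo", "hi"), each = 200),
                                  levels = c("hi", "lo")))
  expect_lt(mw$p, 0.01)
  expect_gt(mean(sc2[201:400]), mean(sc2[1:200]))

  # determinism and seed sensitivity stay bounded
  expect_identical(module_score(cells, sig_genes, seed = 7),
                   module_score(cells, sig_genes, seed = 7))
  s_a <- module_score(spiked, sig_genes, seed = 7)
  s_b <- module_score(spiked, sig_genes, seed = 8)
  expect_lt(mean(abs(s_a - s_b)) / sd(s_a), 0.1)

  expect_error(module_score(cells, c("NOPE1", "NOPE2")), "NOPE1")
})

test_that("random gene sets on unstructured data score near zero", {
  cells <- lognormalize(make_null_cells(n_genes = 400, n_cells = 150, seed = 4))
  means <- sigscreen:::with_seed(99, {
    vapply(1:100, function(i) {
      gs <- sample(rownames(cells$lognorm), 10)
      mean(module_score(cells, gs, seed = i))
    }, numeric(1))
  })
  expect_lt(abs(mean(means)), 0.05)
})

test_that("stratify follows the median tie policy and threshold rule", {
  expect_equal(as.character(stratify(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(stratify(c(1, 2, 2, 3))),
               c("low", "low", "low", "high"))     # tied 2s go low
  expect_equal(as.character(stratify(c(-1, 1), rule = "threshold", cutoff = 0)),
               c("low", "high"))
  expect_error(stratify(c(2, 2, 2)), "threshold")
})

test_that("composition_test matches the hand chi-square and sums to 1", {
  lab <- rep(c("A", "B"), c(30, 30))
  ty <- c(rep("x", 10), rep("y", 20), rep("x", 20), rep("y", 10))
  res <- composition_test(lab, ty)
  expect_equal(res$chisq, 20 / 3, tolerance = 1e-12)  # 6.667 by hand, E = 15
  expect_equal(res$df, 1)
  expect_equal(unname(rowSums(res$proportions)), c(1, 1), tolerance = 1e-12)

  # identical composition: statistic 0, p = 1
  same <- composition_test(rep(c("A", "B"), each = 20),
                           rep(c("x", "y"), times = 20))
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)

  tiny <- composition_test(rep(c("A", "B"), c(2, 8)),
                           c("x", rep("y", 9)))   # expected A/x cell = 0.2
  expect_match(tiny$warning, "expected")
})

test_that("group_compare: exact enumeration, ties, and the AUC identity", {
  res <- group_compare(c(1, 2, 3, 4), factor(rep(c("a", "b"), each = 2),
                                             levels = c("a", "b")))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3)          # 2/6 orderings as extreme
  expect_equal(res$method, "exact")

  # identical groups -> degenerate, p = 1
  same <- group_compare(rep(5, 10), factor(rep(c("a", "b"), 5)))
  expect_equal(same$p, 1)

  # exact matches enumeration oracle across small group sizes
  set.seed(31)
  for (n1 in 2:4) for (n2 in 2:4) {
    x <- sample(100, n1); y <- sample(200, n2) + 0.5
    got <- group_compare(c(x, y), factor(rep(c("a", "b"), c(n1, n2)),
                                         levels = c("a", "b")))
    expect_equal(got$p, oracle_mw_exact(x, y), tolerance = 1e-12)
  }

  # U / (n1 n2) equals the ROC AUC of the same data
  set.seed(32)
  sc <- c(rnorm(20, 1), rnorm(15))
  lab <- rep(c(1, 0), c(20, 15))
  u <- group_compare(sc, factor(lab, levels = c(1, 0)))$U
  expect_equal(u / (20 * 15), roc_auc(sc, lab)$auc)

  # normal and exact branches agree near the crossover
  set.seed(33)
  x <- rnorm(8); y <- rnorm(8, 0.5)
  pe <- group_compare(c(x, y), factor(rep(c("a", "b"), each = 8)))$p
  pn <- group_compare(c(x, y), factor(rep(c("a", "b"), each = 8)),
                      exact_max = 0)$p
  expect_lt(abs(pe - pn), 0.01 + 0.05 * pe)
})

test_that("correlate reproduces textbook values", {
  expect_equal(correlate(1:5, 2 * (1:5) + 1)$estimate, 1)
  x <- c(1, 2, 3, 4.5, 7)
  sp <- correlate(x, x^3, "spearman")
  expect_equal(sp$estimate, 1)
  expect_lt(correlate(x, x^3, "pearson")$estimate, 1)
  expect_equal(correlate(c(1, 2, 3), c(3, 1, 2), "spearman")$estimate, -0.5)
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("patient_aggregate averages the right cells and warns on dropouts", {
  counts <- matrix(c(1, 1, 1, 1), 1, 4,
                   dimnames = list("CXCL1", paste0("c", 1:4)))
  meta <- data.frame(cell_id = paste0("c", 1:4),
                     patient = c("p1", "p1", "p2", "p2"),
                     cell_type = c("tumor", "tumor", "tumor", "Tcell"))
  cd <- cell_data(counts, cell_meta = meta)
  cd$lognorm <- matrix(c(1, 3, 2, 9), 1, 4, dimnames = dimnames(counts))
  agg <- patient_aggregate(cd, "CXCL1", cell_subset = "tumor")
  expect_equal(unname(agg[c("p1", "p2")]), c(2, 2))
  # permuting cells leaves the answer unchanged
  perm <- c(4, 2, 1, 3)
  cd2 <- cell_data(counts[, perm, drop = FALSE],
                   cell_meta = meta[perm, ])
  cd2$lognorm <- cd$lognorm[, perm, drop = FALSE]
  expect_equal(patient_aggregate(cd2, "CXCL1", "tumor")[c("p1", "p2")],
               agg[c("p1", "p2")])
  # subset excluding all of p2's cells drops p2 with a warning
  meta3 <- meta; meta3$cell_type <- c("tumor", "tumor", "Tcell", "Tcell")
  cd3 <- cell_data(counts, cell_meta = meta3); cd3$lognorm <- cd$lognorm
  expect_warning(agg3 <- patient_aggregate(cd3, "CXCL1", "tumor"), "p2")
  expect_false("p2" %in% names(agg3))
})

test_that("spot_coexpression labels spots and counts the both fraction", {
  spots <- matrix(c(1, 0, 2, 0,  1, 1, 0, 0), 4, 2,
                  dimnames = list(paste0("s", 1:4), c("A", "B")))
  res <- spot_coexpression(spots, "A", "B")
  expect_equal(as.character(res$label), c("both", "b_only", "a_only", "none"))
  expect_equal(res$fraction, 0.25)
  none <- spots; none[, "A"] <- 0
  expect_equal(spot_coexpression(none, "A", "B")$fraction, 0)
  all_on <- spots; all_on[] <- 1
  expect_equal(spot_coexpression(all_on, "A", "B")$fraction, 1)
  expect_error(spot_coexpression(spots, "A", "Z"), "absent")
})
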