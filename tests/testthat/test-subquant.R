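test_that("column classification matches the stated substitution rules", {
  # transition vs transversion against the dominant base
  c1 <- classify_column(c(a = "A", b = "A", c = "G"))
  expect_equal(c1$dominant, "A")
  expect_equal(unname(c1$labels), c("C", "C", "S"))
  c2 <- classify_column(c(a = "A", b = "A", c = "C"))
  expect_equal(unname(c2$labels), c("C", "C", "V"))
  # degenerate dominant on ties: first base in A<C<G<T order is the
  # conserved designate, the other tie member a transition/transversion
  c3 <- classify_column(c(a = "A", b = "G"))
  expect_equal(c3$dominant, "R")
  expect_equal(unname(c3$labels), c("C", "S"))
  c4 <- classify_column(c(a = "C", b = "A"))
  expect_equal(c4$dominant, "M")
  expect_equal(unname(c4$labels[c("a", "b")]), c("V", "C"))
  # gap tied with the commonest substitution resolves to deletion
  c5 <- classify_column(c("A", "A", "A", "-", "G"))
  expect_equal(unname(c5$labels), c("C", "C", "C", "D", "S"))
  # gap-dominated column: bases are insertions
  c6 <- classify_column(c("-", "-", "-", "A", "G"))
  expect_equal(c6$dominant, "-")
  expect_equal(unname(c6$labels), c("C", "C", "C", "I", "I"))
  expect_error(classify_column(c("-", "-")), "vacuous")
  expect_error(classify_column(c("A", "B")), "invalid")
})

test_that("classification agrees with the exhaustive rule-table oracle", {
  syms <- c("A", "C", "G", "T", "-")
  for (n in 2:5) {
    grid <- do.call(expand.grid, rep(list(syms), n))
    for (r in seq_len(nrow(grid))) {
      col <- as.character(unlist(grid[r, ]))
      if (all(col == "-")) next
      got <- classify_column(col)
      exp <- oracle_classify(col)
      expect_identical(unname(got$labels), exp$labels,
                       label = paste(col, collapse = ""))
      expect_identical(got$dominant, exp$dominant,
                       label = paste(col, collapse = ""))
    }
  }
})

test_that("classification counts are permutation-invariant and sum to n", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(3:10, 1)
    col <- sample(c("A", "C", "G", "T", "-"), n, TRUE)
    if (all(col == "-")) col[1] <- "A"
    cl <- classify_column(col)
    expect_equal(sum(cl$counts), n)
    perm <- sample(n)
    cl2 <- classify_column(col[perm])
    expect_equal(cl2$counts, cl$counts)
    # conserved count at least as large as any single non-dominant base
    bases <- col[col != "-"]
    if (cl$dominant != "-") {
      nd <- table(bases[bases != sort(names(which.max(table(bases))))[1]])
      if (length(nd)) expect_gte(cl$counts[["C"]], max(nd))
    }
  }
})

test_that("count-ranked weights follow the fixed grid and are monotone", {
  w <- assign_weights(c(C = 40, V = 16, S = 14, D = 5, I = 3))
  expect_equal(unclass(w), c(C = 0, V = 0.25, S = 0.5, D = 0.75, I = 1))
  # monotone: larger count, smaller weight
  set.seed(17)
  for (rep in 1:25) {
    tot <- setNames(sample(0:50, 5), c("C", "S", "V", "D", "I"))
    w <- unclass(assign_weights(tot))
    for (a in names(tot)) for (b in names(tot)) {
      if (tot[[a]] > tot[[b]]) expect_lt(w[[a]], w[[b]])
    }
  }
  # tie broken by the fixed order C, V, S, D, I
  wt <- unclass(assign_weights(c(C = 10, S = 10)))
  expect_equal(wt[["C"]], 0)
  expect_equal(wt[["S"]], 0.25)
  # substitution-only mode uses the fixed weights
  ws <- unclass(assign_weights(c(S = 100, V = 1), substitution_only = TRUE))
  expect_equal(ws[["S"]], 0.25)
  expect_equal(ws[["V"]], 0.5)
  expect_equal(ws[["C"]], 0)
  expect_error(assign_weights(c(C = 1, S = 1, V = 1, D = 1, I = 1, X = 1)),
               "categor")
})

test_that("weighted profiles equal a hand summation on a toy alignment", {
  rows <- c(s1 = "AAAGGTACGT", s2 = "AAAGGTACGT", s3 = "GAAGGTAC-T",
            s4 = "AACGGTACGT")
  dom <- c(rep("A-stem5'", 3), rep("D-loop", 4), rep("T-loop", 3))
  al <- gene_alignment(rows, column_domain = dom)
  cl <- classify_alignment(al)
  w <- assign_weights(cl$totals[cl$totals > 0])
  pr <- weighted_profile(cl, w)
  # independent column-by-column recount
  wt <- unclass(w)
  mat <- al$matrix
  exp_snp <- 0; exp_indel <- 0
  sp_sum <- setNames(numeric(4), rownames(mat))
  for (j in seq_len(ncol(mat))) {
    labs <- oracle_classify(mat[, j])$labels
    vals <- wt[labs]
    exp_snp <- exp_snp + sum(vals[labs %in% c("S", "V")])
    exp_indel <- exp_indel + sum(vals[labs %in% c("D", "I")])
    sp_sum <- sp_sum + unname(vals)
  }
  expect_equal(pr$snp_total, exp_snp)
  expect_equal(pr$indel_total, exp_indel)
  expect_equal(pr$species_weighted, sp_sum)
  expect_equal(pr$species_ratio, sp_sum / 10)
  expect_equal(sum(pr$domain_totals$snp) + sum(pr$domain_totals$indel),
               exp_snp + exp_indel)
  # all-conserved alignment gives zero totals
  al0 <- gene_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"),
                        column_domain = rep("A-stem5'", 4))
  cl0 <- classify_alignment(al0)
  pr0 <- weighted_profile(cl0, assign_weights(cl0$totals[cl0$totals > 0]))
  expect_equal(pr0$snp_total, 0)
  expect_equal(pr0$indel_total, 0)
  # missing domain labels are an error
  expect_error(weighted_profile(cl$classifications, w, column_domain = NULL),
               "domain")
})

test_that("z-score categorization is normalized and maps the four quadrants", {
  x <- c(t1 = 10, t2 = 0, t3 = 9, t4 = 1, t5 = 2)
  y <- c(t1 = 9, t2 = 1, t3 = 0, t4 = 10, t5 = 2)
  zc <- zscore_categorize(x, y)
  expect_equal(mean(zc$z_ci), 0, tolerance = 1e-9)
  expect_equal(stats::sd(zc$z_ci), 1, tolerance = 1e-9)
  expect_equal(mean(zc$z_ht), 0, tolerance = 1e-9)
  expect_equal(stats::sd(zc$z_ht), 1, tolerance = 1e-9)
  # quadrants: hyper/hypo by z sign in each cohort
  expect_equal(zc$category[zc$trna == "t1"], 1L)  # high in both
  expect_equal(zc$category[zc$trna == "t2"], 2L)  # low in both
  expect_equal(zc$category[zc$trna == "t3"], 3L)  # high Ci, low Ht
  expect_equal(zc$category[zc$trna == "t4"], 4L)  # low Ci, high Ht
  # extreme flag at |z| >= 1
  expect_equal(zc$extreme_ci, abs(zc$z_ci) >= 1)
  expect_error(zscore_categorize(c(a = 1, b = 1), c(a = 1, b = 2)),
               "degenerate")
  expect_error(zscore_categorize(c(1, 2), c(2, 1)), "named")
})
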