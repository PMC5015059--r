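test_that("CV uses the sample SD over all cells, zeros included", {
  expect_equal(coefficientOfVariation(rep(7, 10)), 0)
  # a single positive value among C cells gives cv = sqrt(C) exactly
  expect_equal(coefficientOfVariation(c(5, 0, 0)), sqrt(3), tolerance = 1e-12)
  for (C in c(2, 17, 96, 200)) {
    v <- c(runif(1, 1, 50), rep(0, C - 1))
    expect_equal(coefficientOfVariation(v), sqrt(C), tolerance = 1e-12)
  }
  # seeded 96-cell vector against a two-pass mean/variance computation
  set.seed(55)
  v <- rlnorm(96, 1, 1) * rbinom(96, 1, 0.4)
  m <- sum(v) / 96
  s2 <- sum((v - m)^2) / 95
  expect_equal(coefficientOfVariation(v), sqrt(s2) / m, tolerance = 1e-12)
  expect_error(coefficientOfVariation(rep(0, 5)), "mean")
  expect_error(coefficientOfVariation(3), "2 cells")
})

test_that("CV is scale invariant", {
  set.seed(8)
  for (rep in 1:20) {
    v <- rlnorm(50, 1, 0.8) * rbinom(50, 1, 0.5)
    if (sum(v) == 0) next
    for (c in c(1e-3, 0.7, 1, 42, 1e6))
      expect_equal(coefficientOfVariation(c * v), coefficientOfVariation(v),
                   tolerance = 1e-12)
  }
})

test_that("expressed genes stratify on the 30 FPKM boundary", {
  m <- rbind(
    silent = c(2, 1, 0, 0),
    atBoundary = c(30, 5, 0, 0),
    justOver = c(30.01, 5, 0, 0),
    moderate = c(10, 4, 0, 0)
  )
  colnames(m) <- paste0("c", 1:4)
  rec <- stratifyExpressedGenes(m)
  expect_false("silent" %in% rec$gene_id)
  expect_equal(rec$stratum[rec$gene_id == "atBoundary"], "moderate")
  expect_equal(rec$stratum[rec$gene_id == "justOver"], "high")
  expect_equal(rec$stratum[rec$gene_id == "moderate"], "moderate")
  # cv recomputes from the rows
  expect_equal(rec$cv[rec$gene_id == "moderate"],
               coefficientOfVariation(m["moderate", ]), tolerance = 1e-12)

  # 20-gene fixture: stratum labels equal hand assignment by the maximum
  set.seed(13)
  mm <- matrix(rlnorm(20 * 8, 1.5, 1.2), 20, 8,
               dimnames = list(paste0("g", 1:20), paste0("c", 1:8)))
  rec <- stratifyExpressedGenes(mm)
  mx <- apply(mm, 1, max)
  keep <- mx > 3
  expect_setequal(rec$gene_id, names(mx)[keep])
  expect_identical(rec$stratum,
                   unname(ifelse(mx[rec$gene_id] <= 30, "moderate", "high")))
})

test_that("welchTest matches long-form textbook arithmetic", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 10)
  got <- welchTest(x, y)
  ref <- handWelch(x, y)
  expect_equal(got$t_statistic, ref$t, tolerance = 1e-12)
  expect_equal(got$df, ref$df, tolerance = 1e-12)
  expect_equal(got$p_value, ref$p, tolerance = 1e-12)
  expect_lte(got$df, length(x) + length(y) - 2)

  # identical samples: no difference
  same <- welchTest(x, x)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  # antisymmetry under swap
  sw <- welchTest(y, x)
  expect_equal(sw$t_statistic, -got$t_statistic, tolerance = 1e-12)
  expect_equal(sw$p_value, got$p_value, tolerance = 1e-12)

  expect_error(welchTest(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(welchTest(1, c(1, 2)), "at least 2")
})

test_that("welchTest reduces to pooled Student t for equal n and variance", {
  x <- c(1, 2, 3, 4, 5)
  y <- x + 2  # same sample variance, same n
  w <- welchTest(x, y)
  st <- t.test(x, y, var.equal = TRUE)
  expect_equal(w$t_statistic, unname(st$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(st$parameter), tolerance = 1e-12)
  expect_equal(w$p_value, st$p.value, tolerance = 1e-12)
})

test_that("pairwise comparisons cover all six group pairs and surface degeneracy", {
  rec <- data.frame(
    gene_id = paste0("g", 1:40),
    biotype = rep(c("lncRNA", "mRNA"), each = 20),
    stratum = rep(rep(c("moderate", "high"), each = 10), 2),
    cv = c(rnorm(10, 4, 0.5), rnorm(10, 2, 0.3),
           rnorm(10, 2.5, 0.4), rnorm(10, 1, 0.2))
  )
  cmp <- pairwiseCvComparisons(rec)
  expect_equal(nrow(cmp), 6)
  expect_equal(anyDuplicated(paste(cmp$group_a, cmp$group_b)), 0L)

  # two identical groups give p = 1 for that pair only
  rec2 <- rec
  rec2$cv[rec2$biotype == "mRNA" & rec2$stratum == "high"] <-
    rec2$cv[rec2$biotype == "lncRNA" & rec2$stratum == "high"]
  cmp2 <- pairwiseCvComparisons(rec2)
  pair <- cmp2$group_a == "lncRNA-high" & cmp2$group_b == "mRNA-high"
  expect_equal(cmp2$p[pair], 1, tolerance = 1e-9)

  # an empty group is an error naming the group
  expect_error(pairwiseCvComparisons(rec[rec$stratum == "moderate", ]),
               "high")
  # all-constant groups surface the degeneracy
  recc <- rec; recc$cv <- rep(c(1, 2, 3, 4), each = 10)
  expect_error(pairwiseCvComparisons(recc), "zero variance")
})

test_that("box-plot summaries use 1.5 IQR whiskers", {
  v <- c(1:10, 100)
  rec <- data.frame(gene_id = seq_along(v), biotype = "lncRNA",
                    stratum = "moderate", cv = v)
  s <- cvGroupSummary(rec)
  q <- unname(quantile(v, c(0.25, 0.5, 0.75)))
  expect_equal(s$q1, q[1]); expect_equal(s$median, q[2]); expect_equal(s$q3, q[3])
  expect_equal(s$whisker_hi, max(v[v <= q[3] + 1.5 * (q[3] - q[1])]))
  expect_equal(s$n_outliers, 1)  # the 100
})
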