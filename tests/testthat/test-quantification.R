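test_that("fpkm follows the count * 1e9 / (length * librarySize) formula", {
  expect_equal(fpkm(10, 1000, 1e6), 10)
  expect_equal(fpkm(0, 123, 456789), 0)
  expect_error(fpkm(1, 0, 1e6), "length")
  expect_error(fpkm(1, 1000, 0), "library")
  expect_error(fpkm(-1, 1000, 1e6), "non-negative")
  # seeded 200-gene table against direct arithmetic
  set.seed(101)
  cnt <- sample(0:5000, 200, replace = TRUE)
  len <- sample(200:10000, 200, replace = TRUE)
  lib <- 3.7e7
  expect_equal(fpkm(cnt, len, lib), cnt * 1e9 / (len * lib),
               tolerance = 1e-12)
})

test_that("fpkm is linear in count and inversely proportional to length and depth", {
  set.seed(7)
  cnt <- sample(1:1000, 50); len <- sample(300:5000, 50); lib <- 2e7
  base <- fpkm(cnt, len, lib)
  expect_equal(fpkm(3 * cnt, len, lib), 3 * base, tolerance = 1e-12)
  expect_equal(fpkm(cnt, 2 * len, lib), base / 2, tolerance = 1e-12)
  expect_equal(fpkm(cnt, len, 4 * lib), base / 4, tolerance = 1e-12)
})

test_that("fpkmMatrix equals entry-wise fpkm and rejects missing genes", {
  m1 <- matrix(10L, 1, 1, dimnames = list("g1", "c1"))
  se <- fpkmMatrix(m1, c(g1 = 1000), 1e6)
  expect_equal(unname(SummarizedExperiment::assay(se, "fpkm")[1, 1]), 10)

  set.seed(20)
  cnt <- matrix(sample(0:2000, 500), 50, 10,
                dimnames = list(paste0("g", 1:50), paste0("c", 1:10)))
  len <- stats::setNames(sample(200:8000, 50), rownames(cnt))
  libs <- sample(1e6:5e7, 10)
  got <- SummarizedExperiment::assay(fpkmMatrix(cnt, len, libs), "fpkm")
  want <- cnt
  for (i in 1:50) for (j in 1:10)
    want[i, j] <- fpkm(cnt[i, j], len[i], libs[j])
  expect_equal(got, want, tolerance = 1e-12)

  expect_error(fpkmMatrix(cnt, len[-c(1, 5)], libs), "g1.*g5|g1, g5")

  # empty gene set keeps the cells
  empty <- fpkmMatrix(cnt[0, , drop = FALSE], len, libs)
  expect_equal(dim(empty), c(0L, 10L))
  expect_identical(colnames(empty), colnames(cnt))
})

test_that("ambiguity bounds bracket the truth for an antisense-overlapped gene", {
  plus <- function(s, e) GenomicRanges::GRanges("chr6",
    IRanges::IRanges(s, e), strand = "+")
  minus <- function(s, e) GenomicRanges::GRanges("chr6",
    IRanges::IRanges(s, e), strand = "-")

  # disjoint exons: nothing ambiguous, bounds coincide
  b <- ambiguityBounds(plus(1, 1000), minus(5000, 6000), 20, 0, 1e6)
  expect_equal(b$under, b$over)
  expect_equal(b$partition$ambiguous_nt, 0)

  # target fully inside the antisense exon: no exclusive region, under = 0
  b <- ambiguityBounds(plus(100, 200), minus(1, 1000), 0, 30, 1e6)
  expect_equal(b$partition$exclusive_nt, 0)
  expect_equal(b$under, 0)
  expect_gt(b$over, 0)

  # direct arithmetic on a monoexonic 3427 nt target
  b <- ambiguityBounds(plus(10404735, 10408161), minus(10404000, 10406000),
                       5, 15, 1e6)
  expect_equal(b$under, 5e9 / (3427 * 1e6), tolerance = 1e-12)
  expect_equal(b$over, 20e9 / (3427 * 1e6), tolerance = 1e-12)

  # same-strand pairs are a contract violation
  expect_error(ambiguityBounds(plus(1, 10), plus(5, 20), 1, 1, 1e6),
               "opposite-strand")
  expect_error(ambiguityBounds(plus(1, 10), minus(5, 20), -1, 1, 1e6),
               "non-negative")
})

test_that("under <= over across random gene-pair geometries, equal iff no ambiguity", {
  set.seed(33)
  for (rep in 1:1000) {
    nT <- sample(1:4, 1); nA <- sample(1:4, 1)
    ts <- sort(sample(1:5000, nT)); te <- ts + sample(50:500, nT, replace = TRUE)
    as <- sort(sample(1:5000, nA)); ae <- as + sample(50:500, nA, replace = TRUE)
    target <- GenomicRanges::reduce(GenomicRanges::GRanges("chr1",
      IRanges::IRanges(ts, te), strand = "+"))
    anti <- GenomicRanges::reduce(GenomicRanges::GRanges("chr1",
      IRanges::IRanges(as, ae), strand = "-"))
    cAmb <- if (rep %% 3 == 0) 0 else sample(0:50, 1)
    cExc <- sample(0:100, 1)
    b <- ambiguityBounds(target, anti, cExc, cAmb, 1e6)
    expect_lte(b$under, b$over)
    if (cAmb == 0) expect_equal(b$under, b$over) else expect_lt(b$under, b$over)
  }
})

test_that("partition geometry exports as 0-based half-open BED", {
  target <- GenomicRanges::GRanges("chr6", IRanges::IRanges(101, 300),
                                   strand = "+")
  anti <- GenomicRanges::GRanges("chr6", IRanges::IRanges(201, 400),
                                 strand = "-")
  p <- ambiguityPartition(target, anti)
  f <- tempfile(fileext = ".bed")
  writePartitionBed(p, f)
  bed <- read.table(f, sep = "\t", stringsAsFactors = FALSE)
  excl <- bed[bed$V4 == "exclusive", ]
  amb <- bed[bed$V4 == "ambiguous", ]
  expect_equal(c(excl$V2, excl$V3), c(100, 200))  # [101,200] 1-based
  expect_equal(c(amb$V2, amb$V3), c(200, 300))    # [201,300] 1-based
})

test_that("expression matrix TSVs round-trip", {
  set.seed(4)
  m <- matrix(round(runif(30, 0, 40), 3), 6, 5,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:5)))
  f <- tempfile(fileext = ".tsv")
  writeExpressionMatrix(m, f)
  back <- readExpressionMatrix(f)
  expect_equal(back, m, tolerance = 1e-6)
})
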