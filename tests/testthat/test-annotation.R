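test_that("GTF coordinates are read as 1-based inclusive and merged correctly", {
  df <- data.frame(chrom = "chr1", start = c(11, 31), end = c(20, 40),
                   strand = "+", gene = "g1", tx = "NM_000001")
  ann <- parseGtf(writeTempGtf(gtfText(df)))
  expect_equal(unname(unionLengths(ann)), 20L)
  ue <- unionExons(ann, "g1")
  expect_equal(GenomicRanges::start(ue), c(11, 31))
  expect_equal(GenomicRanges::end(ue), c(20, 40))
})

test_that("malformed GTF lines raise errors naming the line", {
  df <- data.frame(chrom = "chr1", start = 11, end = 20, strand = ".",
                   gene = "g1", tx = "t1")
  expect_error(parseGtf(writeTempGtf(gtfText(df))), "strand.*line 1")
  bad <- paste("chr1", "x", "exon", "20", "10", ".", "+", ".",
               'gene_id "g"; transcript_id "t";', sep = "\t")
  expect_error(parseGtf(writeTempGtf(bad)), "coordinates at line 1")
  expect_error(parseGtf(writeTempGtf("chr1\tonly\tthree")), "9 tab-separated")
  expect_error(parseGtf(tempfile()), "not found")
})

test_that("duplicate exon records are deduplicated with a warning", {
  df <- data.frame(chrom = "chr1", start = c(11, 11), end = c(20, 20),
                   strand = "+", gene = "g1", tx = "t1")
  expect_warning(ann <- parseGtf(writeTempGtf(gtfText(df))), "duplicate")
  expect_equal(length(exonRanges(ann)), 1L)
  expect_equal(unname(unionLengths(ann)), 10L)
})

test_that("both GTF attribute dialects are accepted", {
  l1 <- paste("chr1", "x", "exon", "1", "100", ".", "+", ".",
              'gene_id "g1"; transcript_id "NM_1";', sep = "\t")
  l2 <- paste("chr1", "x", "exon", "201", "300", ".", "+", ".",
              "gene_id=g2; transcript_id=NR_2", sep = "\t")
  ann <- parseGtf(writeTempGtf(c(l1, l2)))
  expect_setequal(geneIds(ann), c("g1", "g2"))
  expect_equal(unname(unionLengths(ann)), c(100L, 100L))
})

test_that("a 50-gene fixture matches an independent line-by-line parse", {
  ann <- simulateAnnotation(50, seed = 11)
  gtf <- tempfile(fileext = ".gtf")
  writeGtf(ann, gtf)
  ref <- bruteGtfStats(gtf)
  expect_equal(length(geneIds(ann)), ref$n_genes)
  expect_equal(unionLengths(ann)[names(ref$union_lengths)],
               ref$union_lengths)
  txCount <- vapply(
    split(S4Vectors::mcols(exonRanges(ann))$transcript_id,
          S4Vectors::mcols(exonRanges(ann))$gene_id),
    function(z) length(unique(z)), integer(1))
  expect_equal(txCount[names(ref$n_transcripts)], ref$n_transcripts)
})

test_that("union-exon length counts each base once across isoforms", {
  mk <- function(starts, ends, txs) {
    df <- data.frame(chrom = "chr1", start = starts, end = ends,
                     strand = "+", gene = "g", tx = txs)
    parseGtf(writeTempGtf(gtfText(df)))
  }
  # overlapping exons merge: [1,100] + [51,150] covers 150 bases
  expect_equal(unname(unionLengths(mk(c(1, 51), c(100, 150),
                                      c("t1", "t2")))), 150L)
  # identical exon shared by two isoforms counts once
  expect_equal(unname(unionLengths(mk(c(1, 1), c(100, 100),
                                      c("t1", "t2")))), 100L)
  # the monoexonic case: 1-based inclusive 10404735..10408161 spans 3427 nt
  expect_equal(unname(unionLengths(mk(10404735, 10408161, "t1"))), 3427L)
})

test_that("union length is order-invariant and bounded by the isoform sum", {
  set.seed(42)
  for (rep in 1:10) {
    nEx <- sample(2:6, 1)
    starts <- cumsum(sample(100:500, nEx))
    ends <- starts + sample(50:200, nEx, replace = TRUE)
    df <- data.frame(chrom = "chr1", start = starts, end = ends,
                     strand = "+", gene = "g",
                     tx = paste0("t", sample(1:2, nEx, replace = TRUE)))
    perm <- df[sample(nrow(df)), ]
    a1 <- parseGtf(writeTempGtf(gtfText(df)))
    a2 <- parseGtf(writeTempGtf(gtfText(perm)))
    expect_identical(unionLengths(a1), unionLengths(a2))
    perTx <- sum(ends - starts + 1)
    expect_lte(unname(unionLengths(a1)), perTx)
  }
  # duplicating an exon in another isoform never changes the union
  df <- data.frame(chrom = "chr1", start = c(1, 201), end = c(100, 300),
                   strand = "+", gene = "g", tx = "t1")
  dup <- rbind(df, transform(df[1, ], tx = "t2"))
  expect_identical(unionLengths(parseGtf(writeTempGtf(gtfText(df)))),
                   unionLengths(parseGtf(writeTempGtf(gtfText(dup)))))
})

test_that("biotype rules follow RefSeq prefixes with read-through reclassification", {
  df <- rbind(
    data.frame(chrom = "chr1", start = 1000, end = 2000, strand = "+",
               gene = "coding1", tx = "NM_000001"),
    data.frame(chrom = "chr1", start = 1500, end = 2500, strand = "+",
               gene = "nc_overlap", tx = "NR_000002"),
    data.frame(chrom = "chr1", start = 9000, end = 9500, strand = "+",
               gene = "nc_clean", tx = "NR_024540"),
    data.frame(chrom = "chr1", start = 1500, end = 2500, strand = "-",
               gene = "nc_antisense", tx = "XR_000003"),
    data.frame(chrom = "chr2", start = 100, end = 700, strand = "+",
               gene = "no_evidence", tx = "TX_000004"),
    data.frame(chrom = "chr2", start = 5000, end = 5600, strand = "+",
               gene = "mixed", tx = "NM_000005"),
    data.frame(chrom = "chr2", start = 5000, end = 5600, strand = "+",
               gene = "mixed", tx = "NR_000006")
  )
  ann <- classifyBiotype(parseGtf(writeTempGtf(gtfText(df))))
  bt <- biotypes(ann)
  expect_equal(unname(bt["coding1"]), "coding")
  # same-strand exonic overlap with a coding gene: possible read-through
  expect_equal(unname(bt["nc_overlap"]), "coding")
  expect_match(geneTable(ann)$biotype_reason[
    geneTable(ann)$gene_id == "nc_overlap"], "read-through.*coding1")
  # no overlap: stays noncoding
  expect_equal(unname(bt["nc_clean"]), "noncoding")
  # opposite strand overlap does not trigger read-through
  expect_equal(unname(bt["nc_antisense"]), "noncoding")
  expect_equal(unname(bt["no_evidence"]), "excluded")
  # gene carrying both coding and noncoding transcripts resolves to coding
  expect_equal(unname(bt["mixed"]), "coding")
})

test_that("biotype classification is invariant to record order", {
  ann <- simulateAnnotation(30, seed = 5)
  ex <- exonRanges(ann)
  set.seed(9)
  shuffled <- ex[sample(length(ex))]
  a1 <- classifyBiotype(ann)
  a2 <- classifyBiotype(hetflag:::.buildGeneAnnotation(shuffled))
  expect_identical(biotypes(a1)[sort(geneIds(a1))],
                   biotypes(a2)[sort(geneIds(a2))])
})

test_that("the minimum-length filter is strict at the boundary", {
  df <- rbind(
    data.frame(chrom = "chr1", start = 1, end = 200, strand = "+",
               gene = "len200", tx = "NM_1"),
    data.frame(chrom = "chr1", start = 1000, end = 1200, strand = "+",
               gene = "len201", tx = "NM_2")
  )
  ann <- parseGtf(writeTempGtf(gtfText(df)))
  kept <- filterMinLength(ann, 200)
  expect_identical(geneIds(kept), "len201")
  empty <- filterMinLength(filterMinLength(ann, 1e6), 200)
  expect_length(geneIds(empty), 0L)
})

test_that("writeGtf round-trips through parseGtf", {
  ann <- classifyBiotype(simulateAnnotation(25, seed = 3))
  f <- tempfile(fileext = ".gtf")
  writeGtf(ann, f)
  back <- classifyBiotype(parseGtf(f))
  expect_identical(unionLengths(ann), unionLengths(back))
  expect_identical(biotypes(ann), biotypes(back))
  expect_identical(as.data.frame(geneTable(ann)), as.data.frame(geneTable(back)))
})
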