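# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: brute-force enumeration, long-form arithmetic,
# base-by-base interval marking.

# longest ORF by exhaustive enumeration over (start, first in-frame stop)
bruteLongestOrf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (frame in 0:2) {
    if (n - frame < 3) next
    pos <- seq(frame + 1, n - 2, by = 3)
    cod <- substring(s, pos, pos + 2)
    for (i in seq_along(cod)) {
      if (cod[i] != "ATG") next
      j <- i + 1
      while (j <= length(cod)) {
        if (cod[j] %in% stops) {
          len <- as.integer((j - i + 1) * 3)
          start0 <- as.integer(pos[i] - 1)
          if (is.null(best) || len > best$length ||
              (len == best$length && start0 < best$start))
            best <- list(start = start0, end = as.integer(pos[j] + 2),
                         frame = frame, length = len)
          break
        }
        j <- j + 1
      }
    }
  }
  best
}

# Welch's t-test by long-form textbook arithmetic
handWelch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  mx <- sum(x) / nx; my <- sum(y) / ny
  vx <- sum((x - mx)^2) / (nx - 1)
  vy <- sum((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# two-component Gaussian mixture log-likelihood
mixLogLik <- function(x, lambda, mu, sigma) {
  sum(log(lambda[1] * stats::dnorm(x, mu[1], sigma[1]) +
          lambda[2] * stats::dnorm(x, mu[2], sigma[2])))
}

# posterior of component 1 from known generating parameters
truePosterior <- function(n, lambda, mu, sigma) {
  d1 <- lambda[1] * stats::dnorm(n, mu[1], sigma[1])
  d2 <- lambda[2] * stats::dnorm(n, mu[2], sigma[2])
  d1 / (d1 + d2)
}

# best log-likelihood over a dense parameter grid
gridSearchLogLik <- function(x) {
  lam <- seq(0.1, 0.9, by = 0.1)
  mu1 <- seq(min(x), stats::median(x), length.out = 12)
  mu2 <- seq(stats::median(x), max(x), length.out = 12)
  sig <- exp(seq(log(stats::sd(x) / 20), log(stats::sd(x)), length.out = 8))
  d1 <- outer(seq_along(mu1), seq_along(sig),
              Vectorize(function(i, j) list(stats::dnorm(x, mu1[i], sig[j]))))
  d2 <- outer(seq_along(mu2), seq_along(sig),
              Vectorize(function(i, j) list(stats::dnorm(x, mu2[i], sig[j]))))
  best <- -Inf
  for (a in seq_along(d1)) {
    da <- d1[[a]]
    for (b in seq_along(d2)) {
      db <- d2[[b]]
      for (l in lam) {
        ll <- sum(log(l * da + (1 - l) * db))
        if (ll > best) best <- ll
      }
    }
  }
  best
}

# independent line-by-line GTF statistics: gene/transcript counts and union
# lengths by marking covered bases one at a time
bruteGtfStats <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  genes <- list()
  txByGene <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[3] != "exon") next
    gid <- sub('.*gene_id "([^"]*)".*', "\\1", f[9])
    tid <- sub('.*transcript_id "([^"]*)".*', "\\1", f[9])
    key <- paste(f[1], gid)
    bases <- seq(as.integer(f[4]), as.integer(f[5]))
    genes[[gid]] <- unique(c(genes[[gid]], bases))
    txByGene[[gid]] <- unique(c(txByGene[[gid]], tid))
  }
  list(
    n_genes = length(genes),
    union_lengths = vapply(genes, length, integer(1)),
    n_transcripts = vapply(txByGene, length, integer(1))
  )
}

# count dinucleotides of a sequence
dinucCounts <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  table(paste0(ch[-length(ch)], ch[-1]))
}

# small GTF text builder: exons is a list of data.frames with
# chrom/start/end/strand/gene/tx (1-based inclusive coordinates)
gtfText <- function(df, extra = 'gene_biotype "simulated";') {
  paste(df$chrom, "test", "exon", df$start, df$end, ".", df$strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s"; %s', df$gene, df$tx, extra),
        sep = "\t")
}

writeTempGtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}
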