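#' @include AllClasses.R
#' @importFrom Biostrings readDNAStringSet
NULL

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame on the sense strand
#'
#' Scans the three sense-strand reading frames of a nucleotide sequence for
#' ORFs (ATG through the first in-frame stop codon) and returns the longest.
#' By default the stop codon is included in the reported length, so every ORF
#' length is a multiple of 3 and at least 6 nt (ATG plus stop). Ties are
#' broken towards the smallest start. Codons containing N never match ATG or
#' a stop codon. Only the sense strand is scanned: a transcript is
#' single-stranded.
#'
#' @param sequence nucleotide string over A, C, G, T, N (case-insensitive).
#' @param includeStop if FALSE, the stop codon is excluded from the reported
#'   end and length (alternative length convention).
#' @return A list with \code{start} (0-based offset of the A of ATG),
#'   \code{end} (0-based exclusive), \code{frame} (0, 1 or 2) and
#'   \code{length} (nt), or \code{NULL} when the sequence contains no
#'   complete ORF.
#' @examples
#' longestOrf("ATGTAA")$length  # 6
#' longestOrf("CCCCCC")         # NULL
#' @export
longestOrf <- function(sequence, includeStop = TRUE) {
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  if (grepl("[^ACGTNacgtn]", sequence))
    stop("sequence contains characters outside {A, C, G, T, N}")
  s <- toupper(sequence)
  n <- nchar(s)
  best <- NULL
  for (frame in 0:2) {
    if (n - frame < 3L) next
    pos <- seq.int(frame + 1L, n - 2L, by = 3L)
    cod <- substring(s, pos, pos + 2L)
    atg <- which(cod == "ATG")
    stp <- which(cod %in% .STOP_CODONS)
    if (!length(atg) || !length(stp)) next
    ## first stop codon strictly after each start, in the same frame
    k <- findInterval(atg, stp) + 1L
    ok <- k <= length(stp)
    if (!any(ok)) next
    atg <- atg[ok]; k <- k[ok]
    len <- (stp[k] - atg + 1L) * 3L
    i <- which.max(len)  # ties: earliest start (atg ascending, which.max takes first)
    hit <- list(start = pos[atg[i]] - 1L,
                end = pos[stp[k[i]]] + 2L,
                frame = frame,
                length = len[i])
    if (is.null(best) || hit$length > best$length ||
        (hit$length == best$length && hit$start < best$start))
      best <- hit
  }
  if (is.null(best)) return(NULL)
  if (!includeStop) {
    best$end <- best$end - 3L
    best$length <- best$length - 3L
  }
  best
}

#' Monte-Carlo null for the longest ORF expected by chance
#'
#' Estimates how likely a transcript of the given length and base
#' composition is to contain, by chance alone, an ORF at least as long as
#' the observed one. Replicate sequences are drawn i.i.d. from the base
#' composition (or, with \code{null = "dinuc"}, as dinucleotide-preserving
#' shuffles of a provided sequence), the longest-ORF length of each is
#' recorded (0 when none), and the empirical p-value is computed with the
#' +1 correction \eqn{p = (1 + \#\{rep \ge obs\}) / (reps + 1)}, which never
#' returns exactly 0.
#'
#' @param observedLength observed longest-ORF length in nt.
#' @param transcriptLength transcript length in nt (>= 6).
#' @param composition named base frequencies (A, C, G, T) summing to 1;
#'   ignored for the dinucleotide null.
#' @param reps number of Monte-Carlo replicates (>= 100).
#' @param seed integer RNG seed.
#' @param null \code{"iid"} (default) or \code{"dinuc"}.
#' @param sequence the observed sequence, required for \code{null = "dinuc"}.
#' @return A list with observed_length, replicate_lengths, p_value, reps,
#'   seed and the composition used.
#' @export
orfChancePvalue <- function(observedLength, transcriptLength,
                            composition = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                            reps = 1000L, seed = 1L,
                            null = c("iid", "dinuc"), sequence = NULL) {
  null <- match.arg(null)
  if (reps < 100L) stop("need at least 100 Monte-Carlo replicates")
  if (transcriptLength < 6L) stop("transcript length must be at least 6 nt")
  if (null == "iid") {
    if (!all(c("A", "C", "G", "T") %in% names(composition)) ||
        any(composition < 0) || abs(sum(composition) - 1) > 1e-9)
      stop("composition must give non-negative A/C/G/T frequencies summing to 1")
    composition <- composition[c("A", "C", "G", "T")]
  } else {
    if (is.null(sequence)) stop("the dinucleotide null requires the observed sequence")
    composition <- NULL
  }
  set.seed(as.integer(seed))
  lens <- vapply(seq_len(reps), function(i) {
    s <- if (null == "iid")
      paste(sample(c("A", "C", "G", "T"), transcriptLength, replace = TRUE,
                   prob = composition), collapse = "")
    else dinucShuffle(sequence)
    hit <- longestOrf(s)
    if (is.null(hit)) 0L else hit$length
  }, integer(1))
  list(
    observed_length = observedLength,
    replicate_lengths = lens,
    p_value = (1 + sum(lens >= observedLength)) / (reps + 1),
    reps = reps, seed = seed, composition = composition
  )
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Returns a uniform random permutation of the sequence that preserves its
#' exact dinucleotide counts (Altschul-Erickson Eulerian-path shuffle): a
#' random last-edge arborescence towards the final base is drawn, the
#' remaining edges of each base are permuted, and the Eulerian walk is read
#' off.
#'
#' @param sequence nucleotide string of length >= 2.
#' @return A shuffled string with identical dinucleotide composition. Uses
#'   the current RNG state; seed externally for reproducibility.
#' @export
dinucShuffle <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  if (n < 2L) stop("sequence must have length >= 2")
  verts <- unique(s)
  last <- s[n]
  edges <- split(s[-1], s[-n])  # out-edges per vertex

  repeat {
    ## pick a candidate last edge for every vertex except the final one
    lastEdge <- vapply(verts, function(v) {
      if (v == last || is.null(edges[[v]])) NA_character_
      else edges[[v]][sample.int(length(edges[[v]]), 1L)]
    }, character(1))
    ## the designated last edges must lead every vertex to the final one
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(lastEdge[[v]])) next
      cur <- v; seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || is.na(lastEdge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- lastEdge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }

  ## order each vertex's out-edges: random permutation of the rest, then the
  ## designated last edge
  ordered <- lapply(verts, function(v) {
    ev <- edges[[v]]
    if (is.null(ev)) return(character(0))
    if (v == last || is.na(lastEdge[[v]])) return(sample(ev))
    i <- match(lastEdge[[v]], ev)
    rest <- ev[-i]
    if (length(rest) > 1L) rest <- sample(rest)
    c(rest, ev[i])
  })
  names(ordered) <- verts

  ## Eulerian walk from the first base
  nxt <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- s[1]
  cur <- s[1]
  for (i in 2:n) {
    e <- ordered[[cur]][nxt[[cur]]]
    nxt[[cur]] <- nxt[[cur]] + 1L
    out[i] <- e
    cur <- e
  }
  paste(out, collapse = "")
}

#' Read transcript sequences from FASTA
#'
#' @param path single- or multi-record FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
readTranscripts <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' ORF report for a set of transcripts
#'
#' Runs \code{\link{longestOrf}} and \code{\link{orfChancePvalue}} on each
#' transcript, using each transcript's own mononucleotide composition for
#' the i.i.d. null.
#'
#' @param sequences named character vector (e.g. from
#'   \code{\link{readTranscripts}}).
#' @param reps,seed Monte-Carlo settings, see \code{\link{orfChancePvalue}}.
#' @return data.frame with columns id, length_nt, longest_orf_nt, start,
#'   frame, p_chance.
#' @export
orfReport <- function(sequences, reps = 1000L, seed = 1L) {
  out <- lapply(seq_along(sequences), function(i) {
    s <- toupper(sequences[[i]])
    hit <- longestOrf(s)
    obs <- if (is.null(hit)) 0L else hit$length
    base <- strsplit(s, "")[[1]]
    comp <- table(factor(base, levels = c("A", "C", "G", "T")))
    comp <- comp / sum(comp)
    p <- orfChancePvalue(obs, nchar(s), setNames(as.numeric(comp), names(comp)),
                         reps = reps, seed = seed + i)$p_value
    data.frame(
      id = names(sequences)[i], length_nt = nchar(s),
      longest_orf_nt = obs,
      start = if (is.null(hit)) NA_integer_ else hit$start,
      frame = if (is.null(hit)) NA_integer_ else hit$frame,
      p_chance = p, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
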