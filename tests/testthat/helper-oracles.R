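## Independent oracles used to cross-check the package's own algorithms.
## They share only the published parameter constants, never the search or
## folding code paths.

.B <- c("A", "C", "G", "T")

randDna <- function(n) paste(sample(.B, n, replace = TRUE), collapse = "")

encB <- function(x) match(strsplit(x, "")[[1L]], .B)

## Brute-force sliding-window aligner: enumerates every diagonal 20-nt
## window of probe vs subject and applies the 70%-identity rule directly.
## Returns:
##   hit      - some window has >= minm matches
##   findable - some qualifying window both contains a run of `word`
##              consecutive matches (a seed) and has a match span that
##              reaches the minimum hit length after growing through
##              contiguous flanking matches
bruteForceWindows <- function(probe, subject, win = 20L, minm = 14L,
                              word = 7L) {
  p <- encB(probe); s <- encB(subject)
  n <- length(p); m <- length(s)
  anyWin <- FALSE; findable <- FALSE
  for (d in (1L - n):(m - 1L)) {
    i1 <- max(1L, 1L - d); i2 <- min(n, m - d)
    len <- i2 - i1 + 1L
    if (len < win) next
    mv <- p[i1:i2] == s[(i1:i2) + d]
    cs <- cumsum(c(0L, mv))
    ws <- cs[(win + 1L):(len + 1L)] - cs[1L:(len - win + 1L)]
    q <- which(ws >= minm)
    if (!length(q)) next
    anyWin <- TRUE
    if (findable) next
    for (a in q) {
      seg <- mv[a:(a + win - 1L)]
      r <- rle(seg)
      if (!any(r$lengths[r$values] >= word)) next
      lo <- a; hi <- a + win - 1L
      while (!mv[lo]) lo <- lo + 1L
      while (!mv[hi]) hi <- hi - 1L
      while (lo > 1L && mv[lo - 1L]) lo <- lo - 1L
      while (hi < len && mv[hi + 1L]) hi <- hi + 1L
      if (hi - lo + 1L >= win) { findable <- TRUE; break }
    }
  }
  list(hit = anyWin, findable = findable)
}

## Exhaustive single-hairpin enumeration: every (5' stem start i, 3' stem
## start j, stem length L) triple with Watson-Crick pairs throughout,
## stem >= 3 bp and loop >= 3 nt, scored with the shared parameter table.
hairpinOracle <- function(seq) {
  pars <- hairpinEnergyParams()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b <- strsplit(seq, "")[[1L]]
  n <- length(b)
  best <- Inf
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      span <- j - i + 1L
      if (span < 9L) next
      maxL <- (span - 3L) %/% 2L
      if (maxL < 3L) next
      for (L in 3L:maxL) {
        top <- b[i:(i + L - 1L)]
        bottom <- b[j:(j - L + 1L)]
        if (!all(bottom == comp[top])) next
        stacks <- vapply(seq_len(L - 1L), function(k)
          pars$stack[[paste0(top[k], top[k + 1L])]], numeric(1))
        g <- sum(stacks) + pars$loopPenalty(span - 2L * L)
        if (g < best) best <- g
      }
    }
  }
  best
}

## Spliced-CDS reconstruction from the raw contig, done "the other way
## around" (reverse-complement first, then substring), to cross-check the
## reader's coordinate mirroring.
splicedByRevcomp <- function(contigSeq, exonStartsFwd, exonEndsFwd, strand) {
  if (strand == "+") {
    parts <- substring(contigSeq, exonStartsFwd, exonEndsFwd)
    return(paste(parts, collapse = ""))
  }
  parts <- substring(contigSeq, exonStartsFwd, exonEndsFwd)
  rcParts <- vapply(parts, function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
    character(1))
  paste(rev(rcParts), collapse = "")
}
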