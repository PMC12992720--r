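# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (brute-force enumeration / direct string
# scanning) and share no code with the implementation paths they check.

randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rcStr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

substituteAt <- function(s, pos, base = NULL) {
  ch <- strsplit(s, "")[[1]]
  for (p in pos) {
    ch[p] <- if (is.null(base)) sample(setdiff(c("A", "C", "G", "T"),
                                               ch[p]), 1) else base
  }
  paste(ch, collapse = "")
}

# brute-force coverage oracle: every consensus window against every
# cluster window, plain string equality
naiveCoverage <- function(consensus, cluster, k,
                          orientation = "antisense",
                          bothStrands = FALSE) {
  L <- nchar(consensus)
  covered <- logical(L)
  if (L < k || nchar(cluster) < k) return(covered)
  cw <- substring(cluster, 1:(nchar(cluster) - k + 1),
                  k:nchar(cluster))
  if (bothStrands) {
    rcl <- rcStr(cluster)
    cw <- c(cw, substring(rcl, 1:(nchar(rcl) - k + 1), k:nchar(rcl)))
  }
  cw <- cw[!grepl("N", cw, fixed = TRUE)]
  for (s in 1:(L - k + 1)) {
    w <- substr(consensus, s, s + k - 1)
    probe <- if (orientation == "antisense") rcStr(w) else w
    if (any(probe == cw)) covered[s:(s + k - 1)] <- TRUE
  }
  covered
}

# brute-force ORF enumeration: every ATG, scan codons to the first stop,
# keep the longest ORF per stop (first ATG after the previous stop)
bruteOrfs <- function(s, minAa) {
  L <- nchar(s)
  hits <- list()
  for (a in seq_len(max(L - 2, 0))) {
    if (substr(s, a, a + 2) != "ATG") next
    p <- a
    stopAt <- NA
    while (p + 2 <= L) {
      if (substr(s, p, p + 2) %in% c("TAA", "TAG", "TGA") && p > a) {
        stopAt <- p
        break
      }
      p <- p + 3
    }
    if (!is.na(stopAt)) {
      hits[[length(hits) + 1]] <- data.frame(
        start = a, end = stopAt + 2, frame = (a - 1) %% 3,
        aaLength = (stopAt - a) / 3, openEnded = FALSE)
    } else {
      lastFull <- a + 3 * ((L - a + 1) %/% 3) - 1
      hits[[length(hits) + 1]] <- data.frame(
        start = a, end = lastFull, frame = (a - 1) %% 3,
        aaLength = (lastFull - a + 1) / 3, openEnded = TRUE)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(),
                      frame = integer(), aaLength = integer(),
                      openEnded = logical()))
  df <- do.call(rbind, hits)
  # longest ORF per (frame, end): keep the earliest start
  key <- paste(df$frame, df$end)
  df <- df[order(df$start), ]
  df <- df[!duplicated(paste(df$frame, df$end)), ]
  df <- df[df$aaLength >= minAa, ]
  df <- df[order(df$start, df$frame), ]
  rownames(df) <- NULL
  df
}

# panel of two variant haplotypes (2 carriers each) + a recombinant query;
# breakpoints are placed between diagnostic sites with >= minGap sites in
# every resulting segment. Returns NULL when the variant draw leaves too
# few usable sites.
makeRecombPanel <- function(cons, nSubs = 60, nBreaks = 1, minGap = 10,
                            seed = 1) {
  set.seed(seed)
  vA <- simVariant(cons, nSubs, seed = seed * 2 + 1, id = "varA")
  vB <- simVariant(cons, nSubs, seed = seed * 2 + 2, id = "varB")
  msa0 <- Biostrings::DNAStringSet(c(A1 = vA$seq, A2 = vA$seq,
                                     B1 = vB$seq, B2 = vB$seq))
  sites <- diagnosticSites(msa0, "A1", "A2", "B1", "B2")
  cols <- siteTable(sites)$column
  # restrict switch points to the internal region (between the LTRs)
  ltrLen <- nchar(vA$ltr)
  L <- nchar(vA$seq)
  usable <- which(cols > ltrLen & cols < L - ltrLen)
  if (length(usable) < (nBreaks + 1) * minGap + nBreaks) return(NULL)
  picks <- round(seq(minGap, length(usable) - minGap,
                     length.out = nBreaks + 2))[2:(nBreaks + 1)]
  bps <- vapply(picks, function(i) {
    lo <- cols[usable[i]]
    hi <- cols[usable[i] + 1]
    as.integer(lo + (hi - lo) %/% 2)
  }, integer(1))
  rec <- makeRecombinant(vA$seq, vB$seq, bps, id = "query")
  list(msa = Biostrings::DNAStringSet(c(A1 = vA$seq, A2 = vA$seq,
                                        B1 = vB$seq, B2 = vB$seq,
                                        query = rec$seq)),
       truthBp = bps, ltrA = vA$ltr, ltrB = vB$ltr, cons = cons)
}

smallConsensus <- function(seed = 42) {
  simConsensus("consA",
               simParams(ltrLen = 200L, utr5Len = 100L,
                         orfLens = c(gag = 450L, pol = 600L, envF = 450L),
                         utr3Len = 80L),
               seed = seed)
}
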