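## ORF integrity: ORF scanning, detection of inactivating events
## (frameshift indels, premature stop substitutions) against a reference
## ORF, whole-insertion classification, and env-F remnant discovery by
## translated local alignment.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Scan a sequence for ATG-initiated open reading frames
#'
#' Finds all ATG-initiated ORFs of at least \code{minAa} codons on the
#' \code{+} strand in all three frames. Insertions are extracted in element
#' orientation, so only the forward strand is relevant. Nested ORFs sharing
#' a stop codon are reported once, as the longest (first ATG after the
#' previous stop). An ORF running off the sequence end without a stop is
#' flagged \code{openEnded}.
#'
#' @param seq A \code{DNAString}, \code{InsertionRecord} or character
#'   string.
#' @param minAa Minimum length in codons (excluding the stop codon).
#' @return A \code{data.frame} sorted by \code{start}: \code{start},
#'   \code{end} (1-based closed, stop codon included when present),
#'   \code{frame} (0-2), \code{strand}, \code{aaLength} (codons excluding
#'   the stop), \code{openEnded}.
#' @examples
#' scanOrfs("ATGAAATAA", minAa = 2)  # one 2-codon ORF (Met-Lys)
#' @export
scanOrfs <- function(seq, minAa = 100L) {
  if (is(seq, "InsertionRecord")) seq <- elementSeq(seq)
  s <- as.character(seq)
  stopifnot(minAa >= 1L)
  L <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    if (L - frame < 3L) next
    starts <- seq.int(frame + 1L, L - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    isStop <- codons %in% .STOP_CODONS
    isAtg <- codons == "ATG"
    prevStop <- 0L
    for (j in which(isStop)) {
      cand <- which(isAtg[seq_len(j - 1L)])
      cand <- cand[cand > prevStop]
      if (length(cand)) {
        a <- cand[1L]
        out[[length(out) + 1L]] <- data.frame(
          start = starts[a], end = starts[j] + 2L, frame = frame,
          strand = "+", aaLength = j - a, openEnded = FALSE)
      }
      prevStop <- j
    }
    cand <- which(isAtg)
    cand <- cand[cand > prevStop]
    if (length(cand)) {
      a <- cand[1L]
      nc <- length(codons)
      out[[length(out) + 1L]] <- data.frame(
        start = starts[a], end = starts[nc] + 2L, frame = frame,
        strand = "+", aaLength = nc - a + 1L, openEnded = TRUE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      strand = character(), aaLength = integer(),
                      openEnded = logical()))
  df <- do.call(rbind, out)
  df <- df[df$aaLength >= minAa, , drop = FALSE]
  df <- df[order(df$start, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# shift gap runs in `a` leftwards while the preceding aligned column's `b`
# character equals the run's last `b` character (left-normalized indels in
# homopolymer context -> deterministic coordinates)
.leftAlignGaps <- function(a, b) {
  n <- length(a)
  i <- 2L
  while (i <= n) {
    if (a[i] == "-" && a[i - 1L] != "-") {
      j <- i
      while (j < n && a[j + 1L] == "-") j <- j + 1L
      while (i > 1L && a[i - 1L] != "-" && b[i - 1L] != "-" &&
             b[i - 1L] == b[j]) {
        idx <- c(seq_len(i - 2L), i:j, i - 1L,
                 if (j < n) (j + 1L):n else integer())
        a <- a[idx]
        b <- b[idx]
        i <- i - 1L
        j <- j - 1L
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(a = a, b = b)
}

# 1-based codon index of the first stop in frame 0 of `s` whose codon start
# (0-based) is >= from0; NA if none
.firstStopAfter <- function(s, from0 = 0L) {
  L <- nchar(s)
  if (L < 3L) return(NA_integer_)
  starts <- seq.int(1L, L - 2L, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  hit <- which(codons %in% .STOP_CODONS & (starts - 1L) >= from0)
  if (length(hit)) hit[1L] else NA_integer_
}

#' Detect inactivating mutations against a reference ORF
#'
#' Globally aligns a query region to a reference ORF and reports every
#' indel and every substitution that creates an in-frame stop codon, in
#' reference-ORF coordinates. Indels adjacent to homopolymers are
#' left-aligned so coordinates are deterministic. For each event the first
#' downstream in-frame stop of the query (in the reading frame induced by
#' all upstream events) is reported as a 1-based codon index on the query
#' translation.
#'
#' @param queryRegion Query nucleotide string (the region of an insertion
#'   corresponding to the reference ORF).
#' @param referenceOrf Reference ORF nucleotide string; length divisible by
#'   3, starting ATG.
#' @param minIdentity Alignment identity below which the pair is rejected
#'   as unrelated (default 0.5).
#' @return A \code{data.frame}, one row per event, ordered by reference
#'   position: \code{kind} (\code{insertion}, \code{deletion},
#'   \code{substitution_stop}), \code{refPos} (0-based on the reference
#'   ORF: the base \emph{preceding} an insertion, the first deleted base of
#'   a deletion, the codon start of a stop substitution), \code{length}
#'   (nt; 0 for substitutions), \code{frameshift}, \code{downstreamStopAa},
#'   \code{queryPos} (0-based on the query).
#' @export
detectInactivation <- function(queryRegion, referenceOrf,
                               minIdentity = 0.5) {
  q <- as.character(queryRegion)
  r <- as.character(referenceOrf)
  if (nchar(r) %% 3L != 0L)
    stop("reference ORF length must be divisible by 3")
  if (substr(r, 1L, 3L) != "ATG")
    stop("reference ORF must start with ATG")
  aln <- .alignGlobal(q, r)
  if (.alignIdentity(aln) < minIdentity)
    stop("query and reference ORF share < ", round(100 * minIdentity),
         "% aligned identity")
  al <- .alignedStrings(aln)
  # left-normalize insertions (gaps in ref) then deletions (gaps in query)
  norm <- .leftAlignGaps(al$subject, al$pattern)
  norm <- .leftAlignGaps(norm$b, norm$a)
  qc <- norm$a
  rc <- norm$b
  qpos <- cumsum(qc != "-")
  rpos <- cumsum(rc != "-")
  n <- length(qc)
  ev <- list()
  addEvent <- function(kind, refPos, len, queryPos) {
    fs <- kind != "substitution_stop" && len %% 3L != 0L
    dsa <- if (kind == "substitution_stop") {
      refPos %/% 3L + 1L
    } else {
      .firstStopAfter(q, queryPos)
    }
    ev[[length(ev) + 1L]] <<- data.frame(
      kind = kind, refPos = refPos, length = len, frameshift = fs,
      downstreamStopAa = dsa, queryPos = queryPos)
  }
  # indel runs
  i <- 1L
  while (i <= n) {
    if (rc[i] == "-") {                      # insertion in query
      j <- i
      while (j < n && rc[j + 1L] == "-") j <- j + 1L
      addEvent("insertion", rpos[i] - 1L, j - i + 1L, qpos[i] - 1L)
      i <- j + 1L
    } else if (qc[i] == "-") {               # deletion from reference
      j <- i
      while (j < n && qc[j + 1L] == "-") j <- j + 1L
      addEvent("deletion", rpos[i] - 1L, j - i + 1L, qpos[i])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  # premature stops by substitution: scan reference codons that are fully
  # aligned (no gaps) and in frame on the query (no net upstream shift)
  refLen <- nchar(r)
  i <- 1L
  while (i + 2L <= n) {
    step <- 1L
    if (rc[i] != "-" && (rpos[i] - 1L) %% 3L == 0L) {
      cols <- i:(i + 2L)
      if (all(rc[cols] != "-") && all(qc[cols] != "-")) {
        inFrame <- (qpos[i] - rpos[i]) %% 3L == 0L
        qcod <- paste(qc[cols], collapse = "")
        rcod <- paste(rc[cols], collapse = "")
        if (inFrame && qcod %in% .STOP_CODONS &&
            !rcod %in% .STOP_CODONS && qcod != rcod &&
            rpos[i] + 2L < refLen) {
          addEvent("substitution_stop", rpos[i] - 1L, 0L, qpos[i] - 1L)
        }
        step <- 3L
      }
    }
    i <- i + step
  }
  if (!length(ev))
    return(data.frame(kind = character(), refPos = integer(),
                      length = integer(), frameshift = logical(),
                      downstreamStopAa = integer(), queryPos = integer()))
  df <- do.call(rbind, ev)
  df <- df[order(df$refPos, df$kind), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# codons before the first in-frame stop of `s` (frame 0); open reading
# length if stop-free
.effectiveAa <- function(s) {
  stop1 <- .firstStopAfter(s, 0L)
  if (is.na(stop1)) nchar(s) %/% 3L else stop1 - 1L
}

#' Classify an insertion by ORF integrity
#'
#' Locates each annotated reference ORF (gag, pol and, when annotated,
#' env-F) within an insertion by global alignment to the consensus, runs
#' \code{\link{detectInactivation}} on each region, and assigns a per-ORF
#' status and an overall activity class. An ORF is \code{intact} when it
#' carries no frameshift or premature stop and its uninterrupted reading
#' length reaches at least \code{minAaFraction} of the reference ORF
#' (tolerating terminal raggedness while rejecting major truncations).
#'
#' Classes: \code{retrovirus_active} (gag, pol and env-F all intact),
#' \code{retroelement_active} (gag and pol intact, env-F not),
#' \code{inactive} otherwise.
#'
#' @param insertion An \code{InsertionRecord}, \code{DNAString} or
#'   character string.
#' @param reference A \code{\linkS4class{ConsensusElement}} with GAG and
#'   POL (and optionally ENVF) annotations.
#' @param minAaFraction Fraction of the reference ORF's codon count
#'   required for \code{intact} (default 0.9).
#' @return A list: \code{insertionId}, \code{status} (named character for
#'   \code{gag}, \code{pol}, \code{envF}), \code{class}, \code{events}
#'   (\code{data.frame} with an \code{orf} column).
#' @export
classifyIntegrity <- function(insertion, reference, minAaFraction = 0.9) {
  id <- if (is(insertion, "InsertionRecord")) elementId(insertion) else ""
  insSeq <- if (is(insertion, "InsertionRecord"))
    as.character(elementSeq(insertion)) else as.character(insertion)
  stopifnot(is(reference, "ConsensusElement"))
  if (is.null(featureRange(reference, "GAG")) ||
      is.null(featureRange(reference, "POL")))
    stop("reference must have GAG and POL annotations")
  aln <- .alignGlobal(insSeq, as.character(elementSeq(reference)))
  if (.alignIdentity(aln) < 0.5)
    stop("unrelated_element: insertion shares < 50% aligned identity ",
         "with reference '", elementId(reference), "'")
  map <- .mapSubjectToPattern(aln)
  orfs <- c(gag = "GAG", pol = "POL", envF = "ENVF")
  status <- c(gag = "absent", pol = "absent", envF = "absent")
  events <- list()
  for (nm in names(orfs)) {
    fr <- featureRange(reference, orfs[[nm]])
    if (is.null(fr)) next
    refOrf <- as.character(featureSeq(reference, orfs[[nm]]))
    qs <- map[IRanges::start(fr)]
    qe <- map[IRanges::end(fr)]
    if (is.na(qs) || is.na(qe) || qe - qs + 1L < 0.5 * nchar(refOrf)) next
    region <- substr(insSeq, qs, qe)
    evs <- tryCatch(detectInactivation(region, refOrf),
                    error = function(e) NULL)
    if (is.null(evs)) next
    refAa <- nchar(refOrf) %/% 3L - 1L   # codons excluding the stop
    inact <- evs[evs$frameshift | evs$kind == "substitution_stop", ,
                 drop = FALSE]
    status[nm] <- if (nrow(inact)) {
      first <- inact[which.min(inact$refPos), ]
      if (first$kind == "substitution_stop") "premature_stop" else "frameshift"
    } else if (.effectiveAa(region) >= minAaFraction * refAa) {
      "intact"
    } else {
      "truncated"
    }
    if (nrow(evs)) {
      evs$orf <- nm
      events[[nm]] <- evs
    }
  }
  envAnnotated <- !is.null(featureRange(reference, "ENVF"))
  cls <- if (status[["gag"]] == "intact" && status[["pol"]] == "intact") {
    if (envAnnotated && status[["envF"]] == "intact")
      "retrovirus_active" else "retroelement_active"
  } else {
    "inactive"
  }
  ev <- if (length(events)) do.call(rbind, c(events, make.row.names = FALSE))
        else data.frame(kind = character(), refPos = integer(),
                        length = integer(), frameshift = logical(),
                        downstreamStopAa = integer(), queryPos = integer(),
                        orf = character())
  list(insertionId = id, status = status, class = cls, events = ev)
}

#' Find env-F remnants by translated local alignment
#'
#' Searches a nucleotide region (typically the interval from the 3' end of
#' pol to the 3' LTR of a retroelement consensus) for remnants of the
#' envelope protein: each of the three forward-frame translations is
#' locally aligned (Smith-Waterman, BLOSUM62, gap open 11 / extend 1)
#' against a reference Env protein, and the best hit per frame with score
#' at least \code{minScore} is kept; heavily overlapping hits (more than
#' half of the shorter hit) are resolved greedily by score, while small
#' overlaps are tolerated because local alignments bleed a few residues
#' across frameshift junctions. A fragment interrupted by a frameshift
#' thus appears as two hits in adjacent frames with near-abutting
#' reference intervals.
#'
#' @param region Nucleotide string to search.
#' @param referenceEnvProtein Reference Env amino-acid string.
#' @param minScore Minimum local-alignment score (default 60).
#' @return A \code{data.frame} sorted by query position: \code{frame}
#'   (0-2), \code{queryStart}, \code{queryEnd} (1-based nt on the region),
#'   \code{refStart}, \code{refEnd} (1-based aa on the reference),
#'   \code{score}.
#' @export
findEnvRemnants <- function(region, referenceEnvProtein, minScore = 60) {
  region <- as.character(region)
  refProt <- Biostrings::AAString(as.character(referenceEnvProtein))
  empty <- data.frame(frame = integer(), queryStart = integer(),
                      queryEnd = integer(), refStart = integer(),
                      refEnd = integer(), score = numeric())
  L <- nchar(region)
  if (L < 3L) return(empty)
  hits <- list()
  for (frame in 0:2) {
    nCod <- (L - frame) %/% 3L
    if (nCod < 1L) next
    sub <- substr(region, frame + 1L, frame + 3L * nCod)
    prot <- Biostrings::translate(Biostrings::DNAString(sub),
                                  if.fuzzy.codon = "X")
    aln <- Biostrings::pairwiseAlignment(
      prot, refProt, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    if (Biostrings::score(aln) < minScore) next
    pa <- Biostrings::pattern(aln)
    sa <- Biostrings::subject(aln)
    aaS <- IRanges::start(pa@range)
    aaE <- IRanges::end(pa@range)
    hits[[length(hits) + 1L]] <- data.frame(
      frame = frame,
      queryStart = frame + 3L * (aaS - 1L) + 1L,
      queryEnd = frame + 3L * aaE,
      refStart = IRanges::start(sa@range),
      refEnd = IRanges::end(sa@range),
      score = Biostrings::score(aln))
  }
  if (!length(hits)) return(empty)
  df <- do.call(rbind, hits)
  df <- df[order(-df$score), , drop = FALSE]
  # greedy by score; a hit is discarded only when more than half of the
  # shorter of the two hits overlaps (local alignments may bleed a few
  # residues across a frameshift junction)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      ov <- min(df$queryEnd[i], df$queryEnd[j]) -
        max(df$queryStart[i], df$queryStart[j]) + 1L
      shorter <- min(df$queryEnd[i] - df$queryStart[i],
                     df$queryEnd[j] - df$queryStart[j]) + 1L
      if (ov > 0.5 * shorter) {
        keep[i] <- FALSE
        break
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$queryStart), , drop = FALSE]
  rownames(df) <- NULL
  df
}
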