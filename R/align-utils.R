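## Shared pairwise-alignment contract. One set of nucleotide scoring
## defaults is used everywhere (ORF integrity, LTR extraction/dating,
## variant typing): match +1, mismatch -1, gap open 5, gap extend 1.
## Protein local alignment (env remnants) uses BLOSUM62 with open 11 /
## extend 1.

.NUC_MAT <- NULL

.nucMat <- function() {
  # cached match/mismatch matrix incl. N (N scores 0 against everything)
  if (is.null(.NUC_MAT)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
    utils::assignInMyNamespace(".NUC_MAT", m)
  }
  .NUC_MAT
}

.alignGlobal <- function(a, b, gapOpening = 5, gapExtension = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(as.character(a)),
    Biostrings::DNAString(as.character(b)),
    type = "global", substitutionMatrix = .nucMat(),
    gapOpening = gapOpening, gapExtension = gapExtension)
}

# pattern globally, within a local window of subject
.alignGlobalLocal <- function(pattern, subject, gapOpening = 5,
                              gapExtension = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(as.character(pattern)),
    Biostrings::DNAString(as.character(subject)),
    type = "global-local", substitutionMatrix = .nucMat(),
    gapOpening = gapOpening, gapExtension = gapExtension)
}

# gapped aligned strings of a pairwiseAlignment, as a 2 x ncol char matrix
.alignedStrings <- function(aln) {
  p <- as.character(Biostrings::pattern(aln))
  s <- as.character(Biostrings::subject(aln))
  stopifnot(nchar(p) == nchar(s))
  list(pattern = strsplit(p, "")[[1]], subject = strsplit(s, "")[[1]])
}

# identity = matching columns / alignment length (gapped columns count)
.alignIdentity <- function(aln) {
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::pattern(aln)))
}

# map 1-based positions on the subject (reference) of a global alignment to
# 1-based positions on the pattern (query). Positions falling in a query
# gap map to the next query position (NA past the end).
.mapSubjectToPattern <- function(aln) {
  al <- .alignedStrings(aln)
  pGap <- al$pattern == "-"
  sGap <- al$subject == "-"
  pPos <- cumsum(!pGap)
  sPos <- cumsum(!sGap)
  n <- max(sPos)
  out <- integer(n)
  for (i in seq_along(sPos)) {
    if (!sGap[i] && out[sPos[i]] == 0L)
      out[sPos[i]] <- if (pGap[i]) pPos[i] + 1L else pPos[i]
  }
  out[out > max(pPos)] <- NA_integer_
  out[out == 0L] <- NA_integer_
  out
}
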