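## LTR-variant typing and recombinant detection. Retroviral capsids are
## pseudo-diploid: two co-packaged RNA genomes allow reverse-transcriptase
## template switching, so recombinant proviruses betray themselves by
## mismatched 5'/3' LTR types and by switching parental alleles along the
## element. Parental origin is painted at diagnostic alignment sites --
## columns where two insertions of one variant type share one allele and
## two insertions of the other type share a different one.

#' Create a variant library of reference LTR sequences
#'
#' @param ltrs A named \code{DNAStringSet} (or named character vector) of
#'   reference LTR sequences, one per variant; names are the variant names
#'   (e.g. \code{"LTR-408"}).
#' @return A named \code{DNAStringSet} validated for use with
#'   \code{\link{typeLtr}}.
#' @export
variantLibrary <- function(ltrs) {
  if (is.character(ltrs)) ltrs <- Biostrings::DNAStringSet(ltrs)
  if (is.null(names(ltrs)) || any(!nzchar(names(ltrs))))
    stop("every variant LTR must be named")
  if (anyDuplicated(names(ltrs)))
    stop("duplicate variant names")
  ltrs
}

#' Type an LTR sequence against a variant library
#'
#' Globally aligns the query against every reference LTR and returns the
#' variant with the best identity (matching columns / alignment length).
#' Ties are broken by smaller length difference, then by name. A best
#' identity below \code{minIdentity} yields \code{"untyped"}.
#'
#' @param ltrSeq Query LTR (character or \code{DNAString}).
#' @param library Named \code{DNAStringSet} from
#'   \code{\link{variantLibrary}}.
#' @param minIdentity Typing threshold (default 0.8).
#' @return A list: \code{variant} (name or \code{"untyped"}),
#'   \code{identity}.
#' @export
typeLtr <- function(ltrSeq, library, minIdentity = 0.8) {
  library <- variantLibrary(library)
  q <- as.character(ltrSeq)
  if (!nzchar(q)) stop("empty query LTR")
  ids <- vapply(names(library), function(nm)
    .alignIdentity(.alignGlobal(q, as.character(library[[nm]]))),
    numeric(1))
  lenDiff <- abs(nchar(q) - Biostrings::width(library))
  ord <- order(-ids, lenDiff, names(library))
  best <- ord[1L]
  if (ids[best] < minIdentity)
    return(list(variant = "untyped", identity = unname(ids[best])))
  list(variant = names(library)[best], identity = unname(ids[best]))
}

#' Detect mismatched 5'/3' LTR variant types
#'
#' Types both extracted LTRs of an insertion against a variant library.
#' Differing types indicate a recombinant provirus (template switching
#' between co-packaged variant genomes leaves the two LTRs from different
#' parents). When either LTR is untyped the result is indeterminate
#' (\code{NA}), not a mismatch.
#'
#' @param insertion An \code{InsertionRecord}; LTRs are extracted via
#'   \code{\link{extractLtrPair}} if not already present.
#' @param reference \code{ConsensusElement} used for LTR extraction (only
#'   needed when LTRs are not yet extracted).
#' @param library Variant library (see \code{\link{variantLibrary}}).
#' @param minIdentity Typing threshold (default 0.8).
#' @return A list: \code{mismatch} (TRUE/FALSE/NA), \code{type5},
#'   \code{type3}, \code{identity5}, \code{identity3}.
#' @export
detectLtrMismatch <- function(insertion, library, reference = NULL,
                              minIdentity = 0.8) {
  stopifnot(is(insertion, "InsertionRecord"))
  if (!nzchar(insertion@ltr5) || !nzchar(insertion@ltr3)) {
    if (is.null(reference))
      stop("LTRs not extracted and no reference supplied")
    insertion <- extractLtrPair(insertion, reference)
  }
  t5 <- typeLtr(insertion@ltr5, library, minIdentity)
  t3 <- typeLtr(insertion@ltr3, library, minIdentity)
  mm <- if (t5$variant == "untyped" || t3$variant == "untyped")
    NA else t5$variant != t3$variant
  list(mismatch = mm, type5 = t5$variant, type3 = t3$variant,
       identity5 = t5$identity, identity3 = t3$identity)
}

#' Diagnostic sites separating two variant types in an MSA
#'
#' Given two insertions of one variant type (\code{a1}, \code{a2}) and two
#' of another (\code{b1}, \code{b2}) in a multiple sequence alignment,
#' returns the columns at which the A pair shares one symbol, the B pair
#' shares a different symbol. The gap symbol is a valid shared allele, so
#' indel variants are captured; consecutive gap-diagnostic columns forming
#' one indel event are collapsed to the event's first column (one
#' biological variant, one site). A variant type for which only one good
#' complete sequence exists may be given as a degenerate pair
#' (\code{a1 == a2}); this is flagged in the result.
#'
#' @param msa Aligned \code{DNAStringSet} (see \code{\link{readMsa}}).
#' @param a1,a2,b1,b2 Row ids of the two parental pairs.
#' @param typeA,typeB Names of the two types (default \code{"A"},
#'   \code{"B"}).
#' @param msaId Identifier stored in the result.
#' @return A \code{\linkS4class{DiagnosticSiteSet}}.
#' @export
diagnosticSites <- function(msa, a1, a2, b1, b2, typeA = "A", typeB = "B",
                            msaId = "msa") {
  m <- .msaMatrix(msa)
  need <- unique(c(a1, a2, b1, b2))
  absent <- setdiff(need, rownames(m))
  if (length(absent))
    stop("row id(s) absent from MSA: ", paste(absent, collapse = ", "))
  if (length(unique(c(a1, a2))) + length(unique(c(b1, b2))) < 2L ||
      length(intersect(c(a1, a2), c(b1, b2))))
    stop("parental pairs must not share rows")
  sel <- m[a1, ] == m[a2, ] & m[b1, ] == m[b2, ] & m[a1, ] != m[b1, ]
  cols <- which(sel)
  alleleA <- m[a1, cols]
  alleleB <- m[b1, cols]
  # collapse consecutive columns of one indel event to its first column
  if (length(cols) > 1L) {
    gapSide <- ifelse(alleleA == "-", "A", ifelse(alleleB == "-", "B", ""))
    drop <- c(FALSE, diff(cols) == 1L &
                gapSide[-1L] == gapSide[-length(gapSide)] &
                gapSide[-1L] != "")
    cols <- cols[!drop]
    alleleA <- alleleA[!drop]
    alleleB <- alleleB[!drop]
  }
  new("DiagnosticSiteSet", msaId = msaId, typeA = typeA, typeB = typeB,
      degenerateA = a1 == a2, degenerateB = b1 == b2,
      sites = data.frame(column = cols, alleleA = unname(alleleA),
                         alleleB = unname(alleleB)))
}

#' Paint a query along diagnostic sites and call recombination
#'
#' At each diagnostic site the query symbol is called \code{A} or \code{B}
#' when it equals the corresponding parental allele, and \code{nonref}
#' otherwise (any other variation is a non-reference variant and is
#' ignored for segmentation). Parental calls are segmented into maximal
#' runs; runs supported by fewer than \code{minSitesPerSegment} sites do
#' not create a segment (robustness against isolated convergent
#' mutations), and adjacent same-type segments merge across them. Each
#' template switch is reported as the open column interval between the
#' flanking diagnostic sites of adjacent segments.
#'
#' @param msa Aligned \code{DNAStringSet}.
#' @param queryId Query row id.
#' @param sites A \code{\linkS4class{DiagnosticSiteSet}}.
#' @param minSitesPerSegment Minimum sites per parental segment (default
#'   2).
#' @return A \code{\linkS4class{RecombinationCall}}.
#' @export
callRecombinant <- function(msa, queryId, sites, minSitesPerSegment = 2L) {
  stopifnot(is(sites, "DiagnosticSiteSet"))
  st <- siteTable(sites)
  if (nrow(st) < 2L) stop("need at least 2 diagnostic sites")
  m <- .msaMatrix(msa)
  if (!queryId %in% rownames(m))
    stop("query row '", queryId, "' absent from MSA")
  sym <- m[queryId, st$column]
  call <- ifelse(sym == st$alleleA, "A",
                 ifelse(sym == st$alleleB, "B", "nonref"))
  calls <- data.frame(column = st$column, symbol = unname(sym),
                      call = unname(call))
  par <- calls[calls$call != "nonref", , drop = FALSE]
  if (!nrow(par))
    stop("unrelated_query: all diagnostic sites are non-reference in '",
         queryId, "'")
  r <- rle(par$call)
  # drop runs below the support threshold, then merge adjacent equal runs
  keep <- r$lengths >= minSitesPerSegment
  runsEnd <- cumsum(r$lengths)
  runsStart <- runsEnd - r$lengths + 1L
  segs <- data.frame(call = r$values[keep],
                     startIdx = runsStart[keep], endIdx = runsEnd[keep])
  if (nrow(segs) > 1L) {
    merged <- segs[1L, ]
    for (i in 2L:nrow(segs)) {
      if (segs$call[i] == merged$call[nrow(merged)]) {
        merged$endIdx[nrow(merged)] <- segs$endIdx[i]
      } else {
        merged <- rbind(merged, segs[i, ])
      }
    }
    segs <- merged
  }
  segments <- data.frame(
    call = segs$call,
    startCol = par$column[segs$startIdx],
    endCol = par$column[segs$endIdx],
    nSites = segs$endIdx - segs$startIdx + 1L)
  nSeg <- nrow(segments)
  breakpoints <- if (nSeg > 1L)
    data.frame(from = segments$endCol[-nSeg], to = segments$startCol[-1L])
  else data.frame(from = integer(), to = integer())
  new("RecombinationCall", queryId = queryId, typeA = sites@typeA,
      typeB = sites@typeB, calls = calls, segments = segments,
      breakpoints = breakpoints, nSwitches = max(nSeg - 1L, 0L),
      ltrMismatch = NA)
}

#' Per-column frequency profile of an MSA
#'
#' For every alignment column, the occupancy (fraction of non-gap rows)
#' and the frequencies of the most, second-most and third-most frequent
#' non-gap symbol among the non-gap rows. An invariant column has f1 = 1;
#' the second frequency highlights polymorphic (e.g. variant-segregating)
#' columns. Rank ties are broken by symbol order (A < C < G < N < T) for
#' reporting which base holds each rank.
#'
#' @param msa Aligned \code{DNAStringSet} with at least 2 rows.
#' @return A \code{data.frame}: \code{column}, \code{occupancy},
#'   \code{base1}, \code{f1}, \code{base2}, \code{f2}, \code{base3},
#'   \code{f3}.
#' @export
siteFrequencyProfile <- function(msa) {
  if (length(msa) < 2L) stop("an alignment needs at least 2 rows")
  m <- .msaMatrix(msa)
  nrows <- nrow(m)
  ncols <- ncol(m)
  syms <- c("A", "C", "G", "N", "T")
  out <- data.frame(column = seq_len(ncols), occupancy = 0,
                    base1 = "", f1 = 0, base2 = "", f2 = 0,
                    base3 = "", f3 = 0)
  for (j in seq_len(ncols)) {
    col <- m[, j]
    nonGap <- col[col != "-"]
    out$occupancy[j] <- length(nonGap) / nrows
    if (!length(nonGap)) next
    cnt <- table(factor(nonGap, levels = syms))
    ord <- order(-cnt, syms)
    top <- ord[cnt[ord] > 0]
    freqs <- as.numeric(cnt[top]) / length(nonGap)
    for (rk in seq_len(min(3L, length(top)))) {
      out[[paste0("base", rk)]][j] <- syms[top[rk]]
      out[[paste0("f", rk)]][j] <- freqs[rk]
    }
  }
  out
}
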