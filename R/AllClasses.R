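#' @import methods
#' @importFrom S4Vectors isSingleString
NULL

.FEATURE_LEVELS <- c("LTR5", "UTR5", "GAG", "POL", "ENVF", "UTR3", "LTR3")
.ORF_FEATURES <- c("GAG", "POL", "ENVF")

#' ConsensusElement: an annotated transposable-element consensus
#'
#' Holds one TE consensus sequence together with its feature annotation
#' (both LTRs, untranslated regions and the gag / pol / env-F open reading
#' frames) as a \link[GenomicRanges]{GRanges} on the element itself, plus a
#' subclade label and the envelope status of the lineage.
#'
#' Feature coordinates are stored 1-based closed (the
#' Bioconductor convention); the tab-separated annotation format read by
#' \code{\link{readAnnotationTable}} is 0-based half-open and is converted
#' on input.
#'
#' @slot id Element identifier.
#' @slot sequence A \link[Biostrings]{DNAString} over A/C/G/T/N.
#' @slot features A \code{GRanges} with metadata column \code{feature}
#'   (one of LTR5, UTR5, GAG, POL, ENVF, UTR3, LTR3).
#' @slot subclade Free-text subclade label (may be \code{""}).
#' @slot envStatus One of \code{"full_length"}, \code{"remnant"},
#'   \code{"absent"}, \code{"unknown"}.
#'
#' @seealso \code{\link{consensusElement}}, \code{\link{featureSeq}}
#' @exportClass ConsensusElement
setClass("ConsensusElement",
  representation(
    id = "character",
    sequence = "DNAString",
    features = "GRanges",
    subclade = "character",
    envStatus = "character"
  )
)

setValidity("ConsensusElement", function(object) {
  msg <- character()
  if (!isSingleString(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a non-empty string")
  if (length(object@sequence) < 1L)
    msg <- c(msg, "'sequence' must be non-empty")
  feat <- object@features$feature
  if (is.null(feat))
    msg <- c(msg, "'features' needs a metadata column 'feature'")
  else {
    if (!all(feat %in% .FEATURE_LEVELS))
      msg <- c(msg, paste0("unknown feature(s): ",
                           paste(setdiff(feat, .FEATURE_LEVELS), collapse = ", ")))
    if (!all(c("LTR5", "LTR3") %in% feat))
      msg <- c(msg, "both LTR5 and LTR3 must be annotated")
    if (anyDuplicated(feat))
      msg <- c(msg, "each feature may appear at most once")
    if (length(object@features) &&
        (min(GenomicRanges::start(object@features)) < 1L ||
         max(GenomicRanges::end(object@features)) > length(object@sequence)))
      msg <- c(msg, "feature coordinates exceed the sequence")
    # features must not overlap, except ENVF which may share sequence with
    # POL / UTR3 (overlapping reading frames occur in LTR elements)
    core <- object@features[feat != "ENVF"]
    if (length(core) > 1L) {
      hits <- IRanges::findOverlaps(GenomicRanges::ranges(core),
                                    drop.self = TRUE, drop.redundant = TRUE)
      if (length(hits))
        msg <- c(msg, "non-ENVF features overlap")
    }
  }
  if (!object@envStatus %in% c("full_length", "remnant", "absent", "unknown"))
    msg <- c(msg, "invalid 'envStatus'")
  if (length(msg)) msg else TRUE
})

#' InsertionRecord: one genomic TE insertion
#'
#' A single extracted full-length insertion of an LTR element, in element
#' orientation, with optional flanking sequence and, once
#' \code{\link{extractLtrPair}} has been run, the two extracted LTR copies.
#'
#' @slot id Insertion identifier.
#' @slot seq A \link[Biostrings]{DNAString}.
#' @slot source Source genome / locus label (free text, may be \code{""}).
#' @slot flank5,flank3 Optional flanking sequence (character, \code{""} if
#'   absent).
#' @slot ltr5,ltr3 Extracted LTR copies (character, \code{""} until
#'   extracted).
#'
#' @exportClass InsertionRecord
setClass("InsertionRecord",
  representation(
    id = "character",
    seq = "DNAString",
    source = "character",
    flank5 = "character",
    flank3 = "character",
    ltr5 = "character",
    ltr3 = "character"
  ),
  prototype(source = "", flank5 = "", flank3 = "", ltr5 = "", ltr3 = "")
)

setValidity("InsertionRecord", function(object) {
  if (!isSingleString(object@id) || !nzchar(object@id))
    return("'id' must be a non-empty string")
  if (length(object@seq) < 1L)
    return("'seq' must be non-empty")
  TRUE
})

#' KmerIndex: the distinct k-mers of a piRNA-cluster sequence
#'
#' The set of all distinct k-length substrings (step 1) of a cluster
#' sequence in its transcribed orientation, optionally together with those
#' of its reverse complement for dual-strand clusters. Windows containing N
#' are dropped; multiplicity is discarded (binary coverage makes counts
#' irrelevant).
#'
#' @slot k Word length (default 25 throughout the package, the piRNA-sized
#'   word the coverage statistic mimics).
#' @slot sourceId Cluster identifier.
#' @slot kmers Character vector of distinct k-mers.
#' @slot bothStrands Whether reverse-complement k-mers were included
#'   (dual-strand cluster).
#'
#' @seealso \code{\link{buildKmerIndex}}, \code{\link{kmerCoverage}}
#' @exportClass KmerIndex
setClass("KmerIndex",
  representation(
    k = "integer",
    sourceId = "character",
    kmers = "character",
    bothStrands = "logical"
  )
)

setValidity("KmerIndex", function(object) {
  msg <- character()
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msg <- c(msg, "'k' must be a positive integer")
  if (length(object@kmers) && any(nchar(object@kmers) != object@k))
    msg <- c(msg, "all k-mers must have length k")
  if (length(object@kmers) && any(grepl("N", object@kmers, fixed = TRUE)))
    msg <- c(msg, "k-mers must not contain N")
  if (length(msg)) msg else TRUE
})

#' CoverageProfile: per-position antisense k-mer coverage of a consensus
#'
#' Binary per-position coverage of a consensus sequence by cluster-derived
#' k-mers, with the summary fraction used as the "silencing potential" of
#' the cluster against that element.
#'
#' @slot consensusId,clusterId Identifiers of the pair.
#' @slot orientation \code{"antisense"} or \code{"sense"}.
#' @slot covered Logical vector, one element per consensus position.
#' @slot k Word length used.
#' @slot maxMismatch Hamming mismatches allowed per window.
#' @slot fraction Covered positions / consensus length.
#'
#' @seealso \code{\link{kmerCoverage}}, \code{\link{writeCoverageBed}}
#' @exportClass CoverageProfile
setClass("CoverageProfile",
  representation(
    consensusId = "character",
    clusterId = "character",
    orientation = "character",
    covered = "logical",
    k = "integer",
    maxMismatch = "integer",
    fraction = "numeric"
  )
)

setValidity("CoverageProfile", function(object) {
  msg <- character()
  if (!object@orientation %in% c("antisense", "sense"))
    msg <- c(msg, "'orientation' must be 'antisense' or 'sense'")
  if (length(object@covered) == 0L)
    msg <- c(msg, "'covered' must be non-empty")
  else if (abs(object@fraction - mean(object@covered)) > 1e-12)
    msg <- c(msg, "'fraction' must equal mean(covered)")
  if (object@fraction < 0 || object@fraction > 1)
    msg <- c(msg, "'fraction' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' DiagnosticSiteSet: alignment columns separating two variant types
#'
#' Columns of a multiple sequence alignment at which two insertions of
#' variant type A share one symbol, two insertions of type B share a
#' different symbol. The gap symbol is a valid shared allele, so indel
#' variants are captured; runs of consecutive columns belonging to one
#' indel event are collapsed to the event's first column.
#'
#' @slot msaId Alignment identifier.
#' @slot typeA,typeB Variant type names.
#' @slot degenerateA,degenerateB TRUE when the corresponding parent pair
#'   was supplied as a single sequence (a1 == a2), mirroring variant types
#'   for which only one good complete insertion exists.
#' @slot sites \code{data.frame} with columns \code{column} (1-based MSA
#'   column), \code{alleleA}, \code{alleleB}.
#'
#' @seealso \code{\link{diagnosticSites}}, \code{\link{callRecombinant}}
#' @exportClass DiagnosticSiteSet
setClass("DiagnosticSiteSet",
  representation(
    msaId = "character",
    typeA = "character",
    typeB = "character",
    degenerateA = "logical",
    degenerateB = "logical",
    sites = "data.frame"
  )
)

setValidity("DiagnosticSiteSet", function(object) {
  s <- object@sites
  msg <- character()
  if (!all(c("column", "alleleA", "alleleB") %in% names(s)))
    msg <- c(msg, "'sites' needs columns column, alleleA, alleleB")
  else {
    if (is.unsorted(s$column, strictly = TRUE))
      msg <- c(msg, "'sites' must be strictly sorted by column")
    if (any(s$alleleA == s$alleleB))
      msg <- c(msg, "alleles must differ at every diagnostic site")
  }
  if (length(msg)) msg else TRUE
})

#' RecombinationCall: parental painting of a query along diagnostic sites
#'
#' Per-site parental assignment (A, B or non-reference) of a query
#' insertion, segmentation of the calls into parental blocks, and the
#' breakpoint intervals between adjacent blocks. Breakpoints are open
#' column intervals bounded by the flanking diagnostic sites of the two
#' segments -- resolution is limited by informative sites, so no point
#' estimate is reported.
#'
#' @slot queryId Query row id.
#' @slot typeA,typeB Parental type names.
#' @slot calls \code{data.frame}: \code{column}, \code{symbol} (query
#'   symbol), \code{call} in \{A, B, nonref\}.
#' @slot segments \code{data.frame}: \code{call}, \code{startCol},
#'   \code{endCol}, \code{nSites}.
#' @slot breakpoints \code{data.frame}: \code{from}, \code{to} (open
#'   interval between flanking diagnostic sites).
#' @slot nSwitches Number of template switches (segments - 1).
#' @slot ltrMismatch TRUE/FALSE/NA: whether the 5' and 3' LTRs type to
#'   different variants (NA when not assessed or indeterminate).
#'
#' @exportClass RecombinationCall
setClass("RecombinationCall",
  representation(
    queryId = "character",
    typeA = "character",
    typeB = "character",
    calls = "data.frame",
    segments = "data.frame",
    breakpoints = "data.frame",
    nSwitches = "integer",
    ltrMismatch = "logical"
  )
)

setValidity("RecombinationCall", function(object) {
  msg <- character()
  if (nrow(object@segments) &&
      object@nSwitches != nrow(object@segments) - 1L)
    msg <- c(msg, "nSwitches must equal nrow(segments) - 1")
  if (nrow(object@breakpoints) > 1L) {
    bp <- object@breakpoints
    if (any(bp$from[-1] < bp$to[-nrow(bp)]))
      msg <- c(msg, "breakpoint intervals must be ordered and non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "ConsensusElement", function(object) {
  cat("ConsensusElement '", object@id, "' (", length(object@sequence),
      " nt", sep = "")
  if (nzchar(object@subclade)) cat(", subclade ", object@subclade, sep = "")
  cat(", env-F ", object@envStatus, ")\n", sep = "")
  feat <- object@features
  if (length(feat)) {
    o <- order(GenomicRanges::start(feat))
    cat("  features: ",
        paste0(feat$feature[o], "[", GenomicRanges::start(feat)[o], "-",
               GenomicRanges::end(feat)[o], "]", collapse = " "),
        "\n", sep = "")
  }
})

setMethod("show", "InsertionRecord", function(object) {
  cat("InsertionRecord '", object@id, "' (", length(object@seq), " nt",
      sep = "")
  if (nzchar(object@source)) cat(", source ", object@source, sep = "")
  cat(")", if (nzchar(object@ltr5)) " [LTRs extracted]", "\n", sep = "")
})

setMethod("show", "KmerIndex", function(object) {
  cat("KmerIndex of '", object@sourceId, "': ", length(object@kmers),
      " distinct ", object@k, "-mers",
      if (object@bothStrands) " (both strands)", "\n", sep = "")
})

setMethod("show", "CoverageProfile", function(object) {
  cat(sprintf("CoverageProfile %s ~ %s (%s, k=%d, mm=%d): %.4f covered\n",
              object@consensusId, object@clusterId, object@orientation,
              object@k, object@maxMismatch, object@fraction))
})

setMethod("show", "DiagnosticSiteSet", function(object) {
  cat("DiagnosticSiteSet ", object@typeA, " vs ", object@typeB, ": ",
      nrow(object@sites), " sites",
      if (object@degenerateA) " [A degenerate]",
      if (object@degenerateB) " [B degenerate]", "\n", sep = "")
})

setMethod("show", "RecombinationCall", function(object) {
  cat("RecombinationCall '", object@queryId, "': ", nrow(object@segments),
      " segment(s), ", object@nSwitches, " switch(es)", sep = "")
  if (nrow(object@segments))
    cat(" [", paste(object@segments$call, collapse = ">"), "]", sep = "")
  if (!is.na(object@ltrMismatch))
    cat(", LTR mismatch: ", object@ltrMismatch, sep = "")
  cat("\n")
})

## ---- accessors ----------------------------------------------------------

#' Accessors for ervscape S4 objects
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param x An ervscape S4 object.
#' @param feature For \code{featureSeq}/\code{featureRange}, one of
#'   \code{"LTR5"}, \code{"UTR5"}, \code{"GAG"}, \code{"POL"},
#'   \code{"ENVF"}, \code{"UTR3"}, \code{"LTR3"}.
#' @return \code{elementId}: the identifier. \code{elementSeq}: the
#'   \code{DNAString}. \code{featureRange}: an \code{IRanges} (1-based
#'   closed) or \code{NULL} when the feature is not annotated.
#'   \code{featureSeq}: the feature subsequence as a \code{DNAString}.
#'   \code{coveredFraction}: the coverage fraction.
#'   \code{coveredPositions}: the logical coverage vector.
#'   \code{siteTable}, \code{callTable}, \code{segmentTable},
#'   \code{breakpointTable}: the underlying \code{data.frame}s.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("elementId", function(x) standardGeneric("elementId"))
#' @rdname accessors
#' @export
setGeneric("elementSeq", function(x) standardGeneric("elementSeq"))
#' @rdname accessors
#' @export
setGeneric("featureRange", function(x, feature) standardGeneric("featureRange"))
#' @rdname accessors
#' @export
setGeneric("featureSeq", function(x, feature) standardGeneric("featureSeq"))
#' @rdname accessors
#' @export
setGeneric("coveredFraction", function(x) standardGeneric("coveredFraction"))
#' @rdname accessors
#' @export
setGeneric("coveredPositions", function(x) standardGeneric("coveredPositions"))
#' @rdname accessors
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))
#' @rdname accessors
#' @export
setGeneric("callTable", function(x) standardGeneric("callTable"))
#' @rdname accessors
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))
#' @rdname accessors
#' @export
setGeneric("breakpointTable", function(x) standardGeneric("breakpointTable"))
#' @rdname accessors
#' @export
setGeneric("nSwitches", function(x) standardGeneric("nSwitches"))
#' @rdname accessors
#' @export
setGeneric("ltrMismatch", function(x) standardGeneric("ltrMismatch"))

#' @rdname accessors
setMethod("elementId", "ConsensusElement", function(x) x@id)
#' @rdname accessors
setMethod("elementId", "InsertionRecord", function(x) x@id)
#' @rdname accessors
setMethod("elementSeq", "ConsensusElement", function(x) x@sequence)
#' @rdname accessors
setMethod("elementSeq", "InsertionRecord", function(x) x@seq)

#' @rdname accessors
setMethod("featureRange", "ConsensusElement", function(x, feature) {
  feature <- match.arg(feature, .FEATURE_LEVELS)
  i <- which(x@features$feature == feature)
  if (!length(i)) return(NULL)
  GenomicRanges::ranges(x@features)[i]
})

#' @rdname accessors
setMethod("featureSeq", "ConsensusElement", function(x, feature) {
  r <- featureRange(x, feature)
  if (is.null(r))
    stop("feature '", feature, "' is not annotated on '", x@id, "'")
  Biostrings::subseq(x@sequence, IRanges::start(r), IRanges::end(r))
})

#' @rdname accessors
setMethod("coveredFraction", "CoverageProfile", function(x) x@fraction)
#' @rdname accessors
setMethod("coveredPositions", "CoverageProfile", function(x) x@covered)
#' @rdname accessors
setMethod("siteTable", "DiagnosticSiteSet", function(x) x@sites)
#' @rdname accessors
setMethod("callTable", "RecombinationCall", function(x) x@calls)
#' @rdname accessors
setMethod("segmentTable", "RecombinationCall", function(x) x@segments)
#' @rdname accessors
setMethod("breakpointTable", "RecombinationCall", function(x) x@breakpoints)
#' @rdname accessors
setMethod("nSwitches", "RecombinationCall", function(x) x@nSwitches)
#' @rdname accessors
setMethod("ltrMismatch", "RecombinationCall", function(x) x@ltrMismatch)

## ---- constructors -------------------------------------------------------

#' Construct a ConsensusElement from a sequence and an annotation table
#'
#' Binds a consensus sequence to its feature annotation. \code{annot} uses
#' the on-disk convention of \code{\link{readAnnotationTable}} (columns
#' \code{element_id}, \code{feature}, \code{start}, \code{end}; 0-based
#' half-open); rows for other elements are ignored.
#'
#' @param id Element identifier (must match \code{annot$element_id}).
#' @param seq Sequence: a \code{DNAString} or character string.
#' @param annot Annotation \code{data.frame} (0-based half-open).
#' @param subclade Optional subclade label.
#' @param envStatus Envelope status; default \code{"unknown"}.
#' @return A \code{\linkS4class{ConsensusElement}}.
#' @examples
#' annot <- data.frame(element_id = "e", feature = c("LTR5", "LTR3"),
#'                     start = c(0L, 80L), end = c(20L, 100L))
#' ce <- consensusElement("e", paste(rep("ACGTT", 20), collapse = ""), annot)
#' featureRange(ce, "LTR3")
#' @export
consensusElement <- function(id, seq, annot, subclade = "",
                             envStatus = "unknown") {
  if (is.character(seq)) seq <- Biostrings::DNAString(.normalizeSeq(seq, id))
  annot <- annot[annot$element_id == id, , drop = FALSE]
  if (!nrow(annot))
    stop("no annotation rows for element '", id, "'")
  bad <- annot$end > length(seq)
  if (any(bad))
    stop("annotation for '", id, "' exceeds sequence length (feature ",
         paste(annot$feature[bad], collapse = ", "), ")")
  gr <- GenomicRanges::GRanges(
    seqnames = id,
    ranges = IRanges::IRanges(start = annot$start + 1L, end = annot$end),
    strand = "+",
    feature = as.character(annot$feature)
  )
  new("ConsensusElement", id = id, sequence = seq, features = gr,
      subclade = subclade, envStatus = envStatus)
}

#' Construct an InsertionRecord
#'
#' @param id Insertion identifier.
#' @param seq Sequence (character or \code{DNAString}), element-oriented.
#' @param source Optional source genome / locus label.
#' @param flank5,flank3 Optional flanking sequences.
#' @return An \code{\linkS4class{InsertionRecord}}.
#' @export
insertionRecord <- function(id, seq, source = "", flank5 = "", flank3 = "") {
  if (is.character(seq)) seq <- Biostrings::DNAString(.normalizeSeq(seq, id))
  new("InsertionRecord", id = id, seq = seq, source = source,
      flank5 = flank5, flank3 = flank3)
}
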