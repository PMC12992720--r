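## Synthetic data with ground truth. The generator encodes the generative
## assumptions the analyses invert: proviruses insert with identical LTRs
## and each LTR then accumulates Poisson(r * T * L) substitutions
## independently (JC-symmetric, no indel evolution -- indels enter only via
## injectInactivation / makeRecombinant, keeping the truth exact); piRNA
## clusters are spacer-interleaved oriented TE fragments; recombinants are
## coordinate-based template switches between two homologous parents.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    })
    set.seed(seed)
  }
  expr
}

.randSeq <- function(n, baseComp = c(A = 0.25, C = 0.25, G = 0.25,
                                     T = 0.25)) {
  paste(sample(names(baseComp), n, replace = TRUE, prob = baseComp),
        collapse = "")
}

.NONSTOP_CODONS <- {
  all3 <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                paste0), c("A", "C", "G", "T"), paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

# random ORF: ATG + stop-free internal codons + TAA; length in nt
.randOrf <- function(lenNt) {
  stopifnot(lenNt %% 3L == 0L, lenNt >= 9L)
  nInternal <- lenNt %/% 3L - 2L
  paste0("ATG", paste(sample(.NONSTOP_CODONS, nInternal, replace = TRUE),
                      collapse = ""), "TAA")
}

#' Simulation parameters
#'
#' Defaults describe a compact but structurally complete errantivirus-like
#' element: 400 nt LTRs (a typical Drosophila LTR length and the length
#' used by the dating validation), a 200 nt 5' UTR, gag / pol / env-F ORFs
#' of 900 / 1500 / 900 nt, a 150 nt 3' UTR, uniform base composition
#' (minimizing chance k-mer hits in fixtures), and the Drosophila neutral
#' rate r = 0.0346 subs/site/Myr.
#'
#' @param ltrLen,utr5Len,utr3Len Region lengths in nt.
#' @param orfLens Named nt lengths (multiples of 3) for \code{gag},
#'   \code{pol}, \code{envF}.
#' @param r Substitution rate (subs/site/Myr).
#' @param baseComp Named base probabilities summing to 1.
#' @return A list of validated parameters.
#' @export
simParams <- function(ltrLen = 400L, utr5Len = 200L,
                      orfLens = c(gag = 900L, pol = 1500L, envF = 900L),
                      utr3Len = 150L, r = 0.0346,
                      baseComp = c(A = 0.25, C = 0.25, G = 0.25,
                                   T = 0.25)) {
  stopifnot(ltrLen > 0L, utr5Len > 0L, utr3Len > 0L,
            all(orfLens > 0L), all(orfLens %% 3L == 0L),
            all(c("gag", "pol", "envF") %in% names(orfLens)),
            r > 0, abs(sum(baseComp) - 1) < 1e-9)
  list(ltrLen = as.integer(ltrLen), utr5Len = as.integer(utr5Len),
       orfLens = vapply(orfLens, as.integer, integer(1)),
       utr3Len = as.integer(utr3Len), r = r, baseComp = baseComp)
}

#' Simulate a structured TE consensus element
#'
#' Builds LTR5 + UTR5 + gag + pol + env-F + UTR3 + LTR3 with the two LTRs
#' exactly identical (the state of a provirus at insertion) and each ORF
#' ATG-initiated, internally stop-free in frame 0 and stop-terminated.
#' Identical seeds give byte-identical output.
#'
#' @param id Element id.
#' @param params See \code{\link{simParams}}.
#' @param seed Integer seed.
#' @return A \code{\linkS4class{ConsensusElement}} (envStatus
#'   \code{"full_length"}).
#' @export
simConsensus <- function(id = "consA", params = simParams(), seed = 1L) {
  .withSeed(seed, {
    ltr <- .randSeq(params$ltrLen, params$baseComp)
    utr5 <- .randSeq(params$utr5Len, params$baseComp)
    gag <- .randOrf(params$orfLens[["gag"]])
    pol <- .randOrf(params$orfLens[["pol"]])
    envF <- .randOrf(params$orfLens[["envF"]])
    utr3 <- .randSeq(params$utr3Len, params$baseComp)
    parts <- c(LTR5 = ltr, UTR5 = utr5, GAG = gag, POL = pol, ENVF = envF,
               UTR3 = utr3, LTR3 = ltr)
    lens <- nchar(parts)
    ends <- cumsum(lens)
    starts0 <- ends - lens          # 0-based half-open starts
    annot <- data.frame(element_id = id, feature = names(parts),
                        start = as.integer(starts0),
                        end = as.integer(ends))
    consensusElement(id, paste(parts, collapse = ""), annot,
                     envStatus = "full_length")
  })
}

#' Annotation table of a ConsensusElement
#'
#' Returns the features in the on-disk convention (0-based half-open),
#' suitable for writing next to a FASTA of the element.
#'
#' @param element A \code{ConsensusElement}.
#' @return A \code{data.frame}: \code{element_id}, \code{feature},
#'   \code{start}, \code{end}.
#' @export
annotationTable <- function(element) {
  stopifnot(is(element, "ConsensusElement"))
  f <- element@features
  o <- order(GenomicRanges::start(f))
  data.frame(element_id = elementId(element),
             feature = f$feature[o],
             start = GenomicRanges::start(f)[o] - 1L,
             end = GenomicRanges::end(f)[o])
}

# apply n random substitutions (JC-symmetric target) to chars[idx range]
.mutateChars <- function(chars, n) {
  L <- length(chars)
  if (n == 0L || L == 0L) return(chars)
  pos <- sample.int(L, n, replace = TRUE)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  chars
}

#' Evolve an insertion of known age from a consensus
#'
#' Starting from an exact copy of the consensus, places
#' Poisson(r * age * length) substitutions uniformly and independently on
#' the 5' LTR, the 3' LTR and the internal sequence (JC-symmetric random
#' target base). Because the two LTRs drift independently, their expected
#' pairwise divergence is 2 r T -- the quantity the dating estimator
#' inverts. No indels are introduced.
#'
#' @param consensus A \code{ConsensusElement}.
#' @param ageMyr True insertion age in Myr.
#' @param r Substitution rate (subs/site/Myr).
#' @param seed Integer seed.
#' @param id Insertion id.
#' @return A list: \code{record} (\code{InsertionRecord}), \code{truth}
#'   (\code{data.frame}: id, age_myr, n_sub_ltr5, n_sub_ltr3,
#'   n_sub_internal).
#' @export
evolveInsertion <- function(consensus, ageMyr, r = 0.0346, seed = 1L,
                            id = "ins1") {
  stopifnot(is(consensus, "ConsensusElement"), ageMyr >= 0, r > 0)
  .withSeed(seed, {
    chars <- strsplit(as.character(elementSeq(consensus)), "")[[1]]
    r5 <- featureRange(consensus, "LTR5")
    r3 <- featureRange(consensus, "LTR3")
    i5 <- IRanges::start(r5):IRanges::end(r5)
    i3 <- IRanges::start(r3):IRanges::end(r3)
    iIn <- setdiff(seq_along(chars), c(i5, i3))
    n5 <- stats::rpois(1L, r * ageMyr * length(i5))
    n3 <- stats::rpois(1L, r * ageMyr * length(i3))
    nIn <- stats::rpois(1L, r * ageMyr * length(iIn))
    chars[i5] <- .mutateChars(chars[i5], n5)
    chars[i3] <- .mutateChars(chars[i3], n3)
    chars[iIn] <- .mutateChars(chars[iIn], nIn)
    rec <- insertionRecord(id, paste(chars, collapse = ""),
                           source = elementId(consensus))
    list(record = rec,
         truth = data.frame(id = id, age_myr = ageMyr, n_sub_ltr5 = n5,
                            n_sub_ltr3 = n3, n_sub_internal = nIn))
  })
}

#' Assemble a synthetic piRNA cluster from oriented TE fragments
#'
#' Interleaves random spacers with fragments of consensus elements, each
#' inserted in the planned orientation -- emulating a cluster that has
#' trapped TE insertions, the antisense ones conferring silencing
#' potential. The truth table records, per fragment, the consensus
#' interval it covers and where it landed in the cluster, from which the
#' expected antisense coverage of each consensus follows directly (up to
#' k-1 positions of junction slack per fragment end).
#'
#' @param consensuses Named list of \code{ConsensusElement}s (or named
#'   \code{DNAStringSet}).
#' @param plan \code{data.frame} with columns \code{consensus_id},
#'   \code{start}, \code{end} (1-based closed on the consensus),
#'   \code{orientation} (\code{"sense"} or \code{"antisense"}).
#' @param spacerLen Spacer length between fragments (default 100).
#' @param seed Integer seed (spacers are random).
#' @param id Cluster id.
#' @param baseComp Spacer base composition.
#' @return A list: \code{seq} (named \code{DNAStringSet} of length 1),
#'   \code{truth} (\code{data.frame} adding \code{cluster_start},
#'   \code{cluster_end}, 1-based closed on the cluster).
#' @export
assembleCluster <- function(consensuses, plan, spacerLen = 100L, seed = 1L,
                            id = "cluster1",
                            baseComp = c(A = 0.25, C = 0.25, G = 0.25,
                                         T = 0.25)) {
  getSeq <- function(cid) {
    x <- consensuses[[cid]]
    if (is.null(x)) stop("plan references unknown consensus '", cid, "'")
    if (is(x, "ConsensusElement")) as.character(elementSeq(x))
    else as.character(x)
  }
  stopifnot(all(c("consensus_id", "start", "end", "orientation") %in%
                  names(plan)))
  .withSeed(seed, {
    pieces <- character()
    truth <- plan
    truth$cluster_start <- NA_integer_
    truth$cluster_end <- NA_integer_
    at <- 0L
    for (i in seq_len(nrow(plan))) {
      sp <- .randSeq(spacerLen, baseComp)
      src <- getSeq(plan$consensus_id[i])
      if (plan$start[i] < 1L || plan$end[i] > nchar(src) ||
          plan$start[i] > plan$end[i])
        stop("invalid plan interval in row ", i)
      frag <- substr(src, plan$start[i], plan$end[i])
      if (plan$orientation[i] == "antisense") frag <- revComp(frag)
      else if (plan$orientation[i] != "sense")
        stop("orientation must be 'sense' or 'antisense'")
      pieces <- c(pieces, sp, frag)
      at <- at + nchar(sp)
      truth$cluster_start[i] <- at + 1L
      at <- at + nchar(frag)
      truth$cluster_end[i] <- at
    }
    pieces <- c(pieces, .randSeq(spacerLen, baseComp))
    out <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
    names(out) <- id
    list(seq = out, truth = truth)
  })
}

#' Build a recombinant sequence by template switching between two parents
#'
#' Copies parent 1 up to the first breakpoint, parent 2 (at the homologous
#' coordinate) up to the second, and so on alternating -- the DNA-level
#' emulation of reverse-transcriptase strand switching between the two
#' co-packaged genomes of a pseudo-diploid virion. Equal-length parents
#' map coordinates 1:1; otherwise the homologous coordinate is found via
#' the shared global aligner.
#'
#' @param parent1,parent2 Homologous parental sequences (character or
#'   \code{DNAString}).
#' @param breakpoints Strictly increasing positions in parent-1
#'   coordinates (1-based: the last parent-1-template base before each
#'   switch).
#' @param id Output id.
#' @return A list: \code{seq} (character), \code{truth}
#'   (\code{data.frame}: id, breakpoint positions in both parents'
#'   coordinates).
#' @export
makeRecombinant <- function(parent1, parent2, breakpoints,
                            id = "recomb1") {
  p1 <- as.character(parent1)
  p2 <- as.character(parent2)
  L1 <- nchar(p1)
  if (length(breakpoints)) {
    stopifnot(all(breakpoints >= 1L), all(breakpoints < L1),
              !is.unsorted(breakpoints, strictly = TRUE))
  }
  if (!length(breakpoints))
    return(list(seq = p1,
                truth = data.frame(id = character(), bp_parent1 = integer(),
                                   bp_parent2 = integer())))
  map <- if (nchar(p1) == nchar(p2)) {
    seq_len(L1)
  } else {
    .mapSubjectToPattern(.alignGlobal(p2, p1))   # parent1 -> parent2 coords
  }
  bp2 <- map[breakpoints]
  if (anyNA(bp2))
    stop("breakpoint falls outside the alignable region of parent2")
  bounds1 <- c(0L, breakpoints, L1)
  pieces <- character()
  for (seg in seq_len(length(breakpoints) + 1L)) {
    fromParent1 <- seg %% 2L == 1L
    if (fromParent1) {
      pieces <- c(pieces, substr(p1, bounds1[seg] + 1L, bounds1[seg + 1L]))
    } else {
      from2 <- bp2[seg - 1L] + 1L
      to2 <- if (seg == length(breakpoints) + 1L) nchar(p2)
             else bp2[seg]
      pieces <- c(pieces, substr(p2, from2, to2))
    }
  }
  list(seq = paste(pieces, collapse = ""),
       truth = data.frame(id = id, bp_parent1 = breakpoints,
                          bp_parent2 = bp2))
}

#' Derive a named variant haplotype from a consensus
#'
#' Applies fixed variant-defining substitutions to a consensus element and
#' copies the mutated 5' LTR over the 3' LTR, so the variant -- like a
#' real, recently mobile variant lineage -- carries its own LTR sequence
#' identically at both ends. Useful for building parent/recombinant panels
#' in which recombinants betray themselves by mismatched LTR types.
#'
#' @param consensus A \code{ConsensusElement}.
#' @param nSubs Number of variant-defining substitutions (placed on the
#'   5' LTR + internal sequence, then the LTR is duplicated).
#' @param seed Integer seed.
#' @param id Variant name (e.g. \code{"LTR-408"}).
#' @return A list: \code{seq} (character), \code{ltr} (the variant's LTR
#'   sequence), \code{id}.
#' @export
simVariant <- function(consensus, nSubs, seed = 1L, id = "variant") {
  stopifnot(is(consensus, "ConsensusElement"))
  .withSeed(seed, {
    chars <- strsplit(as.character(elementSeq(consensus)), "")[[1]]
    r3 <- featureRange(consensus, "LTR3")
    i3 <- IRanges::start(r3):IRanges::end(r3)
    head <- .mutateChars(chars[-i3], as.integer(nSubs))
    r5 <- featureRange(consensus, "LTR5")
    ltr <- paste(head[IRanges::start(r5):IRanges::end(r5)], collapse = "")
    list(seq = paste0(paste(head, collapse = ""), ltr), ltr = ltr, id = id)
  })
}

# nearest ORF position (0-based) whose base differs from both neighbours
.nearestCleanPos <- function(orfChars, pos0) {
  n <- length(orfChars)
  clean <- function(p) {
    i <- p + 1L
    left <- if (i > 1L) orfChars[i - 1L] else ""
    right <- if (i < n) orfChars[i + 1L] else ""
    orfChars[i] != left && orfChars[i] != right
  }
  for (d in 0L:(n - 1L)) {
    for (cand in unique(c(pos0 + d, pos0 - d))) {
      if (cand >= 1L && cand <= n - 2L && clean(cand)) return(cand)
    }
  }
  pos0
}

#' Inject a single inactivating mutation into a consensus ORF
#'
#' Applies one insertion, deletion or stop-codon substitution inside the
#' named ORF and records the exact event for verification by
#' \code{\link{detectInactivation}}. By default the event is shifted to
#' the nearest position not adjacent to an identical base (non-homopolymer
#' context), so the alignment placement of the indel is unambiguous and
#' the recorded coordinate exact; the shift, if any, is visible by
#' comparing \code{position} to \code{requested_position} in the truth.
#'
#' @param consensus A \code{ConsensusElement}.
#' @param orf \code{"GAG"}, \code{"POL"} or \code{"ENVF"}.
#' @param kind \code{"insertion"}, \code{"deletion"} or
#'   \code{"substitution_stop"}.
#' @param position 0-based position on the ORF. For an insertion, the new
#'   base goes \emph{after} this position; for a deletion, bases are
#'   removed starting here; for a stop substitution, the containing codon
#'   is replaced by TAA (position snaps to the codon start).
#' @param len Event length in nt (indels only; default 1).
#' @param avoidHomopolymer Shift indels out of homopolymer context
#'   (default TRUE).
#' @param id Id of the mutated element.
#' @return A list: \code{element} (mutated \code{ConsensusElement} with
#'   shifted feature coordinates), \code{truth} (\code{data.frame}: id,
#'   orf, kind, position (final, 0-based ORF-relative),
#'   requested_position, length).
#' @export
injectInactivation <- function(consensus, orf = c("ENVF", "GAG", "POL"),
                               kind = c("insertion", "deletion",
                                        "substitution_stop"),
                               position, len = 1L,
                               avoidHomopolymer = TRUE,
                               id = paste0(elementId(consensus), "_mut")) {
  orf <- match.arg(orf)
  kind <- match.arg(kind)
  stopifnot(is(consensus, "ConsensusElement"))
  fr <- featureRange(consensus, orf)
  if (is.null(fr)) stop("ORF '", orf, "' not annotated")
  orfLen <- IRanges::width(fr)
  if (position < 0L || position >= orfLen)
    stop("position ", position, " outside ORF '", orf, "' (length ",
         orfLen, ")")
  s <- as.character(elementSeq(consensus))
  orfStart1 <- IRanges::start(fr)
  orfChars <- strsplit(substr(s, orfStart1, IRanges::end(fr)), "")[[1]]
  requested <- as.integer(position)
  pos <- requested
  delta <- 0L
  if (kind == "insertion") {
    if (avoidHomopolymer) pos <- .nearestCleanPos(orfChars, pos)
    left <- orfChars[pos + 1L]
    right <- if (pos + 2L <= orfLen) orfChars[pos + 2L] else ""
    base <- setdiff(c("A", "C", "G", "T"), c(left, right))[1L]
    abs1 <- orfStart1 + pos          # insert after this 1-based position
    s <- paste0(substr(s, 1L, abs1), strrep(base, len),
                substr(s, abs1 + 1L, nchar(s)))
    delta <- as.integer(len)
  } else if (kind == "deletion") {
    if (avoidHomopolymer) pos <- .nearestCleanPos(orfChars, pos)
    if (pos + len > orfLen) stop("deletion runs past the ORF")
    abs1 <- orfStart1 + pos          # first deleted 1-based position
    s <- paste0(substr(s, 1L, abs1 - 1L),
                substr(s, abs1 + len, nchar(s)))
    delta <- -as.integer(len)
  } else {
    codon <- pos %/% 3L
    nCodons <- orfLen %/% 3L
    if (codon < 1L || codon >= nCodons - 1L)
      stop("stop substitution must hit an internal codon")
    pos <- 3L * codon
    abs1 <- orfStart1 + pos
    s <- paste0(substr(s, 1L, abs1 - 1L), "TAA",
                substr(s, abs1 + 3L, nchar(s)))
    len <- 0L
  }
  # shift feature coordinates downstream of the event
  f <- annotationTable(consensus)          # 0-based half-open
  eventAbs0 <- (orfStart1 - 1L) + pos      # 0-based on the consensus
  for (i in seq_len(nrow(f))) {
    if (f$start[i] > eventAbs0) f$start[i] <- f$start[i] + delta
    if (f$end[i] > eventAbs0) f$end[i] <- f$end[i] + delta
  }
  f$element_id <- id
  element <- consensusElement(id, s, f, subclade = consensus@subclade,
                              envStatus = consensus@envStatus)
  list(element = element,
       truth = data.frame(id = id, orf = orf, kind = kind,
                          position = pos, requested_position = requested,
                          length = as.integer(len)))
}
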