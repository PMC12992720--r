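## Silencing potential: the fraction of a TE consensus covered by
## cluster-derived k-mers in antisense orientation. A cluster sequence is
## decomposed into all k-length windows (step 1, default k = 25, the piRNA
## footprint); a consensus position counts as covered when it lies inside
## at least one consensus window whose reverse complement (antisense) or
## which itself (sense) occurs in the cluster.

.seqWindows <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character())
  substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
}

#' Build a k-mer index of a piRNA-cluster sequence
#'
#' Decomposes the cluster into all distinct k-length substrings, shifted by
#' 1 nt, in the supplied (transcribed) orientation; windows containing N
#' are dropped and multiplicity is discarded. For dual-strand clusters set
#' \code{bothStrands = TRUE} to also index the reverse complement, since
#' such loci are transcribed from both strands.
#'
#' @param cluster Cluster sequence (named \code{DNAString} element,
#'   character string, or \code{DNAStringSet} of length 1).
#' @param k Word length (default 25).
#' @param bothStrands Also index the reverse complement (default FALSE).
#' @param id Cluster id; defaults to the sequence name when available.
#' @return A \code{\linkS4class{KmerIndex}}. A cluster shorter than
#'   \code{k} yields an empty index with a warning.
#' @export
buildKmerIndex <- function(cluster, k = 25L, bothStrands = FALSE,
                           id = NULL) {
  stopifnot(k >= 1L)
  if (is(cluster, "DNAStringSet")) {
    if (is.null(id)) id <- names(cluster)[1L]
    cluster <- cluster[[1L]]
  }
  s <- as.character(cluster)
  if (is.null(id)) id <- "cluster"
  if (nchar(s) < k) {
    warning("cluster '", id, "' (", nchar(s), " nt) is shorter than k = ",
            k, "; empty index")
    kmers <- character()
  } else {
    w <- .seqWindows(s, k)
    if (bothStrands) w <- c(w, .seqWindows(revComp(s), k))
    kmers <- unique(w[!grepl("N", w, fixed = TRUE)])
  }
  new("KmerIndex", k = as.integer(k), sourceId = id, kmers = kmers,
      bothStrands = isTRUE(bothStrands))
}

# logical coverage vector from matched window starts (1-based), width k
.coverFromStarts <- function(starts, L, k) {
  covered <- logical(L)
  if (length(starts)) {
    delta <- integer(L + 1L)
    for (s in starts) {
      delta[s] <- delta[s] + 1L
      delta[s + k] <- delta[s + k] - 1L
    }
    covered <- cumsum(delta[seq_len(L)]) > 0L
  }
  covered
}

#' Per-position k-mer coverage of a consensus by a cluster index
#'
#' A consensus window \code{[s, s+k)} matches in antisense orientation when
#' its reverse complement is an indexed cluster k-mer (within
#' \code{maxMismatch} Hamming mismatches), and in sense orientation when
#' the window itself is. A position is covered when it lies in at least one
#' matching window; the summary \code{fraction} is covered positions over
#' consensus length (a consensus shorter than k is entirely uncovered).
#' With \code{maxMismatch = 0} (the default, matching exact piRNA
#' complementarity) an exact set-membership scan is used;
#' \code{maxMismatch > 0} switches to a Hamming-tolerant pattern match.
#'
#' @param consensus Consensus sequence (named \code{DNAString} element,
#'   character, or \code{DNAStringSet} of length 1).
#' @param index A \code{\linkS4class{KmerIndex}}.
#' @param orientation \code{"antisense"} (default) or \code{"sense"}.
#' @param maxMismatch Hamming mismatches tolerated per window (0-5).
#' @param id Consensus id; defaults to the sequence name when available.
#' @return A \code{\linkS4class{CoverageProfile}}.
#' @export
kmerCoverage <- function(consensus, index,
                         orientation = c("antisense", "sense"),
                         maxMismatch = 0L, id = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(is(index, "KmerIndex"), maxMismatch >= 0L, maxMismatch <= 5L)
  if (is(consensus, "DNAStringSet")) {
    if (is.null(id)) id <- names(consensus)[1L]
    consensus <- consensus[[1L]]
  }
  s <- as.character(consensus)
  if (is.null(id)) id <- "consensus"
  L <- nchar(s)
  k <- index@k
  covered <- logical(L)
  if (L >= k && length(index@kmers)) {
    # the reverse complement of window [s, s+k) of the consensus is the
    # window starting at L-k+2-s (1-based) of the reverse-complemented
    # consensus, so antisense matching scans rc(consensus) windows
    target <- if (orientation == "antisense") revComp(s) else s
    if (maxMismatch == 0L) {
      wins <- .seqWindows(target, k)
      hit <- which(wins %in% index@kmers)
    } else {
      subj <- Biostrings::DNAString(target)
      hit <- integer()
      for (km in index@kmers) {
        m <- Biostrings::matchPattern(km, subj,
                                      max.mismatch = maxMismatch)
        st <- IRanges::start(m)
        st <- st[IRanges::width(m) == k]   # guard against edge hits
        hit <- c(hit, st)
      }
      hit <- unique(hit)
    }
    starts <- if (orientation == "antisense") L - k + 2L - hit else hit
    covered <- .coverFromStarts(starts, L, k)
  }
  new("CoverageProfile", consensusId = id, clusterId = index@sourceId,
      orientation = orientation, covered = covered, k = k,
      maxMismatch = as.integer(maxMismatch), fraction = mean(covered))
}

#' All-vs-all silencing-potential matrix
#'
#' Computes the antisense coverage fraction of every consensus by every
#' cluster: one row per consensus, one column per cluster. Uni-strand
#' clusters are indexed in their transcribed orientation only; clusters
#' named in \code{bothStrands} (dual-strand loci) are indexed on both
#' strands.
#'
#' @param clusters Named \code{DNAStringSet} of cluster sequences.
#' @param consensuses Named \code{DNAStringSet} of TE consensus sequences.
#' @param k Word length (default 25).
#' @param maxMismatch Hamming mismatches per window (default 0).
#' @param bothStrands Character vector of cluster ids to index on both
#'   strands.
#' @return A numeric matrix of antisense fractions,
#'   \code{consensus x cluster}.
#' @seealso \code{\link{kmerCoverage}}, \code{\link{writeCoverageBed}}
#' @export
silencingMatrix <- function(clusters, consensuses, k = 25L,
                            maxMismatch = 0L, bothStrands = character()) {
  stopifnot(length(clusters) > 0L, length(consensuses) > 0L)
  if (is.null(names(clusters)) || is.null(names(consensuses)))
    stop("clusters and consensuses must be named")
  if (anyDuplicated(names(clusters)))
    stop("duplicate cluster ids")
  if (anyDuplicated(names(consensuses)))
    stop("duplicate consensus ids")
  unknown <- setdiff(bothStrands, names(clusters))
  if (length(unknown))
    stop("bothStrands names not among clusters: ",
         paste(unknown, collapse = ", "))
  m <- matrix(0, nrow = length(consensuses), ncol = length(clusters),
              dimnames = list(names(consensuses), names(clusters)))
  for (cl in names(clusters)) {
    idx <- suppressWarnings(
      buildKmerIndex(clusters[[cl]], k = k,
                     bothStrands = cl %in% bothStrands, id = cl))
    for (co in names(consensuses)) {
      m[co, cl] <- coveredFraction(
        kmerCoverage(consensuses[[co]], idx, "antisense",
                     maxMismatch = maxMismatch, id = co))
    }
  }
  m
}

#' Write a silencing-potential matrix as TSV
#'
#' @param m Matrix from \code{\link{silencingMatrix}}.
#' @param path Output path.
#' @param k,maxMismatch Parameters recorded in the \code{#} header
#'   (mismatch counting is Hamming distance).
#' @return Invisibly, \code{path}.
#' @export
writeSilencingMatrix <- function(m, path, k = 25L, maxMismatch = 0L) {
  df <- data.frame(consensus_id = rownames(m), m, check.names = FALSE)
  .writeTsv(df, path, k = k, mm = maxMismatch, mismatch_metric = "hamming",
            orientation = "antisense")
}
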