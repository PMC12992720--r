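## Sequence I/O and core plumbing: FASTA / aligned FASTA readers with strict
## normalization, the annotation-table format, BED coverage output, and the
## reverse-complement helper shared by the k-mer machinery.

.SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

# uppercase, U->T; any residual character outside A/C/G/T/N is an error.
# Ambiguity codes are rejected rather than converted: exact k-mer matching
# must not silently treat e.g. R as a base.
.normalizeSeq <- function(x, id = "?") {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  bad <- gsub("[ACGTN]", "", x)
  if (nzchar(bad))
    stop("record '", id, "' contains illegal character(s) after ",
         "normalization: ", paste(unique(strsplit(bad, "")[[1]]),
                                  collapse = ", "))
  if (!nzchar(x))
    stop("record '", id, "' has an empty sequence")
  x
}

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are normalized to uppercase with U converted to T; any other
#' character outside A/C/G/T/N is an error naming the offending record.
#' Record order is preserved and duplicate ids are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A named \link[Biostrings]{DNAStringSet}.
#' @seealso \code{\link{writeFasta}}, \code{\link{readMsa}}
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- vapply(seq_along(ss), function(i)
    .normalizeSeq(as.character(ss[[i]]), ids[i]), character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A named \code{DNAStringSet} (or named character vector).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read an aligned FASTA multiple sequence alignment
#'
#' Aligned FASTA is the only accepted MSA dialect: \code{-} is the only gap
#' character (\code{.} is rejected), all rows must have equal length, and
#' ungapping a row must reproduce a valid A/C/G/T/N sequence.
#'
#' @param path Path to an aligned FASTA file.
#' @return A named \code{DNAStringSet} whose elements all have equal width.
#' @export
readMsa <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 2L) stop("an alignment needs at least 2 rows: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate MSA row ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- toupper(as.character(ss))
  rows <- chartr("U", "T", rows)
  if (any(grepl(".", rows, fixed = TRUE)))
    stop("'.' gap characters are not accepted; use '-'")
  bad <- gsub("[ACGTN-]", "", rows)
  if (any(nzchar(bad)))
    stop("illegal character(s) in MSA row(s): ",
         paste(ids[nzchar(bad)], collapse = ", "))
  if (length(unique(nchar(rows))) != 1L)
    stop("MSA rows have unequal lengths")
  out <- Biostrings::DNAStringSet(rows)
  names(out) <- ids
  out
}

# aligned DNAStringSet -> character matrix (rows x columns)
.msaMatrix <- function(msa) {
  m <- do.call(rbind, strsplit(as.character(msa), ""))
  rownames(m) <- names(msa)
  m
}

#' Reverse-complement a nucleotide string
#'
#' Strict A/C/G/T/N alphabet; N maps to N. \code{revComp} is an involution
#' and preserves length.
#'
#' @param x A character string (or \code{DNAString}).
#' @return The reverse complement as a character string.
#' @examples
#' revComp("AAC")  # "GTT"
#' @export
revComp <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  if (nzchar(gsub("[ACGTN]", "", x)))
    stop("illegal character in sequence (alphabet is A/C/G/T/N)")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read a feature annotation table
#'
#' Tab-separated with columns \code{element_id}, \code{feature},
#' \code{start}, \code{end}. Coordinates are 0-based half-open (BED-style);
#' they are converted to 1-based closed \code{IRanges} when bound to a
#' \code{\linkS4class{ConsensusElement}} by \code{\link{consensusElement}},
#' which also checks them against the sequence length. Lines starting with
#' \code{#} are ignored.
#'
#' @param path Path to the TSV file.
#' @return A \code{data.frame} with the four columns, validated.
#' @export
readAnnotationTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("element_id", "feature", "start", "end")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ",
         paste(need, collapse = ", "))
  df <- df[need]
  bad <- !df$feature %in% .FEATURE_LEVELS
  if (any(bad))
    stop("unknown feature name(s): ",
         paste(unique(df$feature[bad]), collapse = ", "))
  if (any(df$start < 0))
    stop("negative start coordinate (coordinates are 0-based half-open)")
  if (any(df$end <= df$start))
    stop("'end' must exceed 'start' (0-based half-open) in row(s): ",
         paste(which(df$end <= df$start), collapse = ", "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

# maximal runs of TRUE as a 2-column matrix of 1-based closed [start, end]
.trueRuns <- function(covered) {
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# "# ervscape <version>; <param>=<value>; ..." header line for writers
.headerLine <- function(...) {
  params <- c(...)
  ver <- as.character(utils::packageVersion("ervscape"))
  line <- paste0("# ervscape ", ver)
  if (length(params))
    line <- paste0(line, "; ", paste(names(params), params, sep = "=",
                                     collapse = "; "))
  line
}

# TSV writer with a '#' header line carrying the parameters
.writeTsv <- function(df, path, ...) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.headerLine(...), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a coverage profile as BED intervals
#'
#' Emits the maximal covered runs of a \code{\linkS4class{CoverageProfile}}
#' as BED6 lines (0-based half-open) on the consensus, named by the cluster
#' id, preceded by a \code{#} header recording the parameters. An all-false
#' profile yields a header-only file.
#'
#' @param profile A \code{CoverageProfile}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeCoverageBed <- function(profile, path) {
  stopifnot(is(profile, "CoverageProfile"))
  runs <- .trueRuns(profile@covered)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.headerLine(cluster = profile@clusterId,
                         orientation = profile@orientation,
                         k = profile@k, mm = profile@maxMismatch), con)
  if (nrow(runs)) {
    strand <- if (profile@orientation == "antisense") "-" else "+"
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                     profile@consensusId, runs[, "start"] - 1L,
                     runs[, "end"], profile@clusterId, 0L, strand)
    writeLines(lines, con)
  }
  invisible(path)
}
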