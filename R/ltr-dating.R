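## Insertion dating from pairwise LTR divergence. The two LTRs of a
## provirus are identical at integration and drift independently
## thereafter, so their pairwise divergence K accumulates at twice the
## neutral substitution rate: T = K / (2 r), with r in
## substitutions/site/Myr (default 0.0346, the Drosophila neutral rate
## assuming ten generations per year).

#' Extract the 5' and 3' LTR copies of an insertion
#'
#' Locates each LTR copy by anchored alignment of the reference LTR
#' (globally) against a terminal window of the insertion spanning 150% of
#' the reference LTR length, and extracts the matched subsequence. An LTR
#' whose anchored identity falls below \code{minIdentity} is treated as
#' missing (solo or truncated insertion, which cannot be dated).
#'
#' @param insertion An \code{InsertionRecord} (or character /
#'   \code{DNAString}).
#' @param reference A \code{ConsensusElement} with LTR5 and LTR3
#'   annotations.
#' @param minIdentity Minimum anchored identity per LTR (default 0.6).
#' @return The \code{InsertionRecord} with \code{ltr5}/\code{ltr3} filled
#'   in (accessible via \code{ltrSeqs}).
#' @export
extractLtrPair <- function(insertion, reference, minIdentity = 0.6) {
  if (!is(insertion, "InsertionRecord"))
    insertion <- insertionRecord("query", as.character(insertion))
  stopifnot(is(reference, "ConsensusElement"))
  s <- as.character(elementSeq(insertion))
  L <- nchar(s)
  ltrs <- list()
  for (side in c("LTR5", "LTR3")) {
    refLtr <- as.character(featureSeq(reference, side))
    win <- min(L, ceiling(1.5 * nchar(refLtr)))
    if (side == "LTR5") {
      offset <- 0L
      windowSeq <- substr(s, 1L, win)
    } else {
      offset <- L - win
      windowSeq <- substr(s, offset + 1L, L)
    }
    aln <- .alignGlobalLocal(refLtr, windowSeq)
    ident <- .alignIdentity(aln)
    if (ident < minIdentity)
      stop("solo_or_truncated: ", side, " of '", elementId(insertion),
           "' not found (identity ", sprintf("%.2f", ident), " < ",
           minIdentity, ")")
    sa <- Biostrings::subject(aln)
    ltrs[[side]] <- substr(s, offset + IRanges::start(sa@range),
                           offset + IRanges::end(sa@range))
  }
  insertion@ltr5 <- ltrs[["LTR5"]]
  insertion@ltr3 <- ltrs[["LTR3"]]
  validObject(insertion)
  insertion
}

#' @rdname extractLtrPair
#' @param x An \code{InsertionRecord} after LTR extraction.
#' @return \code{ltrSeqs}: named character vector \code{c(ltr5=, ltr3=)}.
#' @export
ltrSeqs <- function(x) {
  stopifnot(is(x, "InsertionRecord"))
  if (!nzchar(x@ltr5) || !nzchar(x@ltr3))
    stop("LTRs not yet extracted; run extractLtrPair() first")
  c(ltr5 = x@ltr5, ltr3 = x@ltr3)
}

#' Pairwise divergence between two LTR copies
#'
#' Globally aligns the two LTRs, excludes gapped columns (indels are not
#' part of the substitution clock), and returns the proportion of
#' differing ungapped columns \code{p} together with the divergence
#' \code{K}: either raw (\code{model = "p"}) or Jukes-Cantor corrected
#' (\code{model = "JC69"}, the default), \code{K = -3/4 log(1 - 4p/3)}.
#'
#' @param ltr5,ltr3 Nucleotide strings (order does not matter).
#' @param model \code{"JC69"} (default) or \code{"p"}.
#' @return A list: \code{p}, \code{K}, \code{nColumns} (ungapped columns),
#'   \code{model}.
#' @examples
#' ltrDivergence("ACGTACGTAC", "ACGTACGTAC")$K  # 0
#' @export
ltrDivergence <- function(ltr5, ltr3, model = c("JC69", "p")) {
  model <- match.arg(model)
  a <- as.character(ltr5)
  b <- as.character(ltr3)
  if (!nzchar(a) || !nzchar(b)) stop("both LTR sequences must be non-empty")
  aln <- .alignGlobal(a, b)
  al <- .alignedStrings(aln)
  ok <- al$pattern != "-" & al$subject != "-"
  n <- sum(ok)
  if (n == 0L) stop("zero ungapped aligned columns")
  p <- sum(al$pattern[ok] != al$subject[ok]) / n
  K <- if (model == "p") {
    p
  } else {
    if (p >= 0.75)
      stop("p = ", signif(p, 4),
           " >= 0.75: outside the Jukes-Cantor domain")
    -0.75 * log(1 - 4 * p / 3)
  }
  list(p = p, K = K, nColumns = n, model = model)
}

#' Insertion age from LTR divergence
#'
#' Applies the molecular-clock formula T = K / (2 r), with \code{r} in
#' substitutions per site per Myr. The default r = 0.0346 is the
#' Drosophila neutral rate assuming ten generations per year (the
#' generation-time assumption is already folded into r).
#'
#' @param K Pairwise LTR divergence (substitutions/site).
#' @param r Substitution rate in subs/site/Myr (default 0.0346).
#' @return A list: \code{K}, \code{r}, \code{T_years}, \code{T_TYA}
#'   (thousand years ago).
#' @examples
#' insertionAge(0.0692)$T_years  # 1,000,000: K = 2r means 1 Myr
#' @export
insertionAge <- function(K, r = 0.0346) {
  if (K < 0) stop("K must be non-negative")
  if (r <= 0) stop("r must be positive")
  Tyears <- K / (2 * r) * 1e6
  list(K = K, r = r, T_years = Tyears, T_TYA = Tyears / 1e3)
}

#' Date a panel of insertions
#'
#' Convenience wrapper: extracts both LTRs of each insertion against the
#' reference, computes divergence and age, and returns one row per
#' insertion. Insertions whose LTRs cannot be extracted (solo/truncated)
#' are reported with NA values and the error message.
#'
#' @param insertions A list of \code{InsertionRecord}s (or a named
#'   \code{DNAStringSet}).
#' @param reference A \code{ConsensusElement}.
#' @param model,r Passed to \code{\link{ltrDivergence}} /
#'   \code{\link{insertionAge}}.
#' @return A \code{data.frame}: \code{insertion_id}, \code{ltr_len5},
#'   \code{ltr_len3}, \code{p}, \code{K}, \code{T_years}, \code{T_TYA},
#'   \code{note}.
#' @export
dateInsertions <- function(insertions, reference, model = "JC69",
                           r = 0.0346) {
  if (is(insertions, "DNAStringSet"))
    insertions <- lapply(seq_along(insertions), function(i)
      insertionRecord(names(insertions)[i],
                      as.character(insertions[[i]])))
  rows <- lapply(insertions, function(ins) {
    res <- tryCatch({
      ins <- extractLtrPair(ins, reference)
      ltrs <- ltrSeqs(ins)
      div <- ltrDivergence(ltrs[["ltr5"]], ltrs[["ltr3"]], model = model)
      age <- insertionAge(div$K, r = r)
      data.frame(insertion_id = elementId(ins),
                 ltr_len5 = nchar(ltrs[["ltr5"]]),
                 ltr_len3 = nchar(ltrs[["ltr3"]]),
                 p = div$p, K = div$K, T_years = age$T_years,
                 T_TYA = age$T_TYA, note = "")
    }, error = function(e) {
      data.frame(insertion_id = elementId(ins), ltr_len5 = NA_integer_,
                 ltr_len3 = NA_integer_, p = NA_real_, K = NA_real_,
                 T_years = NA_real_, T_TYA = NA_real_,
                 note = conditionMessage(e))
    })
    res
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
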