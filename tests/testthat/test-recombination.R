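test_that("typeLtr picks the best variant and reports identity", {
  set.seed(23)
  ltrA <- randSeq(408)
  ltrB <- substituteAt(randSeq(408), integer())
  lib <- variantLibrary(c("LTR-408" = ltrA, "LTR-other" = ltrB))
  t <- typeLtr(ltrA, lib)
  expect_equal(t$variant, "LTR-408")
  expect_equal(t$identity, 1.0)
  q <- substituteAt(ltrA, sample(408, 5))
  t <- typeLtr(q, lib)
  expect_equal(t$variant, "LTR-408")
  expect_equal(t$identity, 403 / 408)
  t <- typeLtr(randSeq(400), lib)
  expect_equal(t$variant, "untyped")
})

test_that("LTR mismatch flags cross-variant recombinants only", {
  cons <- smallConsensus()
  vA <- simVariant(cons, 40, seed = 1, id = "varA")
  vB <- simVariant(cons, 40, seed = 2, id = "varB")
  lib <- variantLibrary(c(varA = vA$ltr, varB = vB$ltr))
  L <- nchar(vA$seq)
  rec <- makeRecombinant(vA$seq, vB$seq, L %/% 2, id = "q")
  res <- detectLtrMismatch(insertionRecord("q", rec$seq), lib,
                           reference = cons)
  expect_true(res$mismatch)
  expect_equal(res$type5, "varA")
  expect_equal(res$type3, "varB")
  res <- detectLtrMismatch(insertionRecord("p", vA$seq), lib,
                           reference = cons)
  expect_false(res$mismatch)
  # an extractable but heavily diverged LTR is untyped -> indeterminate,
  # not a mismatch
  set.seed(29)
  odd <- substituteAt(vA$seq, sample(200, 60))
  res <- detectLtrMismatch(insertionRecord("u", odd), lib,
                           reference = cons)
  expect_equal(res$type5, "untyped")
  expect_true(is.na(res$mismatch))
  # a missing LTR propagates the extraction error
  expect_error(
    detectLtrMismatch(insertionRecord("s", substr(vA$seq, 301, L - 300)),
                      lib, reference = cons),
    "solo_or_truncated")
})

test_that("diagnosticSites finds exactly the planted type-separating columns", {
  set.seed(37)
  base <- randSeq(600)
  planted <- sort(sample(600, 30))
  hapB <- substituteAt(base, planted)
  # private (non-diagnostic) mutations in single carriers
  a1 <- substituteAt(base, sample(setdiff(1:600, planted), 4))
  b2 <- substituteAt(hapB, sample(setdiff(1:600, planted), 4))
  msa <- Biostrings::DNAStringSet(c(A1 = a1, A2 = base, B1 = hapB, B2 = b2))
  sites <- diagnosticSites(msa, "A1", "A2", "B1", "B2")
  expect_identical(siteTable(sites)$column, planted)
  # symmetric under swapping the type pairs (alleles relabeled)
  swapped <- diagnosticSites(msa, "B1", "B2", "A1", "A2")
  expect_identical(siteTable(swapped)$column, planted)
  expect_identical(siteTable(swapped)$alleleA, siteTable(sites)$alleleB)
  expect_error(diagnosticSites(msa, "A1", "A2", "B1", "nope"), "absent")
})

test_that("gap alleles are diagnostic and indel runs collapse to one site", {
  msa <- Biostrings::DNAStringSet(c(
    A1 = "ACGTAC---GTACGT",
    A2 = "ACGTAC---GTACGT",
    B1 = "ACGTACTTAGTACGA",
    B2 = "ACGTACTTAGTACGA"))
  sites <- diagnosticSites(msa, "A1", "A2", "B1", "B2")
  st <- siteTable(sites)
  # one collapsed indel site (column 7) + the terminal substitution
  expect_identical(st$column, c(7L, 15L))
  expect_identical(st$alleleA[1], "-")
  # degenerate parent pair is allowed and flagged
  one <- diagnosticSites(msa, "A1", "A1", "B1", "B2")
  expect_true(one@degenerateA)
})

test_that("callRecombinant paints parents and localizes switches", {
  cons <- smallConsensus()
  # pure parent: one segment, no switches
  panel <- makeRecombPanel(cons, nSubs = 50, nBreaks = 1, seed = 5)
  expect_false(is.null(panel))
  sites <- diagnosticSites(panel$msa, "A1", "A2", "B1", "B2")
  pureCall <- callRecombinant(panel$msa, "A1", sites)
  expect_equal(nSwitches(pureCall), 0L)
  expect_equal(segmentTable(pureCall)$call, "A")
  # single template switch: breakpoint interval brackets the truth
  call <- callRecombinant(panel$msa, "query", sites)
  expect_equal(nSwitches(call), 1L)
  expect_equal(segmentTable(call)$call, c("A", "B"))
  bp <- breakpointTable(call)
  expect_true(bp$from <= panel$truthBp && panel$truthBp < bp$to)
  # double recombinant
  panel2 <- makeRecombPanel(cons, nSubs = 60, nBreaks = 2, seed = 6)
  sites2 <- diagnosticSites(panel2$msa, "A1", "A2", "B1", "B2")
  call2 <- callRecombinant(panel2$msa, "query", sites2)
  expect_equal(nSwitches(call2), 2L)
  expect_equal(segmentTable(call2)$call, c("A", "B", "A"))
  bp2 <- breakpointTable(call2)
  expect_true(all(bp2$from <= panel2$truthBp & panel2$truthBp < bp2$to))
  # a query that is non-reference at every diagnostic site is rejected
  row <- function(fill, at, sym) {
    ch <- rep(fill, 40)
    ch[at] <- sym
    paste(ch, collapse = "")
  }
  at <- c(5L, 15L, 25L, 35L)
  msa3 <- Biostrings::DNAStringSet(c(
    A1 = row("C", at, "A"), A2 = row("C", at, "A"),
    B1 = row("C", at, "G"), B2 = row("C", at, "G"),
    far = row("C", at, "T")))
  sites3 <- diagnosticSites(msa3, "A1", "A2", "B1", "B2")
  expect_error(callRecombinant(msa3, "far", sites3), "unrelated_query")
})

test_that("short parental runs do not create segments", {
  # calls: A at 10,20,30,40 / isolated B at 25 -> one A segment
  msaCols <- 60
  mkRow <- function(alleles) {
    ch <- rep("C", msaCols)
    for (nm in names(alleles)) ch[as.integer(nm)] <- alleles[[nm]]
    paste(ch, collapse = "")
  }
  diag <- c(`10` = "A", `20` = "A", `25` = "A", `30` = "A", `40` = "A")
  hapA <- mkRow(diag)
  hapB <- mkRow(setNames(rep("G", 5), names(diag)))
  qry <- mkRow(c(`10` = "A", `20` = "A", `25` = "G", `30` = "A",
                 `40` = "A"))
  msa <- Biostrings::DNAStringSet(c(A1 = hapA, A2 = hapA, B1 = hapB,
                                    B2 = hapB, q = qry))
  sites <- diagnosticSites(msa, "A1", "A2", "B1", "B2")
  call <- callRecombinant(msa, "q", sites, minSitesPerSegment = 2)
  expect_equal(nSwitches(call), 0L)
  expect_equal(segmentTable(call)$call, "A")
  expect_equal(sum(callTable(call)$call == "B"), 1L)  # raw track kept
})

test_that("siteFrequencyProfile counts ranked non-gap frequencies", {
  msa <- Biostrings::DNAStringSet(c(r1 = "A-", r2 = "A-", r3 = "A-",
                                    r4 = "C-", r5 = "G-", r6 = "--"))
  prof <- siteFrequencyProfile(msa)
  expect_equal(prof$occupancy, c(5 / 6, 0))
  expect_equal(prof$f1, c(3 / 5, 0))
  expect_equal(prof$base2[1], "C")   # lexicographic tie-break over G
  expect_equal(prof$f2[1], 1 / 5)
  expect_equal(prof$f3[1], 1 / 5)
  expect_true(all(prof$f1 >= prof$f2 & prof$f2 >= prof$f3))
  expect_true(all(prof$f1 + prof$f2 + prof$f3 <= 1 + 1e-12))
  # invariant column; row permutation invariance
  msa2 <- Biostrings::DNAStringSet(c(a = "AC", b = "AC", c = "AG"))
  p2 <- siteFrequencyProfile(msa2)
  expect_equal(p2$f1, c(1, 2 / 3))
  expect_equal(p2$f2, c(0, 1 / 3))
  expect_identical(siteFrequencyProfile(rev(msa2)), p2)
})
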