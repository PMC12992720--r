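test_that("scanOrfs handles the canonical small cases", {
  hits <- scanOrfs("ATGAAATAA", minAa = 2)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$aaLength, 2L)          # Met + Lys, stop not counted
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, 9L)               # stop codon included in the span
  expect_false(hits$openEnded)
  # stop-free ATG-initiated sequence is one open-ended hit
  set.seed(2)
  body <- paste(sample(setdiff(ervscape:::.NONSTOP_CODONS, "ATG"), 29,
                       replace = TRUE), collapse = "")
  hits <- scanOrfs(paste0("ATG", body), minAa = 2)
  hits <- hits[hits$frame == 0, ]
  expect_equal(nrow(hits), 1L)
  expect_true(hits$openEnded)
  expect_equal(hits$aaLength, 30L)
})

test_that("scanOrfs equals brute-force enumeration on random sequences", {
  set.seed(101)
  for (i in 1:60) {
    s <- randSeq(sample(60:600, 1))
    minAa <- sample(1:10, 1)
    got <- scanOrfs(s, minAa = minAa)
    want <- bruteOrfs(s, minAa)
    expect_equal(got$start, want$start, info = paste("seed case", i))
    expect_equal(got$end, want$end, info = paste("seed case", i))
    expect_equal(got$aaLength, want$aaLength, info = paste("seed case", i))
    expect_equal(got$openEnded, want$openEnded, info = paste("seed case", i))
  }
})

test_that("detectInactivation is empty for identical sequences and finds planted events", {
  cons <- smallConsensus()
  refOrf <- as.character(featureSeq(cons, "ENVF"))
  expect_equal(nrow(detectInactivation(refOrf, refOrf)), 0L)

  # single insertion after 0-based position p: recovered at p with the
  # downstream stop confirmed by direct translation of the mutant
  set.seed(5)
  for (i in 1:10) {
    mut <- injectInactivation(cons, "ENVF", "insertion",
                              position = sample(30:400, 1))
    region <- as.character(featureSeq(mut$element, "ENVF"))
    ev <- detectInactivation(region, refOrf)
    ev <- ev[ev$kind == "insertion", ]
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$refPos, mut$truth$position)
    expect_true(ev$frameshift)
    # independent oracle for the downstream stop: scan mutant codons
    codons <- substring(region, seq(1, nchar(region) - 2, 3),
                        seq(3, nchar(region), 3))
    firstStop <- which(codons %in% c("TAA", "TAG", "TGA") &
                         seq_along(codons) * 3 - 3 >= ev$queryPos)[1]
    expect_equal(ev$downstreamStopAa, firstStop)
  }
})

test_that("detectInactivation reports premature stop substitutions at the codon", {
  cons <- smallConsensus()
  refOrf <- as.character(featureSeq(cons, "POL"))
  mut <- injectInactivation(cons, "POL", "substitution_stop",
                            position = 300)
  region <- as.character(featureSeq(mut$element, "POL"))
  ev <- detectInactivation(region, refOrf)
  expect_equal(ev$kind, "substitution_stop")
  expect_equal(ev$refPos, mut$truth$position)
  expect_equal(ev$refPos %% 3, 0)
  expect_equal(ev$downstreamStopAa, ev$refPos / 3 + 1)
})

test_that("detectInactivation rejects unrelated sequences", {
  cons <- smallConsensus()
  refOrf <- as.character(featureSeq(cons, "GAG"))
  set.seed(8)
  expect_error(detectInactivation(randSeq(nchar(refOrf)), refOrf),
               "identity")
})

test_that("indels in homopolymer context are left-aligned", {
  # ref ...ATG | CCA AAA GGT ...; inserting A anywhere in the A-run aligns
  # to the run's leftmost position
  ref <- paste0("ATGCCAAAAGGT", "TGTACTGAT", "TAA")
  stopifnot(nchar(ref) %% 3 == 0)
  qry <- paste0("ATGCCAAAAAGGT", "TGTACTGAT", "TAA")  # one extra A
  ev <- detectInactivation(qry, ref)
  ev <- ev[ev$kind == "insertion", ]
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$refPos, 4L)   # 0-based: after the C preceding the run
})

test_that("classifyIntegrity applies the activity-class rules", {
  cons <- smallConsensus()
  copy <- insertionRecord("copy", as.character(elementSeq(cons)))
  rep <- classifyIntegrity(copy, cons)
  expect_equal(unname(rep$status), rep("intact", 3))
  expect_equal(rep$class, "retrovirus_active")

  mutEnv <- injectInactivation(cons, "ENVF", "insertion", position = 200)
  rep <- classifyIntegrity(
    insertionRecord("m1", as.character(elementSeq(mutEnv$element))), cons)
  expect_equal(rep$status[["envF"]], "frameshift")
  expect_equal(rep$class, "retroelement_active")

  mutPol <- injectInactivation(cons, "POL", "substitution_stop",
                               position = 150)
  rep <- classifyIntegrity(
    insertionRecord("m2", as.character(elementSeq(mutPol$element))), cons)
  expect_equal(rep$status[["pol"]], "premature_stop")
  expect_equal(rep$class, "inactive")

  # an in-frame 3-nt deletion is not inactivating (< 10% length loss)
  mutIF <- injectInactivation(cons, "GAG", "deletion", position = 99,
                              len = 3L)
  rep <- classifyIntegrity(
    insertionRecord("m3", as.character(elementSeq(mutIF$element))), cons)
  expect_equal(rep$status[["gag"]], "intact")

  set.seed(31)
  expect_error(
    classifyIntegrity(insertionRecord("rnd", randSeq(1000)), cons),
    "unrelated_element")
})

test_that("findEnvRemnants recovers planted Env fragments", {
  cons <- smallConsensus()
  envNt <- as.character(featureSeq(cons, "ENVF"))
  envProt <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(envNt, 1, nchar(envNt) - 3))))
  set.seed(13)
  bg <- randSeq(500)
  fragNt <- substr(envNt, 121, 300)        # 60 aa, aa 41..100
  region <- paste0(substr(bg, 1, 150), fragNt, substr(bg, 151, 500))
  hits <- findEnvRemnants(region, envProt, minScore = 60)
  expect_equal(nrow(hits), 1L)
  expect_lte(abs(hits$queryStart - 151), 15)
  expect_lte(abs(hits$queryEnd - 330), 15)
  expect_lte(abs(hits$refStart - 41), 5)
  expect_lte(abs(hits$refEnd - 100), 5)
  # random sequence: no hits at a stringent score
  expect_equal(nrow(findEnvRemnants(bg, envProt, minScore = 60)), 0L)
  # a 1-nt deletion splits the fragment into two adjacent-frame hits with
  # abutting reference intervals
  fragDel <- paste0(substr(fragNt, 1, 90), substr(fragNt, 92, 180))
  region2 <- paste0(substr(bg, 1, 150), fragDel, substr(bg, 151, 500))
  hits2 <- findEnvRemnants(region2, envProt, minScore = 40)
  expect_equal(nrow(hits2), 2L)
  expect_equal(length(unique(hits2$frame)), 2L)
  expect_lte(abs(hits2$refStart[2] - hits2$refEnd[1]), 6)
})
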