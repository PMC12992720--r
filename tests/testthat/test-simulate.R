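test_that("simConsensus builds the canonical element structure deterministically", {
  p <- simParams(ltrLen = 150L, utr5Len = 80L,
                 orfLens = c(gag = 300L, pol = 450L, envF = 300L),
                 utr3Len = 60L)
  c1 <- simConsensus("e", p, seed = 5)
  c2 <- simConsensus("e", p, seed = 5)
  expect_identical(as.character(elementSeq(c1)),
                   as.character(elementSeq(c2)))
  expect_identical(annotationTable(c1), annotationTable(c2))
  c3 <- simConsensus("e", p, seed = 6)
  expect_false(identical(as.character(elementSeq(c1)),
                         as.character(elementSeq(c3))))
  # LTR5 equals LTR3 exactly
  expect_identical(as.character(featureSeq(c1, "LTR5")),
                   as.character(featureSeq(c1, "LTR3")))
  # the scanner reports an ORF ending at each annotated stop; the start
  # may extend upstream when an in-frame ATG precedes the annotated one
  # (longest ORF per stop), so containment is the right check
  orfs <- scanOrfs(elementSeq(c1), minAa = 90)
  for (orf in c("GAG", "POL", "ENVF")) {
    r <- featureRange(c1, orf)
    i <- which(orfs$end == IRanges::end(r))
    expect_length(i, 1)
    expect_lte(orfs$start[i], IRanges::start(r))
    expect_false(orfs$openEnded[i])
  }
  # total length is the sum of the parts
  expect_equal(length(elementSeq(c1)), 2 * 150 + 80 + 300 + 450 + 300 + 60)
})

test_that("evolveInsertion places close-to-Poisson substitution counts", {
  cons <- smallConsensus()
  z <- evolveInsertion(cons, 0, seed = 1, id = "i0")
  expect_identical(as.character(elementSeq(z$record)),
                   as.character(elementSeq(cons)))
  # expected pairwise LTR differences ~ 2 r T L
  r <- 0.0346
  age <- 0.5
  Lltr <- 200
  nDiff <- vapply(1:300, function(s) {
    ev <- evolveInsertion(cons, age, r = r, seed = s, id = "i")
    s1 <- strsplit(substr(as.character(elementSeq(ev$record)), 1, Lltr),
                   "")[[1]]
    L <- length(strsplit(as.character(elementSeq(ev$record)), "")[[1]])
    full <- as.character(elementSeq(ev$record))
    s2 <- strsplit(substr(full, nchar(full) - Lltr + 1, nchar(full)),
                   "")[[1]]
    sum(s1 != s2)
  }, numeric(1))
  lambda <- 2 * r * age * Lltr
  se <- sqrt(lambda / 300)  # Poisson sd / sqrt(n), ignoring double hits
  expect_lte(abs(mean(nDiff) - lambda), 4 * se + 0.2)
  # determinism
  a <- evolveInsertion(cons, 0.3, seed = 9, id = "x")
  b <- evolveInsertion(cons, 0.3, seed = 9, id = "x")
  expect_identical(as.character(elementSeq(a$record)),
                   as.character(elementSeq(b$record)))
  expect_identical(a$truth, b$truth)
})

test_that("assembleCluster truth predicts antisense coverage", {
  cons <- smallConsensus()
  L <- length(elementSeq(cons))
  # one full-length antisense fragment: fraction 1
  full <- assembleCluster(list(consA = cons),
                          data.frame(consensus_id = "consA", start = 1,
                                     end = L, orientation = "antisense"),
                          seed = 2)
  idx <- buildKmerIndex(full$seq, k = 25)
  expect_equal(coveredFraction(
    kmerCoverage(elementSeq(cons), idx, "antisense")), 1)
  # one sense fragment: antisense fraction ~ 0 (odd k)
  sens <- assembleCluster(list(consA = cons),
                          data.frame(consensus_id = "consA", start = 1,
                                     end = L, orientation = "sense"),
                          seed = 3)
  idx <- buildKmerIndex(sens$seq, k = 25)
  expect_lt(coveredFraction(
    kmerCoverage(elementSeq(cons), idx, "antisense")), 1e-3)
  # truth table records fragment placement exactly
  plan <- data.frame(consensus_id = "consA", start = c(11, 301),
                     end = c(120, 420),
                     orientation = c("antisense", "sense"))
  clu <- assembleCluster(list(consA = cons), plan, spacerLen = 50,
                         seed = 4, id = "k")
  cs <- as.character(clu$seq[[1]])
  s0 <- as.character(elementSeq(cons))
  for (i in 1:2) {
    frag <- substr(cs, clu$truth$cluster_start[i], clu$truth$cluster_end[i])
    want <- substr(s0, plan$start[i], plan$end[i])
    if (plan$orientation[i] == "antisense") want <- rcStr(want)
    expect_identical(frag, want)
  }
  expect_error(
    assembleCluster(list(consA = cons),
                    data.frame(consensus_id = "consA", start = 1,
                               end = L + 10, orientation = "sense")),
    "invalid plan")
})

test_that("makeRecombinant splices at the requested coordinates", {
  set.seed(51)
  p1 <- randSeq(600)
  p2 <- substituteAt(p1, sample(600, 40))
  expect_identical(makeRecombinant(p1, p2, integer())$seq, p1)
  rec <- makeRecombinant(p1, p2, c(200, 400), id = "r")
  expect_identical(substr(rec$seq, 1, 200), substr(p1, 1, 200))
  expect_identical(substr(rec$seq, 201, 400), substr(p2, 201, 400))
  expect_identical(substr(rec$seq, 401, 600), substr(p1, 401, 600))
  expect_equal(rec$truth$bp_parent1, c(200, 400))
  expect_error(makeRecombinant(p1, p2, 700), "breakpoints")
  # unequal-length parents: homologous coordinates via alignment
  p2i <- paste0(substr(p2, 1, 300), "TTTTT", substr(p2, 301, 600))
  rec2 <- makeRecombinant(p1, p2i, 200, id = "r2")
  expect_identical(substr(rec2$seq, 1, 200), substr(p1, 1, 200))
  expect_identical(substr(rec2$seq, 201, nchar(rec2$seq)),
                   substr(p2i, 201, nchar(p2i)))
})

test_that("injectInactivation events are recovered exactly by the detector", {
  cons <- smallConsensus()
  set.seed(61)
  kinds <- c("insertion", "deletion", "substitution_stop")
  for (i in 1:15) {
    orf <- sample(c("GAG", "POL", "ENVF"), 1)
    kind <- kinds[(i %% 3) + 1]
    orfLen <- IRanges::width(featureRange(cons, orf))
    pos <- sample(30:(orfLen - 60), 1)
    mut <- injectInactivation(cons, orf, kind, position = pos)
    expect_equal(mut$truth$kind, kind)
    region <- as.character(featureSeq(mut$element, orf))
    ev <- detectInactivation(region,
                             as.character(featureSeq(cons, orf)))
    ev <- ev[ev$kind == kind, ]
    expect_equal(nrow(ev), 1L, info = paste(i, orf, kind))
    expect_equal(ev$refPos, mut$truth$position,
                 info = paste(i, orf, kind))
  }
  # the feature table stays consistent after the indel shift
  mut <- injectInactivation(cons, "GAG", "insertion", position = 100)
  expect_equal(length(elementSeq(mut$element)),
               length(elementSeq(cons)) + 1L)
  expect_identical(as.character(featureSeq(mut$element, "LTR3")),
                   as.character(featureSeq(cons, "LTR3")))
  expect_error(injectInactivation(cons, "GAG", "insertion",
                                  position = 10000), "outside")
})
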