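## File-based orchestration of the analysis stages. Plain files only --
## stages communicate through the declared FASTA/TSV/BED formats, every
## writer stamps its parameters into a '#' header, and a manifest of
## md5 checksums makes reruns verifiable. All randomness flows from the
## single config seed through per-stage derived seeds, so stages are
## reproducible independently.

.PIPELINE_STAGES <- c("simulate", "annotate", "date", "silencing",
                      "recombination")

.CONFIG_KEYS <- list(
  top = c("seed", "out_dir", "stages", "sim", "params"),
  sim = c("n_insertions", "ages_myr", "ltr_len", "utr5_len", "orf_lens",
          "utr3_len", "spacer_len", "n_variant_subs", "breakpoint"),
  params = c("k", "max_mm", "model", "r", "min_seg")
)

.stageSeed <- function(seed, stage) {
  # stable small derived seed per stage
  (as.integer(seed) * 131L + match(stage, .PIPELINE_STAGES) * 7919L) %%
    2147483587L
}

.checkKeys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
}

#' Validate and normalize a pipeline configuration
#'
#' @param config A list, or path to a YAML file. Recognized top-level
#'   keys: \code{seed}, \code{out_dir}, \code{stages}, \code{sim},
#'   \code{params}; unknown keys anywhere are rejected before any stage
#'   runs.
#' @return The normalized config list with defaults filled in.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  .checkKeys(config, .CONFIG_KEYS$top, "top level")
  .checkKeys(config$sim, .CONFIG_KEYS$sim, "'sim'")
  .checkKeys(config$params, .CONFIG_KEYS$params, "'params'")
  defSim <- list(n_insertions = 4L, ages_myr = c(0.05, 0.15, 0.5, 1),
                 ltr_len = 400L, utr5_len = 200L,
                 orf_lens = list(gag = 900L, pol = 1500L, envF = 900L),
                 utr3_len = 150L, spacer_len = 100L, n_variant_subs = 40L,
                 breakpoint = NULL)
  defPar <- list(k = 25L, max_mm = 0L, model = "JC69", r = 0.0346,
                 min_seg = 2L)
  config$sim <- utils::modifyList(defSim, config$sim %||% list())
  config$params <- utils::modifyList(defPar, config$params %||% list())
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) stop("config must set 'out_dir'")
  if (is.null(config$stages)) config$stages <- .PIPELINE_STAGES
  bad <- setdiff(config$stages, .PIPELINE_STAGES)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-check pipeline input files
#'
#' Report-based validation (nothing is thrown): checks that every
#' annotated element exists in the FASTA and that feature coordinates fit
#' inside the corresponding sequence. Elements without any annotation are
#' warnings; dangling annotations and out-of-range coordinates are fatal.
#'
#' @param fastaPath Path to the consensus FASTA.
#' @param annotPath Path to the annotation TSV.
#' @return A \code{data.frame} with columns \code{level} (\code{"fatal"} /
#'   \code{"warning"}) and \code{message}; zero rows when fully
#'   consistent.
#' @export
validateInputs <- function(fastaPath, annotPath) {
  report <- data.frame(level = character(), message = character())
  add <- function(level, msg) {
    report <<- rbind(report, data.frame(level = level, message = msg))
  }
  seqs <- tryCatch(readFasta(fastaPath), error = function(e) {
    add("fatal", conditionMessage(e))
    NULL
  })
  annot <- tryCatch(readAnnotationTable(annotPath), error = function(e) {
    add("fatal", conditionMessage(e))
    NULL
  })
  if (is.null(seqs) || is.null(annot)) return(report)
  dangling <- setdiff(annot$element_id, names(seqs))
  for (d in dangling)
    add("fatal", paste0("annotation references absent element '", d, "'"))
  for (i in which(annot$element_id %in% names(seqs))) {
    L <- Biostrings::width(seqs)[names(seqs) == annot$element_id[i]]
    if (annot$end[i] > L)
      add("fatal", sprintf("%s %s [%d,%d) exceeds sequence length %d",
                           annot$element_id[i], annot$feature[i],
                           annot$start[i], annot$end[i], L))
  }
  for (u in setdiff(names(seqs), annot$element_id))
    add("warning", paste0("element '", u, "' has no annotation"))
  report
}

.log <- function(...) message("[ervscape] ", sprintf(...))

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order (simulate, annotate,
#' date, silencing, recombination), each reading and writing only the
#' declared plain-file formats under \code{out_dir}, and finishes by
#' writing \code{manifest.tsv} with the md5 checksum of every output.
#' The whole run is a pure function of the config (including its seed):
#' rerunning with an unchanged config reproduces every checksum.
#'
#' The simulate stage generates a consensus element, a panel of insertions
#' of known ages (plus one env-F frameshifted copy), a piRNA-like cluster
#' with antisense fragments, and a parent/recombinant panel of two variant
#' haplotypes; downstream stages consume those files exactly as they would
#' consume real extracted data.
#'
#' @param config List or YAML path; see \code{\link{pipelineConfig}}.
#' @return Invisibly, the manifest \code{data.frame} (\code{path},
#'   \code{md5}).
#' @export
runPipeline <- function(config) {
  cfg <- pipelineConfig(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  out <- function(name) {
    p <- file.path(cfg$out_dir, name)
    outputs <<- union(outputs, p)
    p
  }
  runStage <- function(stage, fn) {
    if (!stage %in% cfg$stages) return(invisible())
    .log("stage %s ...", stage)
    tryCatch(fn(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sim <- cfg$sim
  par <- cfg$params
  params <- simParams(ltrLen = sim$ltr_len, utr5Len = sim$utr5_len,
                      orfLens = unlist(sim$orf_lens), utr3Len = sim$utr3_len,
                      r = par$r)

  runStage("simulate", function() {
    seed <- .stageSeed(cfg$seed, "simulate")
    cons <- simConsensus("consA", params, seed = seed)
    writeFasta(stats::setNames(
      Biostrings::DNAStringSet(as.character(elementSeq(cons))), "consA"),
      out("consensus.fasta"))
    .writeTsv(annotationTable(cons), out("consensus_annot.tsv"),
              coords = "0-based half-open", seed = seed)
    # insertion panel of known ages + one env-F frameshifted copy
    ages <- rep_len(unlist(sim$ages_myr), sim$n_insertions)
    recs <- list()
    truths <- list()
    for (i in seq_len(sim$n_insertions)) {
      ev <- evolveInsertion(cons, ages[i], r = par$r, seed = seed + i,
                            id = sprintf("ins%02d", i))
      recs[[i]] <- ev$record
      truths[[i]] <- ev$truth
    }
    mut <- injectInactivation(cons, "ENVF", "insertion",
                              position = params$orfLens[["envF"]] %/% 2L,
                              id = "ins_envfs")
    recs[[length(recs) + 1L]] <- insertionRecord(
      "ins_envfs", as.character(elementSeq(mut$element)))
    fa <- Biostrings::DNAStringSet(vapply(recs, function(x)
      as.character(elementSeq(x)), character(1)))
    names(fa) <- vapply(recs, elementId, character(1))
    writeFasta(fa, out("insertions.fasta"))
    .writeTsv(do.call(rbind, truths), out("insertions_truth.tsv"),
              r = par$r, seed = seed)
    .writeTsv(mut$truth, out("inactivation_truth.tsv"), seed = seed)
    # cluster with antisense fragments of the consensus
    L <- length(elementSeq(cons))
    plan <- data.frame(
      consensus_id = "consA",
      start = c(1L, round(L * 0.4)),
      end = c(round(L * 0.25), round(L * 0.75)),
      orientation = c("antisense", "antisense"))
    clu <- assembleCluster(list(consA = cons), plan,
                           spacerLen = sim$spacer_len, seed = seed + 100L)
    writeFasta(clu$seq, out("cluster.fasta"))
    .writeTsv(clu$truth, out("cluster_truth.tsv"), seed = seed + 100L)
    # two variant haplotypes, two carriers each, one recombinant query
    varSeed <- seed + 200L
    base <- as.character(elementSeq(cons))
    hapA <- simVariant(cons, sim$n_variant_subs, seed = varSeed,
                       id = "varA")$seq
    hapB <- simVariant(cons, sim$n_variant_subs, seed = varSeed + 1L,
                       id = "varB")$seq
    bp <- sim$breakpoint %||% (nchar(base) %/% 2L)
    rec <- makeRecombinant(hapA, hapB, bp, id = "query1")
    panel <- Biostrings::DNAStringSet(c(A1 = hapA, A2 = hapA, B1 = hapB,
                                        B2 = hapB, query1 = rec$seq))
    writeFasta(panel, out("panel_msa.fasta"))
    .writeTsv(rec$truth, out("recombinant_truth.tsv"), seed = varSeed)
  })

  runStage("annotate", function() {
    cons <- .loadConsensus(cfg$out_dir)
    ins <- readFasta(file.path(cfg$out_dir, "insertions.fasta"))
    rows <- lapply(names(ins), function(id) {
      rep <- classifyIntegrity(insertionRecord(id, as.character(ins[[id]])),
                               cons)
      ev <- rep$events
      data.frame(insertion_id = id, gag_status = rep$status[["gag"]],
                 pol_status = rep$status[["pol"]],
                 envF_status = rep$status[["envF"]], class = rep$class,
                 events = paste(sprintf("%s@%d", ev$kind, ev$refPos),
                                collapse = ";"))
    })
    .writeTsv(do.call(rbind, rows), out("orf_report.tsv"))
  })

  runStage("date", function() {
    cons <- .loadConsensus(cfg$out_dir)
    ins <- readFasta(file.path(cfg$out_dir, "insertions.fasta"))
    ages <- dateInsertions(ins, cons, model = par$model, r = par$r)
    .writeTsv(ages, out("ages.tsv"), model = par$model, r = par$r)
  })

  runStage("silencing", function() {
    clusters <- readFasta(file.path(cfg$out_dir, "cluster.fasta"))
    cons <- readFasta(file.path(cfg$out_dir, "consensus.fasta"))
    m <- silencingMatrix(clusters, cons, k = par$k,
                         maxMismatch = par$max_mm)
    writeSilencingMatrix(m, out("silencing_matrix.tsv"), k = par$k,
                         maxMismatch = par$max_mm)
    for (cl in names(clusters)) {
      idx <- buildKmerIndex(clusters[[cl]], k = par$k, id = cl)
      for (co in names(cons)) {
        prof <- kmerCoverage(cons[[co]], idx, "antisense",
                             maxMismatch = par$max_mm, id = co)
        writeCoverageBed(prof, out(sprintf("coverage_%s_%s.bed", co, cl)))
      }
    }
  })

  runStage("recombination", function() {
    msa <- readMsa(file.path(cfg$out_dir, "panel_msa.fasta"))
    sites <- diagnosticSites(msa, "A1", "A2", "B1", "B2")
    call <- callRecombinant(msa, "query1", sites,
                            minSitesPerSegment = par$min_seg)
    seg <- segmentTable(call)
    bp <- breakpointTable(call)
    .writeTsv(data.frame(
      query_id = call@queryId, n_switches = nSwitches(call),
      segments = paste(sprintf("%s:%d-%d", seg$call, seg$startCol,
                               seg$endCol), collapse = ";"),
      breakpoints = if (nrow(bp))
        paste(sprintf("(%d,%d)", bp$from, bp$to), collapse = ";") else ""),
      out("recombination_calls.tsv"), min_seg = par$min_seg)
    .writeTsv(callTable(call), out("recombination_sites.tsv"),
              min_seg = par$min_seg)
  })

  manifest <- data.frame(path = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)))
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .log("done: %d output file(s)", nrow(manifest))
  invisible(manifest)
}

.loadConsensus <- function(dir) {
  fa <- readFasta(file.path(dir, "consensus.fasta"))
  annot <- readAnnotationTable(file.path(dir, "consensus_annot.tsv"))
  consensusElement(names(fa)[1L], as.character(fa[[1L]]), annot,
                   envStatus = "full_length")
}
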