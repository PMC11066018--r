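# End-to-end orchestration: design -> oligos -> RCA/digest -> reads -> QC
# -> solubility report, under one master seed with per-stage substreams.

#' Build a pipeline configuration
#'
#' A single master seed governs all stochastic stages (each stage draws a
#' derived substream so stages stay independently reproducible). The
#' configuration round-trips losslessly through JSON.
#'
#' @param seed master integer seed.
#' @param alphabet X-position alphabet for the demo library.
#' @param maxMotifs cap on the number of motifs carried forward.
#' @param scrambleIterations annealing iterations per oligo.
#' @param nUnits concatemer size for the digestion stage.
#' @param fMC methyl-dCTP fraction.
#' @param cBlocking blocking-cytosine count per site.
#' @param sizeWindow gel selection window in bp.
#' @param nReads,readLen,subRate,indelRate,revcompFraction read simulation
#'   parameters.
#' @param qc QC thresholds, see [qcThresholds].
#' @param nRepeatsExpressed hexapeptide repeats in the expressed construct.
#' @param context solubility classification context.
#' @param outputDir output directory for [runPipeline].
#' @return Named list (class "synidpPipelineConfig").
#' @export
pipelineConfig <- function(seed = 1L,
                           alphabet = c("A", "G", "S", "T", "Q", "L", "H"),
                           maxMotifs = 12L,
                           scrambleIterations = 250L,
                           nUnits = 2000L,
                           fMC = 0.25, cBlocking = 4L,
                           sizeWindow = c(360L, 576L),
                           nReads = 60L, readLen = 250L,
                           subRate = 0, indelRate = 0,
                           revcompFraction = 0,
                           qc = qcThresholds(),
                           nRepeatsExpressed = 24L,
                           context = "fusion",
                           outputDir = tempfile("synidp_run_")) {
  structure(list(seed = as.integer(seed), alphabet = alphabet,
                 maxMotifs = as.integer(maxMotifs),
                 scrambleIterations = as.integer(scrambleIterations),
                 nUnits = as.integer(nUnits), fMC = fMC,
                 cBlocking = as.integer(cBlocking),
                 sizeWindow = as.integer(sizeWindow),
                 nReads = as.integer(nReads), readLen = as.integer(readLen),
                 subRate = subRate, indelRate = indelRate,
                 revcompFraction = revcompFraction, qc = qc,
                 nRepeatsExpressed = as.integer(nRepeatsExpressed),
                 context = context, outputDir = outputDir),
            class = "synidpPipelineConfig")
}

#' Run the full discovery pipeline
#'
#' Stages, in order: motif enumeration; oligo design (codon scrambling with
#' the junction-split SexAI site); RCA digestion simulation and size
#' selection; read simulation; QC alignment, filtering and summary;
#' solubility report over the assembled constructs. Every output file is
#' recorded with its md5 checksum in the run manifest; identical
#' config + seed give an identical manifest.
#'
#' @param config see [pipelineConfig].
#' @return list(manifest, library, oligos, digest, qcSummary, solubility,
#'   recovery) invisibly; files under `config$outputDir`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "synidpPipelineConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outputDir, f)

  # stage 1: motif enumeration
  spec <- MotifSpec(alphabet = config$alphabet)
  lib <- enumerateMotifs(spec)
  m <- motifTable(lib)
  if (nrow(m) == 0L) stop("stage design: no admissible motifs")
  m <- head(m, config$maxMotifs)
  exportLibrary(new("MotifLibrary", motifs = m, spec = spec),
                fastaFile = out("library.fasta"),
                tsvFile = out("library.tsv"))

  # stage 2: oligo design
  oligos <- lapply(seq_len(nrow(m)), function(i) {
    d <- tryCatch(
      reverseTranslateScrambled(
        buildRepeatUnit(m$peptide[i], 4L),
        seed = deriveSeed(config$seed, 100L + i),
        iterations = config$scrambleIterations),
      error = function(e) stop("stage oligo_design [", m$multisetKey[i],
                               "]: ", conditionMessage(e)))
    d@motifId <- m$multisetKey[i]
    d
  })
  seqs <- setNames(vapply(oligos, oligoSeq, ""), m$multisetKey)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                              out("oligos.fasta"))

  # stage 3: RCA digestion + size selection
  digest <- simulateDigest(config$nUnits,
                           ProtectionModel(config$fMC, config$cBlocking),
                           seed = deriveSeed(config$seed, 2L))
  sel <- sizeSelect(digest$lengthBp[!digest$terminal],
                    config$sizeWindow[1], config$sizeWindow[2])
  write.table(digest, out("fragments.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # stage 4: read simulation
  reads <- simulateReads(seqs, nReads = config$nReads,
                         readLen = config$readLen,
                         subRate = config$subRate,
                         indelRate = config$indelRate,
                         revcompFraction = config$revcompFraction,
                         seed = deriveSeed(config$seed, 3L),
                         file = out("reads.fastq"))

  # stage 5: QC
  alns <- alignReadsToLibrary(reads, seqs)
  verdicts <- lapply(seq_along(alns), function(i)
    classifyRead(alns[[i]], reads[[i]], config$qc))
  qcTable <- do.call(rbind, lapply(seq_along(alns), function(i) {
    a <- alns[[i]]
    data.frame(readId = a@readId, reference = a@reference,
               orientation = a@orientation, phase = a@phaseOffset,
               edits = a@nEdits, perfectRepeats = a@nPerfectRepeats,
               status = verdicts[[i]]$status,
               reasons = paste(verdicts[[i]]$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  write.table(qcTable, out("qc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  qcSummary <- summarizeLibrary(alns, verdicts, unname(reads))

  # recovery against the generator's ground truth in the read names
  truth <- do.call(rbind, strsplit(names(reads), "|", fixed = TRUE))
  recovered <- qcTable$reference == truth[, 2] &
    qcTable$orientation == truth[, 4]
  recovery <- mean(recovered[qcTable$status == "pass"])

  # stage 6: solubility report on the expressed constructs
  constructs <- setNames(vapply(seq_len(nrow(m)), function(i)
    assembleConstruct(buildRepeatUnit(m$peptide[i], 1L, phase = "GP"),
                      config$nRepeatsExpressed), ""), m$multisetKey)
  sol <- solubilityReport(constructs, context = config$context)
  write.table(sol, out("solubility.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  jsonlite::write_json(
    list(config = unclass(config), qcSummary = qcSummary,
         sizeSelection = sel[c("countFraction", "massFraction")],
         recovery = recovery),
    out("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- sort(list.files(config$outputDir, full.names = TRUE))
  files <- files[basename(files) != "MANIFEST.tsv"]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, out("MANIFEST.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(manifest = manifest, library = m, oligos = oligos,
                 digest = digest, sizeSelection = sel, reads = reads,
                 qcTable = qcTable, qcSummary = qcSummary,
                 solubility = sol, recovery = recovery))
}

#' Generate deterministic test fixtures
#'
#' Synthetic stand-ins for the study's raw data: sequencing reads
#' ("reads"), noisy scattering profiles ("scattering"), CD spectra ("cd"),
#' and labeled hydropathy tables with a planted integer separation
#' threshold ("table1_style").
#'
#' @param kind one of "reads", "scattering", "cd", "table1_style".
#' @param params named list of kind-specific parameters; see Details.
#' @param seed integer seed.
#' @param dir output directory (created when needed).
#' @return The fixture object invisibly; files written under `dir`.
#'
#' @details
#' "reads": params designs (named sequences), nReads, readLen, subRate,
#' indelRate, revcompFraction. "scattering": params model
#' ("debye"|"rod"|"pev"), Rg or L, nu, noise (relative sd). "cd": params
#' kind2 = "coil" or "helix". "table1_style": params threshold (planted
#' integer), nPerClass, gap.
#' @export
makeFixtures <- function(kind, params = list(), seed = 1L,
                         dir = tempfile("fixtures_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- params
  switch(kind,
    reads = {
      designs <- p$designs
      if (is.null(designs)) {
        lib <- enumerateMotifs(MotifSpec(alphabet = c("A", "G", "S")))
        m <- motifTable(lib)
        designs <- setNames(vapply(seq_len(nrow(m)), function(i)
          oligoSeq(reverseTranslateScrambled(
            buildRepeatUnit(m$peptide[i], 4L),
            seed = deriveSeed(seed, 50L + i), iterations = 150L)), ""),
          m$multisetKey)
      }
      reads <- simulateReads(designs,
                             nReads = p$nReads %||% 50L,
                             readLen = p$readLen %||% 250L,
                             subRate = p$subRate %||% 0,
                             indelRate = p$indelRate %||% 0,
                             revcompFraction = p$revcompFraction %||% 0,
                             seed = seed,
                             file = file.path(dir, "reads.fastq"))
      invisible(list(reads = reads, designs = designs, dir = dir))
    },
    scattering = {
      q <- p$q %||% exp(seq(log(0.012), log(0.6), length.out = 120))
      model <- p$model %||% "pev"
      base <- switch(model,
        debye = debyeChain(q, p$Rg %||% 42),
        rod = rodFormFactor(q, p$L %||% 300),
        pev = pevIntensity(q, p$Rg %||% 42, p$nu %||% 0.5),
        stop("unknown scattering model"))
      noise <- p$noise %||% 0.02
      I0 <- intensity(base)
      I <- withSeed(seed, I0 * (1 + rnorm(length(q), 0, noise)))
      prof <- ScatteringProfile(q, pmax(I, 1e-12), noise * I0)
      writeScatteringProfile(prof, file.path(dir, "profile.dat"))
      invisible(list(profile = prof, truth = p, dir = dir))
    },
    cd = {
      wl <- 190:260
      el <- if ((p$kind2 %||% "coil") == "coil")
        -6 * exp(-(wl - 197)^2 / 18) + 1.2 * exp(-(wl - 215)^2 / 40)
      else
        -5 * exp(-(wl - 208)^2 / 30) - 5 * exp(-(wl - 222)^2 / 30)
      d <- data.frame(wavelength = wl, ellipticity = el)
      write.table(d, file.path(dir, "cd.dat"), quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      invisible(list(spectrum = d, dir = dir))
    },
    table1_style = {
      t <- p$threshold %||% 42L
      nPer <- p$nPerClass %||% 6L
      tbl <- withSeed(seed, {
        # the top insoluble score sits in (t-1, t) so that t is the
        # *smallest* separating integer by construction
        ins <- c(t - runif(1, 0.05, 0.9),
                 t - runif(nPer - 1L, 1, 15))
        sol <- t + runif(nPer, 0.1, 15)
        data.frame(score = c(ins, sol),
                   label = rep(c("insoluble", "soluble"), each = nPer),
                   stringsAsFactors = FALSE)
      })
      write.table(tbl, file.path(dir, "table1_style.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      invisible(list(table = tbl, threshold = t, dir = dir))
    },
    stop("unknown fixture kind: ", kind)
  )
}
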