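#' @include AllClasses.R simulate-stack.R registration.R segmentation.R
#' @include colocalization.R group-stats.R longread.R io.R
NULL

# ---- configuration --------------------------------------------------------

.defaultConfig <- function(mode) {
  list(
    mode = mode,
    seed = 1,
    outDir = NULL,
    input = NULL,                                # or list(stacks=, beadStack=, reads=)
    simulation = list(
      nNuclei = 25, delayKb = 0, intron = 23, intronProbeWidth = 3000,
      bacSpan = NULL, probes = NULL, nReads = 5000, polyAFraction = 0.1,
      optics = list(), render = list()),
    gene = NULL,                                 # NULL -> tgGeneModel()
    register = TRUE,
    qc = list(minContainment = 0.8, minVoxels = 100),
    boundaryTol = 10
  )
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read and normalize an experiment configuration
#'
#' Accepts a YAML file path or a named list and merges it over the built-in
#' defaults. Exactly one of \code{input} (paths to TIFF stacks / BED12
#' reads) or \code{simulation} drives an experiment; when \code{input} is
#' set the simulation block is ignored.
#'
#' @param config YAML path or named list; must contain or be given
#'   \code{mode} (\code{"overlap"}, \code{"pcc"} or \code{"introns"}).
#' @param mode default mode when the config names none.
#' @return normalized configuration list.
#' @export
readExperimentConfig <- function(config, mode = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) paramError("config must be a list or a YAML path")
  m <- config$mode %||% mode
  if (is.null(m) || !m %in% c("overlap", "pcc", "introns"))
    paramError("mode must be one of overlap, pcc, introns")
  .mergeConfig(.defaultConfig(m), config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.buildGene <- function(cfg) {
  g <- cfg$gene
  if (is.null(g)) return(tgGeneModel())
  if (is(g, "GeneModel")) return(g)
  if (!is.null(g$path)) return(readGeneModel(g$path, g$gene %||% NULL))
  do.call(makeGeneModel, g)
}

.buildOptics <- function(cfg, nChannels) {
  o <- cfg$simulation$optics
  if (is(o, "OpticsConfig")) return(o)
  o$nChannels <- o$nChannels %||% nChannels
  if (!is.null(o$shifts)) o$shifts <- matrix(unlist(o$shifts), ncol = 3,
                                             byrow = TRUE)
  do.call(OpticsConfig, o)
}

.buildProbes <- function(cfg, gene) {
  sim <- cfg$simulation
  if (!is.null(sim$probes)) {
    return(lapply(sim$probes, function(p) {
      if (is(p, "ProbeSet")) return(p)
      if (!is.null(p$intron))
        probeForIntron(gene, p$intron, p$width %||% 3000, p$channel,
                       p$name %||% paste0("intron", p$intron))
      else ProbeSet(p$name %||% "probe",
                    matrix(unlist(p$targets), ncol = 2, byrow = TRUE),
                    p$channel)
    }))
  }
  span <- sim$bacSpan %||% c(0, min(153000, geneLength(gene)))
  list(probeForIntron(gene, sim$intron, sim$intronProbeWidth, channel = 1),
       bacProbe(gene, span, channel = 2))
}

# Simulate (or load) the stacks for an imaging experiment and correct
# chromatic shift. Returns list(stacks, truth, shiftTable, log).
.prepareStacks <- function(cfg, gene, delay, probes) {
  logLines <- character()
  if (!is.null(cfg$input)) {
    files <- cfg$input$stacks
    if (length(files) == 1 && dir.exists(files))
      files <- list.files(files, pattern = "\\.tiff?$", full.names = TRUE)
    if (!length(files)) stop("no input stacks found")
    stacks <- lapply(files, readImageStack)
    truth <- rep(list(NULL), length(stacks))
    names(stacks) <- basename(files)
    beadFile <- cfg$input$beadStack
    shiftTab <- NULL
    if (!is.null(beadFile)) {
      shiftTab <- estimateShift(readImageStack(beadFile))
      stacks <- lapply(stacks, applyShift, shifts = shiftTab)
      logLines <- c(logLines, "chromatic shift estimated from bead stack")
    }
    return(list(stacks = stacks, truth = truth, shiftTable = shiftTab,
                log = logLines))
  }
  optics <- .buildOptics(cfg, max(vapply(probes, function(p) p@channel, 0L)) + 1L)
  sim <- do.call(simulateLoopStack,
                 c(list(gene = gene, delay = delay, probes = probes,
                        optics = optics, nNuclei = cfg$simulation$nNuclei,
                        seed = cfg$seed), cfg$simulation$render))
  shiftTab <- NULL
  if (isTRUE(cfg$register) && any(optics@shifts != 0)) {
    beads <- simulateBeadStack(6, optics, seed = subSeed(cfg$seed, 9999))
    shiftTab <- estimateShift(beads$stack)
    sim$stacks <- lapply(sim$stacks, applyShift, shifts = shiftTab)
    logLines <- c(logLines,
                  sprintf("registered %d stacks against simulated bead field",
                          length(sim$stacks)))
  }
  names(sim$stacks) <- sprintf("sim_nucleus_%03d", seq_along(sim$stacks))
  list(stacks = sim$stacks, truth = sim$truth, shiftTable = shiftTab,
       log = logLines)
}

.writeOutputs <- function(outDir, tables, cfg) {
  if (is.null(outDir)) return(invisible(NULL))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    if (is.data.frame(tables[[nm]]))
      write.csv(tables[[nm]], file.path(outDir, paste0(nm, ".csv")),
                row.names = FALSE)
  cfg$gene <- NULL                                # S4 objects are not JSON
  meta <- list(config = cfg, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               package = as.character(utils::packageVersion("loopSplice")))
  jsonlite::write_json(meta, file.path(outDir, "run-metadata.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(NULL)
}

# ---- experiments ----------------------------------------------------------

#' Run an end-to-end overlap-ratio experiment
#'
#' Simulates (or loads) image stacks, corrects chromatic shift against a
#' bead field, segments the central nucleus and the two FISH channels,
#' computes the overlap ratio with the 80\%-containment QC per nucleus, and
#' summarizes the QC-passing nuclei with a boxplot five-number summary.
#' QC-failing nuclei stay in the raw table but are excluded from the
#' summary.
#'
#' @param config configuration (list or YAML path), see
#'   \code{\link{readExperimentConfig}}. Key simulation fields:
#'   \code{nNuclei}, \code{delayKb}, \code{intron} (probe target),
#'   \code{bacSpan}, \code{optics}.
#' @return list with \code{table} (one row per nucleus), \code{summary}
#'   (NULL when nothing passes QC), \code{shiftTable}, \code{log} and
#'   \code{config}.
#' @export
runOverlapExperiment <- function(config) {
  cfg <- readExperimentConfig(config, "overlap")
  gene <- .buildGene(cfg)
  delay <- DelayModel(delayKb = cfg$simulation$delayKb)
  probes <- .buildProbes(cfg, gene)
  prep <- .prepareStacks(cfg, gene, delay, probes)
  rows <- vector("list", length(prep$stacks))
  for (i in seq_along(prep$stacks)) {
    st <- prep$stacks[[i]]
    row <- data.frame(stack = names(prep$stacks)[i], vIntron = NA_real_,
                      vBac = NA_real_, vOverlap = NA_real_, ratio = NA_real_,
                      containment = NA_real_, qcPass = FALSE,
                      trueRatio = prep$truth[[i]]$trueRatio %||% NA_real_,
                      note = "")
    res <- tryCatch({
      nuc <- segmentNucleus(st)
      li <- segmentFish(getChannel(st, 1), nuc, voxelSize(st))
      lb <- segmentFish(getChannel(st, 2), nuc, voxelSize(st))
      ov <- overlapRatio(li, lb, cfg$qc$minContainment)
      row[c("vIntron", "vBac", "vOverlap", "ratio", "containment",
            "qcPass")] <- overlapStats(ov)
      row
    }, error = function(e) { row$note <- conditionMessage(e); row })
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  passed <- tab$ratio[tab$qcPass]
  summary <- if (length(passed)) summarizeBox(passed, cfg$mode) else NULL
  log <- c(prep$log, sprintf("%d/%d nuclei passed QC", sum(tab$qcPass),
                             nrow(tab)))
  out <- list(table = tab,
              summary = summary, shiftTable = prep$shiftTable, log = log,
              config = cfg)
  .writeOutputs(cfg$outDir, list(overlap_per_nucleus = tab), cfg)
  out
}

#' Run an end-to-end masked-PCC experiment
#'
#' As \code{\link{runOverlapExperiment}}, but computes the masked 3D
#' Pearson correlation between the two FISH channels per nucleus (both
#' alleles pooled into a single coefficient).
#'
#' @param config configuration; \code{simulation$probes} should define two
#'   probe sets on channels 1 and 2 (possibly with identical targets for a
#'   positive control).
#' @return list with \code{table}, \code{summary}, \code{shiftTable},
#'   \code{log}, \code{config}.
#' @export
runPccExperiment <- function(config) {
  cfg <- readExperimentConfig(config, "pcc")
  gene <- .buildGene(cfg)
  delay <- DelayModel(delayKb = cfg$simulation$delayKb)
  probes <- .buildProbes(cfg, gene)
  prep <- .prepareStacks(cfg, gene, delay, probes)
  rows <- vector("list", length(prep$stacks))
  for (i in seq_along(prep$stacks)) {
    st <- prep$stacks[[i]]
    row <- data.frame(stack = names(prep$stacks)[i], pcc = NA_real_,
                      nVoxels = NA_real_, qcPass = FALSE, note = "")
    rows[[i]] <- tryCatch({
      nuc <- segmentNucleus(st)
      a <- getChannel(st, 1); b <- getChannel(st, 2)
      m <- pccMask(a, b, nuc)
      r <- pcc(a, b, m, minVoxels = cfg$qc$minVoxels)
      row$pcc <- pccValue(r); row$nVoxels <- r@nVoxels
      row$qcPass <- qcPass(r)
      row
    }, error = function(e) { row$note <- conditionMessage(e); row })
  }
  tab <- do.call(rbind, rows)
  passed <- tab$pcc[tab$qcPass & !is.na(tab$pcc)]
  summary <- if (length(passed)) summarizeBox(passed, "pcc") else NULL
  log <- c(prep$log, sprintf("%d/%d nuclei passed QC", sum(tab$qcPass),
                             nrow(tab)))
  out <- list(table = tab, summary = summary, shiftTable = prep$shiftTable,
              log = log, config = cfg)
  .writeOutputs(cfg$outDir, list(pcc_per_nucleus = tab), cfg)
  out
}

#' Run an end-to-end nascent-read intron experiment
#'
#' Simulates nascent long reads (or loads BED12 alignments), classifies
#' per-intron states, selects intron-containing reads and produces the
#' read-length histogram (300-nt bins), the introns-per-read distribution,
#' per-intron retained-read coverage and per-intron delay estimates.
#'
#' @param config configuration; simulation fields \code{nReads},
#'   \code{delayKb}, \code{polyAFraction}; or \code{input$reads} (BED12).
#' @return list with \code{reads}, \code{calls}, \code{lengthHist},
#'   \code{intronsPerRead}, \code{coverage}, \code{delayEstimates},
#'   \code{nReadThrough}, \code{log}, \code{config}.
#' @export
runIntronExperiment <- function(config) {
  cfg <- readExperimentConfig(config, "introns")
  gene <- .buildGene(cfg)
  if (!is.null(cfg$input)) {
    reads <- readBed12(cfg$input$reads)
  } else {
    sim <- simulateReads(gene, DelayModel(delayKb = cfg$simulation$delayKb),
                         cfg$simulation$nReads,
                         cfg$simulation$polyAFraction, seed = cfg$seed)
    reads <- sim$reads
  }
  icr <- intronContainingReads(reads, gene, cfg$boundaryTol)
  if (!length(icr)) stop("no intron-containing reads")
  calls <- classifyReads(icr, gene, cfg$boundaryTol)
  out <- list(reads = icr,
              calls = calls,
              lengthHist = readLengthHist(icr),
              intronsPerRead = intronsPerReadHist(calls),
              coverage = intronCoverage(icr, gene, cfg$boundaryTol),
              delayEstimates = estimateDelay(icr, gene, cfg$boundaryTol),
              nReadThrough = attr(icr, "nReadThrough"),
              log = sprintf("%d intron-containing of %d reads (%d read-through excluded)",
                            length(icr), length(reads),
                            attr(icr, "nReadThrough")),
              config = cfg)
  .writeOutputs(cfg$outDir,
                list(intron_calls = calls, read_length_hist = out$lengthHist,
                     introns_per_read = out$intronsPerRead,
                     intron_coverage = out$coverage,
                     delay_estimates = out$delayEstimates), cfg)
  out
}
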