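# End-to-end pipeline over synthetic data: every stage reads its inputs
# from the files the previous stages wrote, so one run exercises all
# readers and writers, and a manifest of MD5 checksums makes reruns
# verifiable. Stages whose outputs already match the manifest of a
# previous run with the same configuration are skipped.

#' Default pipeline configuration
#'
#' Study-scale defaults mirroring the experimental design the package
#' targets (4 replicates per treatment group for RNA-seq derived
#' stages, 5 per group for methylation arrays, two donor-age strata
#' for the clock study) with the documented analysis thresholds:
#' |delta Psi| > 0.1 with FDR < 0.05 for differential splicing, a
#' 5-reads-in-20%-of-samples expression filter, GSEA with 5000
#' permutations and an FDR 0.1 cutoff, and |lfc(M)| > 1 with
#' FDR < 0.05 for differentially methylated probes.
#'
#' @param seed master seed; per-stage child seeds are derived from it.
#' @return a nested configuration list for [runPipeline()].
#' @export
defaultConfig <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    annotation = list(nGenes = 40, eventsPerGene = 1,
                      categoryMix = c(frameshift = 0.10,
                                      premature_stop = 0.10,
                                      domain_loss = 0.10,
                                      no_disruption = 0.55,
                                      noncoding_region = 0.15)),
    splicing = list(nReps = 4, depth = 200, minCoverage = 10,
                    fracChanged = 0.4, deltaMagnitude = 0.3,
                    deltaCutoff = 0.1, sigCutoff = 0.05,
                    selectBy = "fdr", presenceThreshold = 0.1),
    expression = list(nGenes = 600, nPerGroup = 4, fracDe = 0.15,
                      lfcMagnitude = 2, dispersion = 0.1,
                      minReads = 5, minFraction = 0.2),
    gsea = list(nPerm = 5000, minSize = 5, fdrCutoff = 0.1,
                signatureSize = 500, adjCutoff = 0.05,
                correlationTopN = 650, nDecoySets = 8, decoySize = 25),
    clock = list(nGenes = 50, intercept = 12, agesMonths = c(4, 20),
                 nReps = 4, rejuvenationShift = 5, noiseSd = 0.5),
    methylation = list(nProbes = 800, fracDmp = 0.05, deltaM = 2,
                       nPerGroup = 5, lfcCutoff = 1, fdrCutoff = 0.05,
                       targetState = "enhancer")
  )
}

configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config), tf)
  unname(tools::md5sum(tf))
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [defaultConfig()] entries;
#' missing entries keep their defaults. Referenced input paths (if
#' any) are checked at validation time.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("readConfig: file not found: ", path)
  user <- yaml::read_yaml(path)
  base <- defaultConfig(seed = user$seed %||% 1)
  for (section in names(user)) {
    if (is.list(user[[section]]) && section %in% names(base)) {
      for (k in names(user[[section]]))
        base[[section]][[k]] <- user[[section]][[k]]
    } else {
      base[[section]] <- user[[section]]
    }
  }
  base
}

pipelineDeviations <- c(
  "differential splicing: Welch t on replicate Psi values (no hierarchical junction model)",
  "differential expression: Welch t on log2 RLE-normalized counts (no negative-binomial model)",
  "differential methylation: per-probe Welch t on M-values (no empirical-Bayes moderation)",
  "post-hoc contrasts: pairwise Welch t with BH (no studentized-range correction)")

#' Run the full synthetic pipeline
#'
#' Executes all stages in dependency order — annotation simulation,
#' junction counts and Psi, differential splicing, consequence
#' classification, splicing damage, expression simulation and DE,
#' signatures and GSEA association, signature correlation, clock study,
#' methylation and chromatin-state enrichment — writing every
#' intermediate as an annotated TSV under `outDir` and a
#' `manifest.json` with per-stage MD5 checksums. Rerunning with an
#' unchanged configuration skips stages whose outputs already match
#' the manifest.
#'
#' @param config list from [defaultConfig()] or [readConfig()].
#' @param outDir output directory.
#' @param quiet suppress progress messages?
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = defaultConfig(), outDir, quiet = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(config)
  meta <- c(config_hash = hash, seed = as.character(config$seed))
  say <- function(...) if (!quiet) message(...)

  prev <- NULL
  manifestPath <- file.path(outDir, "manifest.json")
  if (file.exists(manifestPath)) {
    prev <- tryCatch(jsonlite::read_json(manifestPath,
                                         simplifyVector = TRUE),
                     error = function(e) NULL)
    if (!is.null(prev) && !identical(prev$config_hash, hash)) prev <- NULL
  }
  upToDate <- function(stage, files) {
    if (is.null(prev) || is.null(prev$stages[[stage]])) return(FALSE)
    old <- unlist(prev$stages[[stage]])
    if (!setequal(names(old), basename(files))) return(FALSE)
    all(file.exists(files)) &&
      identical(unname(old[basename(files)]),
                unname(tools::md5sum(files)[files]))
  }
  stages <- list()
  runStage <- function(stage, files, fn) {
    if (upToDate(stage, files)) {
      say("  [skip] ", stage)
    } else {
      say("  [run ] ", stage)
      fn()
      missing <- files[!file.exists(files)]
      if (length(missing))
        stop("pipeline stage '", stage, "' did not produce: ",
             paste(basename(missing), collapse = ", "))
    }
    stages[[stage]] <<- as.list(setNames(unname(tools::md5sum(files)),
                                         basename(files)))
  }
  p <- function(...) file.path(outDir, ...)
  writeConfigYaml <- p("config.yaml")
  writeLines(yaml::as.yaml(config), writeConfigYaml)

  ## --- annotation -------------------------------------------------
  annDir <- p("annotation")
  annFiles <- file.path(annDir, c("genome.fa", "annotation.gtf",
                                  "domains.bed", "events.tsv",
                                  "truth_events.tsv"))
  runStage("annotation", annFiles, function() {
    sim <- simulateGenomeAnnotation(
      seed = childSeed(config$seed, "annotation"),
      nGenes = config$annotation$nGenes,
      categoryMix = unlist(config$annotation$categoryMix),
      eventsPerGene = config$annotation$eventsPerGene)
    writeAnnotation(sim, annDir)
  })

  ## --- junction counts and Psi ------------------------------------
  spDir <- p("splicing"); dir.create(spDir, showWarnings = FALSE)
  spFiles <- file.path(spDir, c("junction_counts.tsv", "psi.tsv",
                                "sample_groups.tsv", "truth_psi.tsv"))
  runStage("psi", spFiles, function() {
    events <- readEvents(file.path(annDir, "events.tsv"))
    cfg <- config$splicing
    sseed <- childSeed(config$seed, "splicing")
    nEv <- length(events)
    psiDelta <- withSeed(sseed, {
      psi0 <- runif(nEv, 0.2, 0.8)
      changed <- runif(nEv) < cfg$fracChanged
      # retained introns preferentially lose inclusion under treatment,
      # mirroring the splicing-repair phenotype the pipeline emulates
      types <- vapply(events, function(e) e@type, "")
      sgn <- ifelse(types == "RI",
                    ifelse(runif(nEv) < 0.8, -1, 1),
                    sample(c(-1, 1), nEv, replace = TRUE))
      list(psi0 = psi0, delta = ifelse(changed, sgn * cfg$deltaMagnitude, 0))
    })
    sim <- simulateSplicingCounts(events, psiDelta$psi0, psiDelta$delta,
                                  nReps = cfg$nReps, depth = cfg$depth,
                                  seed = sseed + 1L)
    writeTsv(sim$counts, file.path(spDir, "junction_counts.tsv"), meta)
    writeTsv(data.frame(sample = names(sim$groups),
                        group = as.character(sim$groups)),
             file.path(spDir, "sample_groups.tsv"), meta)
    writeTsv(sim$truth, file.path(spDir, "truth_psi.tsv"), meta)
    pm <- psiMatrix(sim$counts, minCoverage = cfg$minCoverage)
    writeMatrixTsv(SummarizedExperiment::assay(pm, "psi"),
                   file.path(spDir, "psi.tsv"), "event_id", meta)
  })

  ## --- differential splicing --------------------------------------
  dsFiles <- file.path(spDir, c("diff_splicing.tsv",
                                "direction_summary.tsv"))
  runStage("diff_splicing", dsFiles, function() {
    cfg <- config$splicing
    counts <- readTsv(file.path(spDir, "junction_counts.tsv"))
    gr <- readTsv(file.path(spDir, "sample_groups.tsv"))
    pm <- psiMatrix(counts, minCoverage = cfg$minCoverage)
    groups <- gr$group[match(colnames(pm), gr$sample)]
    ds <- differentialSplicing(pm, groups, deltaCutoff = cfg$deltaCutoff,
                               sigCutoff = cfg$sigCutoff,
                               selectBy = cfg$selectBy)
    writeTsv(ds, file.path(spDir, "diff_splicing.tsv"), meta)
    writeTsv(directionSummary(ds),
             file.path(spDir, "direction_summary.tsv"), meta)
  })

  ## --- consequence classification and damage ----------------------
  cqDir <- p("consequence"); dir.create(cqDir, showWarnings = FALSE)
  cqFiles <- file.path(cqDir, c("consequence_calls.tsv",
                                "damage_differential.tsv",
                                "damage_standing.tsv",
                                "damage_contrasts.tsv"))
  runStage("consequence", cqFiles, function() {
    genome <- readGenome(file.path(annDir, "genome.fa"))
    transcripts <- readTranscripts(file.path(annDir, "annotation.gtf"))
    events <- readEvents(file.path(annDir, "events.tsv"))
    domains <- readDomains(file.path(annDir, "domains.bed"))
    calls <- classifyConsequences(transcripts, events, genome, domains)
    writeTsv(calls, file.path(cqDir, "consequence_calls.tsv"), meta)
    ds <- readTsv(file.path(spDir, "diff_splicing.tsv"))
    writeTsv(splicingDamage(calls, records = ds, mode = "differential"),
             file.path(cqDir, "damage_differential.tsv"), meta)
    counts <- readTsv(file.path(spDir, "junction_counts.tsv"))
    pm <- psiMatrix(counts, minCoverage = config$splicing$minCoverage)
    standing <- splicingDamage(calls, psi = pm, mode = "standing",
                               presenceThreshold =
                                 config$splicing$presenceThreshold)
    writeTsv(standing, file.path(cqDir, "damage_standing.tsv"), meta)
    gr <- readTsv(file.path(spDir, "sample_groups.tsv"))
    grp <- gr$group[match(standing$sample, gr$sample)]
    writeTsv(pairwiseWelch(standing$proportion, grp),
             file.path(cqDir, "damage_contrasts.tsv"), meta)
  })

  ## --- expression -------------------------------------------------
  exDir <- p("expression"); dir.create(exDir, showWarnings = FALSE)
  exFiles <- file.path(exDir, c("counts.tsv", "normalized.tsv",
                                "de.tsv", "de_replicate.tsv",
                                "truth_expression.tsv",
                                "expression_groups.tsv"))
  runStage("expression", exFiles, function() {
    cfg <- config$expression
    eseed <- childSeed(config$seed, "expression")
    sim <- simulateExpression(cfg$nGenes, cfg$nPerGroup, cfg$fracDe,
                              cfg$lfcMagnitude, cfg$dispersion,
                              seed = eseed)
    writeMatrixTsv(sim$counts, file.path(exDir, "counts.tsv"),
                   "gene", meta)
    writeTsv(sim$truth, file.path(exDir, "truth_expression.tsv"), meta)
    writeTsv(data.frame(sample = names(sim$groups),
                        group = as.character(sim$groups)),
             file.path(exDir, "expression_groups.tsv"), meta)
    filt <- filterGenes(readMatrixTsv(file.path(exDir, "counts.tsv")),
                        cfg$minReads, cfg$minFraction)
    norm <- rleNormalize(filt)
    writeMatrixTsv(norm$normalized, file.path(exDir, "normalized.tsv"),
                   "gene", c(meta, size_factors =
                               paste(signif(norm$sizeFactors, 6),
                                     collapse = ",")))
    de <- differentialExpression(norm$normalized, sim$groups)
    writeTsv(de, file.path(exDir, "de.tsv"), meta)
    # independent replicate run of the same design, for the pairwise
    # signature-correlation stage
    sim2 <- simulateExpression(cfg$nGenes, cfg$nPerGroup, cfg$fracDe,
                               cfg$lfcMagnitude, cfg$dispersion,
                               seed = eseed + 1L, trueLfc = sim$truth$lfc)
    norm2 <- rleNormalize(filterGenes(sim2$counts, cfg$minReads,
                                      cfg$minFraction))
    writeTsv(differentialExpression(norm2$normalized, sim2$groups),
             file.path(exDir, "de_replicate.tsv"), meta)
  })

  ## --- signatures, GSEA association, correlation ------------------
  enDir <- p("enrichment"); dir.create(enDir, showWarnings = FALSE)
  enFiles <- file.path(enDir, c("signatures.gmt", "gsea.tsv",
                                "association.tsv",
                                "signature_correlation.tsv"))
  runStage("enrichment", enFiles, function() {
    cfg <- config$gsea
    de <- readTsv(file.path(exDir, "de.tsv"))
    deRep <- readTsv(file.path(exDir, "de_replicate.tsv"))
    truth <- readTsv(file.path(exDir, "truth_expression.tsv"))
    sigs <- buildSignature(de, n = cfg$signatureSize,
                           adjCutoff = cfg$adjCutoff, split = TRUE,
                           name = "treatment_signature")
    sigs$truth_up <- truth$gene[truth$is_de & truth$lfc > 0]
    sigs$truth_down <- truth$gene[truth$is_de & truth$lfc < 0]
    gseed <- childSeed(config$seed, "gsea")
    decoys <- withSeed(gseed, {
      out <- lapply(seq_len(cfg$nDecoySets), function(i)
        sample(de$gene, cfg$decoySize))
      names(out) <- sprintf("decoy_%02d", seq_along(out))
      out
    })
    sets <- c(sigs, decoys)
    writeGmt(sets, file.path(enDir, "signatures.gmt"))
    res <- gseaPreranked(rankedList(de), readGmt(file.path(enDir,
                                                           "signatures.gmt")),
                         nPerm = cfg$nPerm, seed = gseed,
                         minSize = cfg$minSize,
                         fdrCutoff = cfg$fdrCutoff)
    writeTsv(res, file.path(enDir, "gsea.tsv"), meta)
    assoc <- signatureAssociation(
      list(treated_vs_control = de, replicate_run = deRep),
      sets[c("truth_up", "truth_down")],
      nPerm = cfg$nPerm, seed = gseed, minSize = cfg$minSize)
    writeTsv(assoc, file.path(enDir, "association.tsv"), meta)
    sc <- signatureCorrelation(de, deRep, n = cfg$correlationTopN)
    writeTsv(data.frame(pair = "de_vs_replicate", rho = sc$rho,
                        n_union = sc$n_union),
             file.path(enDir, "signature_correlation.tsv"), meta)
  })

  ## --- transcriptomic clock ---------------------------------------
  ckDir <- p("clock"); dir.create(ckDir, showWarnings = FALSE)
  ckFiles <- file.path(ckDir, c("clock_model.tsv", "clock_expression.tsv",
                                "clock_design.tsv", "tage.tsv",
                                "tage_contrasts.tsv"))
  runStage("clock", ckFiles, function() {
    cfg <- config$clock
    cseed <- childSeed(config$seed, "clock")
    clock <- syntheticClock(cfg$nGenes, cfg$intercept, seed = cseed)
    writeClockModel(clock, file.path(ckDir, "clock_model.tsv"))
    design <- expand.grid(rep = seq_len(cfg$nReps),
                          treatment = c("control", "treated"),
                          age = cfg$agesMonths)
    design$sample <- sprintf("age%d_%s_%d", design$age,
                             design$treatment, design$rep)
    trueAges <- setNames(as.numeric(design$age), design$sample)
    shift <- ifelse(design$treatment == "treated",
                    cfg$rejuvenationShift, 0)
    study <- simulateClockStudy(clock, trueAges, noiseSd = cfg$noiseSd,
                                shift = shift, seed = cseed + 1L)
    writeMatrixTsv(study$expr, file.path(ckDir, "clock_expression.tsv"),
                   "gene", meta)
    writeTsv(cbind(design[, c("sample", "age", "treatment")],
                   target_age = study$truth$target_age),
             file.path(ckDir, "clock_design.tsv"), meta)
    preds <- applyClock(readMatrixTsv(file.path(ckDir,
                                                "clock_expression.tsv")),
                        readClockModel(file.path(ckDir,
                                                 "clock_model.tsv")))
    writeTsv(preds, file.path(ckDir, "tage.tsv"), meta)
    writeTsv(compareTAges(preds, design$treatment,
                          strata = design$age, control = "control"),
             file.path(ckDir, "tage_contrasts.tsv"), meta)
  })

  ## --- methylation ------------------------------------------------
  meDir <- p("methylation"); dir.create(meDir, showWarnings = FALSE)
  meFiles <- file.path(meDir, c("beta.tsv", "state_map.tsv",
                                "methylation_groups.tsv",
                                "truth_methylation.tsv", "dmp.tsv",
                                "state_enrichment.tsv",
                                "mean_methylation.tsv"))
  runStage("methylation", meFiles, function() {
    cfg <- config$methylation
    mseed <- childSeed(config$seed, "methylation")
    sim <- simulateMethylation(cfg$nProbes, fracDmp = cfg$fracDmp,
                               deltaM = cfg$deltaM,
                               nPerGroup = cfg$nPerGroup,
                               targetState = cfg$targetState,
                               seed = mseed)
    writeMatrixTsv(sim$beta, file.path(meDir, "beta.tsv"), "probe", meta)
    writeTsv(sim$stateMap, file.path(meDir, "state_map.tsv"), meta)
    writeTsv(data.frame(sample = names(sim$groups),
                        group = as.character(sim$groups)),
             file.path(meDir, "methylation_groups.tsv"), meta)
    writeTsv(sim$truth, file.path(meDir, "truth_methylation.tsv"), meta)
    beta <- filterProbes(readMatrixTsv(file.path(meDir, "beta.tsv")),
                         sim$detection)
    M <- betaToM(beta)
    gr <- readTsv(file.path(meDir, "methylation_groups.tsv"))
    dmps <- differentialMethylation(M, gr$group[match(colnames(M),
                                                      gr$sample)],
                                    lfcCutoff = cfg$lfcCutoff,
                                    fdrCutoff = cfg$fdrCutoff)
    writeTsv(dmps, file.path(meDir, "dmp.tsv"), meta)
    stateMap <- readStateMap(file.path(meDir, "state_map.tsv"))
    writeTsv(chromatinStateEnrichment(dmps, rownames(beta), stateMap),
             file.path(meDir, "state_enrichment.tsv"), meta)
    mm <- meanMethylation(beta)
    writeTsv(data.frame(sample = names(mm), mean_beta = mm),
             file.path(meDir, "mean_methylation.tsv"), meta)
  })

  manifest <- list(
    tool = "rejuvomics",
    version = as.character(packageVersion("rejuvomics")),
    config_hash = hash, seed = config$seed,
    deviations = pipelineDeviations,
    stages = stages)
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE)
  say("pipeline complete: ", manifestPath)
  invisible(manifest)
}
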