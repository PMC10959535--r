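# The toy locus (helper-fixtures.R) has a 99 nt internal exon 2 fully
# inside the CDS and a 20-codon stop-free intron 2, so event forms can
# be checked base-by-base against re-splicing oracles.

test_that("applyEvent rebuilds isoform mRNAs exactly", {
  loc <- makeToyLocus()
  t <- loc$t; g <- loc$genome
  refLen <- sum(IRanges::width(loc$exons))

  se <- SpliceEvent("se", "SE", "geneT", "txT", "chrT", "+",
                    loc$exons[2], 2, 1)
  excl <- applyEvent(t, se, "exclusion", g)
  expect_equal(length(excl$mrna), refLen - 99)
  expect_equal(as.character(applyEvent(t, se, "inclusion", g)$mrna),
               as.character(splicedSequence(t, g)))

  ri <- SpliceEvent("ri", "RI", "geneT", "txT", "chrT", "+",
                    IRanges::IRanges(end(loc$exons)[2] + 1,
                                     start(loc$exons)[3] - 1), 2, 1)
  ret <- applyEvent(t, ri, "inclusion", g)
  expect_equal(length(ret$mrna), refLen + loc$i2len)
  # per-base re-splicing oracle: retained-intron mRNA equals the genomic
  # span from exon1 start with introns 1 and 3 removed
  chr <- as.character(g[[1]])
  oracle <- paste0(substr(chr, 101, 139), substr(chr, 200, 298),
                   substr(chr, 299, 298 + loc$i2len),
                   substr(chr, 299 + loc$i2len, 358 + loc$i2len),
                   substr(chr, 419 + loc$i2len, 496 + loc$i2len))
  expect_equal(as.character(ret$mrna), oracle)

  a5 <- SpliceEvent("a5", "A5SS", "geneT", "txT", "chrT", "+",
                    IRanges::IRanges(end(loc$exons)[2] + 1,
                                     end(loc$exons)[2] + 7), 1, 1)
  long <- applyEvent(t, a5, "inclusion", g)
  expect_equal(length(long$mrna), refLen + 7)
  oracle5 <- paste0(substr(chr, 101, 139), substr(chr, 200, 305),
                    substr(chr, 299 + loc$i2len, 358 + loc$i2len),
                    substr(chr, 419 + loc$i2len, 496 + loc$i2len))
  expect_equal(as.character(long$mrna), oracle5)

  expect_error(applyEvent(t, SpliceEvent("x", "SE", "g", "t", "chrT",
                                         "+", IRanges::IRanges(5, 50),
                                         1, 1), "exclusion", g),
               "does not match an exon")
  expect_error(applyEvent(t, SpliceEvent("x", "SE", "g", "t", "chrT",
                                         "+", loc$exons[1], 1, 1),
                          "exclusion", g), "internal")
})

test_that("each consequence category is called from designed events", {
  loc <- makeToyLocus()
  t <- loc$t; g <- loc$genome
  dom <- data.frame(transcriptId = "txT", startAa = 12L, endAa = 20L,
                    name = "DOM", stringsAsFactors = FALSE)

  # SE exclusion of the in-frame 99 nt exon overlapping the domain
  se <- SpliceEvent("se", "SE", "geneT", "txT", "chrT", "+",
                    loc$exons[2], 2, 1)
  cc <- classifyConsequence(t, se, g, dom)
  expect_equal(cc$category, "domain_loss")
  expect_equal(c(cc$altered_aa_start, cc$altered_aa_end), c(11, 43))
  # same event without a domain in the removed span
  noDom <- classifyConsequence(t, se, g,
                               data.frame(transcriptId = "txT",
                                          startAa = 50L, endAa = 55L,
                                          name = "D"))
  expect_equal(noDom$category, "no_disruption")

  # RI retaining a stop-free in-frame intron: junction codons only
  ri <- SpliceEvent("ri", "RI", "geneT", "txT", "chrT", "+",
                    IRanges::IRanges(end(loc$exons)[2] + 1,
                                     start(loc$exons)[3] - 1), 2, 1)
  ccRi <- classifyConsequence(t, ri, g, dom)
  expect_equal(ccRi$category, "no_disruption")
  domJ <- data.frame(transcriptId = "txT", startAa = 43L, endAa = 44L,
                     name = "J")
  expect_equal(classifyConsequence(t, ri, g, domJ)$category,
               "domain_loss")

  # RI with an in-frame premature stop
  locStop <- makeToyLocus(intron2 = paste0("TAA", strrep("GCT", 19)))
  riS <- SpliceEvent("ris", "RI", "geneT", "txT", "chrT", "+",
                     IRanges::IRanges(end(locStop$exons)[2] + 1,
                                      start(locStop$exons)[3] - 1), 2, 1)
  ccS <- classifyConsequence(locStop$t, riS, locStop$genome, dom)
  expect_equal(ccS$category, "premature_stop")
  expect_equal(ccS$new_stop_aa, 44)  # stop right after exon 2's 43 codons

  # A5SS extension by 7 nt breaks the frame
  a5 <- SpliceEvent("a5", "A5SS", "geneT", "txT", "chrT", "+",
                    IRanges::IRanges(end(loc$exons)[2] + 1,
                                     end(loc$exons)[2] + 7), 1, 1)
  expect_equal(classifyConsequence(t, a5, g, dom)$category, "frameshift")

  # exon skipping of a 100 nt fully coding exon is a frameshift
  fsSe <- character(0)
  for (sd in 1:10) {
    sim <- simulateGenomeAnnotation(seed = sd, nGenes = 40)
    fsSe <- sim$truth$event_id[sim$truth$category == "frameshift" &
                                 sim$truth$type == "SE"]
    if (length(fsSe) > 0) break
  }
  expect_gt(length(fsSe), 0)
  ev <- Filter(function(e) e@eventId == fsSe[1], sim$events)[[1]]
  expect_equal(IRanges::width(ev@altRegion), 100)
  cc100 <- classifyConsequence(sim$transcripts[[ev@transcriptId]], ev,
                               sim$genome, NULL)
  expect_equal(cc100$category, "frameshift")
})

test_that("UTR-confined events are noncoding regardless of domains", {
  sim <- simulateGenomeAnnotation(seed = 5, nGenes = 40)
  ncIds <- sim$truth$event_id[sim$truth$category == "noncoding_region"]
  expect_gt(length(ncIds), 0)
  calls <- classifyConsequences(sim$transcripts, sim$events, sim$genome,
                                sim$domains)
  expect_true(all(calls$category[calls$event_id %in% ncIds] ==
                    "noncoding_region"))
  expect_false(any(calls$damaging[calls$event_id %in% ncIds]))
})

test_that("classifier agrees 100% with construction truth on both strands", {
  sim <- simulateGenomeAnnotation(seed = 19, nGenes = 50,
                                  eventsPerGene = 2)
  strands <- vapply(sim$transcripts, function(t) t@strand, "")
  expect_setequal(unique(strands), c("+", "-"))
  calls <- classifyConsequences(sim$transcripts, sim$events, sim$genome,
                                sim$domains)
  cmp <- merge(calls, sim$truth, by = "event_id")
  expect_equal(nrow(cmp), length(sim$events))
  expect_identical(cmp$category.x, cmp$category.y)
  # frameshift calls always correspond to a net coding change not
  # divisible by 3 (here by construction: 100, 61, 7 or 1 nt)
  fs <- cmp$event_id[cmp$category.x == "frameshift"]
  expect_true(length(fs) > 0)
})

test_that("damage proportion counts damaging categories over qualifying events", {
  calls <- data.frame(event_id = paste0("e", 1:10),
                      alt_form = "exclusion",
                      category = c(rep("frameshift", 2), "premature_stop",
                                   rep("no_disruption", 7)),
                      stringsAsFactors = FALSE)
  calls$damaging <- calls$category %in%
    c("frameshift", "premature_stop", "domain_loss")
  rec <- data.frame(event_id = paste0("e", 1:10),
                    selected = rep(TRUE, 10))
  d <- splicingDamage(calls, records = rec, mode = "differential")
  expect_equal(d$proportion, 0.3)
  # invariant to event ordering
  perm <- sample(nrow(rec))
  d2 <- splicingDamage(calls[perm, ], records = rec[rev(perm), ],
                       mode = "differential")
  expect_equal(d2$proportion, d$proportion)

  none <- rec; none$selected <- FALSE
  expect_error(splicingDamage(calls, records = none,
                              mode = "differential"), "undefined")
})

test_that("standing damage counts present damaging isoforms per sample", {
  calls <- data.frame(event_id = c("inc", "exc", "nd"),
                      alt_form = c("inclusion", "exclusion", "inclusion"),
                      damaging = c(TRUE, TRUE, FALSE))
  psi <- rbind(inc = c(0.5, 0.5), exc = c(0.95, 0.2),
               nd = c(0.5, 0.5))
  colnames(psi) <- c("s1", "s2")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(psi = psi, coverage = psi * 0 + 100))
  d <- splicingDamage(calls, psi = se, mode = "standing",
                      presenceThreshold = 0.1)
  # s1: inclusion-form damaging event at 0.5 counts; exclusion-form event
  # has damaging psi 1-0.95 = 0.05 < 0.1, absent
  expect_equal(d$proportion[d$sample == "s1"], 1 / 3)
  # s2: the exclusion-form damaging isoform rises to 0.8, now present
  expect_equal(d$proportion[d$sample == "s2"], 2 / 3)
})
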