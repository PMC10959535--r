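test_that("Psi follows the length-normalized inclusion ratio", {
  expect_equal(computePsi(7, 7, 1, 1), 0.5)
  expect_equal(computePsi(0, 12, 3, 7), 0)
  expect_equal(computePsi(18, 6, 2, 1), 9 / (9 + 6))
  expect_true(is.na(computePsi(4, 4, 1, 1, minCoverage = 10)))
  expect_true(is.na(computePsi(0, 0, 1, 1, minCoverage = 0)))
  expect_error(computePsi(-1, 2, 1, 1), "non-negative")
  expect_error(computePsi(1, 2, 0, 1), "positive")

  # monotone increasing in I, decreasing in S at fixed lengths
  iSeq <- computePsi(0:50, 20, 2, 1, minCoverage = 0)
  expect_true(all(diff(iSeq[-1]) > 0))
  sSeq <- computePsi(20, 0:50, 2, 1, minCoverage = 0)
  expect_true(all(diff(sSeq) < 0))
})

test_that("simulated binomial counts concentrate around the true Psi", {
  ev <- SpliceEvent("e1", "SE", "g", "t", "chr1", "+",
                    IRanges::IRanges(10, 29), 1, 1)
  sim <- simulateSplicingCounts(list(ev), psiControl = 0.6, delta = 0,
                                nReps = 200, depth = 500, seed = 4)
  psi <- computePsi(sim$counts$inclusion_count,
                    sim$counts$skipping_count, 1, 1)
  mcSe <- sd(psi) / sqrt(length(psi))
  expect_lt(abs(mean(psi) - 0.6), 3 * mcSe)

  z <- simulateSplicingCounts(list(ev), 0, 0, nReps = 3, depth = 100,
                              seed = 1)
  expect_true(all(z$counts$inclusion_count == 0))
  o <- simulateSplicingCounts(list(ev), 1, 0, nReps = 3, depth = 100,
                              seed = 1)
  expect_true(all(o$counts$skipping_count == 0))
})

test_that("differential splicing tests replicate Psi with BH selection", {
  mkCounts <- function(psiA, psiB, depth = 100) {
    rows <- list()
    for (i in seq_along(psiA))
      rows[[i]] <- data.frame(
        event_id = "ev1", type = "SE",
        sample = c(paste0("c", i), paste0("t", i)),
        inclusion_count = round(depth * c(psiA[i], psiB[i])),
        skipping_count = depth - round(depth * c(psiA[i], psiB[i])),
        len_inclusion = 1, len_skipping = 1)
    do.call(rbind, rows)
  }
  cnt <- mkCounts(c(0.2, 0.3, 0.4), c(0.6, 0.7, 0.8))
  pm <- psiMatrix(cnt, minCoverage = 10)
  groups <- ifelse(grepl("^c", colnames(pm)), "control", "treated")
  ds <- differentialSplicing(pm, groups)
  expect_equal(ds$delta_psi, 0.4, tolerance = 1e-12)
  expect_equal(ds$p_value, 0.008049893, tolerance = 1e-5)

  # identical Psi vectors: delta 0, never selected
  same <- mkCounts(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  ds2 <- differentialSplicing(psiMatrix(same, 10),
                              c("control", "treated")[
                                1 + grepl("^t", colnames(psiMatrix(same)))])
  expect_equal(ds2$delta_psi, 0)
  expect_false(ds2$selected)
})

test_that("events missing a group are untested and leave the BH family", {
  psi <- rbind(ev_ok = c(0.1, 0.2, 0.8, 0.9),
               ev_miss = c(NA, NA, 0.5, 0.6),
               ev_ok2 = c(0.4, 0.5, 0.5, 0.6))
  colnames(psi) <- c("c1", "c2", "t1", "t2")
  ds <- differentialSplicing(psi, c("control", "control",
                                    "treated", "treated"))
  expect_false(ds$tested[ds$event_id == "ev_miss"])
  expect_true(is.na(ds$fdr[ds$event_id == "ev_miss"]))
  tested <- ds[ds$tested, ]
  expect_equal(tested$fdr, bhAdjust(tested$p_value))  # family of 2 only
  expect_error(differentialSplicing(psi, rep("onlygroup", 4)),
               "two groups")
})

test_that("p-value selection mode reproduces the alternative cutoff rule", {
  withr::with_seed(31, {
    psi <- matrix(runif(40 * 8), 40, 8,
                  dimnames = list(paste0("e", 1:40), paste0("s", 1:8)))
    groups <- rep(c("control", "treated"), each = 4)
    byF <- differentialSplicing(psi, groups, selectBy = "fdr")
    byP <- differentialSplicing(psi, groups, selectBy = "pvalue")
    expect_identical(byP$selected,
                     byP$tested & byP$p_value < 0.05 &
                       abs(byP$delta_psi) > 0.1)
    expect_true(all(byF$selected | !byF$selected))  # no NA
    expect_true(sum(byP$selected) >= sum(byF$selected))
  })
})

test_that("direction summary tallies selected events per type", {
  rec <- data.frame(
    event_id = paste0("e", 1:8),
    type = c(rep("RI", 5), rep("SE", 3)),
    delta_psi = c(-0.2, -0.3, -0.15, 0.12, -0.5, 0.3, -0.2, 0.4),
    selected = c(rep(TRUE, 5), TRUE, TRUE, FALSE))
  ds <- directionSummary(rec)
  expect_equal(ds$n_positive[ds$type == "RI"], 1)
  expect_equal(ds$n_negative[ds$type == "RI"], 4)
  expect_equal(ds$n_positive[ds$type == "SE"], 1)
  expect_equal(ds$n_negative[ds$type == "SE"], 1)
  expect_equal(sum(ds$n_positive + ds$n_negative), sum(rec$selected))

  none <- rec; none$selected <- FALSE
  dn <- directionSummary(none)
  expect_true(all(dn$n_positive == 0 & dn$n_negative == 0))

  # brute-force tally oracle on random records
  withr::with_seed(17, {
    rr <- data.frame(event_id = paste0("x", 1:60),
                     type = sample(c("SE", "RI", "MXE"), 60, TRUE),
                     delta_psi = runif(60, -1, 1),
                     selected = sample(c(TRUE, FALSE), 60, TRUE))
    dr <- directionSummary(rr)
    for (tp in dr$type) {
      expect_equal(dr$n_positive[dr$type == tp],
                   sum(rr$selected & rr$type == tp & rr$delta_psi > 0))
      expect_equal(dr$n_negative[dr$type == tp],
                   sum(rr$selected & rr$type == tp & rr$delta_psi < 0))
    }
  })
})

test_that("event tables round-trip through the TSV dialect", {
  sim <- simulateGenomeAnnotation(seed = 2, nGenes = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEvents(sim$events, f)
  back <- readEvents(f)
  expect_equal(length(back), length(sim$events))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]@eventId, sim$events[[i]]@eventId)
    expect_equal(start(back[[i]]@altRegion),
                 start(sim$events[[i]]@altRegion))
    expect_equal(altForm(back[[i]]), altForm(sim$events[[i]]))
  }
})
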