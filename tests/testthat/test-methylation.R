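test_that("probe filtering removes missing and poorly detected probes", {
  beta <- matrix(0.5, 4, 3,
                 dimnames = list(paste0("cg", 1:4), paste0("s", 1:3)))
  det <- matrix(0.001, 4, 3, dimnames = dimnames(beta))
  beta["cg2", 2] <- NA
  det["cg3", 1] <- 0.02
  f <- filterProbes(beta, det)
  expect_setequal(rownames(f), c("cg1", "cg4"))
  expect_error(filterProbes(beta, det[1:3, ]), "misaligned")

  withr::with_seed(6, {
    b <- matrix(runif(200 * 4), 200, 4,
                dimnames = list(paste0("p", 1:200), NULL))
    d <- matrix(runif(200 * 4, 0, 0.03), 200, 4, dimnames = dimnames(b))
    b[sample(length(b), 10)] <- NA
    kept <- rownames(filterProbes(b, d))
    oracle <- rownames(b)[vapply(seq_len(nrow(b)), function(i)
      !anyNA(b[i, ]) && all(d[i, ] <= 0.01), TRUE)]
    expect_identical(kept, oracle)
  })
})

test_that("beta to M conversion is the clamped logit", {
  expect_equal(betaToM(0.5), 0)
  expect_equal(betaToM(0.8), 2)
  eps <- 1e-6
  expect_equal(betaToM(1), log2((1 - eps) / eps))
  expect_true(is.finite(betaToM(0)))
  expect_error(betaToM(1.2), "\\[0, 1\\]")
  b <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(betaToM(b)) > 0))            # strictly increasing
  expect_equal(betaToM(b), -betaToM(1 - b))         # antisymmetric at 0.5
  expect_equal(mToBeta(betaToM(b)), b, tolerance = 1e-12)
})

test_that("differential methylation applies the joint lfc/FDR rule", {
  withr::with_seed(30, {
    sim <- simulateMethylation(nProbes = 600, fracDmp = 0.05,
                               deltaM = 2, nPerGroup = 5, seed = 18)
    M <- betaToM(sim$beta)
    dm <- differentialMethylation(M, sim$groups)
    truth <- sim$truth$probe[sim$truth$is_dmp]
    hits <- dm$probe[dm$selected]
    expect_gte(sum(truth %in% hits) / length(truth), 0.9)   # recall
    fp <- sum(!hits %in% truth)
    expect_lte(fp, qbinom(0.995, length(hits), 0.05) + 1)
    # hypomethylation simulated: selected DMPs are hypo-directed
    expect_true(all(dm$direction[dm$selected] == "hypo"))
    expect_identical(dm$selected,
                     abs(dm$lfcM) > 1 & dm$fdr < 0.05)
  })
  flat <- matrix(c(1, 1, 1, 1), 1, 4,
                 dimnames = list("cg1", paste0("s", 1:4)))
  dm0 <- differentialMethylation(flat, rep(c("a", "b"), each = 2))
  expect_equal(dm0$lfcM, 0)
  expect_false(dm0$selected)
})

test_that("mean methylation is the per-sample column mean", {
  b <- matrix(c(0, 1, 0.5, 0.5), 2, 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  expect_equal(unname(meanMethylation(b)), c(0.5, 0.5))
  withr::with_seed(2, {
    r <- matrix(runif(50 * 4), 50, 4,
                dimnames = list(paste0("p", 1:50), paste0("s", 1:4)))
    expect_equal(meanMethylation(r), colMeans(r))
  })
  expect_error(meanMethylation(matrix(numeric(0), 0, 2)), "empty")
})

test_that("state enrichment reproduces the worked 2x2 example", {
  universe <- paste0("p", 1:20)
  stateMap <- data.frame(probe = universe,
                         state = rep(c("inState", "other"), each = 10))
  # 6 selected hypo DMPs, 5 of them inside the 10-probe state
  dmps <- data.frame(probe = c(paste0("p", 1:5), "p11", "p12"),
                     direction = "hypo",
                     selected = c(rep(TRUE, 6), FALSE))
  en <- chromatinStateEnrichment(dmps, universe, stateMap)
  row <- en[en$state == "inState" & en$direction == "hypo", ]
  expect_equal(row$overlap, 5)
  expect_equal(row$odds_ratio, (5 * 9) / (1 * 5))
  expect_equal(row$p_value, 0.07043344, tolerance = 1e-6)
  expect_gt(row$signed_log10_adj_p, 0)
  # 2x2 cells always sum to the universe
  expect_true(all(en$n_state + (20 - en$n_state) == 20))
  other <- en[en$state == "other" & en$direction == "hypo", ]
  expect_lt(other$odds_ratio, 1)
  expect_lt(other$signed_log10_adj_p, 0)
  expect_error(chromatinStateEnrichment(
    data.frame(probe = "zz", direction = "hypo", selected = TRUE),
    universe, stateMap), "outside")
})

test_that("state enrichment recovers the designed target state", {
  withr::with_seed(77, {
    ok <- 0
    for (rep in 1:20) {
      sim <- simulateMethylation(nProbes = 500, fracDmp = 0.06,
                                 deltaM = 2.5, nPerGroup = 5,
                                 targetState = "enhancer",
                                 seed = 500 + rep)
      dm <- differentialMethylation(betaToM(sim$beta), sim$groups)
      en <- chromatinStateEnrichment(dm, rownames(sim$beta),
                                     sim$stateMap)
      hit <- en[en$state == "enhancer" & en$direction == "hypo", ]
      if (hit$odds_ratio > 1 && hit$signed_log10_adj_p > 0) ok <- ok + 1
    }
    expect_gte(ok, 19)
  })
})

test_that("permuted DMP labels yield near-nominal enrichment rates", {
  withr::with_seed(13, {
    sig <- 0; total <- 0
    for (rep in 1:10) {
      universe <- paste0("p", 1:400)
      stateMap <- data.frame(probe = universe,
                             state = sample(paste0("st", 1:5), 400,
                                            replace = TRUE))
      dmps <- data.frame(probe = sample(universe, 30),
                         direction = sample(c("hyper", "hypo"), 30,
                                            replace = TRUE),
                         selected = TRUE)
      en <- chromatinStateEnrichment(dmps, universe, stateMap)
      sig <- sig + sum(en$adj_p < 0.05)
      total <- total + nrow(en)
    }
    expect_lte(sig, qbinom(0.995, total, 0.05) + 1)
  })
})

test_that("state maps accept the two documented layouts", {
  tsv <- writeTempTsv(data.frame(probe = c("a", "b"),
                                 state = c("s1", "s2")))
  expect_equal(readStateMap(tsv)$state, c("s1", "s2"))
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("a\t0\t1\tenhancer", "b\t0\t1\tpromoter"), bed)
  expect_equal(readStateMap(bed)$state, c("enhancer", "promoter"))
})
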