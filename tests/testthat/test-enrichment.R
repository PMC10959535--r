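test_that("the ranking metric is signed -log10(p)", {
  expect_equal(rankingMetric(0.001, 2), 3)
  expect_equal(rankingMetric(0.5, 0), 0)
  expect_equal(rankingMetric(0.05, -1), -1.30103, tolerance = 1e-5)
  expect_equal(rankingMetric(1e-320, 1), 300)  # floored before log
  expect_error(rankingMetric(0, 1), "\\(0, 1\\]")
  r <- rankedList(data.frame(gene = c("b", "a", "c"),
                             lfc = c(1, 1, -2), pv = c(0.01, 0.01, 0.5)))
  expect_identical(names(r), c("a", "b", "c"))  # tie broken by gene id
  expect_true(all(diff(unname(r)) <= 0))
})

test_that("signatures take the largest |lfc| among significant genes", {
  de <- data.frame(gene = paste0("g", 1:6),
                   lfc = c(3, -2.5, 2, 1, -4, 0.5),
                   fdr = c(0.01, 0.01, 0.01, 0.2, 0.001, 0.04))
  s <- buildSignature(de, n = 3, name = "sig")
  expect_setequal(s$sig, c("g5", "g1", "g2"))
  all3 <- buildSignature(de, n = 500)
  expect_setequal(all3$signature, c("g1", "g2", "g3", "g5", "g6"))
  sp <- buildSignature(de, n = 3, split = TRUE, name = "s")
  expect_setequal(sp$s_up, c("g1"))
  expect_setequal(sp$s_down, c("g5", "g2"))
  expect_warning(e <- buildSignature(data.frame(gene = "g", lfc = 1,
                                                fdr = 0.9)),
                 "no significant")
  expect_length(e$signature, 0)

  # sort oracle: every member's |lfc| >= every excluded significant gene
  withr::with_seed(3, {
    big <- data.frame(gene = sprintf("g%04d", 1:1000),
                      lfc = rnorm(1000, 0, 2),
                      fdr = runif(1000, 0, 0.049))
    s5 <- buildSignature(big, n = 500)$signature
    expect_length(s5, 500)
    sig <- big[big$fdr < 0.05, ]
    excluded <- setdiff(sig$gene, s5)
    expect_gte(min(abs(sig$lfc[sig$gene %in% s5])),
               max(abs(sig$lfc[sig$gene %in% excluded])))
  })
})

test_that("the enrichment score equals brute-force running sums", {
  withr::with_seed(8, {
    for (rep in 1:20) {
      N <- sample(10:50, 1)
      metric <- sort(rnorm(N), decreasing = TRUE)
      names(metric) <- sprintf("g%02d", seq_len(N))
      set <- sample(names(metric), sample(3:(N %/% 2), 1))
      es <- rejuvomics:::enrichmentScore(metric, names(metric) %in% set)
      expect_equal(es, oracleES(metric, set), tolerance = 1e-12)
      # weight 0: classic unweighted (KS-style) statistic
      es0 <- rejuvomics:::enrichmentScore(metric, names(metric) %in% set,
                                          weight = 0)
      expect_equal(es0, oracleES(metric, set, weight = 0),
                   tolerance = 1e-12)
      # scale invariance of the running sum at weight 1
      es2 <- rejuvomics:::enrichmentScore(metric * 7.3,
                                          names(metric) %in% set)
      expect_equal(es2, es, tolerance = 1e-12)
      # negating metrics and reversing the list negates the ES
      rev <- -metric[rev(seq_len(N))]
      esR <- rejuvomics:::enrichmentScore(rev, names(rev) %in% set)
      expect_equal(esR, -es, tolerance = 1e-12)
    }
  })
  # a set occupying the top ranks with positive metrics scores ES = 1
  m <- setNames(seq(5, 1), paste0("g", 1:5))
  expect_equal(rejuvomics:::enrichmentScore(m, c(TRUE, TRUE, rep(FALSE, 3))),
               1)
})

test_that("the enrichment score matches the fgsea reference statistic", {
  skip_if_not_installed("fgsea")
  withr::with_seed(15, for (rep in 1:10) {
    N <- 40
    metric <- sort(rnorm(N), decreasing = TRUE)
    names(metric) <- sprintf("g%02d", seq_len(N))
    idx <- sort(sample(N, 8))
    es <- rejuvomics:::enrichmentScore(metric, seq_len(N) %in% idx)
    ref <- fgsea::calcGseaStat(metric, idx, gseaParam = 1,
                               scoreType = "std")
    expect_equal(es, ref, tolerance = 1e-12)
  })
})

test_that("permutation p-values are seed-reproducible and seed-stable", {
  withr::with_seed(91, {
    de <- data.frame(gene = sprintf("g%03d", 1:200),
                     lfc = rnorm(200), pv = runif(200))
  })
  ranked <- rankedList(de)
  sets <- list(top = names(ranked)[1:12],
               rand = sample(names(ranked), 15))
  r1 <- gseaPreranked(ranked, sets, nPerm = 500, seed = 7)
  r2 <- gseaPreranked(ranked, sets, nPerm = 500, seed = 7)
  expect_identical(r1, r2)  # bit-exact under a fixed seed
  expect_true(all(sign(r1$nes) == sign(r1$es)))
  expect_true(all(r1$fdr >= 0 & r1$fdr <= 1))

  # across seeds, p varies within Monte-Carlo error; only same-sign null
  # scores enter the p-value, so the effective sample is about nPerm/2
  ps <- vapply(1:6, function(s)
    gseaPreranked(ranked, sets["rand"], nPerm = 500, seed = s)$p_value, 1)
  p0 <- mean(ps)
  mcSe <- sqrt(p0 * (1 - p0) / 250)
  expect_true(all(abs(ps - p0) < 3 * mcSe + 1e-3))

  # self-enrichment of the top of the list is strongly positive
  expect_gt(r1$nes[r1$set == "top"], 1.5)
  expect_lt(r1$fdr[r1$set == "top"], 0.1)

  # disjoint sets produce an error record, not a failure
  r3 <- gseaPreranked(ranked, list(gone = c("zz1", "zz2")), nPerm = 100,
                      seed = 1)
  expect_match(r3$error, "disjoint")
  expect_true(is.na(r3$es))
})

test_that("signature association recovers injected directions", {
  withr::with_seed(33, {
    nOk <- 0
    for (rep in 1:20) {
      de <- data.frame(gene = sprintf("g%03d", 1:150),
                       lfc = rnorm(150, 0, 0.3), pv = runif(150))
      up <- sample(de$gene, 15)
      de$lfc[de$gene %in% up] <- abs(rnorm(15, 2, 0.3))
      de$pv[de$gene %in% up] <- runif(15, 0, 0.01)
      res <- signatureAssociation(list(cond = de), list(aging_up = up),
                                  nPerm = 200, seed = rep)
      if (res$nes > 0) nOk <- nOk + 1
    }
    expect_gte(nOk, 19)  # >= 95% direction recovery
  })
})

test_that("signature correlation uses the union of top low-p genes", {
  withr::with_seed(27, {
    de <- data.frame(gene = sprintf("g%03d", 1:300),
                     lfc = rnorm(300), pv = runif(300))
    expect_equal(signatureCorrelation(de, de, n = 100)$rho, 1)
    neg <- de; neg$lfc <- -neg$lfc
    expect_equal(signatureCorrelation(de, neg, n = 100)$rho, -1)

    other <- data.frame(gene = de$gene, lfc = rnorm(300),
                        pv = runif(300))
    got <- signatureCorrelation(de, other, n = 80)
    topA <- de$gene[order(de$pv, de$gene)][1:80]
    topB <- other$gene[order(other$pv, other$gene)][1:80]
    un <- union(topA, topB)
    expect_equal(got$n_union, length(un))
    expect_equal(got$rho,
                 cor(de$lfc[match(un, de$gene)],
                     other$lfc[match(un, other$gene)],
                     method = "spearman"), tolerance = 1e-12)
  })
  expect_error(signatureCorrelation(
    data.frame(gene = "a", lfc = 1, pv = 0.5),
    data.frame(gene = "a", lfc = 1, pv = 0.5)), "smaller than 3")
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g2"))
  f <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(sets, f)
  expect_equal(readGmt(f), sets)
  writeLines("badline\tonly2", f)
  expect_error(readGmt(f), "line 1")
})
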