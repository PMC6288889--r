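test_that("ratio differences follow the share-denominator arithmetic", {
  ## CRS stratum: 5 instances expressed in E1, 20 expression events across
  ## the other experiments; non-CRS stratum: 3 and 13
  crsM <- rbind(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
                c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
                c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  nonM <- rbind(matrix(TRUE, 2, 6),
                matrix(c(TRUE, rep(FALSE, 5)), 1, 6),
                matrix(FALSE, 1, 6))
  m <- rbind(crsM, nonM)
  colnames(m) <- sprintf("E%d", 1:6)
  rownames(m) <- sprintf("i%d", 1:9)
  hc <- c(rep(TRUE, 5), rep(FALSE, 4))
  rd <- ratioDifference(m, hc, "E1")
  expect_equal(rd$r_crs, 5 / sum(crsM[, -1]))
  expect_equal(rd$r_notcrs, 3 / sum(nonM[, -1]))
  expect_equal(rd$r_d, rd$r_crs - rd$r_notcrs)
  ## identical strata give a zero difference
  same <- ratioDifference(rbind(crsM, crsM),
                          rep(c(TRUE, FALSE), each = 5), 1)
  expect_equal(same$r_d, 0)
  ## the any-other reading counts instances, not events
  alt <- ratioDifference(m, hc, "E1", denominator = "any_other")
  expect_equal(alt$r_crs, 5 / 5)   # all CRS instances on somewhere else
  ## zero denominator is flagged undefined
  silent <- matrix(c(TRUE, rep(FALSE, 5)), 1, 6)
  colnames(silent) <- sprintf("E%d", 1:6)
  und <- ratioDifference(rbind(silent, nonM), c(TRUE, rep(FALSE, nrow(nonM))), 1)
  expect_true(is.na(und$r_crs))
  expect_true(is.na(und$r_d))
})

test_that("stage enrichment tests direction, family and Bonferroni", {
  set.seed(43)
  nExp <- 12
  ## CRS instances concentrated in experiments 1-3, non-CRS flat
  crsM <- matrix(FALSE, 20, nExp)
  crsM[, 1:3] <- runif(60) < 0.9
  crsM[, 4:nExp] <- runif(20 * 9) < 0.1
  nonM <- matrix(runif(60 * nExp) < 0.3, 60, nExp)
  colnames(crsM) <- colnames(nonM) <- sprintf("E%02d", seq_len(nExp))
  mat <- rbind(crsM, nonM)
  rownames(mat) <- sprintf("i%d", seq_len(nrow(mat)))
  hasCrs <- rep(c(TRUE, FALSE), c(20, 60))
  out <- stageEnrichment(list(intron = list(mat = mat, has_crs = hasCrs)),
                         method = "location")
  expect_equal(nrow(out), nExp)
  expect_equal(out$test, rep("wilcoxon", nExp))
  ## alternative follows the sign of the ratio difference
  expect_true(all(out$alternative[out$r_d > 0] == "less"))
  expect_true(all(out$alternative[out$r_d < 0] == "greater"))
  ## Bonferroni is raw p times the number of performed tests, capped
  done <- !is.na(out$p)
  expect_equal(out$p_adj[done], pmin(1, out$p[done] * sum(done)))
  ## the planted stage shows the strongest enrichment signal
  expect_true(all(order(out$p)[1:3] %in% 1:3))
  ## the t-test family is selected by biotype name
  outT <- stageEnrichment(list(coding_exon = list(mat = mat,
                                                  has_crs = hasCrs)),
                          method = "location")
  expect_equal(unique(outT$test), "t")
  ## the default prediction method detects the same planted stages
  outP <- stageEnrichment(list(intron = list(mat = mat, has_crs = hasCrs)))
  expect_equal(unique(outP$test), "t_prediction")
  expect_true(all(order(outP$p)[1:3] %in% 1:3))
  ## with the CRS ratio at the sample mean the prediction p is one half
  flat <- matrix(rep(c(TRUE, FALSE), 30), 10, 6)
  colnames(flat) <- sprintf("E%d", 1:6)
  symm <- stageEnrichment(list(intron = list(
    mat = rbind(flat, flat), has_crs = rep(c(TRUE, FALSE), each = 10))))
  expect_true(all(abs(symm$p[!is.na(symm$p) & symm$test != "sign"] - 0.5)
                  < 0.2))
  ## constant non-CRS ratios under the t-test fall back to the sign test
  ## (uniform expression makes every per-experiment share identical)
  constM <- rbind(crsM, matrix(TRUE, 30, nExp))
  colnames(constM) <- colnames(crsM)
  outS <- stageEnrichment(list(utr5_exon = list(
    mat = constM, has_crs = rep(c(TRUE, FALSE), c(20, 30)))),
    method = "location")
  expect_true(all(outS$test[!is.na(outS$p)] == "sign"))
})

test_that("stratified window sampling matches per-bin prediction counts", {
  interg <- gr("c", c(1, 20001), c(15000, 40000))
  set.seed(3)
  blocks <- gr("c", seq(1, 39000, by = 400), seq(300, 39299, by = 400),
               gc = runif(98), identity = runif(98))
  grid <- new("BinGrid", gcEdges = c(0, 0.5, 1),
              identityEdges = c(0, 0.5, 1))
  counts <- matrix(c(10L, 0L, 3L, 5L), 2)
  win <- sampleIntergenicWindows(interg, blocks, grid, counts, seed = 9)
  got <- table(factor(win$gc_bin, 1:2), factor(win$id_bin, 1:2))
  expect_equal(as.integer(got), as.integer(counts))
  ## deterministic under the seed
  win2 <- sampleIntergenicWindows(interg, blocks, grid, counts, seed = 9)
  expect_identical(GenomicRanges::start(win), GenomicRanges::start(win2))
  ## a bin with too few windows yields everything it has, with a warning
  big <- matrix(c(10000L, 0L, 0L, 0L), 2)
  expect_warning(all <- sampleIntergenicWindows(interg, blocks, grid, big,
                                                seed = 9),
                 "only")
})

test_that("differential-expression scores combine Hamming distances as
          specified", {
  ## all structured instances flip between the experiments, none of the
  ## unstructured ones: maximal score
  crsM <- cbind(A = c(TRUE, TRUE), B = c(FALSE, FALSE))
  nonM <- cbind(A = c(TRUE, FALSE), B = c(TRUE, FALSE))
  expect_equal(diffExpressionScore(crsM, nonM, "A", "B"), 1)
  ## 0.5 x |0.5 - 0.2|
  crs2 <- cbind(A = c(TRUE, TRUE, FALSE, FALSE),
                B = c(FALSE, TRUE, FALSE, TRUE))
  non2 <- cbind(A = rep(TRUE, 5), B = c(FALSE, rep(TRUE, 4)))
  expect_equal(diffExpressionScore(crs2, non2, "A", "B"), 0.5 * 0.3)
  ## identical experiments give zero
  expect_equal(diffExpressionScore(crs2, non2, "A", "A"), 0)
  ## empty stratum is flagged
  expect_warning(na <- diffExpressionScore(crs2[0, , drop = FALSE], non2,
                                           "A", "B"),
                 "empty")
  expect_true(is.na(na))
})

test_that("E_diff matrices are symmetric, zero-diagonal and bounded", {
  set.seed(47)
  for (rep in 1:5) {
    nExp <- sample(4:10, 1)
    crsM <- matrix(runif(12 * nExp) < 0.4, 12, nExp)
    nonM <- matrix(runif(30 * nExp) < 0.4, 30, nExp)
    colnames(crsM) <- colnames(nonM) <- sprintf("E%d", seq_len(nExp))
    m <- diffExpressionMatrix(crsM, nonM)
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("independently expressed introns split into the two tiers", {
  introns <- data.frame(intron_id = c("I1", "I2", "I3"),
                        gene_id = c("G1", "G2", "G3"),
                        left_exon = c("X1", "X3", NA),
                        right_exon = c("X2", "X4", "X6"))
  exonIds <- c("X1", "X2", "X3", "X4", "X5", "X6")
  exonMat <- matrix(FALSE, 6, 2, dimnames = list(exonIds, c("EA", "EB")))
  ## G1 has a distal expressed exon X5; G2's flanks are silent and no
  ## other exon either; G3's only known flank X6 is silent
  exonMat["X5", "EA"] <- TRUE
  intronMat <- matrix(TRUE, 3, 2,
                      dimnames = list(introns$intron_id, c("EA", "EB")))
  geneExons <- list(G1 = c("X1", "X2", "X5"), G2 = c("X3", "X4"),
                    G3 = c("X6"))
  out <- findIndependentIntrons(introns, intronMat, exonMat, geneExons,
                                "EA")
  ## I1: flanks silent but X5 expressed -> tier 1 only
  expect_true(out$tier1[out$intron_id == "I1"])
  expect_false(out$tier2[out$intron_id == "I1"])
  ## I2: nothing expressed anywhere in the gene -> both tiers
  expect_true(out$tier1[out$intron_id == "I2"])
  expect_true(out$tier2[out$intron_id == "I2"])
  ## I3: evaluated on the available flank, flagged as edge case
  expect_true(out$edge[out$intron_id == "I3"])
  expect_true(out$tier1[out$intron_id == "I3"])
  ## co-expressed intron and flanks: neither tier
  exonMat2 <- exonMat; exonMat2[c("X1", "X2"), "EA"] <- TRUE
  out2 <- findIndependentIntrons(introns, intronMat, exonMat2, geneExons,
                                 "EA")
  expect_false(out2$tier1[out2$intron_id == "I1"])
})
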