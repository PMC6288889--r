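test_that("generators are deterministic under a fixed seed", {
  cfg <- simulationConfig(seed = 11)
  g1 <- simulateGenome(cfg)
  g2 <- simulateGenome(cfg)
  expect_identical(g1$geneModels, g2$geneModels)
  expect_identical(g1$ncrna, g2$ncrna)
  expect_identical(g1$repeats, g2$repeats)
  b1 <- simulateBlocksAndMotifs(cfg, g1)
  b2 <- simulateBlocksAndMotifs(cfg, g2)
  expect_identical(b1$native, b2$native)
  expect_identical(b1$shuffled, b2$shuffled)
  ## a different seed changes the stream
  g3 <- simulateGenome(simulationConfig(seed = 12))
  expect_false(identical(GenomicRanges::start(g1$genes),
                         GenomicRanges::start(g3$genes)))
})

test_that("simulated genome respects structural targets", {
  cfg <- simulationConfig(seed = 4)
  g <- simulateGenome(cfg)
  expect_equal(length(g$genes), cfg$genome$n_genes)
  ## genes do not overlap
  expect_true(IRanges::isDisjoint(BiocGenerics::unstrand(g$genes)))
  ## repeats cover about the configured fraction
  repFrac <- sum(GenomicRanges::width(g$repeats)) /
    sum(as.numeric(g$seqlengths))
  expect_gt(repFrac, cfg$genome$repeat_fraction * 0.9)
  expect_lt(repFrac, cfg$genome$repeat_fraction * 1.5)
  ## the fraction of UTR-exon nt covered by ncRNA features is near target
  u <- crscreen:::.utrParts(g$geneModels)
  utr <- mergeTrack(c(u$utr5, u$utr3))
  covered <- sum(GenomicRanges::width(GenomicRanges::intersect(
    utr, mergeTrack(g$ncrna), ignore.strand = TRUE)))
  frac <- covered / sum(GenomicRanges::width(utr))
  expect_gt(frac, cfg$genome$utr_ncrna_overlap_frac - 0.02)
  expect_lt(frac, cfg$genome$utr_ncrna_overlap_frac + 0.02)
  ## infeasible packing is a config error
  tiny <- simulationConfig(seed = 1, genome = list(chrom_length = 20000L))
  expect_error(simulateGenome(tiny), class = "crsConfigError")
  ## a gene-free genome unifies to pure intergenic sequence
  none <- simulationConfig(seed = 1,
                           genome = list(n_genes = 2L, n_ncrna = 0L,
                                         utr_ncrna_overlap_frac = 0))
  gn <- simulateGenome(none)
  expect_equal(length(gn$ncrna), 0L)
})

test_that("block and motif sets follow the screen's input contract", {
  cfg <- simulationConfig(seed = 8)
  g <- simulateGenome(cfg)
  bm <- simulateBlocksAndMotifs(cfg, g)
  ## GC and identity distributions land in the configured mass ranges
  expect_gt(mean(bm$blocks$gc > 0.3 & bm$blocks$gc < 0.6), 0.8)
  expect_gt(mean(bm$blocks$identity > 0.4 & bm$blocks$identity < 0.8), 0.8)
  expect_true(all(bm$blocks$n_species >= 1 & bm$blocks$n_species <= 27))
  ## all predictions lie on blocks that pass the input filter
  usable <- filterInputBlocks(bm$blocks)
  expect_true(all(IRanges::overlapsAny(bm$native, usable,
                                       ignore.strand = TRUE)))
  ## true motifs are a subset of the native set, absent from shuffled
  expect_true(all(bm$groundTruth$true_ids %in% bm$native$id))
  expect_false(any(bm$groundTruth$true_ids %in% bm$shuffled$id))
  ## with no true motifs planted, the estimated FDR saturates near 1
  noise <- simulationConfig(seed = 8, motifs = list(planted_fdr = 1))
  bmN <- simulateBlocksAndMotifs(noise, g)
  grid <- new("BinGrid", gcEdges = c(0, 1), identityEdges = c(0, 1))
  tab <- fdrTable(estimateFdr(bmN$native, bmN$shuffled,
                              filterInputBlocks(bmN$blocks), grid,
                              cutoffs = 50))
  expect_gt(tab$fdr, 0.75)
})

test_that("average estimated FDR decreases with the pscore cutoff", {
  cfg <- simulationConfig(seed = 30,
                          genome = list(n_genes = 20L,
                                        chrom_length = 400000L,
                                        n_chroms = 1L))
  g <- simulateGenome(cfg)
  bm <- simulateBlocksAndMotifs(cfg, g)
  grid <- new("BinGrid", gcEdges = c(0, 1), identityEdges = c(0, 1))
  tab <- fdrTable(estimateFdr(bm$native, bm$shuffled,
                              filterInputBlocks(bm$blocks), grid,
                              cutoffs = c(50, 80, 110, 140)))
  expect_true(all(diff(tab$fdr) <= 0.02))
  expect_lt(tab$fdr[tab$cutoff == 140], tab$fdr[tab$cutoff == 50])
})

test_that("expression patterns honour class structure and planted pairs", {
  cfg <- simulationConfig(seed = 5)
  feats <- gr("chrS1", seq(1000, 120000, by = 400),
              seq(1149, 120149, by = 400))
  feats$id <- sprintf("F%04d", seq_along(feats))
  pairs <- data.frame(crs_id = c("F0001", "F0002"),
                      gene_id = c("F0100", "F0101"), target = c(1, -1))
  ex <- simulateExpression(cfg, feats, pairs = pairs, dropout = 0)
  gt <- ex$groundTruth$pattern_class
  expect_equal(nrow(ex$meta), 80L)
  expect_equal(unname(table(ex$meta$stage_group)[c(
    "embryo", "larva", "prepupa", "adult", "cell_line")]),
    c(30L, 12L, 6L, 12L, 20L), ignore_attr = TRUE)
  ## ubiquitous features are on in at least ~90% of experiments
  ubi <- names(gt)[gt == "ubiquitous"]
  expect_gt(length(ubi), 0)
  expect_gte(mean(rowMeans(ex$patterns[ubi, , drop = FALSE])), 0.9)
  ## stage-specific features are never on outside their group
  spec <- names(gt)[gt == "specific"]
  for (f in head(spec, 20)) {
    grp <- ex$groundTruth$group[[f]]
    outside <- ex$meta$stage_group != grp
    expect_false(any(ex$patterns[f, outside]))
  }
  ## perfect positive pair: gene on exactly where the CRS is on
  expect_identical(ex$patterns["F0100", ], ex$patterns["F0001", ])
  ## perfect negative pair: gene on exactly where the CRS is off
  expect_identical(ex$patterns["F0101", ], !ex$patterns["F0002", ])
  ## dropout only removes calls
  exN <- simulateExpression(cfg, feats, pairs = pairs, dropout = 0.2)
  expect_true(all(exN$observed <= exN$patterns))
  expect_lt(sum(exN$observed), sum(exN$patterns))
  ## unknown pair ids are rejected
  bad <- data.frame(crs_id = "nope", gene_id = "F0100", target = 1)
  expect_error(simulateExpression(cfg, feats, pairs = bad),
               class = "crsConfigError")
})

test_that("orthology events break exactly the intended synteny criteria", {
  cfg0 <- simulationConfig(seed = 9,
                           orthology = list(insertion_rate = 0,
                                            rearrangement_rate = 0,
                                            missing_rate = 0))
  genes <- gr("chrS1", c(10000, 40000, 80000), c(12000, 43000, 83000),
              strand = "+", ID = c("G1", "G2", "G3"))
  crs <- gr("chrS1", 30000, 30100, id = "DCX")
  pairs <- data.frame(crs_id = "DCX", gene_id = "G2")
  o0 <- simulateOrthology(cfg0, genes, crs, pairs)
  v0 <- syntenyTests(pairs, crs, genes, o0$orthologs, o0$speciesGenes,
                     o0$speciesCrs)
  expect_true(v0$verdicts$strict)
  expect_true(v0$verdicts$orientation)
  expect_true(v0$verdicts$distance)

  ## insertions break the strict criterion but not orientation
  cfgI <- simulationConfig(seed = 9,
                           orthology = list(insertion_rate = 1,
                                            rearrangement_rate = 0,
                                            missing_rate = 0))
  oI <- simulateOrthology(cfgI, genes, crs, pairs)
  vI <- syntenyTests(pairs, crs, genes, oI$orthologs, oI$speciesGenes,
                     oI$speciesCrs)
  expect_false(vI$verdicts$strict)
  expect_true(vI$verdicts$orientation)

  ## distance inflation beyond the cutoff breaks the distance criterion
  cfgD <- simulationConfig(seed = 9,
                           orthology = list(insertion_rate = 0,
                                            rearrangement_rate = 0,
                                            distance_inflation_rate = 1,
                                            missing_rate = 0))
  oD <- simulateOrthology(cfgD, genes, crs, pairs)
  vD <- syntenyTests(pairs, crs, genes, oD$orthologs, oD$speciesGenes,
                     oD$speciesCrs)
  expect_true(vD$verdicts$orientation)
  expect_false(vD$verdicts$distance)

  ## mirroring breaks orientation
  cfgM <- simulationConfig(seed = 9,
                           orthology = list(insertion_rate = 0,
                                            rearrangement_rate = 1,
                                            missing_rate = 0))
  oM <- simulateOrthology(cfgM, genes, crs, pairs)
  vM <- syntenyTests(pairs, crs, genes, oM$orthologs, oM$speciesGenes,
                     oM$speciesCrs)
  expect_false(vM$verdicts$orientation)
})

test_that("emitted files are readable by the package's own readers", {
  cfg <- simulationConfig(seed = 3, genome = list(n_genes = 30L,
                                                  chrom_length = 120000L))
  g <- simulateGenome(cfg)
  bm <- simulateBlocksAndMotifs(cfg, g)
  dir <- withr::local_tempdir()
  suppressWarnings(rtracklayer::export(g$geneModels,
                                       file.path(dir, "genes.gff3")))
  writeBed(g$repeats, file.path(dir, "repeats.bed"))
  writeBlockTable(bm$blocks, file.path(dir, "blocks.tsv"))
  writeMotifTable(bm$native, file.path(dir, "native.tsv"))
  expect_no_warning({
    gm <- readGeneModels(file.path(dir, "genes.gff3"))
    rep <- readBed(file.path(dir, "repeats.bed"))
    blocks <- readBlockTable(file.path(dir, "blocks.tsv"))
    motifs <- readMotifTable(file.path(dir, "native.tsv"))
  })
  expect_equal(length(motifs), length(bm$native))
  expect_equal(length(blocks), length(bm$blocks))
  expect_equal(sum(GenomicRanges::width(rep)),
               sum(GenomicRanges::width(g$repeats)))
})
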