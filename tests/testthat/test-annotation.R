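test_that("unified annotation applies category priorities and partitions
          the genome", {
  gm <- tinyGeneModels()
  ## ncRNA feature straddling the start of the 5'-UTR exon of gene A
  ## (UTR is 1001-1100): 951-1050 covers intergenic space and UTR
  nc <- gr("chrT", 951, 1050, id = "NC1", class = "snRNA",
           bp_content = 0.8)
  GenomeInfoDb::seqlengths(nc) <- GenomeInfoDb::seqlengths(gm)
  ua <- unifyAnnotation(gm, nc)
  expect_true(methods::validObject(ua))
  seg <- annotationSegments(ua)

  catAt <- function(pos) {
    hit <- GenomicRanges::findOverlaps(gr("chrT", pos, pos), seg,
                                       ignore.strand = TRUE)
    as.character(seg$category[S4Vectors::subjectHits(hit)])
  }
  ## ncRNA overrides the UTR where they overlap, and also claims the
  ## intergenic part it covers
  expect_equal(catAt(1020), "ncrna_exon")
  expect_equal(catAt(980), "ncrna_exon")
  ## untouched 5'-UTR stays 5'-UTR
  expect_equal(catAt(1075), "utr5_exon")
  ## CDS-covered exon positions are coding
  expect_equal(catAt(1200), "coding_exon")
  expect_equal(catAt(2200), "coding_exon")
  ## inside the gene span but no exon: intron
  expect_equal(catAt(1700), "intron")
  ## minus-strand gene: UTR sides flip in genome coordinates
  expect_equal(catAt(5100), "utr3_exon")
  expect_equal(catAt(5900), "utr5_exon")
  ## non-coding gene exon and plain intergenic space
  expect_equal(catAt(8100), "ncrna_exon")
  expect_equal(catAt(9500), "intergenic")
  ## exact partition: segment widths sum to the chromosome length
  expect_equal(sum(GenomicRanges::width(seg)), 10000)
  expect_true(IRanges::isDisjoint(seg))
})

test_that("overlapping 5'- and 3'-UTR exons become the both-UTR category", {
  sl <- c(chrT = 5000L)
  mk <- function(start, end, strand, type, id, parent) {
    GenomicRanges::GRanges("chrT", IRanges::IRanges(start, end),
                           strand = strand, type = type, ID = id,
                           Parent = parent, coding = TRUE,
                           seqlengths = sl)
  }
  ## two overlapping coding genes on the + strand: 1801-1900 is the 3'-UTR
  ## of GA and at the same time the 5'-UTR of GB
  gm <- c(mk(1001, 1900, "+", "gene", "GA", NA),
          mk(1001, 1900, "+", "exon", "GA.E1", "GA"),
          mk(1001, 1800, "+", "CDS", "GA.C1", "GA"),
          mk(1801, 2600, "+", "gene", "GB", NA),
          mk(1801, 2600, "+", "exon", "GB.E1", "GB"),
          mk(1901, 2600, "+", "CDS", "GB.C1", "GB"))
  ua <- unifyAnnotation(gm)
  seg <- annotationSegments(ua)
  both <- seg[seg$category == "both_utr_exon"]
  expect_length(both, 1L)
  expect_equal(GenomicRanges::start(both), 1801)
  expect_equal(GenomicRanges::end(both), 1900)
  expect_equal(sum(GenomicRanges::width(seg)), 5000)
})

test_that("fractional counts split equally over elements and sum exactly", {
  gm <- tinyGeneModels()
  ua <- unifyAnnotation(gm)
  ## locus inside one intron element only
  one <- gr("chrT", 1500, 1600, id = "L1")
  t1 <- assignFractionalCategories(one, ua)
  expect_equal(t1$count[t1$category == "intron"], 1)
  ## locus spanning the intron/exon boundary: 0.5 each
  two <- gr("chrT", 1950, 2050, id = "L2")
  t2 <- assignFractionalCategories(two, ua)
  expect_equal(t2$count[t2$category == "intron"], 0.5)
  expect_equal(t2$count[t2$category == "coding_exon"], 0.5)
  ## locus touching two intron elements and the intergenic gap between
  ## genes A and B: here use exon2 end through intergenic into gene B
  ## (3 elements: utr3, intergenic, utr3 of B) -> thirds
  three <- gr("chrT", 2550, 5100, id = "L3")
  t3 <- assignFractionalCategories(three, ua)
  expect_equal(t3$count[t3$category == "utr3_exon"], 2 / 3)
  expect_equal(t3$count[t3$category == "intergenic"], 1 / 3)
  ## unmapped chromosome and exact total
  mix <- suppressWarnings(c(one, two, three, gr("chrUn", 1, 50, id = "L4")))
  tm <- assignFractionalCategories(mix, ua)
  expect_equal(sum(tm$count), 4)
  expect_equal(tm$count[tm$category == "unmapped"], 1)
})

test_that("fold enrichment and normal-approximation p behave as specified", {
  expect_equal(foldEnrichment(50, 100, 1000, 4000), 2)
  expect_equal(foldEnrichment(77, 77, 1234, 1234), 1)
  expect_equal(foldEnrichment(0, 100, 1000, 4000), 0)
  expect_warning(fe0 <- foldEnrichment(5, 10, 0, 100), "undefined")
  expect_true(is.na(fe0))

  ## exactly at the null mean: p = 0.5
  expect_equal(enrichmentPvalue(25, 100, 0.25), 0.5)
  ## the tail case: mu 25, sigma 4.3301, z 5.7735
  p <- enrichmentPvalue(50, 100, 0.25)
  expect_equal(p, pnorm(50, 25, sqrt(100 * 0.25 * 0.75),
                        lower.tail = FALSE))
  expect_lt(p, 4e-9)
  expect_gt(p, 3.8e-9)
  ## depletion gives a lower-tail p below 0.5
  expect_lt(enrichmentPvalue(10, 100, 0.25), 0.5)
  expect_warning(pd <- enrichmentPvalue(5, 10, 0), "degenerate")
  expect_true(is.na(pd))
})

test_that("enrichment p agrees with a binomial Monte-Carlo null", {
  set.seed(101)
  n <- 200; f <- 0.3
  draws <- rbinom(1e4, n, f)
  for (obs in c(75, 80, 90)) {
    mc <- mean(draws >= obs)
    approx <- enrichmentPvalue(obs, n, f)
    expect_lt(abs(mc - approx), 4 * sqrt(mc * (1 - mc) / 1e4) + 0.01)
  }
})

test_that("ncRNA feature filtering applies all three gates with exact
          boundaries", {
  blocks <- mergeTrack(gr("c", 1, 1000))
  reps <- mergeTrack(gr("c", 901, 960))
  f <- gr("c", c(101, 201, 1301, 901),
          c(200, 300, 1500, 1000),
          id = 1:4, class = "tRNA",
          bp_content = c(0.29, 0.30, 0.9, 0.9))
  ## f1 fails bp content (0.29 < 0.3); f2 passes everything;
  ## f3 lies outside the blocks; f4 is exactly 60% repeat-covered
  out <- filterNcrnaFeatures(f, blocks, reps)
  expect_equal(out$id, 2L)
  ## exactly 50% repeat coverage is removed (strict <)
  half <- gr("c", 901, 1020, id = 9L, class = "tRNA", bp_content = 0.9)
  expect_length(filterNcrnaFeatures(half, blocks, reps), 0L)
})

test_that("recovery table counts either-side 50% overlaps per class", {
  feats <- gr("c", c(101, 301, 501, 701, 901, 1101),
              c(200, 400, 600, 800, 1000, 1200),
              id = 1:6,
              class = c("scaRNA", "scaRNA", "scaRNA", "scaRNA", "scaRNA",
                        "scaRNA"),
              bp_content = 0.9)
  feats$class <- c(rep("scaRNA", 6))
  ## loci covering three of the six features
  loci <- gr("c", c(101, 301, 501), c(200, 400, 600), id = c("a", "b", "c"))
  tab <- ncrnaRecoveryTable(loci, feats)
  sca <- tab[tab$class == "scaRNA", ]
  expect_equal(sca$n_filtered, 6L)
  expect_equal(sca$n_overlapped, 3L)
  expect_equal(sca$percentage, 50)
  expect_equal(sca$n_crs, 3L)
  all <- tab[tab$class == "All", ]
  expect_equal(all$percentage, 50)
  ## a class without filtered features reports NA, printed as "-"
  empty <- ncrnaRecoveryTable(loci, feats[0])
  expect_true(is.na(empty$percentage[empty$class == "All"]))
  ## a locus covering less than half of a large feature (and vice versa)
  ## does not count
  big <- gr("c", 2001, 3000, id = 7L, class = "lncRNA", bp_content = 0.9)
  small <- gr("c", 2001, 2100, id = "z")   # 10% of the feature
  t2 <- ncrnaRecoveryTable(small, big)
  ## 100% of the locus is inside the feature, so the either-side rule
  ## does report it
  expect_equal(t2$n_overlapped[t2$class == "lncRNA"], 1L)
  tiny <- gr("c", 2951, 3060, id = "w")  # 50/110 of locus, 5% of feature
  t3 <- ncrnaRecoveryTable(tiny, big)
  expect_equal(t3$n_overlapped[t3$class == "lncRNA"], 0L)
})

test_that("screen comparison matrices count asymmetric 1-bp overlaps", {
  a <- gr("c", c(1, 101, 201), c(50, 150, 250), id = 1:3)
  b <- gr("c", c(40, 400), c(120, 500), id = 1:2)
  m <- compareScreens(list(A = a, B = b))
  expect_equal(m["A", "A"], 3L)
  expect_equal(m["B", "B"], 2L)
  expect_equal(m["A", "B"], 2L)   # two A predictions touch the one B
  expect_equal(m["B", "A"], 1L)
  ## identical screens saturate; disjoint screens share nothing
  ident <- compareScreens(list(X = a, Y = a))
  expect_equal(ident["X", "Y"], 3L)
  disj <- compareScreens(list(X = a, Y = gr("c", 900, 950)))
  expect_equal(disj["X", "Y"], 0L)
  ## expected overlap is the product of sensitivities
  expect_equal(expectedOverlap(0.18, 0.65), 0.117)
  expect_equal(round(expectedOverlap(0.18, 0.65), 2), 0.12)
})
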