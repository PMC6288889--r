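#' Pipeline configuration
#'
#' Bundles every stage threshold with the simulation configuration.  The
#' defaults are the screen's canonical settings: pscore gate 80, bin FDR
#' gate 0.1, strand-independent merge gap 30 nt, expressed-overlap fraction
#' 0.5, at least 3 expressed experiments for co-expression, score cutoffs
#' +/-0.5, synteny fraction 2/3 with a 20,000 nt distance cutoff, 100-nt
#' windows with 10 sampling replicates, an 8 x 8 bin grid, and a pscore scan
#' from 50 to 150.
#'
#' @param seed integer master seed (mandatory for any sampling stage)
#' @param sim a [simulationConfig()]; defaults to one built from \code{seed}
#' @param pscoreMin,fdrMax,mergeGap,expressedFrac,minExpr,posCut,negCut,
#'   syntenyFraction,maxDistance,window,nSamples,nGcBins,nIdentityBins,
#'   cutoffs stage thresholds, see module functions
#' @return a list of class "PipelineConfig"
#' @export
pipelineConfig <- function(seed = 1L, sim = simulationConfig(seed),
                           pscoreMin = 80, fdrMax = 0.1, mergeGap = 30L,
                           expressedFrac = 0.5, minExpr = 3L, posCut = 0.5,
                           negCut = -0.5, syntenyFraction = 2 / 3,
                           maxDistance = 20000L, window = 100L,
                           nSamples = 10L, nGcBins = 8L, nIdentityBins = 8L,
                           cutoffs = seq(50, 150, by = 10)) {
  cfg <- list(seed = as.integer(seed), sim = sim, pscoreMin = pscoreMin,
              fdrMax = fdrMax, mergeGap = mergeGap,
              expressedFrac = expressedFrac, minExpr = minExpr,
              posCut = posCut, negCut = negCut,
              syntenyFraction = syntenyFraction, maxDistance = maxDistance,
              window = window, nSamples = nSamples, nGcBins = nGcBins,
              nIdentityBins = nIdentityBins, cutoffs = cutoffs)
  if (fdrMax < 0 || fdrMax > 1 || expressedFrac < 0 || expressedFrac > 1 ||
      syntenyFraction < 0 || syntenyFraction > 1)
    .crsStop("threshold out of range in pipeline configuration",
             "crsConfigError")
  if (!pscoreMin %in% cutoffs)
    .crsStop("pscoreMin must be one of the scanned cutoffs",
             "crsConfigError")
  structure(cfg, class = "PipelineConfig")
}

#' Gene elements for co-expression: UTR exon parts and ncRNA exons
#'
#' @param geneModels gene/exon/CDS GRanges
#' @param ncrna ncRNA feature GRanges with id
#' @return GRanges with id and gene_id columns
#' @export
geneElementRanges <- function(geneModels, ncrna = GenomicRanges::GRanges()) {
  genes <- geneModels[geneModels$type == "gene"]
  exons <- geneModels[geneModels$type == "exon"]
  cds <- geneModels[geneModels$type == "CDS"]
  codingGenes <- unique(cds$Parent)
  out <- list()
  u <- .utrParts(geneModels)
  if (length(u$gene)) {
    parts <- u$parts
    parts$gene_id <- u$gene
    parts$id <- sprintf("%s.EL%d", u$gene,
                        stats::ave(seq_along(u$gene), u$gene,
                                   FUN = seq_along))
    out[[length(out) + 1L]] <- parts
  }
  ncEx <- exons[!(exons$Parent %in% codingGenes)]
  if (length(ncEx)) {
    parts <- GenomicRanges::reduce(BiocGenerics::unstrand(ncEx))
    gi <- GenomicRanges::findOverlaps(parts, genes, ignore.strand = TRUE,
                                      select = "first")
    parts <- parts[!is.na(gi)]
    gid <- genes$ID[gi[!is.na(gi)]]
    parts$gene_id <- gid
    parts$id <- sprintf("%s.EL%d", gid,
                        stats::ave(seq_along(gid), gid, FUN = seq_along))
    out[[length(out) + 1L]] <- parts
  }
  if (length(ncrna)) {
    nc <- GenomicRanges::granges(ncrna)
    nc$gene_id <- ncrna$id
    nc$id <- ncrna$id
    out[[length(out) + 1L]] <- nc
  }
  if (!length(out)) return(GenomicRanges::GRanges(id = character(0),
                                                  gene_id = character(0)))
  el <- do.call(c, out)
  el[, c("id", "gene_id")]
}

#' Intron instances with flanking-exon bookkeeping
#'
#' @param geneModels gene/exon/CDS GRanges
#' @return list(ranges = GRanges with id/gene_id, flanks =
#'   data.frame(intron_id, gene_id, left_exon, right_exon))
#' @export
intronRanges <- function(geneModels) {
  exons <- BiocGenerics::sort(geneModels[geneModels$type == "exon"],
                              ignore.strand = TRUE)
  if (!length(exons))
    return(list(ranges = GenomicRanges::GRanges(), flanks = NULL))
  ## consecutive exons of the same gene on the same chromosome flank an
  ## intron when there is a gap between them
  n <- length(exons)
  sameGene <- exons$Parent[-n] == exons$Parent[-1L] &
    as.character(GenomeInfoDb::seqnames(exons))[-n] ==
      as.character(GenomeInfoDb::seqnames(exons))[-1L]
  st <- GenomicRanges::end(exons)[-n] + 1L
  en <- GenomicRanges::start(exons)[-1L] - 1L
  ok <- which(sameGene & en >= st)
  if (!length(ok))
    return(list(ranges = GenomicRanges::GRanges(), flanks = NULL))
  gid <- exons$Parent[ok]
  gr <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(exons)[ok], IRanges::IRanges(st[ok], en[ok]),
    seqinfo = GenomeInfoDb::seqinfo(exons))
  gr$id <- sprintf("%s.I%d", gid, stats::ave(seq_along(gid), gid,
                                             FUN = seq_along))
  gr$gene_id <- gid
  list(ranges = gr,
       flanks = data.frame(intron_id = gr$id, gene_id = gid,
                           left_exon = exons$ID[ok],
                           right_exon = exons$ID[ok + 1L]))
}

#' Run the full synthetic-screen analysis pipeline
#'
#' Chains simulate, filter, merge, annotate, express, coexpress, stages and
#' compare.  Every stage records its input/retained counts in the funnel
#' log, and all artifacts are written as plain-text files under
#' \code{outputDir} together with a run manifest (configuration digest and
#' seed), so a run is reproducible and auditable end-to-end.
#'
#' @param config a [pipelineConfig()]
#' @param outputDir directory for artifacts (created); NULL keeps everything
#'   in memory
#' @param stages character vector of stages to run; "all" (default) runs the
#'   complete chain.  Later stages require the earlier ones in the same
#'   call.
#' @param plantPairs number of perfect positive and negative co-expression
#'   pairs to plant (default 2 each); 0 disables planting
#' @return a list with one element per executed stage plus \code{funnel}
#' @export
runPipeline <- function(config = pipelineConfig(), outputDir = NULL,
                        stages = "all", plantPairs = 2L) {
  stopifnot(inherits(config, "PipelineConfig"))
  all <- c("simulate", "filter", "merge", "annotate", "express",
           "coexpress", "stages", "compare")
  if (identical(stages, "all")) stages <- all
  bad <- setdiff(stages, all)
  if (length(bad))
    .crsStop(paste("unknown stage(s):", paste(bad, collapse = ", ")),
             "crsConfigError")
  need <- function(s) {
    if (!s %in% stages)
      .crsStop(sprintf("stage requires upstream stage '%s' in this run", s),
               "crsConfigError")
  }
  if (!is.null(outputDir))
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  funnel <- list()
  note <- function(stage, metric, value)
    funnel[[length(funnel) + 1L]] <<- data.frame(stage = stage,
                                                 metric = metric,
                                                 value = value)
  res <- list()

  ## ---- simulate ----
  if ("simulate" %in% stages) {
    genome <- simulateGenome(config$sim)
    bm <- simulateBlocksAndMotifs(config$sim, genome)
    res$genome <- genome
    res$blocksAndMotifs <- bm
    note("simulate", "blocks", length(bm$blocks))
    note("simulate", "native_predictions", length(bm$native))
    note("simulate", "shuffled_predictions", length(bm$shuffled))
    note("simulate", "genes", length(genome$genes))
    if (!is.null(outputDir)) {
      rtracklayer::export(genome$geneModels,
                          file.path(outputDir, "gene_models.gff3"))
      writeBed(genome$repeats, file.path(outputDir, "repeats.bed"))
      nc <- genome$ncrna
      names(nc) <- nc$id
      writeBed(GenomicRanges::granges(nc, use.names = TRUE),
               file.path(outputDir, "ncrna.bed"))
      write.table(data.frame(id = nc$id, class = nc$class,
                             bp_content = nc$bp_content),
                  file.path(outputDir, "ncrna_classes.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      writeBlockTable(bm$blocks, file.path(outputDir, "blocks.tsv"))
      writeMotifTable(bm$native, file.path(outputDir, "motifs_native.tsv"))
      writeMotifTable(bm$shuffled,
                      file.path(outputDir, "motifs_shuffled.tsv"))
    }
  }

  ## ---- filter ----
  if ("filter" %in% stages) {
    need("simulate")
    blocks <- filterInputBlocks(res$blocksAndMotifs$blocks)
    note("filter", "blocks_retained", length(blocks))
    nat <- filterPscore(res$blocksAndMotifs$native, 50)
    shuf <- filterPscore(res$blocksAndMotifs$shuffled, 50)
    note("filter", "native_pscore50", length(nat))
    natR <- filterRepeatOverlap(nat, res$genome$repeats)
    shufR <- filterRepeatOverlap(shuf, res$genome$repeats)
    note("filter", "native_repeat_removed", natR$removed)
    note("filter", "native_after_repeat", length(natR$motifs))
    grid <- buildBins(natR$motifs, config$nGcBins, config$nIdentityBins)
    fdr <- estimateFdr(natR$motifs, shufR$motifs, blocks, grid,
                       cutoffs = config$cutoffs)
    sel <- selectCrsMotifs(natR$motifs, fdr, pscoreMin = config$pscoreMin,
                           fdrMax = config$fdrMax)
    note("filter", "selected_motifs", length(sel$motifs))
    note("filter", "excluded_undefined_fdr", sel$excluded_undefined)
    res$filteredBlocks <- blocks
    res$grid <- grid
    res$fdr <- fdr
    res$selected <- sel$motifs
    if (!is.null(outputDir)) {
      write.table(fdrTable(fdr), file.path(outputDir, "fdr_table.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      writeMotifTable(sel$motifs,
                      file.path(outputDir, "motifs_selected.tsv"))
    }
  }

  ## ---- merge ----
  if ("merge" %in% stages) {
    need("filter")
    loci <- buildLoci(res$selected, maxGap = config$mergeGap)
    note("merge", "loci", length(loci))
    res$loci <- loci
    if (!is.null(outputDir))
      writeLoci(loci, file.path(outputDir, "loci.bed"),
                file.path(outputDir, "loci.tsv"))
  }

  ## ---- annotate ----
  if ("annotate" %in% stages) {
    need("merge")
    unified <- unifyAnnotation(res$genome$geneModels, res$genome$ncrna)
    enr <- annotationEnrichmentTable(res$loci, unified, res$filteredBlocks)
    filteredNc <- filterNcrnaFeatures(res$genome$ncrna, res$filteredBlocks,
                                      res$genome$repeats)
    recov <- ncrnaRecoveryTable(res$loci, filteredNc)
    note("annotate", "unified_segments", length(annotationSegments(unified)))
    note("annotate", "ncrna_filtered", length(filteredNc))
    res$unified <- unified
    res$annotationTable <- enr
    res$filteredNcrna <- filteredNc
    res$recoveryTable <- recov
    if (!is.null(outputDir)) {
      seg <- annotationSegments(unified)
      names(seg) <- as.character(seg$category)
      writeBed(seg, file.path(outputDir, "unified_annotation.bed"))
      write.table(enr, file.path(outputDir, "annotation_enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(recov, file.path(outputDir, "ncrna_recovery.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## ---- express ----
  if ("express" %in% stages) {
    need("annotate")
    loci <- res$loci
    lociGr <- GenomicRanges::granges(loci)
    lociGr$id <- loci$id
    elements <- geneElementRanges(res$genome$geneModels, res$genome$ncrna)
    exons <- res$genome$geneModels[res$genome$geneModels$type == "exon"]
    exonGr <- GenomicRanges::granges(exons)
    exonGr$id <- exons$ID
    intr <- intronRanges(res$genome$geneModels)
    intronGr <- GenomicRanges::granges(intr$ranges)
    intronGr$id <- intr$ranges$id
    elementGr <- GenomicRanges::granges(elements)
    elementGr$id <- elements$id
    features <- c(lociGr, elementGr, exonGr, intronGr)
    features <- features[!duplicated(features$id)]

    pairs <- NULL
    if (plantPairs > 0) {
      pairs <- .pickPlantablePairs(loci, res$unified, elements,
                                   n = 2L * plantPairs)
      if (!is.null(pairs))
        pairs$target <- rep_len(c(1, -1), nrow(pairs))
    }
    expr <- simulateExpression(config$sim, features, pairs = pairs)
    se <- buildExpressionMatrix(features, expr$tracks, expr$meta,
                                minFrac = config$expressedFrac)
    note("express", "features", length(features))
    note("express", "expressed_in_any",
         sum(rowSums(expressedMatrix(se)) > 0))
    enrich <- expressionEnrichment(
      GenomicRanges::granges(loci), res$genome$seqlengths, expr$tracks,
      window = config$window, nSamples = config$nSamples,
      seed = config$seed)
    res$expression <- expr
    res$se <- se
    res$intronInfo <- intr
    res$geneElements <- elements
    res$plantedPairs <- pairs
    res$expressionEnrichment <- enrich
    if (!is.null(outputDir)) {
      m <- expressedMatrix(se)
      write.table(data.frame(id = rownames(m), m + 0L,
                             check.names = FALSE),
                  file.path(outputDir, "expression_matrix.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(expr$meta, file.path(outputDir, "experiments.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(enrich,
                  file.path(outputDir, "expression_enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## ---- coexpress ----
  if ("coexpress" %in% stages) {
    need("express")
    interg <- .intergenicLoci(res$loci, res$unified)
    lociGr <- GenomicRanges::granges(interg)
    lociGr$id <- interg$id
    coex <- computeCoexpression(lociGr, res$geneElements, res$se,
                                minExpr = config$minExpr,
                                posCut = config$posCut,
                                negCut = config$negCut)
    note("coexpress", "intergenic_considered", length(interg))
    note("coexpress", "scored", nrow(coex))
    note("coexpress", "positive", sum(coex$class == "positive"))
    note("coexpress", "negative", sum(coex$class == "negative"))
    res$coexpression <- coex
    candidates <- coex[coex$class %in% c("positive", "negative") &
                         !is.na(coex$gene_id), ]
    if (nrow(candidates)) {
      synPairs <- unique(data.frame(crs_id = candidates$crs_id,
                                    gene_id = candidates$gene_id))
      ## map element gene ids to gene spans where they exist
      synPairs <- synPairs[synPairs$gene_id %in% res$genome$genes$ID, ]
      if (nrow(synPairs)) {
        crsGr <- lociGr[lociGr$id %in% synPairs$crs_id]
        orth <- simulateOrthology(config$sim, res$genome$genes, crsGr,
                                  synPairs)
        verdicts <- syntenyTests(
          synPairs, crsGr, res$genome$genes, orth$orthologs,
          orth$speciesGenes, orth$speciesCrs,
          requiredFraction = config$syntenyFraction,
          maxDistance = config$maxDistance)
        res$orthology <- orth
        res$synteny <- verdicts
        note("coexpress", "synteny_pairs", nrow(synPairs))
      }
    }
    if (!is.null(outputDir))
      write.table(coex, file.path(outputDir, "coexpression.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- stages ----
  if ("stages" %in% stages) {
    need("express")
    mat <- expressedMatrix(res$se)
    lociGr <- GenomicRanges::granges(res$loci)
    blocksM <- mergeTrack(res$filteredBlocks)
    mkBiotype <- function(gr, ids) {
      keep <- rowSums(mat[ids, , drop = FALSE]) >= 3 &
        coverageFraction(gr, blocksM) >= 0.5
      list(mat = mat[ids[keep], , drop = FALSE],
           has_crs = .hasCrs(gr[keep], lociGr))
    }
    intr <- res$intronInfo
    exons <- res$genome$geneModels[res$genome$geneModels$type == "exon"]
    biotypes <- list(
      intron = mkBiotype(intr$ranges, intr$ranges$id),
      coding_exon = mkBiotype(GenomicRanges::granges(exons), exons$ID))
    biotypes <- Filter(function(b) nrow(b$mat) >= 2 && any(b$has_crs) &&
                         any(!b$has_crs), biotypes)
    if (length(biotypes)) {
      res$stageEnrichment <- stageEnrichment(biotypes)
      note("stages", "tests", sum(!is.na(res$stageEnrichment$p)))
    }
    bi <- biotypes[["intron"]]
    if (!is.null(bi) && any(bi$has_crs) && any(!bi$has_crs)) {
      res$diffExpr <- diffExpressionMatrix(
        bi$mat[bi$has_crs, , drop = FALSE],
        bi$mat[!bi$has_crs, , drop = FALSE])
    }
    if (!is.null(outputDir) && !is.null(res$stageEnrichment))
      write.table(res$stageEnrichment,
                  file.path(outputDir, "stage_enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }

  ## ---- compare ----
  if ("compare" %in% stages) {
    need("merge")
    trueIds <- res$blocksAndMotifs$groundTruth$true_ids
    trueMotifs <- res$blocksAndMotifs$native[
      res$blocksAndMotifs$native$id %in% trueIds]
    screens <- list(crs_loci = GenomicRanges::granges(res$loci),
                    planted_true = GenomicRanges::granges(trueMotifs),
                    annotated_ncrna = GenomicRanges::granges(
                      res$genome$ncrna))
    res$screenMatrix <- compareScreens(screens)
    if (!is.null(outputDir))
      write.table(res$screenMatrix,
                  file.path(outputDir, "screen_overlaps.tsv"), sep = "\t",
                  quote = FALSE, col.names = NA)
  }

  res$funnel <- do.call(rbind, funnel)
  if (!is.null(outputDir)) {
    write.table(res$funnel, file.path(outputDir, "funnel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest <- list(seed = config$seed,
                     stages = stages,
                     thresholds = config[setdiff(names(config), "sim")],
                     files = list.files(outputDir))
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

## loci lying mostly (>50%) in intergenic segments
.intergenicLoci <- function(loci, unified) {
  seg <- annotationSegments(unified)
  interg <- mergeTrack(seg[seg$category == "intergenic"])
  loci[coverageFraction(loci, interg) > 0.5]
}

## instance has a CRS: >= 50% of instance or locus size overlap
.hasCrs <- function(instances, loci) {
  hit <- overlapPairs(instances, loci, minFracQuery = 0.5,
                      minFracTarget = 0.5, eitherSuffices = TRUE)
  out <- logical(length(instances))
  out[unique(hit$queryIdx)] <- TRUE
  out
}

## intergenic loci whose closest gene element does not overlap them and is
## unique; used to pick planted co-expression pairs
.pickPlantablePairs <- function(loci, unified, elements, n) {
  interg <- .intergenicLoci(loci, unified)
  rows <- list()
  for (i in seq_along(interg)) {
    if (length(rows) >= n) break
    lociGr <- interg[i]
    cf <- closestFeatures(lociGr, elements)
    if (nrow(cf) != 1L || cf$side[1] == "overlapping" || cf$distance[1] == 0)
      next
    gid <- elements$gene_id[cf$featureIdx[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      crs_id = interg$id[i], gene_id = elements$id[cf$featureIdx[1]],
      focal_gene = gid)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
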