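test_that("fixture generation is byte-identical for the same seed", {
  d1 <- localTmpDir(); d2 <- localTmpDir()
  fixtureSet(d1, seed = 7, nContigs = 6)
  fixtureSet(d2, seed = 7, nContigs = 6)
  files <- list.files(d1)
  expect_true(length(files) > 10)
  expect_identical(sort(files), sort(list.files(d2)))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  d3 <- localTmpDir()
  fixtureSet(d3, seed = 8, nContigs = 6)
  expect_false(identical(readLines(file.path(d1, "contigs.fna")),
                         readLines(file.path(d3, "contigs.fna"))))
})

test_that("planted features do not overlap and match the truth GFF3", {
  gc <- genContigs(3, nContigs = 8, featureDensity = 0.8)
  f <- gc$features
  for (ctg in unique(as.character(GenomicRanges::seqnames(f)))) {
    fr <- f[as.character(GenomicRanges::seqnames(f)) == ctg]
    if (length(fr) < 2) next
    hits <- IRanges::findOverlaps(GenomicRanges::ranges(fr),
                                  drop.self = TRUE)
    expect_identical(length(hits), 0L)
  }
  expect_true(all(GenomicRanges::end(f) <=
                    Biostrings::width(gc$contigs)[
                      match(as.character(GenomicRanges::seqnames(f)),
                            names(gc$contigs))]))
  # density 0 -> no features
  none <- genContigs(3, nContigs = 3, featureDensity = 0)
  expect_identical(length(none$features), 0L)
  # CDS lengths pass the default ORF filter
  expect_true(all(gc$orfs$nt_length >= 180))
  expect_identical(nrow(filterOrfs(gc$orfs)), nrow(gc$orfs))
})

test_that("every generated file is consumed by its parser (closure property)", {
  d <- localTmpDir()
  truth <- fixtureSet(d, seed = 11, nContigs = 8, contamination = 0.1)
  expect_silent({
    contigs <- readContigs(file.path(d, "contigs.fna"))
    orfs <- readOrfTable(file.path(d, "orfs.tsv"))
    trna <- readFeatureTable(file.path(d, "trna.tsv"), "tRNA")
    crispr <- readFeatureTable(file.path(d, "crispr.tsv"), "CRISPR")
    gdb <- readPairwiseHits(file.path(d, "genomedb.tsv"))
    sp <- readPairwiseHits(file.path(d, "sprot.tsv"))
    pf <- readDomainHits(file.path(d, "pfam.domtblout"), "Pfam")
    tg <- readDomainHits(file.path(d, "tigrfam.domtblout"), "TIGRFAM")
    fo <- readDomainHits(file.path(d, "foam.domtblout"), "FOAM")
    refmap <- readIdMap(file.path(d, "refmap.tsv"))
    binmap <- readIdMap(file.path(d, "binmap.tsv"))
    defs <- readPathwayDefs(file.path(d, "pathways.tsv"))
    fams <- readFamilyMap(file.path(d, "ko_map.tsv"))
    dt <- readDepthTable(file.path(d, "depth.txt"))
    spec <- readSpectralTable(file.path(d, "plevel.tsv"))
    gff <- readGff3(file.path(d, "truth.gff3"))
  })
  expect_identical(length(contigs), 8L)
  expect_true(all(orfs$gene_id %in% gdb$query_id))
  expect_identical(sort(names(binmap)), sort(names(contigs)))
  expect_equal(dt$contigs$total_avg_depth, unname(rowSums(dt$depth)),
               tolerance = 1e-6)
  expect_true(file.exists(file.path(d, "truth.json")))
  # every FOAM model name respects the KO grammar
  for (m in unique(fo$model_name)) expect_silent(parseFoamName(m))
  # all observed families have at least one supporting gene
  expect_setequal(intersect(truth$pathways$observed, fams$family_id),
                  truth$pathways$observed)
})

test_that("planted lineages are recovered gene by gene under zero noise", {
  d <- localTmpDir()
  truth <- fixtureSet(d, seed = 5, nContigs = 8, decoyRate = 0,
                      identityNoise = 0)
  gdb <- readPairwiseHits(file.path(d, "genomedb.tsv"))
  refmap <- readIdMap(file.path(d, "refmap.tsv"))
  for (g in names(truth$geneLineage)) {
    b <- evidenceBundle(g, genomedb = gdb[gdb$query_id == g, ])
    expect_identical(classifyGene(b, refmap), truth$geneLineage[[g]])
  }
})

test_that("decoy hits never beat the planted best hit", {
  d <- localTmpDir()
  truth <- fixtureSet(d, seed = 13, nContigs = 8, decoyRate = 0.5)
  gdb <- readPairwiseHits(file.path(d, "genomedb.tsv"))
  for (g in unique(gdb$query_id)) {
    h <- gdb[gdb$query_id == g, ]
    best <- selectBestHit(h)
    expect_identical(best$subject_id, paste0("SUBJ|", g))
  }
})

test_that("zero replicate noise duplicates samples exactly", {
  d <- localTmpDir()
  fixtureSet(d, seed = 4, nContigs = 5, replicateNoise = 0)
  dt <- readDepthTable(file.path(d, "depth.txt"))
  expect_equal(dt$depth[, 1], dt$depth[, 2])
  expect_equal(dt$depth[, 2], dt$depth[, 3])
  spec <- readSpectralTable(file.path(d, "plevel.tsv"))
  expect_equal(spec[, 1], spec[, 2])
})

test_that("planted contamination fractions are exact by construction", {
  genes <- sprintf("g%03d", 1:100)
  magOf <- stats::setNames(rep(c("MAG01", "MAG02"), each = 50), genes)
  lins <- c(MAG01 = "d__B;p__P1;c__C1;o__O1;f__F1;g__G1;",
            MAG02 = "d__B;p__P2;c__C2;o__O2;f__F2;g__G2;")
  ml <- genMagLineages(genes, magOf, lins, q = c(MAG01 = 0.1, MAG02 = 0),
                       seed = 3)
  expect_equal(unname(ml$realizedQ), c(0.1, 0))
  m1 <- ml$lineage[genes[1:50]]
  expect_identical(sum(m1 != lins["MAG01"]), 5L)
})
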