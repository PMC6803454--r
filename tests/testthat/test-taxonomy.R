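CUPR <- "d__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Betaproteobacteriales;f__Burkholderiaceae;g__Cupriavidus;"

test_that("lineage strings parse to canonical ranks and round-trip", {
  lin <- parseLineage(CUPR)
  expect_identical(length(lin), 6L)
  expect_identical(unname(lin["g"]), "Cupriavidus")
  expect_identical(lineageString(lin), CUPR)
  expect_identical(length(parseLineage("")), 0L)
  expect_error(parseLineage("p__X;d__Y"), class = "lineageFormatError")
  expect_error(parseLineage("d__X;c__Y"), class = "lineageFormatError") # gap
  expect_error(parseLineage("q__X"), class = "lineageFormatError")
})

test_that("gene classification follows the best reference hit", {
  refmap <- c(sA = "d__Bacteria;p__A;", sB = "d__Bacteria;p__B;")
  hits <- data.frame(query_id = "g1", subject_id = c("sA", "sB"),
                     pct_identity = 90, aln_len = 10, mismatch = 0,
                     gapopen = 0, qstart = 1, qend = 10, sstart = 1,
                     send = 10, evalue = c(1e-30, 1e-60),
                     bitscore = c(80, 120), qlen = 10, qcov = 100,
                     stringsAsFactors = FALSE)
  b <- evidenceBundle("g1", genomedb = hits)
  expect_identical(classifyGene(b, refmap), "d__Bacteria;p__B;")
  expect_identical(classifyGene(evidenceBundle("g1"), refmap), "")
  # hit-order invariance
  expect_identical(classifyGene(evidenceBundle("g1",
                                               genomedb = hits[2:1, ]),
                                refmap), "d__Bacteria;p__B;")
  bad <- evidenceBundle("g1", genomedb = transform(hits, subject_id = "sX"))
  expect_error(classifyGene(bad, refmap), class = "missingSubjectError")
})

test_that("taxon tree weights aggregate and conserve at every node", {
  lin <- c(g1 = "d__B;p__P1;c__C;o__O;f__F;g__G;s__S1;",
           g2 = "d__B;p__P1;c__C;o__O;f__F;g__G;s__S2;",
           g3 = "d__B;p__P2;", g4 = "")
  w <- matrix(c(10, 30, 40, 20), 4, 1, dimnames = list(names(lin), "s1"))
  tree <- buildTaxonTree(lin, w)
  tw <- treeWeights(tree)
  expect_equal(tw["root", "s1"], 100)
  expect_equal(tw["B|P1", "s1"], 40)
  expect_equal(tw["B|P2", "s1"], 40)
  expect_equal(tw["unclassified", "s1"], 20)
  genus <- tw["B|P1|C|O|F|G", "s1"]
  expect_equal(genus, 40)

  # two genes same genus, equal weight -> proportion 1 at genus within P1
  p <- ringProportions(tree, "phylum")
  expect_equal(sort(unname(p[, 1])), c(0.2, 0.4, 0.4))
  expect_equal(sum(p[, 1]), 1)

  expect_error(buildTaxonTree(lin, -w), class = "negativeWeightError")
})

test_that("random trees satisfy parent/child weight conservation per node", {
  set.seed(21)
  pool <- c("", sprintf("d__B;p__P%d;", 1:3),
            sprintf("d__B;p__P1;c__C%d;o__O;f__F;g__G%d;", 1:4, 1:4))
  lin <- stats::setNames(sample(pool, 500, TRUE), sprintf("g%03d", 1:500))
  w <- matrix(runif(1000, 0, 5), 500, 2,
              dimnames = list(names(lin), c("s1", "s2")))
  tree <- buildTaxonTree(lin, w)
  nodes <- treeNodes(tree)
  tw <- treeWeights(tree)
  for (i in which(nodes$rank != "species")) {
    kids <- which(nodes$parent == nodes$path[i])
    if (!length(kids)) next
    expect_equal(unname(tw[i, ]),
                 unname(colSums(tw[kids, , drop = FALSE])))
  }
  expect_equal(unname(tw["root", ]), unname(colSums(w)))
})

test_that("contamination report recovers plurality and discordance", {
  lin <- c(rep("d__B;p__P;c__C;o__O;f__F;g__A;", 97),
           rep("d__B;p__P;c__C;o__O;f__F;g__B;", 3))
  rep1 <- contaminationReport(lin, "genus")
  expect_identical(rep1$plurality, "A")
  expect_equal(rep1$discordant_fraction, 0.03)

  expect_equal(contaminationReport(rep(lin[1], 10),
                                   "genus")$discordant_fraction, 0)

  split <- c(rep("d__B;p__P;c__C;o__O;f__F;g__Zeta;", 5),
             rep("d__B;p__P;c__C;o__O;f__F;g__Alpha;", 5))
  r <- contaminationReport(split, "genus")
  expect_identical(r$plurality, "Alpha")  # lexicographic tie-break
  expect_equal(r$discordant_fraction, 0.5)

  # genes unclassified at the rank leave the denominator
  mix <- c(lin[1:4], "d__B;p__P;", "")
  r2 <- contaminationReport(mix, "genus")
  expect_identical(r2$n_classified, 4L)
  expect_identical(r2$n_unclassified, 2L)
  expect_error(contaminationReport(c("", "d__B;"), "genus"),
               class = "noClassifiedGenesError")
})

test_that("MAG extraction partitions records exactly, unbinned included", {
  rec <- S4Vectors::DataFrame(id = sprintf("g%d", 1:6),
                              contigid = c("c1", "c1", "c2", "c3", "c3",
                                           "c4"))
  binmap <- c(c1 = "MAG1", c2 = "MAG2", c3 = "MAG1")
  parts <- extractMagAnnotations(rec, binmap)
  expect_setequal(names(parts), c("MAG1", "MAG2", "unbinned"))
  expect_identical(nrow(parts$MAG1), 4L)
  expect_identical(nrow(parts$MAG2), 1L)
  expect_identical(parts$unbinned$id, "g6")
  expect_identical(sum(vapply(parts, nrow, 0L)), nrow(rec))

  all_un <- extractMagAnnotations(rec, character())
  expect_identical(nrow(all_un$unbinned), nrow(rec))

  set.seed(13)
  big <- S4Vectors::DataFrame(id = sprintf("g%d", 1:200),
                              contigid = sprintf("c%d",
                                                 sample.int(20, 200, TRUE)))
  bm <- stats::setNames(sprintf("MAG%d", sample.int(4, 15, TRUE)),
                        sprintf("c%d", 1:15))
  ps <- extractMagAnnotations(big, bm)
  expect_identical(sum(vapply(ps, nrow, 0L)), 200L)
})

test_that("tree serialization is ordered, lossless and invertible", {
  lin <- c(g1 = "d__B;p__P1;c__C;o__O;f__F;g__G;s__S;",
           g2 = "d__B;p__P2;", g3 = "")
  w <- matrix(c(5, 3, 2, 1, 1, 1), 3, 2,
              dimnames = list(names(lin), c("s1", "s2")))
  tree <- buildTaxonTree(lin, w)
  doc <- treeToList(tree)
  # single-lineage chain depth equals rank count
  depth <- 0; node <- doc
  while (length(node$children)) { node <- node$children[[1]]; depth <- depth + 1 }
  expect_identical(depth, 7)
  # children ordered by descending total weight then name
  kidW <- vapply(doc$children, function(k) sum(unlist(k$weight)), 0)
  expect_true(all(diff(kidW) <= 0))
  back <- treeFromList(doc)
  expect_equal(treeWeights(back), treeWeights(tree))
  expect_identical(treeNodes(back)$path, treeNodes(tree)$path)

  d <- localTmpDir()
  writeTreeJson(tree, file.path(d, "t.json"))
  parsed <- jsonlite::read_json(file.path(d, "t.json"),
                                simplifyVector = FALSE)
  expect_equal(treeWeights(treeFromList(parsed)), treeWeights(tree))
})
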