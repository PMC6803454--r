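writeDepthFixture <- function(path, contigs = c(c1 = 1000, c2 = 2000),
                              depths = rbind(c(10, 20), c(5, 0))) {
  samples <- sprintf("s%d", seq_len(ncol(depths)))
  hdr <- paste(c("contigName", "contigLen", "totalAvgDepth",
                 as.vector(rbind(paste0(samples, ".bam"),
                                 paste0(samples, ".bam-var")))),
               collapse = "\t")
  rows <- vapply(seq_along(contigs), function(i)
    paste(c(names(contigs)[i], contigs[i], sprintf("%.4f", sum(depths[i, ])),
            as.vector(rbind(sprintf("%.4f", depths[i, ]),
                            sprintf("%.4f", depths[i, ] * 0.1)))),
          collapse = "\t"), "")
  writeLines(c(hdr, rows), path)
  path
}

test_that("MetaBat depth dialect parses, variance columns discarded", {
  d <- localTmpDir()
  p <- writeDepthFixture(file.path(d, "depth.txt"))
  dt <- readDepthTable(p)
  expect_identical(dt$samples, c("s1", "s2"))
  expect_equal(dt$depth["c1", ], c(s1 = 10, s2 = 20))
  expect_equal(dt$contigs$total_avg_depth,
               unname(rowSums(dt$depth)))  # fixture construction identity

  writeLines("contigName\tcontigLen\ttotalAvgDepth", file.path(d, "h.txt"))
  empty <- readDepthTable(file.path(d, "h.txt"))
  expect_identical(nrow(empty$contigs), 0L)
  expect_identical(empty$samples, character(0))

  writeLines("not-a-depth-file", file.path(d, "bad.txt"))
  expect_error(readDepthTable(file.path(d, "bad.txt")), class = "parseError")
})

test_that("genes inherit their contig's per-sample depth", {
  d <- localTmpDir()
  p <- writeDepthFixture(file.path(d, "depth.txt"),
                         contigs = c(cA = 5000),
                         depths = matrix(82.0316, 1, 1))
  dt <- readDepthTable(p)
  rec <- S4Vectors::DataFrame(id = c("g1", "g2"), contigid = c("cA", "cA"))
  rec2 <- attachGeneDepth(rec, dt)
  expect_equal(unname(rec2$depth[, 1]), c(82.0316, 82.0316))
  expect_equal(rec2$total_avg_depth, c(82.0316, 82.0316))

  recX <- S4Vectors::DataFrame(id = "g3", contigid = "cMissing")
  expect_error(attachGeneDepth(recX, dt), class = "unknownContigError")
  expect_warning(r0 <- attachGeneDepth(recX, dt, strict = FALSE))
  expect_equal(unname(r0$depth[, 1]), 0)

  # zero-depth contigs keep their genes, with zero weight
  p0 <- writeDepthFixture(file.path(d, "d0.txt"), contigs = c(cA = 100),
                          depths = matrix(0, 1, 1))
  r00 <- attachGeneDepth(S4Vectors::DataFrame(id = "g1", contigid = "cA"),
                         readDepthTable(p0))
  expect_equal(unname(r00$depth[, 1]), 0)
})

test_that("weighted profiles normalise per sample with explicit unassigned", {
  cats <- c(g1 = "K1", g2 = "K2")
  w <- matrix(c(10, 30), 2, 1, dimnames = list(names(cats), "s1"))
  pm <- weightedProfile(cats, w)
  expect_equal(unname(relAbundance(pm)[, 1]), c(0.25, 0.75))

  one <- weightedProfile(c(g1 = "K1"), c(g1 = 5))
  expect_equal(unname(relAbundance(one)[1, 1]), 1)

  mixed <- weightedProfile(c(g1 = "K1", g2 = NA),
                           matrix(c(1, 3), 2, 1,
                                  dimnames = list(c("g1", "g2"), "s1")))
  expect_true("unassigned" %in% rownames(profileWeights(mixed)))
  expect_equal(sum(relAbundance(mixed)[, 1]), 1)

  expect_error(weightedProfile(cats, -w), class = "negativeWeightError")
})

test_that("profile columns sum to one for every weighting source", {
  set.seed(31)
  n <- 1000
  genes <- sprintf("g%04d", seq_len(n))
  cats <- stats::setNames(sample(c(sprintf("K%02d", 1:15), NA), n, TRUE),
                          genes)
  w <- matrix(rexp(n * 3), n, 3, dimnames = list(genes, c("a", "b", "c")))
  pm <- weightedProfile(cats, w)
  expect_equal(unname(colSums(relAbundance(pm))), rep(1, 3),
               tolerance = 1e-9)
  # zero-total sample flagged, all-zero abundances
  w[, 2] <- 0
  pm0 <- weightedProfile(cats, w)
  expect_true(pm0@zeroSamples[2])
  expect_equal(sum(relAbundance(pm0)[, 2]), 0)
  # equal depths reproduce the count profile
  cnt <- weightedProfile(cats, matrix(1, n, 1, dimnames = list(genes, "s")))
  eq <- weightedProfile(cats, matrix(7.5, n, 1, dimnames = list(genes, "s")))
  expect_equal(relAbundance(cnt), relAbundance(eq))
})

test_that("spectral tables parse, reject duplicates, default absent genes to zero", {
  d <- localTmpDir()
  p <- file.path(d, "plevel.tsv")
  writeLines(c("gene_id\ts1\ts2\ts3", "g1\t1.5\t2\t0", "g2\t0\t4\t1"), p)
  m <- readSpectralTable(p)
  expect_identical(dim(m), c(2L, 3L))
  expect_equal(m["g1", "s2"], 2)
  sw <- spectralWeights(m, c("g1", "g2", "g3"))
  expect_equal(unname(sw["g3", ]), c(0, 0, 0))

  writeLines(c("gene_id\ts1", "g1\t1", "g1\t2"), p)
  expect_error(readSpectralTable(p), class = "duplicateGeneError")

  # round trip
  writeLines(c(paste(c("gene_id", colnames(m)), collapse = "\t"),
               vapply(rownames(m), function(g)
                 paste(c(g, m[g, ]), collapse = "\t"), "")), p)
  expect_equal(readSpectralTable(p), m)
})

test_that("pathway activity sums supporting-gene weights per observed family", {
  defs <- data.frame(pathway_id = "P1", name = "p",
                     stringsAsFactors = FALSE)
  defs$members <- list(c("K1", "K2"))
  fams <- data.frame(family_id = c("K1", "K2"), stringsAsFactors = FALSE)
  fams$gene_ids <- list("g1", c("g1", "g2"))
  recon <- reconstructMinimal(c("K1", "K2"), defs, "exact")
  w <- matrix(c(2, 3), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  pm <- pathwayActivity(recon, defs, fams, w)
  # g1 supports two families of P1: counted once per family => 2 + (2+3)
  expect_equal(unname(profileWeights(pm)["P1", 1]), 7)
  expect_equal(unname(relAbundance(pm)["P1", 1]), 1)
})
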