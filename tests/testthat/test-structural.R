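test_that("overlapping model hits keep only the lowest E-value, ties all kept", {
  h <- rrnaHits(c("c1", "c1"), c("Bacteria", "Archaea"), c("16S", "16S"),
                c(100, 120), c(400, 420), "+", c(1e-30, 1e-10))
  out <- resolveModelHits(h)
  expect_identical(out$domain_model, "Bacteria")

  tie <- rrnaHits(c("c1", "c1"), c("Bacteria", "Archaea"), c("16S", "16S"),
                  c(100, 120), c(400, 420), "+", c(1e-20, 1e-20))
  expect_identical(nrow(resolveModelHits(tie)), 2L)

  apart <- rrnaHits(c("c1", "c1"), c("Bacteria", "Archaea"),
                    c("16S", "23S"), c(100, 900), c(400, 1100), "+",
                    c(1e-30, 1e-5))
  expect_identical(nrow(resolveModelHits(apart)), 2L)  # no conflict
})

test_that("transitively overlapping hits resolve as one group", {
  # a-b overlap, b-c overlap, a-c do not: still one conflict group
  h <- rrnaHits(rep("c1", 3), c("Bacteria", "Archaea", "Eukaryota"),
                rep("16S", 3), c(1, 80, 160), c(100, 180, 260), "+",
                c(1e-10, 1e-30, 1e-20))
  out <- resolveModelHits(h)
  expect_identical(out$domain_model, "Archaea")
})

test_that("model-hit resolution matches the pairwise brute-force oracle", {
  set.seed(42)
  for (i in 1:50) {
    h <- randomHitSet(n = sample(2:10, 1))
    expect_identical(resolveModelHits(h), oracleResolveHits(h))
  }
})

test_that("masking replaces exactly the covered positions and keeps length", {
  ctg <- Biostrings::DNAStringSet(c(c1 = "ACGTACGTAC"))
  f <- featureIntervals("c1", 3, 5, "+", "tRNA", "tRNA-Ala")
  m <- maskContigs(ctg, f)
  expect_identical(as.character(m[["c1"]]), "ACNNNCGTAC")

  expect_identical(as.character(maskContigs(ctg, f[0])[["c1"]]),
                   "ACGTACGTAC")

  ov <- featureIntervals(c("c1", "c1"), c(2, 4), c(6, 9), "+", "rRNA", "16S")
  mm <- maskContigs(ctg, ov)
  # per-position membership oracle
  pos <- unique(c(2:6, 4:9))
  chars <- strsplit(as.character(mm[["c1"]]), "")[[1]]
  expect_identical(sum(chars == "N"), length(pos))
  expect_identical(which(chars == "N"), sort(pos))

  oob <- featureIntervals("c1", 8, 15, "+", "rRNA", "16S")
  expect_error(maskContigs(ctg, oob), class = "outOfBoundsError")
})

test_that("masking conserves length and unmasked characters on random inputs", {
  set.seed(5)
  for (i in 1:20) {
    len <- sample(50:200, 1)
    ctg <- Biostrings::DNAStringSet(stats::setNames(
      paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), "c1"))
    nf <- sample(1:5, 1)
    s <- sample.int(len - 10, nf)
    f <- featureIntervals(rep("c1", nf), s,
                          pmin(len, s + sample(3:30, nf, TRUE)), "+",
                          "tRNA", "t")
    m <- maskContigs(ctg, f)
    expect_identical(Biostrings::width(m), Biostrings::width(ctg))
    covered <- rep(FALSE, len)
    for (k in seq_len(nf))
      covered[GenomicRanges::start(f)[k]:GenomicRanges::end(f)[k]] <- TRUE
    orig <- strsplit(as.character(ctg[[1]]), "")[[1]]
    masked <- strsplit(as.character(m[[1]]), "")[[1]]
    expect_identical(masked[!covered], orig[!covered])
    expect_true(all(masked[covered] == "N"))
  }
})

test_that("ORF filter uses a strict 180 nt default threshold", {
  orfs <- orfCalls(c("g1", "g2", "g3"), "c1", c(1, 1, 1),
                   c(179, 180, 300), "+")
  kept <- filterOrfs(orfs)
  expect_identical(kept$gene_id, c("g2", "g3"))
  expect_identical(nrow(filterOrfs(orfs[0, ])), 0L)
  expect_identical(nrow(filterOrfs(orfs, 0)), 3L)
})

test_that("feature tables parse with validation of coordinates and types", {
  d <- localTmpDir()
  p <- file.path(d, "f.tsv")
  writeLines("c1\t10\t85\t+\ttRNA-Ala", p)
  f <- readFeatureTable(p, ftype = "tRNA")
  expect_identical(as.character(GenomicRanges::seqnames(f)), "c1")
  expect_identical(GenomicRanges::start(f), 10L)
  expect_identical(GenomicRanges::end(f), 85L)
  expect_identical(S4Vectors::mcols(f)$subtype, "tRNA-Ala")

  writeLines("c1\t12\t12\t+\tsingle", p)
  expect_identical(GenomicRanges::width(readFeatureTable(p, "CRISPR")), 1L)

  writeLines("c1\t85\t10\t+\tbad", p)
  expect_error(readFeatureTable(p, "tRNA"), class = "coordinateError")

  writeLines("c1\tten\t20\t+\tbad", p)
  expect_error(readFeatureTable(p, "tRNA"), class = "parseError")
})

test_that("rRNA genes inherit the lineage of their oracle-selected best hit", {
  refmap <- c(s1 = "d__Bacteria;p__Firmicutes;",
              s2 = "d__Archaea;p__Euryarchaeota;")
  one <- data.frame(query_id = "r1", subject_id = "s1", pct_identity = 99,
                    aln_len = 100, mismatch = 1, gapopen = 0, qstart = 1,
                    qend = 100, sstart = 1, send = 100, evalue = 1e-40,
                    bitscore = 180, qlen = 100, qcov = 100)
  expect_identical(classifyRrna(one, refmap), "d__Bacteria;p__Firmicutes;")
  expect_identical(classifyRrna(one[0, ], refmap), "")
  expect_error(classifyRrna(transform(one, subject_id = "sX"), refmap),
               class = "missingSubjectError")
  set.seed(9)
  for (i in 1:10) {
    n <- 20
    hits <- data.frame(query_id = "r1",
                       subject_id = sample(names(refmap), n, TRUE),
                       pct_identity = 90, aln_len = 100, mismatch = 0,
                       gapopen = 0, qstart = 1, qend = 100, sstart = 1,
                       send = 100, evalue = 10^runif(n, -50, -10),
                       bitscore = runif(n, 50, 200), qlen = 100, qcov = 100)
    expect_identical(classifyRrna(hits, refmap),
                     unname(refmap[oracleBestHit(hits)$subject_id]))
  }
})
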