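makeHit <- function(q = "g1", s = "s1", evalue = 1e-20, bits = 100,
                    qstart = 1, qend = 100, qlen = NA_integer_, pid = 95) {
  data.frame(query_id = q, subject_id = s, pct_identity = pid,
             aln_len = qend - qstart + 1, mismatch = 0, gapopen = 0,
             qstart = qstart, qend = qend, sstart = 1,
             send = qend - qstart + 1, evalue = evalue, bitscore = bits,
             qlen = qlen,
             qcov = if (is.na(qlen)) NA_real_ else
               100 * (qend - qstart + 1) / qlen,
             stringsAsFactors = FALSE)
}

test_that("12/13-column tabular hit files parse positionally with qcov", {
  d <- localTmpDir()
  p <- file.path(d, "hits.tsv")
  writeLines("g1\ts1\t100.00\t163\t0\t0\t1\t163\t1\t163\t1.4e-89\t320.5", p)
  h <- readPairwiseHits(p)
  expect_identical(h$subject_id, "s1")
  expect_identical(h$evalue, 1.4e-89)
  expect_true(is.na(h$qcov))

  writeLines("g1\ts1\t100.00\t163\t0\t0\t1\t163\t1\t163\t1.4e-89\t320.5\t163",
             p)
  h <- readPairwiseHits(p)
  expect_equal(h$qcov, 100)

  writeLines(character(), p)
  expect_identical(nrow(readPairwiseHits(p)), 0L)

  writeLines("g1\ts1\tonly-three", p)
  expect_error(readPairwiseHits(p), class = "parseError")
})

test_that("domtblout parses comments, repeated domains and the description tail", {
  d <- localTmpDir()
  p <- file.path(d, "dom.tbl")
  writeLines(c("# comment", "#"), p)
  expect_identical(nrow(readDomainHits(p, "Pfam")), 0L)

  ln <- function(from, to) paste(
    "Fer4", "PF00037.27", "60", "g1", "-", "163", "1e-12", "53.6", "0.1",
    "1", "2", "3e-08", "2e-07", "24.1", "0.1", "1", "20", from, to,
    from, to, "0.90", "4Fe-4S binding domain")
  writeLines(c("# header", ln(61, 80), ln(97, 118)), p)
  h <- readDomainHits(p, "Pfam")
  expect_identical(nrow(h), 2L)                 # repeated domain retained
  expect_identical(h$model_id, rep("PF00037.27", 2))
  expect_identical(h$model_name, rep("Fer4", 2))
  expect_identical(h$evalue, rep(2e-07, 2))     # i-evalue column
  expect_identical(h$ali_from, c(61L, 97L))
  expect_identical(h$description[1], "4Fe-4S binding domain")
})

test_that("best-hit selection matches the exhaustive-scan oracle", {
  expect_null(selectBestHit(makeHit()[0, ]))
  one <- makeHit()
  expect_identical(selectBestHit(one)$subject_id, "s1")
  two <- rbind(makeHit(s = "a", evalue = 1e-20),
               makeHit(s = "b", evalue = 1e-50))
  expect_identical(selectBestHit(two)$subject_id, "b")
  set.seed(3)
  for (i in 1:20) {
    n <- 100
    hits <- makeHit()[rep(1, n), ]
    hits$subject_id <- sprintf("s%03d", sample.int(30, n, TRUE))
    hits$evalue <- sample(c(1e-50, 1e-30, 1e-10), n, TRUE)
    hits$bitscore <- sample(c(100, 200), n, TRUE)
    expect_identical(selectBestHit(hits)$subject_id,
                     oracleBestHit(hits)$subject_id)
  }
})

test_that("significance filtering keeps hits at or below the cutoff", {
  h <- rbind(makeHit(evalue = 1e-7), makeHit(evalue = 1e-3))
  expect_identical(nrow(significanceFilter(h, 1e-5)), 1L)
  expect_identical(nrow(significanceFilter(h, Inf)), 2L)
  set.seed(8)
  ev <- 10^runif(50, -30, 0)
  h <- makeHit()[rep(1, 50), ]
  h$evalue <- ev
  expect_identical(nrow(significanceFilter(h, 1e-5)), sum(ev <= 1e-5))
})

test_that("FOAM model-name grammar yields KO and EC accessions", {
  p <- parseFoamName("KO:K00390_1.8.4.8")
  expect_identical(p$kos, "K00390")
  expect_identical(p$ecs, "1.8.4.8")
  expect_identical(parseFoamName("KO:K01234")$ecs, character(0))
  multi <- parseFoamName("KO:K00001,K00002_1.1.1.1")
  expect_identical(multi$kos, c("K00001", "K00002"))
  wild <- parseFoamName("KO:K00338_7.1.1.-")
  expect_identical(wild$ecs, "7.1.1.-")
  expect_error(parseFoamName("K00390"), class = "grammarError")
  set.seed(2)
  for (i in 1:20) {
    kos <- sprintf("K%05d", sample.int(99999, sample(1:3, 1)))
    ecs <- sprintf("%d.%d.%d.%d", sample(1:7, 1), sample(1:9, 1),
                   sample(1:9, 1), sample(1:99, 1))
    name <- paste0("KO:", paste(kos, collapse = ","),
                   if (runif(1) < 0.5) paste0("_", ecs) else "")
    got <- parseFoamName(name)
    expect_identical(got$kos, kos)
  }
})

test_that("merged records honour union ordering and the hypothetical rule", {
  gene <- orfCalls("g1", "c1", 1, 489, "+")
  refs <- referenceMaps(
    sprot = data.frame(subject_id = "sp|X|Y", description = "Widget kinase",
                       ec = "1.2.3.4", kos = "K11111", go = "GO:1;GO:2",
                       stringsAsFactors = FALSE),
    pfam = data.frame(model_name = "Dom1", description = "Widget domain",
                      stringsAsFactors = FALSE))
  foamHit <- data.frame(query_id = "g1", model_id = "H1",
                        model_name = "KO:K22222_5.6.7.8", db_tag = "FOAM",
                        evalue = 1e-10, dom_score = 40, seq_score = 45,
                        ali_from = 1, ali_to = 50, qlen = 163,
                        description = "-", stringsAsFactors = FALSE)
  b <- evidenceBundle("g1", sprot = makeHit(s = "sp|X|Y"),
                      domains = list(FOAM = foamHit))
  rec <- mergeEvidence(gene[1, ], b, refs)
  expect_identical(rec$product, "Widget kinase")
  expect_identical(rec$allec_ids, "1.2.3.4;5.6.7.8")  # SwissProt EC first
  expect_identical(rec$allko_ids, "K22222;K11111")    # FOAM KO first
  expect_identical(rec$go_terms, "GO:1;GO:2")

  empty <- mergeEvidence(gene[1, ], evidenceBundle("g1"), refs)
  expect_identical(empty$product, "hypothetical protein")
  expect_true(is.na(empty$allec_ids))
  expect_true(is.na(empty$sprot_target))

  pfHit <- data.frame(query_id = "g1", model_id = "PF1", model_name = "Dom1",
                      db_tag = "Pfam", evalue = 1e-9, dom_score = 30,
                      seq_score = 35, ali_from = 2, ali_to = 60, qlen = 163,
                      description = "", stringsAsFactors = FALSE)
  onlyPfam <- mergeEvidence(gene[1, ], evidenceBundle(
    "g1", domains = list(Pfam = pfHit)), refs)
  expect_identical(onlyPfam$product, "Widget domain")
  expect_true(is.na(onlyPfam$allec_ids))
})

test_that("merging never fabricates identifiers and is duplicate-free", {
  gene <- orfCalls("g1", "c1", 1, 300, "+")
  refs <- referenceMaps(
    sprot = data.frame(subject_id = "s1", description = "P",
                       ec = "1.1.1.1;2.2.2.2", kos = "K00001;K00002",
                       go = "GO:9", stringsAsFactors = FALSE))
  foam <- data.frame(query_id = "g1", model_id = "H", db_tag = "FOAM",
                     model_name = "KO:K00002_1.1.1.1", evalue = 1e-8,
                     dom_score = 1, seq_score = 1, ali_from = 1, ali_to = 9,
                     qlen = 100, description = "", stringsAsFactors = FALSE)
  rec <- mergeEvidence(gene[1, ], evidenceBundle(
    "g1", sprot = makeHit(s = "s1"), domains = list(FOAM = foam)), refs)
  ecs <- strsplit(rec$allec_ids, ";")[[1]]
  kos <- strsplit(rec$allko_ids, ";")[[1]]
  expect_false(anyDuplicated(ecs) > 0)
  expect_false(anyDuplicated(kos) > 0)
  expect_true(all(ecs %in% c("1.1.1.1", "2.2.2.2")))
  expect_true(all(kos %in% c("K00001", "K00002")))
})
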