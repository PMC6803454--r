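## Deterministic synthetic-data generator. Every input dialect consumed by
## the pipeline can be produced here with planted ground truth, so the full
## workflow and all property tests run with no external binaries or
## reference databases. One master seed fans out to independent per-file
## sub-seeds.

subSeed <- function(seed, k) as.integer((seed + k * 1000003) %% 2147483629)

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")

#' Generate random contigs with planted structural features
#'
#' Contigs are uniform random A/C/G/T sequences; tRNA/rRNA/CRISPR/CDS
#' intervals are planted without overlap (rejection sampling). CDS lengths
#' are multiples of 3 of at least 180 nt so the default ORF filter keeps
#' them all.
#'
#' @param seed integer master seed.
#' @param nContigs number of contigs.
#' @param lengthRange integer length range in bp.
#' @param featureDensity expected features per kb (default 0.6).
#' @return list: \code{contigs} (DNAStringSet), \code{features} (GRanges
#'   with ftype/subtype/ID), \code{orfs} (data.frame).
#' @export
genContigs <- function(seed, nContigs = 12, lengthRange = c(2000, 6000),
                       featureDensity = 0.6) {
  stopifnot(nContigs >= 1)
  set.seed(subSeed(seed, 1))
  lens <- sample(lengthRange[1]:lengthRange[2], nContigs, replace = TRUE)
  ids <- sprintf("ctg%03d", seq_len(nContigs))
  seqs <- vapply(lens, randSeq, "")
  contigs <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  feats <- list()
  for (ci in seq_len(nContigs)) {
    nFeat <- max(0L, stats::rpois(1, featureDensity * lens[ci] / 1000))
    placed <- IRanges::IRanges()
    tries <- 0
    while (length(placed) < nFeat) {
      tries <- tries + 1
      if (tries > 200 * max(1, nFeat))
        mStop("infeasibleDensityError",
              sprintf("cannot place %d non-overlapping features on contig %s",
                      nFeat, ids[ci]))
      ft <- sample(c("CDS", "CDS", "CDS", "tRNA", "rRNA", "CRISPR"), 1)
      w <- switch(ft,
                  CDS = 3 * sample(60:300, 1),        # 180..900 nt
                  tRNA = sample(70:90, 1),
                  rRNA = sample(110:160, 1),
                  CRISPR = sample(150:250, 1))
      if (w + 2 > lens[ci]) next
      s <- sample.int(lens[ci] - w, 1)
      cand <- IRanges::IRanges(s, s + w - 1)
      if (length(placed) &&
          length(IRanges::findOverlaps(cand, placed)) > 0) next
      placed <- c(placed, cand)
      sub <- switch(ft,
                    CDS = "", tRNA = paste0("tRNA-", sample(LETTERS, 1)),
                    rRNA = sample(c("16S", "23S", "5S"), 1),
                    CRISPR = "repeat_region")
      feats[[length(feats) + 1]] <- data.frame(
        contig_id = ids[ci], start = s, end = s + w - 1,
        strand = sample(c("+", "-"), 1), ftype = ft, subtype = sub,
        stringsAsFactors = FALSE)
    }
  }
  fdf <- do.call(rbind, feats) %||%
    data.frame(contig_id = character(), start = integer(), end = integer(),
               strand = character(), ftype = character(),
               subtype = character())
  fdf <- fdf[ordC(fdf$contig_id, fdf$start), , drop = FALSE]
  isCds <- fdf$ftype == "CDS"
  fdf$ID <- character(nrow(fdf))
  fdf$ID[isCds] <- sprintf("%s_g%03d", fdf$contig_id[isCds],
                           stats::ave(seq_len(sum(isCds)),
                                      fdf$contig_id[isCds],
                                      FUN = seq_along))
  fdf$ID[!isCds] <- sprintf("%s_%s%02d", fdf$contig_id[!isCds],
                            tolower(fdf$ftype[!isCds]),
                            stats::ave(seq_len(sum(!isCds)),
                                       fdf$contig_id[!isCds],
                                       FUN = seq_along))
  gr <- featureIntervals(fdf$contig_id, fdf$start, fdf$end, fdf$strand,
                         fdf$ftype, fdf$subtype)
  S4Vectors::mcols(gr)$ID <- fdf$ID
  orfs <- orfCalls(fdf$ID[isCds], fdf$contig_id[isCds], fdf$start[isCds],
                   fdf$end[isCds], fdf$strand[isCds])
  list(contigs = contigs, features = gr, orfs = orfs)
}

magLineagePool <- function(nMags) {
  stats::setNames(vapply(seq_len(nMags), function(m) sprintf(
    "d__Bacteria;p__Phylum%02d;c__Class%02d;o__Order%02d;f__Family%02d;g__Genus%02d;s__Species%02d;",
    m, m, m, m, m, m), ""), sprintf("MAG%02d", seq_len(nMags)))
}

#' Plant per-gene lineages with a known contamination fraction
#'
#' Each MAG's genes inherit the MAG lineage except a planted fraction
#' \code{q}, which inherit the next MAG's lineage (differing at every
#' rank, genus included). The realized fraction is
#' \code{round(q * n) / n} for each MAG, reported back exactly.
#'
#' @param geneIds character gene ids.
#' @param magOf named character gene id -> MAG id.
#' @param magLineage named character MAG id -> lineage string.
#' @param q contamination fraction, scalar or named per MAG.
#' @param seed integer seed for choosing which genes are contaminated.
#' @return list: \code{lineage} (named per gene), \code{realizedQ} (named
#'   per MAG).
#' @export
genMagLineages <- function(geneIds, magOf, magLineage, q = 0, seed = 1) {
  set.seed(subSeed(seed, 2))
  mags <- names(magLineage)
  if (is.null(names(q))) q <- stats::setNames(rep_len(q, length(mags)), mags)
  lineage <- stats::setNames(magLineage[magOf[geneIds]], geneIds)
  realized <- stats::setNames(numeric(length(mags)), mags)
  for (mi in seq_along(mags)) {
    m <- mags[mi]
    gs <- geneIds[magOf[geneIds] == m]
    if (!length(gs)) next
    k <- round(q[[m]] * length(gs))
    realized[m] <- k / length(gs)
    if (k > 0) {
      other <- magLineage[mags[mi %% length(mags) + 1]]
      contaminated <- sample(gs, k)
      lineage[contaminated] <- other
    }
  }
  list(lineage = lineage, realizedQ = realized)
}

#' Generate a pathway world with a provably unique minimum cover
#'
#' Builds pathway definitions in which each planted pathway owns at least
#' one private observed family (a family in no other pathway), so every
#' cover must contain all planted pathways and the planted set is the
#' unique minimum cover. Every observed family is a member of at least one
#' planted pathway. For worlds of at most 12 pathways the uniqueness is
#' re-verified by exhaustive subset enumeration at generation time.
#'
#' @param seed integer seed.
#' @param nPathways total pathways (>= 2).
#' @param nFamilies total family ids in the world.
#' @param coverSize number of planted pathways (default 3).
#' @return list: \code{defs} (data.frame like \code{readPathwayDefs}),
#'   \code{observed} (character), \code{planted} (character pathway ids).
#' @export
genPathwayWorld <- function(seed, nPathways = 8, nFamilies = 24,
                            coverSize = 3) {
  stopifnot(nPathways >= 2, coverSize >= 1, coverSize <= nPathways,
            nFamilies >= 2 * coverSize)
  set.seed(subSeed(seed, 3))
  fams <- sprintf("K%05d", sample(10000:99999, nFamilies))
  pids <- sprintf("map%04d", seq_len(nPathways))
  planted <- sortC(sample(pids, coverSize))
  private <- fams[seq_len(coverSize)]            # one private family each
  rest <- fams[-seq_len(coverSize)]
  members <- vector("list", nPathways)
  names(members) <- pids
  for (p in pids) {
    pool <- sample(rest, sample(3:6, 1))
    members[[p]] <- unique(pool)
  }
  for (i in seq_len(coverSize))
    members[[planted[i]]] <- unique(c(private[i], members[[planted[i]]]))
  ## observed = private families + a shared sample of planted members
  shared <- unique(unlist(lapply(planted, function(p)
    sample(members[[p]], min(2, length(members[[p]]))))))
  observed <- sortC(unique(c(private, shared)))
  ## keep only observed families that planted pathways can cover (true by
  ## construction) and ensure privates remain private
  for (p in setdiff(pids, planted))
    members[[p]] <- setdiff(members[[p]], private)
  defs <- data.frame(pathway_id = pids,
                     name = sprintf("Pathway %s", pids),
                     stringsAsFactors = FALSE)
  defs$members <- unname(members)
  if (nPathways <= 12) {
    recon <- reconstructMinimal(observed, defs, mode = "exact")
    stopifnot(identical(keptPathways(recon), planted))
  }
  list(defs = defs, observed = observed, planted = planted)
}

evalueStr <- function(x) sprintf("%.2e", x)

pairwiseLine <- function(q, s, pid, alen, qlen, evalue, bits) {
  paste(q, s, sprintf("%.2f", pid), alen, 0, 0, 1, alen,
        1, alen, evalueStr(evalue), sprintf("%.1f", bits), qlen,
        sep = "\t")
}

domtbloutLine <- function(model, acc, gene, qlen, seqScore, iE, domScore,
                          aliFrom, aliTo, desc) {
  paste(model, acc, 120, gene, "-", qlen, evalueStr(iE / 10),
        sprintf("%.1f", seqScore), "0.1", 1, 1, evalueStr(iE),
        evalueStr(iE), sprintf("%.1f", domScore), "0.1",
        1, aliTo - aliFrom + 1, aliFrom, aliTo, aliFrom, aliTo, "0.90",
        desc, sep = " ")
}

#' Generate homology evidence files with planted best hits
#'
#' Every planted CDS gets a GenomeDB best hit to its own subject (whose
#' lineage is the gene's planted lineage), drawn at a lower E-value than
#' any decoy; decoy hits to other subjects appear at \code{decoyRate}.
#' Subsets of genes receive SwissProt hits (with EC/KO/GO metadata), Pfam
#' and TIGRFAM domains, and FOAM domains carrying the gene's planted KO
#' family; a planted fraction of genes receives no functional evidence at
#' all and must come out "hypothetical protein".
#'
#' @param seed integer seed.
#' @param orfs data.frame of planted CDS calls.
#' @param lineage named character gene -> lineage string.
#' @param observedFamilies KO family ids to distribute over genes (every
#'   family gets at least one supporting gene).
#' @param decoyRate probability of an extra decoy GenomeDB hit per gene.
#' @param identityNoise sd of the identity jitter (percent).
#' @param hypotheticalRate fraction of genes with no functional evidence.
#' @return list of tables and maps (see source) plus \code{truth} with the
#'   planted per-gene assignments.
#' @export
genEvidence <- function(seed, orfs, lineage, observedFamilies = character(),
                        decoyRate = 0.1, identityNoise = 5,
                        hypotheticalRate = 0.1) {
  set.seed(subSeed(seed, 4))
  genes <- orfs$gene_id
  n <- length(genes)
  qlen <- pmax(1L, orfs$nt_length %/% 3L)
  subj <- sprintf("SUBJ|%s", genes)
  refmap <- stats::setNames(unname(lineage[genes]), subj)
  decoySubj <- "SUBJ|decoy"
  refmap[decoySubj] <- "d__Bacteria;p__DecoyPhylum;"
  hypo <- stats::runif(n) < hypotheticalRate
  ident <- function(k) pmin(100, pmax(30,
    100 - abs(stats::rnorm(k, 0, identityNoise))))

  genomedb <- character(); sprot <- character()
  pfam <- character(); tigrfam <- character(); foam <- character()
  koMap <- character()
  sprotSubjects <- character()
  geneKo <- stats::setNames(rep(NA_character_, n), genes)

  ## distribute observed KO families round-robin so every family gets at
  ## least one supporting gene (a gene may carry several FOAM families)
  eligible <- genes[!hypo]
  famsOf <- stats::setNames(vector("list", length(eligible)), eligible)
  if (length(observedFamilies) && length(eligible)) {
    for (i in seq_along(observedFamilies)) {
      g <- eligible[(i - 1) %% length(eligible) + 1]
      famsOf[[g]] <- c(famsOf[[g]], observedFamilies[i])
    }
    bare <- eligible[lengths(famsOf[eligible]) == 0]
    pick <- bare[stats::runif(length(bare)) < 0.6]
    for (g in pick)
      famsOf[[g]] <- sample(observedFamilies, 1)
  }

  for (i in seq_len(n)) {
    g <- genes[i]
    trueE <- 10^stats::runif(1, -90, -60)
    genomedb <- c(genomedb, pairwiseLine(g, subj[i], ident(1),
                                         qlen[i], qlen[i], trueE,
                                         200 + stats::runif(1, 0, 50)))
    if (stats::runif(1) < decoyRate)
      genomedb <- c(genomedb, pairwiseLine(g, decoySubj, ident(1),
                                           qlen[i], qlen[i],
                                           10^stats::runif(1, -30, -10),
                                           50 + stats::runif(1, 0, 20)))
    if (hypo[i]) next
    if (stats::runif(1) < 0.7) {
      sp <- sprintf("sp|P%05d|GENE_%s", i, toupper(substr(g, 1, 6)))
      sprotSubjects <- c(sprotSubjects, sp)
      sprot <- c(sprot, pairwiseLine(g, sp, ident(1), qlen[i], qlen[i],
                                     10^stats::runif(1, -80, -40),
                                     150 + stats::runif(1, 0, 50)))
    }
    if (stats::runif(1) < 0.5)
      pfam <- c(pfam, domtbloutLine(sprintf("PfamDom%02d", sample(1:20, 1)),
                                    sprintf("PF%05d.1", sample(1:99999, 1)),
                                    g, qlen[i], 60, 10^stats::runif(1, -20, -8),
                                    40, 5, min(qlen[i], 60), "-"))
    if (stats::runif(1) < 0.3)
      tigrfam <- c(tigrfam, domtbloutLine(
        sprintf("TigrDom%02d", sample(1:10, 1)),
        sprintf("TIGR%05d", sample(1:99999, 1)), g, qlen[i], 90,
        10^stats::runif(1, -30, -10), 70, 3, min(qlen[i], 80), "-"))
    gf <- famsOf[[g]]
    if (length(gf)) {
      geneKo[g] <- paste(gf, collapse = ";")
      for (fam in gf) {
        foam <- c(foam, domtbloutLine(sprintf("KO:%s", fam),
                                      sprintf("HMMsoil%03d",
                                              sample(1:999, 1)),
                                      g, qlen[i], 45,
                                      10^stats::runif(1, -15, -6), 35, 2,
                                      min(qlen[i], 50), "-"))
        koMap <- c(koMap, paste(g, fam, sep = "\t"))
      }
    }
  }
  sprotMeta <- data.frame(
    subject_id = unique(sprotSubjects), stringsAsFactors = FALSE)
  ns <- nrow(sprotMeta)
  sprotMeta$description <- sprintf("Synthetic protein %03d", seq_len(ns))
  sprotMeta$ec <- ifelse(stats::runif(ns) < 0.5,
                         sprintf("%d.%d.%d.%d", sample(1:7, ns, TRUE),
                                 sample(1:9, ns, TRUE), sample(1:9, ns, TRUE),
                                 sample(1:99, ns, TRUE)), "")
  sprotMeta$kos <- ifelse(stats::runif(ns) < 0.5,
                          sprintf("K%05d", sample(10000:99999, ns)), "")
  sprotMeta$go <- sprintf("GO:%07d", sample(1:9999999, ns))
  pfamMeta <- data.frame(model_name = sprintf("PfamDom%02d", 1:20),
                         description = sprintf("Pfam domain %02d", 1:20),
                         stringsAsFactors = FALSE)
  tigrfamMeta <- data.frame(
    model_name = sprintf("TigrDom%02d", 1:10),
    description = sprintf("TIGRFAM family %02d", 1:10),
    go = sprintf("GO:%07d", sample(1:9999999, 10)),
    mainrole = "Energy metabolism", sub1role = "Electron transport",
    stringsAsFactors = FALSE)
  list(genomedb = genomedb, sprot = sprot, pfam = pfam, tigrfam = tigrfam,
       foam = foam, koMap = sortC(koMap), refmap = refmap,
       sprotMeta = sprotMeta, pfamMeta = pfamMeta,
       tigrfamMeta = tigrfamMeta,
       truth = list(hypothetical = genes[hypo], geneKo = geneKo))
}

#' Generate depth and spectral-count tables
#'
#' MetaBat-dialect depth file (mean + variance column pairs per sample;
#' totalAvgDepth is the sum of the per-sample means) and a spectral count
#' TSV. Replicate samples share a per-contig (per-gene) base value and
#' differ by multiplicative log-normal noise (depths) or a Poisson-like
#' integer jitter (spectral counts); zero noise gives identical replicates.
#'
#' @param seed integer seed.
#' @param contigs \code{DNAStringSet}.
#' @param geneIds gene ids for the spectral table.
#' @param nSamples number of replicate samples (default 3).
#' @param replicateNoise log-normal sd / jitter scale (default 0.1).
#' @return list: \code{depthLines}, \code{spectralLines}, \code{samples},
#'   \code{baseDepth} (named per contig).
#' @export
genDepthSpectral <- function(seed, contigs, geneIds, nSamples = 3,
                             replicateNoise = 0.1) {
  stopifnot(nSamples >= 1)
  set.seed(subSeed(seed, 5))
  samples <- sprintf("sample%d", seq_len(nSamples))
  base <- stats::setNames(stats::rlnorm(length(contigs), log(40), 0.8),
                          names(contigs))
  d <- sapply(seq_len(nSamples), function(j)
    base * exp(stats::rnorm(length(base), 0, replicateNoise)))
  d <- matrix(d, nrow = length(base))
  hdr <- paste(c("contigName", "contigLen", "totalAvgDepth",
                 as.vector(rbind(paste0(samples, ".bam"),
                                 paste0(samples, ".bam-var")))),
               collapse = "\t")
  rows <- vapply(seq_along(contigs), function(i)
    paste(c(names(contigs)[i], Biostrings::width(contigs)[i],
            fmtDepth(sum(d[i, ])),
            as.vector(rbind(fmtDepth(d[i, ]), fmtDepth(d[i, ] * 0.1)))),
          collapse = "\t"), "")
  baseExpr <- stats::setNames(stats::rlnorm(length(geneIds), log(20), 1),
                              geneIds)
  expressed <- geneIds[stats::runif(length(geneIds)) < 0.6]
  e <- sapply(seq_len(nSamples), function(j)
    round(baseExpr[expressed] *
            exp(stats::rnorm(length(expressed), 0, replicateNoise)), 2))
  e <- matrix(e, nrow = length(expressed))
  sHdr <- paste(c("gene_id", samples), collapse = "\t")
  sRows <- vapply(seq_along(expressed), function(i)
    paste(c(expressed[i], sprintf("%.2f", e[i, ])), collapse = "\t"), "")
  list(depthLines = c(hdr, rows), spectralLines = c(sHdr, sRows),
       samples = samples, baseDepth = base)
}

#' Generate a complete fixture directory
#'
#' Emits every input dialect the pipeline consumes, with the planted
#' ground truth serialized alongside as \code{truth.json}: contig FASTA,
#' truth and feature tables, competing rRNA model hits, homology evidence
#' (pairwise tabular and domtblout), reference maps, bin map, pathway
#' definitions and gene-family maps, MetaBat-dialect depth table, and
#' spectral counts. The same seed always produces byte-identical files.
#'
#' The defaults emulate a small mock community: a dozen contigs of 2-6 kb
#' binned into 3 MAGs, 3 replicate samples with 10\% multiplicative depth
#' noise, an 8-pathway world with a planted 3-pathway minimum cover, 10\%
#' decoy hits, and no binning contamination unless requested.
#'
#' @param dir output directory (created).
#' @param seed integer master seed.
#' @param nContigs,lengthRange,featureDensity see \code{genContigs}.
#' @param nMags number of MAGs (contigs assigned round-robin).
#' @param contamination per-MAG contamination fraction (scalar or named).
#' @param nPathways,nFamilies,coverSize see \code{genPathwayWorld}.
#' @param nSamples,replicateNoise see \code{genDepthSpectral}.
#' @param decoyRate,identityNoise,hypotheticalRate see \code{genEvidence}.
#' @return the planted truth (also written to \code{truth.json}),
#'   invisibly.
#' @export
fixtureSet <- function(dir, seed = 1, nContigs = 12,
                       lengthRange = c(2000, 6000), featureDensity = 0.6,
                       nMags = 3, contamination = 0, nPathways = 8,
                       nFamilies = 24, coverSize = 3, nSamples = 3,
                       replicateNoise = 0.1, decoyRate = 0.1,
                       identityNoise = 5, hypotheticalRate = 0.1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gc0 <- genContigs(seed, nContigs, lengthRange, featureDensity)
  contigs <- gc0$contigs; features <- gc0$features; orfs <- gc0$orfs

  mags <- sprintf("MAG%02d", seq_len(nMags))
  binmap <- stats::setNames(mags[(seq_along(contigs) - 1) %% nMags + 1],
                            names(contigs))
  magLineage <- magLineagePool(nMags)
  magOf <- stats::setNames(binmap[orfs$contig_id], orfs$gene_id)
  ml <- genMagLineages(orfs$gene_id, magOf, magLineage, contamination, seed)

  world <- genPathwayWorld(seed, nPathways, nFamilies, coverSize)
  ev <- genEvidence(seed, orfs, ml$lineage, world$observed, decoyRate,
                    identityNoise, hypotheticalRate)
  ds <- genDepthSpectral(seed, contigs, orfs$gene_id, nSamples,
                         replicateNoise)

  ## competing rRNA model hits: true model lowest E, plus overlapping decoy
  ## models on the same region
  set.seed(subSeed(seed, 6))
  isR <- S4Vectors::mcols(features)$ftype == "rRNA"
  rr <- features[isR]
  modelLines <- character()
  for (i in seq_along(rr)) {
    ctg <- as.character(GenomicRanges::seqnames(rr))[i]
    s <- GenomicRanges::start(rr)[i]; e <- GenomicRanges::end(rr)[i]
    st <- as.character(GenomicRanges::strand(rr))[i]
    rt <- S4Vectors::mcols(rr)$subtype[i]
    trueE <- 10^stats::runif(1, -40, -25)
    modelLines <- c(modelLines, paste(ctg, "Bacteria", rt, s, e, st,
                                      evalueStr(trueE), "80.0", sep = "\t"))
    for (dm in sample(c("Archaea", "Eukaryota"), sample(0:2, 1)))
      modelLines <- c(modelLines, paste(
        ctg, dm, rt, max(1, s - sample(0:20, 1)), e + sample(0:20, 1), st,
        evalueStr(10^stats::runif(1, -20, -8)), "40.0", sep = "\t"))
  }
  ## rRNA classification evidence: each rRNA gene hits a reference subject
  ## carrying its MAG's lineage
  rrnaRefmap <- stats::setNames(unname(magLineage[binmap[
    as.character(GenomicRanges::seqnames(rr))]]),
    sprintf("SILVA|%s", S4Vectors::mcols(rr)$ID))
  rrnaHitLines <- vapply(seq_along(rr), function(i)
    pairwiseLine(S4Vectors::mcols(rr)$ID[i],
                 sprintf("SILVA|%s", S4Vectors::mcols(rr)$ID[i]),
                 97, 100, 100, 1e-50, 180), "")

  ## ---- write everything ---------------------------------------------------
  writeContigFasta(contigs, file.path(dir, "contigs.fna"))
  writeGff3(features, records = NULL, path = file.path(dir, "truth.gff3"))
  featTsv <- function(sel, path) {
    f <- features[S4Vectors::mcols(features)$ftype == sel]
    writeLinesC(vapply(seq_along(f), function(i)
      paste(as.character(GenomicRanges::seqnames(f))[i],
            GenomicRanges::start(f)[i], GenomicRanges::end(f)[i],
            as.character(GenomicRanges::strand(f))[i],
            S4Vectors::mcols(f)$subtype[i], sep = "\t"), ""), path)
  }
  featTsv("tRNA", file.path(dir, "trna.tsv"))
  featTsv("CRISPR", file.path(dir, "crispr.tsv"))
  writeLinesC(modelLines, file.path(dir, "rrna_model_hits.tsv"))
  writeLinesC(rrnaHitLines, file.path(dir, "rrna_hits.tsv"))
  writeLinesC(paste(names(rrnaRefmap), rrnaRefmap, sep = "\t"),
              file.path(dir, "rrna_refmap.tsv"))
  writeLinesC(vapply(seq_len(nrow(orfs)), function(i)
    paste(orfs$gene_id[i], orfs$contig_id[i], orfs$start[i], orfs$end[i],
          orfs$strand[i], sep = "\t"), ""), file.path(dir, "orfs.tsv"))
  writeLinesC(ev$genomedb, file.path(dir, "genomedb.tsv"))
  writeLinesC(ev$sprot, file.path(dir, "sprot.tsv"))
  writeLinesC(ev$pfam, file.path(dir, "pfam.domtblout"))
  writeLinesC(ev$tigrfam, file.path(dir, "tigrfam.domtblout"))
  writeLinesC(ev$foam, file.path(dir, "foam.domtblout"))
  writeLinesC(paste(names(ev$refmap), ev$refmap, sep = "\t"),
              file.path(dir, "refmap.tsv"))
  writeMetaTsv <- function(df, path)
    writeLinesC(c(paste(colnames(df), collapse = "\t"),
                  do.call(paste, c(as.list(df), sep = "\t"))), path)
  writeMetaTsv(ev$sprotMeta, file.path(dir, "sprot_meta.tsv"))
  writeMetaTsv(ev$pfamMeta, file.path(dir, "pfam_meta.tsv"))
  writeMetaTsv(ev$tigrfamMeta, file.path(dir, "tigrfam_meta.tsv"))
  writeLinesC(paste(names(binmap), binmap, sep = "\t"),
              file.path(dir, "binmap.tsv"))
  writeLinesC(vapply(seq_len(nrow(world$defs)), function(i)
    paste(world$defs$pathway_id[i], world$defs$name[i],
          paste(world$defs$members[[i]], collapse = ","), sep = "\t"), ""),
    file.path(dir, "pathways.tsv"))
  writeLinesC(ev$koMap, file.path(dir, "ko_map.tsv"))
  writeLinesC(ds$depthLines, file.path(dir, "depth.txt"))
  writeLinesC(ds$spectralLines, file.path(dir, "plevel.tsv"))

  truth <- list(
    seed = seed,
    params = list(nContigs = nContigs, nMags = nMags,
                  nSamples = nSamples, replicateNoise = replicateNoise,
                  decoyRate = decoyRate, contamination = contamination,
                  featureDensity = featureDensity),
    contigs = as.list(stats::setNames(Biostrings::width(contigs),
                                      names(contigs))),
    featureCounts = as.list(table(S4Vectors::mcols(features)$ftype)),
    binmap = as.list(binmap),
    magLineage = as.list(magLineage),
    geneLineage = as.list(ml$lineage),
    realizedContamination = as.list(ml$realizedQ),
    contaminationRank = "genus",
    pathways = list(planted = world$planted, observed = world$observed),
    hypothetical = ev$truth$hypothetical,
    geneKo = as.list(ev$truth$geneKo[!is.na(ev$truth$geneKo)]),
    samples = ds$samples)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(truth)
}
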