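#' Read a two-column id-to-value TSV (lineage map, bin map)
#'
#' @param path file path.
#' @return named character vector.
#' @export
readIdMap <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(stats::setNames(character(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2))
    mStop("parseError",
          sprintf("map line %d: expected 2 columns",
                  which(lengths(parts) < 2)[1]))
  stats::setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
}

#' Read an ORF call table
#'
#' TSV: gene_id, contig_id, start, end, strand (one predicted
#' protein-coding gene per line, 1-based inclusive coordinates).
#'
#' @param path file path.
#' @return data.frame from \code{orfCalls}.
#' @export
readOrfTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(orfCalls(character(), character(), integer(), integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 5))
    mStop("parseError", "ORF table: expected 5 columns")
  f <- function(i) vapply(parts, `[`, "", i)
  orfCalls(f(1), f(2), as.integer(f(3)), as.integer(f(4)), f(5))
}

readMetaTsv <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- lapply(body, function(l)
    strsplit(paste0(l, "\t\x01"), "\t", fixed = TRUE)[[1]])
  as.data.frame(lapply(stats::setNames(seq_along(hdr), hdr), function(j)
    vapply(parts, `[`, "", j)), stringsAsFactors = FALSE,
    check.names = FALSE)
}

#' Assemble a pipeline run configuration
#'
#' @param contigs input contig FASTA.
#' @param outdir output directory.
#' @param trna,crispr optional structural-feature TSVs.
#' @param rrnaModelHits optional competing rRNA model hit TSV.
#' @param rrnaHits,rrnaRefmap optional rRNA classification evidence.
#' @param orfs ORF call TSV.
#' @param sprot,genomedb pairwise hit tables.
#' @param pfam,tigrfam,foam domtblout tables.
#' @param sprotMeta,pfamMeta,tigrfamMeta reference metadata TSVs.
#' @param refmap GenomeDB subject -> lineage TSV.
#' @param binmap optional contig -> MAG TSV.
#' @param pathwayDefs,koMap optional pathway world inputs.
#' @param depthFile optional MetaBat depth table.
#' @param spectralFile optional spectral count table.
#' @param minContigLen minimum contig length (default 200).
#' @param minOrfNt minimum ORF length in nt (default 180).
#' @param maxEvaluePairwise,maxEvalueDomain significance cutoffs.
#' @param weighting taxa/function profile weighting: "depth" (default when
#'   a depth file is given), "count", or "depth_x_len".
#' @param force rerun all stages even when cached outputs match.
#' @return list of class \code{runConfig}.
#' @export
newRunConfig <- function(contigs, outdir, trna = NULL, crispr = NULL,
                         rrnaModelHits = NULL, rrnaHits = NULL,
                         rrnaRefmap = NULL, orfs = NULL, sprot = NULL,
                         genomedb = NULL, pfam = NULL, tigrfam = NULL,
                         foam = NULL, sprotMeta = NULL, pfamMeta = NULL,
                         tigrfamMeta = NULL, refmap = NULL, binmap = NULL,
                         pathwayDefs = NULL, koMap = NULL,
                         depthFile = NULL, spectralFile = NULL,
                         minContigLen = 200, minOrfNt = 180,
                         maxEvaluePairwise = 1e-5, maxEvalueDomain = 1e-5,
                         weighting = NULL, force = FALSE) {
  stopifnot(minContigLen >= 0, minOrfNt >= 0)
  weighting <- weighting %||% if (!is.null(depthFile)) "depth" else "count"
  weighting <- match.arg(weighting, c("depth", "count", "depth_x_len"))
  structure(as.list(environment()), class = "runConfig")
}

#' Point a run configuration at a fixture directory
#'
#' Convenience constructor wiring every file emitted by
#' \code{\link{fixtureSet}} into a \code{runConfig}.
#'
#' @param fixtureDir directory written by \code{fixtureSet}.
#' @param outdir pipeline output directory.
#' @param ... further arguments to \code{newRunConfig}.
#' @return \code{runConfig}.
#' @export
fixtureRunConfig <- function(fixtureDir, outdir, ...) {
  p <- function(f) file.path(fixtureDir, f)
  newRunConfig(contigs = p("contigs.fna"), outdir = outdir,
               trna = p("trna.tsv"), crispr = p("crispr.tsv"),
               rrnaModelHits = p("rrna_model_hits.tsv"),
               rrnaHits = p("rrna_hits.tsv"),
               rrnaRefmap = p("rrna_refmap.tsv"), orfs = p("orfs.tsv"),
               sprot = p("sprot.tsv"), genomedb = p("genomedb.tsv"),
               pfam = p("pfam.domtblout"), tigrfam = p("tigrfam.domtblout"),
               foam = p("foam.domtblout"), sprotMeta = p("sprot_meta.tsv"),
               pfamMeta = p("pfam_meta.tsv"),
               tigrfamMeta = p("tigrfam_meta.tsv"), refmap = p("refmap.tsv"),
               binmap = p("binmap.tsv"), pathwayDefs = p("pathways.tsv"),
               koMap = p("ko_map.tsv"), depthFile = p("depth.txt"),
               spectralFile = p("plevel.tsv"), ...)
}

## Stage driver: a stage is skipped when its recorded parameter hash
## matches and every recorded output file still exists; otherwise it runs
## and its state is re-recorded.
runStage <- function(config, name, paramSubset, outputs, fun, log) {
  stateDir <- file.path(config$outdir, ".state")
  dir.create(stateDir, recursive = TRUE, showWarnings = FALSE)
  stateFile <- file.path(stateDir, paste0(name, ".json"))
  hash <- paramHash(paramSubset)
  outPaths <- file.path(config$outdir, outputs)
  if (!config$force && file.exists(stateFile)) {
    st <- jsonlite::read_json(stateFile)
    if (identical(st$hash, hash) && all(file.exists(outPaths))) {
      log(sprintf("[%s] skipped (cached, hash %s)", name, hash))
      return(invisible(hash))
    }
  }
  log(sprintf("[%s] running (hash %s)", name, hash))
  fun()
  jsonlite::write_json(list(hash = hash, outputs = outputs,
                            status = "done"),
                       stateFile, auto_unbox = TRUE)
  invisible(hash)
}

#' Run the full annotation pipeline
#'
#' Executes the stages preprocess, structural, homology-merge, taxonomy,
#' pathways, abundance, and reports in order, persisting every stage's
#' outputs under \code{outdir}. On a rerun with the same inputs and
#' parameters each stage whose recorded parameter hash and outputs are
#' intact is skipped, so resumed runs reproduce fresh runs byte for byte;
#' any parameter change re-executes the affected stage and everything
#' downstream (stage hashes chain).
#'
#' @param config \code{runConfig} from \code{newRunConfig} or
#'   \code{fixtureRunConfig}.
#' @return list: paths of the emitted reports, the stage hashes, and the
#'   in-memory products (records, tree, reconstruction, profiles).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(config$outdir, "run.log")
  logCon <- file(logFile, open = "a")
  on.exit(close(logCon))
  log <- function(msg) {
    writeLines(msg, logCon)
    invisible(msg)
  }
  log(sprintf("run: minContigLen=%d minOrfNt=%d evaluePairwise=%g evalueDomain=%g weighting=%s",
              config$minContigLen, config$minOrfNt,
              config$maxEvaluePairwise, config$maxEvalueDomain,
              config$weighting))
  out <- function(f) file.path(config$outdir, f)

  ## --- preprocess ----------------------------------------------------------
  h1 <- runStage(config, "preprocess",
                 list(contigs = config$contigs,
                      minContigLen = config$minContigLen),
                 c("cleaned.fna", "preprocess_report.tsv"), function() {
    pp <- preprocessContigs(config$contigs, config$minContigLen)
    writeContigFasta(pp$contigs, out("cleaned.fna"))
    writePreprocessReport(pp$report, out("preprocess_report.tsv"))
  }, log)
  contigs <- Biostrings::readDNAStringSet(out("cleaned.fna"))
  names(contigs) <- sub("\\s.*$", "", names(contigs))

  ## --- structural ----------------------------------------------------------
  h2 <- runStage(config, "structural",
                 list(prev = h1, trna = config$trna, crispr = config$crispr,
                      rrnaModelHits = config$rrnaModelHits,
                      rrnaHits = config$rrnaHits,
                      rrnaRefmap = config$rrnaRefmap, orfs = config$orfs,
                      minOrfNt = config$minOrfNt),
                 c("masked.fna", "features.gff3", "orfs_kept.tsv",
                   "rrna_class.tsv"), function() {
    feats <- featureIntervals(character(), integer(), integer(),
                              character(), character(), character())
    addTsv <- function(path, ftype) {
      if (is.null(path)) return()
      f <- readFeatureTable(path, ftype = ftype)
      S4Vectors::mcols(f)$ID <- sprintf("%s_%s%03d",
        as.character(GenomicRanges::seqnames(f)), tolower(ftype),
        seq_along(f))
      feats <<- suppressWarnings(c(feats, f))
    }
    addTsv(config$trna, "tRNA")
    addTsv(config$crispr, "CRISPR")
    rrnaClass <- data.frame(id = character(), lineage = character())
    mhLines <- if (is.null(config$rrnaModelHits)) character() else
      readLines(config$rrnaModelHits)
    if (length(mhLines)) {
      raw <- utils::read.table(text = mhLines, sep = "\t",
                               stringsAsFactors = FALSE,
                               col.names = c("contig_id", "domain_model",
                                             "rna_type", "start", "end",
                                             "strand", "evalue", "score"))
      res <- resolveModelHits(raw)
      rf <- featureIntervals(res$contig_id, res$start, res$end, res$strand,
                             "rRNA", res$rna_type)
      S4Vectors::mcols(rf)$ID <- sprintf("%s_rrna%03d",
        res$contig_id, stats::ave(seq_len(nrow(res)), res$contig_id,
                                  FUN = seq_along))
      feats <- suppressWarnings(c(feats, rf))
      if (!is.null(config$rrnaHits) && !is.null(config$rrnaRefmap)) {
        hits <- readPairwiseHits(config$rrnaHits)
        refm <- readIdMap(config$rrnaRefmap)
        ## rRNA hit query ids refer to the planted feature ids; classify
        ## by best hit per query
        rrnaClass <- do.call(rbind, lapply(unique(hits$query_id),
          function(q) data.frame(
            id = q,
            lineage = classifyRrna(hits[hits$query_id == q, ], refm,
                                   strict = FALSE),
            stringsAsFactors = FALSE))) %||% rrnaClass
      }
    }
    noncoding <- feats[S4Vectors::mcols(feats)$ftype != "CDS"]
    masked <- maskContigs(contigs, noncoding)
    writeContigFasta(masked, out("masked.fna"))
    orfs <- filterOrfs(readOrfTable(config$orfs), config$minOrfNt)
    cdsGr <- featureIntervals(orfs$contig_id, orfs$start, orfs$end,
                              orfs$strand, "CDS", "")
    S4Vectors::mcols(cdsGr)$ID <- orfs$gene_id
    writeGff3(suppressWarnings(c(feats, cdsGr)), records = NULL, path = out("features.gff3"))
    writeLinesC(vapply(seq_len(nrow(orfs)), function(i)
      paste(orfs$gene_id[i], orfs$contig_id[i], orfs$start[i],
            orfs$end[i], orfs$strand[i], sep = "\t"), ""),
      out("orfs_kept.tsv"))
    writeLinesC(c("id\tlineage",
                  if (nrow(rrnaClass)) paste(rrnaClass$id,
                                             rrnaClass$lineage,
                                             sep = "\t")),
                out("rrna_class.tsv"))
  }, log)
  orfs <- readOrfTable(out("orfs_kept.tsv"))

  ## --- homology-merge ------------------------------------------------------
  h3 <- runStage(config, "homology",
                 list(prev = h2, sprot = config$sprot,
                      genomedb = config$genomedb, pfam = config$pfam,
                      tigrfam = config$tigrfam, foam = config$foam,
                      refmap = config$refmap,
                      maxEvaluePairwise = config$maxEvaluePairwise,
                      maxEvalueDomain = config$maxEvalueDomain),
                 "annotations.tsv", function() {
    loadPairwise <- function(p) if (is.null(p)) NULL else readPairwiseHits(p)
    loadDom <- function(p, tag) if (is.null(p)) NULL else
      readDomainHits(p, tag)
    sprotH <- loadPairwise(config$sprot)
    genomedbH <- loadPairwise(config$genomedb)
    doms <- list(Pfam = loadDom(config$pfam, "Pfam"),
                 TIGRFAM = loadDom(config$tigrfam, "TIGRFAM"),
                 FOAM = loadDom(config$foam, "FOAM"))
    refs <- referenceMaps(
      sprot = if (is.null(config$sprotMeta)) NULL else
        readMetaTsv(config$sprotMeta),
      pfam = if (is.null(config$pfamMeta)) NULL else
        readMetaTsv(config$pfamMeta),
      tigrfam = if (is.null(config$tigrfamMeta)) NULL else
        readMetaTsv(config$tigrfamMeta),
      lineage = if (is.null(config$refmap)) character() else
        readIdMap(config$refmap))
    bundles <- lapply(stats::setNames(nm = orfs$gene_id), function(g)
      evidenceBundle(g,
        sprot = if (!is.null(sprotH))
          sprotH[sprotH$query_id == g, , drop = FALSE],
        genomedb = if (!is.null(genomedbH))
          genomedbH[genomedbH$query_id == g, , drop = FALSE],
        domains = lapply(doms, function(d)
          if (is.null(d)) NULL else d[d$query_id == g, , drop = FALSE])))
    records <- annotateGenes(orfs, bundles, refs,
                             maxEvaluePairwise = config$maxEvaluePairwise,
                             maxEvalueDomain = config$maxEvalueDomain)
    writeMasterTable(records, out("annotations.tsv"))
  }, log)
  records <- readMasterTable(out("annotations.tsv"))

  ## --- taxonomy ------------------------------------------------------------
  depth <- if (!is.null(config$depthFile)) readDepthTable(config$depthFile)
  geneWeights <- function() {
    if (config$weighting == "count" || is.null(depth)) {
      matrix(1, nrow(records), 1, dimnames = list(records$id, "count"))
    } else {
      i <- match(records$contigid, depth$contigs$contig_id)
      m <- depth$depth[i, , drop = FALSE]
      rownames(m) <- records$id
      if (config$weighting == "depth_x_len")
        m <- m * (abs(records$end - records$start) + 1)
      m
    }
  }
  h4 <- runStage(config, "taxonomy",
                 list(prev = h3, binmap = config$binmap,
                      weighting = config$weighting,
                      depthFile = config$depthFile),
                 c("taxonomy_tree.json", "mag_report.tsv"), function() {
    lin <- stats::setNames(ifelse(is.na(records$genomedb_oc), "",
                                  records$genomedb_oc), records$id)
    tree <- buildTaxonTree(lin, geneWeights())
    writeTreeJson(tree, out("taxonomy_tree.json"))
    bm <- if (is.null(config$binmap)) character() else
      readIdMap(config$binmap)
    writeMagReport(magReport(records, bm, ranks = c("phylum", "genus")),
                   out("mag_report.tsv"))
  }, log)

  ## --- pathways ------------------------------------------------------------
  h5 <- runStage(config, "pathways",
                 list(prev = h3, pathwayDefs = config$pathwayDefs,
                      koMap = config$koMap),
                 c("pathway_report.tsv", "pathways.json"), function() {
    if (is.null(config$pathwayDefs) || is.null(config$koMap)) {
      writeLinesC("pathway_id\tname\tn_members\tn_observed\tfill\tobserved_members",
                  out("pathway_report.tsv"))
      jsonlite::write_json(list(), out("pathways.json"))
      return()
    }
    defs <- readPathwayDefs(config$pathwayDefs)
    fams <- readFamilyMap(config$koMap)
    recon <- reconstructMinimal(fams$family_id, defs, mode = "auto")
    rep <- pathwayReport(recon, defs)
    writeLinesC(c(paste(colnames(rep), collapse = "\t"),
                  vapply(seq_len(nrow(rep)), function(i)
                    paste(c(rep$pathway_id[i], rep$name[i],
                            rep$n_members[i], rep$n_observed[i],
                            fmtDepth(rep$fill[i]),
                            rep$observed_members[i]), collapse = "\t"),
                    "")), out("pathway_report.tsv"))
    jsonlite::write_json(
      list(mode = recon@mode, kept = keptPathways(recon),
           uncovered = uncoveredFamilies(recon),
           fill = as.list(pathwayFill(recon))),
      out("pathways.json"), auto_unbox = TRUE, digits = NA)
  }, log)

  ## --- abundance -----------------------------------------------------------
  h6 <- runStage(config, "abundance",
                 list(prev = c(h4, h5), depthFile = config$depthFile,
                      spectralFile = config$spectralFile,
                      weighting = config$weighting),
                 c("annotations_final.tsv", "profile_taxon.tsv",
                   "profile_function.tsv", "profile_pathway.tsv"),
                 function() {
    if (!is.null(depth))
      records <- attachGeneDepth(records, depth)
    writeMasterTable(records, out("annotations_final.tsv"))
    gw <- geneWeights()
    lin <- stats::setNames(ifelse(is.na(records$genomedb_oc), NA,
      vapply(records$genomedb_oc, function(s) {
        l <- parseLineage(s)
        if (length(l)) lineageString(l) else NA_character_
      }, "", USE.NAMES = FALSE)), records$id)
    writeProfileTable(weightedProfile(lin, gw), out("profile_taxon.tsv"))
    ko <- stats::setNames(vapply(strsplit(
      ifelse(is.na(records$allko_ids), "", records$allko_ids), ";",
      fixed = TRUE), function(x) if (length(x)) x[1] else NA_character_,
      ""), records$id)
    writeProfileTable(weightedProfile(ko, gw), out("profile_function.tsv"))
    if (!is.null(config$pathwayDefs) && !is.null(config$koMap)) {
      defs <- readPathwayDefs(config$pathwayDefs)
      fams <- readFamilyMap(config$koMap)
      recon <- reconstructMinimal(fams$family_id, defs, mode = "auto")
      writeProfileTable(pathwayActivity(recon, defs, fams, gw),
                        out("profile_pathway.tsv"))
    } else {
      writeLinesC("category", out("profile_pathway.tsv"))
    }
    if (!is.null(config$spectralFile)) {
      spec <- readSpectralTable(config$spectralFile)
      sw <- spectralWeights(spec, records$id)
      writeProfileTable(weightedProfile(ko, sw),
                        out("profile_function_proteome.tsv"))
    }
  }, log)
  records <- readMasterTable(out("annotations_final.tsv"))

  ## --- reports -------------------------------------------------------------
  h7 <- runStage(config, "reports", list(prev = h6),
                 c("annotated.gff3", "index.html", "manifest.json"),
                 function() {
    feats <- readGff3(out("features.gff3"))
    writeGff3(feats, records = records, path = out("annotated.gff3"))
    emitted <- c("cleaned.fna", "masked.fna", "preprocess_report.tsv",
                 "features.gff3", "annotated.gff3", "annotations.tsv",
                 "annotations_final.tsv", "taxonomy_tree.json",
                 "mag_report.tsv", "pathway_report.tsv", "pathways.json",
                 "profile_taxon.tsv", "profile_function.tsv",
                 "profile_pathway.tsv", "rrna_class.tsv", "orfs_kept.tsv")
    if (!is.null(config$spectralFile))
      emitted <- c(emitted, "profile_function_proteome.tsv")
    emitted <- emitted[file.exists(file.path(config$outdir, emitted))]
    writeHtmlIndex(config$outdir,
                   stats::setNames(emitted, emitted),
                   embedJson = c(taxonomy = "taxonomy_tree.json",
                                 pathways = "pathways.json"))
    writeManifest(config$outdir, c(emitted, "index.html"),
                  stageHashes = c(preprocess = h1, structural = h2,
                                  homology = h3, taxonomy = h4,
                                  pathways = h5, abundance = h6))
  }, log)

  invisible(list(outdir = config$outdir,
                 stageHashes = c(preprocess = h1, structural = h2,
                                 homology = h3, taxonomy = h4,
                                 pathways = h5, abundance = h6,
                                 reports = h7),
                 records = records))
}
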