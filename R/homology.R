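#' @importFrom utils read.table
NULL

## Column names of the 12-column BLAST/DIAMOND tabular dialect; an optional
## 13th column carries the query length and enables query coverage.
PAIRWISE_COLS <- c("query_id", "subject_id", "pct_identity", "aln_len",
                   "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read pairwise hits (BLAST/DIAMOND tabular, outfmt-6 dialect)
#'
#' Parses the standard 12-column tab-separated hit table
#' (\code{qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore}); an optional 13th \code{qlen} column enables the
#' derived query coverage \code{qcov = 100 (qend - qstart + 1) / qlen}.
#'
#' @param path file path.
#' @return data.frame of hits; \code{qcov} is NA when qlen is absent.
#' @export
readPairwiseHits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.frame(matrix(nrow = 0, ncol = 13,
                             dimnames = list(NULL, c(PAIRWISE_COLS, "qlen"))))
  empty$query_id <- character(); empty$subject_id <- character()
  if (!length(lines)) { empty$qcov <- numeric(); return(empty) }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(!nc %in% c(12L, 13L)))
    mStop("parseError",
          sprintf("hit table line %d: expected 12 or 13 columns, got %d",
                  which(!nc %in% c(12L, 13L))[1], nc[!nc %in% c(12L, 13L)][1]))
  f <- function(i) vapply(parts, function(p) p[i] %||% NA_character_, "")
  num <- function(i) {
    v <- suppressWarnings(as.numeric(f(i)))
    if (any(is.na(v) & nc >= i))
      mStop("parseError",
            sprintf("hit table line %d: non-numeric field %d",
                    which(is.na(v))[1], i))
    v
  }
  h <- data.frame(query_id = f(1), subject_id = f(2),
                  pct_identity = num(3), aln_len = as.integer(num(4)),
                  mismatch = as.integer(num(5)), gapopen = as.integer(num(6)),
                  qstart = as.integer(num(7)), qend = as.integer(num(8)),
                  sstart = as.integer(num(9)), send = as.integer(num(10)),
                  evalue = num(11), bitscore = num(12),
                  stringsAsFactors = FALSE)
  h$qlen <- if (all(nc == 13L)) as.integer(num(13)) else NA_integer_
  h$qcov <- ifelse(is.na(h$qlen), NA_real_,
                   100 * (h$qend - h$qstart + 1) / h$qlen)
  h
}

#' Read profile-search domain hits (HMMER3 domtblout dialect)
#'
#' Whitespace-separated table with 22 fixed columns followed by a free-text
#' description, in hmmscan orientation: the target is the profile model
#' (name in column 1, accession in column 2) and the query is the gene.
#' The per-domain independent E-value (column 13) becomes the hit's
#' \code{evalue}; repeated domains of the same model on one gene are all
#' retained.
#'
#' @param path file path.
#' @param dbTag one of Pfam, TIGRFAM, FOAM, MetabolicHMM, CasGene.
#' @return data.frame of domain hits.
#' @export
readDomainHits <- function(path, dbTag) {
  dbTag <- match.arg(dbTag, c("Pfam", "TIGRFAM", "FOAM", "MetabolicHMM",
                              "CasGene"))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.frame(query_id = character(), model_id = character(),
                      model_name = character(), db_tag = character(),
                      evalue = numeric(), dom_score = numeric(),
                      seq_score = numeric(), ali_from = integer(),
                      ali_to = integer(), qlen = integer(),
                      description = character(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  parts <- strsplit(trimws(lines), "\\s+")
  nc <- lengths(parts)
  if (any(nc < 22))
    mStop("parseError",
          sprintf("domtblout line %d: expected >= 22 fields",
                  which(nc < 22)[1]))
  f <- function(i) vapply(parts, `[`, "", i)
  num <- function(i) {
    v <- suppressWarnings(as.numeric(f(i)))
    if (any(is.na(v)))
      mStop("parseError",
            sprintf("domtblout line %d: non-numeric field %d",
                    which(is.na(v))[1], i))
    v
  }
  desc <- vapply(parts, function(p)
    if (length(p) > 22) paste(p[23:length(p)], collapse = " ") else "", "")
  data.frame(query_id = f(4), model_id = f(2), model_name = f(1),
             db_tag = dbTag, evalue = num(13), dom_score = num(14),
             seq_score = num(8), ali_from = as.integer(num(18)),
             ali_to = as.integer(num(19)), qlen = as.integer(num(6)),
             description = desc, stringsAsFactors = FALSE)
}

#' Select the best pairwise hit
#'
#' Minimises (evalue, -bitscore, subject_id) lexicographically; the
#' deterministic subject-id tie-break makes annotation independent of the
#' order hits appear in the search output.
#'
#' @param hits data.frame of pairwise hits sharing one query.
#' @return one-row data.frame, or \code{NULL} for an empty input.
#' @export
selectBestHit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  i <- ordC(hits$evalue, -hits$bitscore, hits$subject_id)[1]
  hits[i, , drop = FALSE]
}

#' Filter hits by E-value significance
#'
#' @param hits data.frame with an \code{evalue} column (pairwise or domain).
#' @param maxEvalue keep hits with \code{evalue <= maxEvalue}; default 1e-5.
#' @return filtered data.frame, input order preserved.
#' @export
significanceFilter <- function(hits, maxEvalue = 1e-5) {
  stopifnot(maxEvalue > 0)
  if (is.null(hits) || nrow(hits) == 0) return(hits)
  hits[hits$evalue <= maxEvalue, , drop = FALSE]
}

#' Parse a FOAM model name into KO and EC accessions
#'
#' FOAM model names follow the grammar \code{KO:K#####[_EC]*}, with
#' comma-separated KO alternatives and optional EC segments that may carry
#' \code{-} wildcards (e.g. \code{KO:K00390_1.8.4.8}).
#'
#' @param name model name string.
#' @return list with \code{kos} and \code{ecs} character vectors.
#' @export
parseFoamName <- function(name) {
  if (!startsWith(name, "KO:"))
    mStop("grammarError",
          sprintf("FOAM model name lacks 'KO:' prefix: '%s'", name))
  toks <- unlist(strsplit(strsplit(sub("^KO:", "", name), "_",
                                   fixed = TRUE)[[1]], ",", fixed = TRUE))
  toks <- toks[nzchar(toks)]
  isKo <- grepl("^K\\d+$", toks)
  isEc <- grepl("^[0-9]+(\\.[0-9-]+){1,3}$", toks)
  list(kos = toks[isKo], ecs = toks[isEc & !isKo])
}

## Target strings rendered in the annotation record, mirroring the
## "db:<db>|<id> <from> <to> evalue:<e> ..." style of the master table.
formatPairwiseTarget <- function(db, hit) {
  s <- sprintf("db:%s|%s %d %d evalue:%s", db, hit$subject_id,
               hit$qstart, hit$qend, fmtEvalue(hit$evalue))
  if (!is.na(hit$qcov))
    s <- sprintf("%s qcov:%.2f", s, hit$qcov)
  sprintf("%s identity:%.2f", s, hit$pct_identity)
}

formatDomainTarget <- function(db, hit) {
  s <- sprintf("db:%s|%s %d %d evalue:%s", db, hit$model_id,
               hit$ali_from, hit$ali_to, fmtEvalue(hit$evalue))
  if (!is.na(hit$qlen) && hit$qlen > 0)
    s <- sprintf("%s qcov:%.2f", s,
                 100 * (hit$ali_to - hit$ali_from + 1) / hit$qlen)
  sprintf("%s score:%.1f seqT:%.1f name:%s", s, hit$dom_score,
          hit$seq_score, hit$model_name)
}

DOMAIN_DB_FILES <- c(Pfam = "Pfam-A.hmm", TIGRFAM = "TIGRFAMs.hmm",
                     FOAM = "FOAM-hmm_rel1a.hmm",
                     MetabolicHMM = "metabolic.hmm",
                     CasGene = "casgenes.hmm")

#' Assemble the per-gene evidence bundle
#'
#' @param gene_id gene identifier.
#' @param sprot,genomedb data.frames of pairwise hits for this gene (may be
#'   NULL or empty).
#' @param domains named list of domain-hit data.frames keyed by db tag
#'   (Pfam, TIGRFAM, FOAM, MetabolicHMM, CasGene).
#' @param sp,tm_num optional motif evidence: signal-peptide annotation
#'   string and transmembrane-helix count, attached verbatim.
#' @return list of class \code{evidenceBundle}.
#' @export
evidenceBundle <- function(gene_id, sprot = NULL, genomedb = NULL,
                           domains = list(), sp = NA_character_,
                           tm_num = NA_integer_) {
  structure(list(gene_id = gene_id, sprot = sprot, genomedb = genomedb,
                 domains = domains, sp = sp, tm_num = tm_num),
            class = "evidenceBundle")
}

#' Reference metadata maps used during evidence merging
#'
#' @param sprot data.frame subject_id, description, ec, kos, go (the last
#'   three are ";"-joined lists).
#' @param pfam data.frame model_name, description.
#' @param tigrfam data.frame model_name, description, go, mainrole, sub1role.
#' @param lineage named character subject_id -> lineage string (GenomeDB).
#' @param koOntology optional named character KO -> ontology string.
#' @return list of class \code{referenceMaps}.
#' @export
referenceMaps <- function(sprot = NULL, pfam = NULL, tigrfam = NULL,
                          lineage = character(), koOntology = character()) {
  structure(list(sprot = sprot, pfam = pfam, tigrfam = tigrfam,
                 lineage = lineage, koOntology = koOntology),
            class = "referenceMaps")
}

joinVals <- function(x) paste(x, collapse = ";")
splitVals <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
}

lookupMeta <- function(meta, key, column, id) {
  if (is.null(meta)) return(NA_character_)
  i <- match(id, meta[[key]])
  if (is.na(i)) NA_character_ else meta[[column]][i]
}

#' Merge all evidence for one gene into an annotation record
#'
#' Combines the significant pairwise and profile evidence into the per-gene
#' record: the single best hit per pairwise source (SwissProt, GenomeDB) and
#' all significant domains per profile source. Union fields follow the
#' master-table convention: \code{allec_ids} is the ordered, de-duplicated
#' union of the SwissProt ECs followed by the FOAM ECs; \code{allko_ids}
#' puts the FOAM KOs first, then the SwissProt KOs. The product is the
#' SwissProt best-hit description when available, otherwise the first
#' significant domain description in priority order TIGRFAM > Pfam > FOAM >
#' MetabolicHMM > CasGene; genes without any functional evidence are
#' \code{"hypothetical protein"}.
#'
#' @param gene one-row data.frame from \code{orfCalls} (or a list with
#'   gene_id/contig_id/start/end/strand).
#' @param bundle \code{evidenceBundle} for this gene.
#' @param refs \code{referenceMaps}.
#' @param maxEvaluePairwise,maxEvalueDomain significance cutoffs (default
#'   1e-5 each).
#' @return named list: one annotation record.
#' @export
mergeEvidence <- function(gene, bundle, refs = referenceMaps(),
                          maxEvaluePairwise = 1e-5,
                          maxEvalueDomain = 1e-5) {
  rec <- list(id = gene$gene_id, contigid = gene$contig_id,
              start = gene$start %||% NA_integer_,
              end = gene$end %||% NA_integer_,
              strand = gene$strand %||% NA_character_)
  blank <- NA_character_
  for (f in c("product", "allec_ids", "allko_ids", "allko_ontology",
              "go_terms", "sprot_desc", "sprot_ec", "sprot_kos", "sprot_go",
              "sprot_target", "genomedb_oc", "genomedb_target",
              "pfam_id", "pfam_desc", "pfam_target",
              "tigrfam_id", "tigrfam_desc", "tigrfam_go",
              "tigrfam_mainrole", "tigrfam_sub1role", "tigrfam_target",
              "foam_kos", "foam_ecs", "foam_target",
              "metabolic_target", "casgene_target"))
    rec[[f]] <- blank
  rec$sp <- bundle$sp
  rec$tm_num <- bundle$tm_num

  sprotEc <- character(); sprotKo <- character()
  foamEc <- character(); foamKo <- character()
  goTerms <- character()
  anyFunctional <- FALSE

  sBest <- selectBestHit(significanceFilter(bundle$sprot, maxEvaluePairwise))
  if (!is.null(sBest)) {
    anyFunctional <- TRUE
    rec$sprot_target <- formatPairwiseTarget("uniprot_sprot", sBest)
    rec$sprot_desc <- lookupMeta(refs$sprot, "subject_id", "description",
                                 sBest$subject_id)
    sprotEc <- splitVals(lookupMeta(refs$sprot, "subject_id", "ec",
                                    sBest$subject_id))
    sprotKo <- splitVals(lookupMeta(refs$sprot, "subject_id", "kos",
                                    sBest$subject_id))
    goTerms <- c(goTerms, splitVals(lookupMeta(refs$sprot, "subject_id",
                                               "go", sBest$subject_id)))
    if (length(sprotEc)) rec$sprot_ec <- joinVals(sprotEc)
    if (length(sprotKo)) rec$sprot_kos <- joinVals(sprotKo)
    g <- splitVals(lookupMeta(refs$sprot, "subject_id", "go",
                              sBest$subject_id))
    if (length(g)) rec$sprot_go <- joinVals(g)
  }

  gBest <- selectBestHit(significanceFilter(bundle$genomedb,
                                            maxEvaluePairwise))
  if (!is.null(gBest)) {
    rec$genomedb_target <- formatPairwiseTarget("genomedb", gBest)
    lin <- refs$lineage[gBest$subject_id]
    if (!is.na(lin)) rec$genomedb_oc <- unname(lin)
  }

  domDesc <- c(TIGRFAM = NA_character_, Pfam = NA_character_,
               FOAM = NA_character_, MetabolicHMM = NA_character_,
               CasGene = NA_character_)
  for (tag in names(DOMAIN_DB_FILES)) {
    hits <- significanceFilter(bundle$domains[[tag]], maxEvalueDomain)
    if (is.null(hits) || nrow(hits) == 0) next
    anyFunctional <- TRUE
    targets <- vapply(seq_len(nrow(hits)), function(i)
      formatDomainTarget(DOMAIN_DB_FILES[[tag]], hits[i, ]), "")
    tgt <- paste(targets, collapse = "; ")
    models <- unique(hits$model_name)
    if (tag == "Pfam") {
      rec$pfam_target <- tgt
      rec$pfam_id <- joinVals(models)
      d <- vapply(models, function(m)
        lookupMeta(refs$pfam, "model_name", "description", m), "")
      d <- d[!is.na(d)]
      if (length(d)) { rec$pfam_desc <- joinVals(d); domDesc["Pfam"] <- d[1] }
    } else if (tag == "TIGRFAM") {
      rec$tigrfam_target <- tgt
      rec$tigrfam_id <- joinVals(models)
      meta <- function(col) {
        v <- vapply(models, function(m)
          lookupMeta(refs$tigrfam, "model_name", col, m), "",
          USE.NAMES = FALSE)
        v[!is.na(v)]
      }
      d <- meta("description")
      if (length(d)) { rec$tigrfam_desc <- joinVals(d)
                       domDesc["TIGRFAM"] <- d[1] }
      g <- unlist(lapply(meta("go"), splitVals))
      if (length(g)) { rec$tigrfam_go <- joinVals(unique(g))
                       goTerms <- c(goTerms, g) }
      mr <- meta("mainrole"); if (length(mr)) rec$tigrfam_mainrole <- mr[1]
      sr <- meta("sub1role"); if (length(sr)) rec$tigrfam_sub1role <- sr[1]
    } else if (tag == "FOAM") {
      rec$foam_target <- tgt
      for (m in models) {
        p <- parseFoamName(m)
        foamKo <- c(foamKo, p$kos)
        foamEc <- c(foamEc, p$ecs)
      }
      foamKo <- unique(foamKo); foamEc <- unique(foamEc)
      if (length(foamKo)) rec$foam_kos <- joinVals(foamKo)
      if (length(foamEc)) rec$foam_ecs <- joinVals(foamEc)
      domDesc["FOAM"] <- models[1]
    } else if (tag == "MetabolicHMM") {
      rec$metabolic_target <- tgt
      domDesc["MetabolicHMM"] <- if (nzchar(hits$description[1]))
        hits$description[1] else models[1]
    } else if (tag == "CasGene") {
      rec$casgene_target <- tgt
      domDesc["CasGene"] <- if (nzchar(hits$description[1]))
        hits$description[1] else models[1]
    }
  }

  allEc <- unique(c(sprotEc, foamEc))       # SwissProt first, then FOAM
  allKo <- unique(c(foamKo, sprotKo))       # FOAM first, then SwissProt
  if (length(allEc)) rec$allec_ids <- joinVals(allEc)
  if (length(allKo)) rec$allko_ids <- joinVals(allKo)
  goTerms <- unique(goTerms)
  if (length(goTerms)) rec$go_terms <- joinVals(goTerms)
  if (length(allKo) && length(refs$koOntology)) {
    ont <- refs$koOntology[allKo]
    ont <- ont[!is.na(ont)]
    if (length(ont)) rec$allko_ontology <- unname(ont[1])
  }

  rec$product <- if (!is.null(sBest) && !is.na(rec$sprot_desc)) {
    rec$sprot_desc
  } else {
    d <- domDesc[!is.na(domDesc)]
    if (length(d)) unname(d[1]) else "hypothetical protein"
  }
  if (!anyFunctional) rec$product <- "hypothetical protein"
  rec
}

#' Merge evidence for all genes into the annotation table
#'
#' @param orfs data.frame of retained ORFs (\code{orfCalls}).
#' @param bundles named list of \code{evidenceBundle}s keyed by gene id;
#'   genes without a bundle get an empty one (hypothetical protein).
#' @param refs \code{referenceMaps}.
#' @param ... cutoffs passed to \code{mergeEvidence}.
#' @return \code{DataFrame} with one row per gene, rows ordered by
#'   (contig, start).
#' @export
annotateGenes <- function(orfs, bundles = list(), refs = referenceMaps(),
                          ...) {
  orfs <- orfs[ordC(orfs$contig_id, orfs$start), , drop = FALSE]
  recs <- lapply(seq_len(nrow(orfs)), function(i) {
    g <- orfs[i, ]
    b <- bundles[[g$gene_id]] %||% evidenceBundle(g$gene_id)
    mergeEvidence(g, b, refs, ...)
  })
  cols <- names(recs[[1]])
  out <- S4Vectors::DataFrame(lapply(stats::setNames(cols, cols), function(f)
    unlist(lapply(recs, function(r) r[[f]] %||% NA))))
  rownames(out) <- out$id
  out
}
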