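#' @import GenomicRanges
#' @importFrom IRanges IRanges reduce
#' @importFrom S4Vectors mcols mcols<-
NULL

FEATURE_TYPES <- c("CRISPR", "tRNA", "rRNA", "CDS")

#' Construct a set of located structural features
#'
#' Features (CRISPR arrays, tRNA, rRNA genes, CDS) are represented as a
#' \code{GRanges} with 1-based inclusive coordinates and metadata columns
#' \code{ftype} and \code{subtype} (e.g. \code{16S}, \code{tRNA-Ala}).
#'
#' @param contig_id,start,end,strand,ftype,subtype parallel vectors.
#' @return \code{GRanges} with ftype/subtype metadata.
#' @export
featureIntervals <- function(contig_id, start, end, strand = ".",
                             ftype, subtype = "") {
  n <- length(contig_id)
  strand <- rep_len(strand, n)
  subtype <- rep_len(subtype, n)
  ftype <- rep_len(ftype, n)
  if (any(start < 1) || any(end < start))
    mStop("coordinateError", "invalid feature coordinates (need 1 <= start <= end)")
  bad <- setdiff(unique(ftype), FEATURE_TYPES)
  if (length(bad))
    mStop("featureTypeError",
          sprintf("unknown feature type '%s'", bad[1]))
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(contig_id, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$ftype <- ftype
  S4Vectors::mcols(gr)$subtype <- subtype
  gr
}

#' Read a structural-feature table (TSV dialect or GFF3)
#'
#' The TSV dialect carries columns \code{contig_id}, \code{start},
#' \code{end}, \code{strand}, \code{subtype} and optional free-form
#' attributes, with 1-based inclusive coordinates. GFF3 input is read with
#' rtracklayer; the GFF3 \code{type} column supplies the feature type when
#' \code{ftype} is NULL.
#'
#' @param path file path.
#' @param ftype feature kind for every row (TSV input), one of CRISPR, tRNA,
#'   rRNA, CDS.
#' @param format "tsv" or "gff3".
#' @return \code{GRanges} as from \code{featureIntervals}.
#' @export
readFeatureTable <- function(path, ftype = NULL,
                             format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    ft <- ftype %||% as.character(S4Vectors::mcols(gr)$type)
    sub <- S4Vectors::mcols(gr)$subtype %||%
      S4Vectors::mcols(gr)$Name %||% rep("", length(gr))
    return(featureIntervals(as.character(GenomicRanges::seqnames(gr)),
                            GenomicRanges::start(gr), GenomicRanges::end(gr),
                            as.character(GenomicRanges::strand(gr)),
                            ft, as.character(sub)))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(featureIntervals(character(), integer(), integer(),
                            character(), character(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 5))
    mStop("parseError",
          sprintf("feature table line %d: expected >= 5 tab-separated fields",
                  which(nc < 5)[1]))
  f <- function(i) vapply(parts, `[`, "", i)
  start <- suppressWarnings(as.integer(f(2)))
  end <- suppressWarnings(as.integer(f(3)))
  if (any(is.na(start)) || any(is.na(end)))
    mStop("parseError",
          sprintf("feature table line %d: non-integer coordinate",
                  which(is.na(start) | is.na(end))[1]))
  if (any(end < start))
    mStop("coordinateError",
          sprintf("feature table line %d: end < start",
                  which(end < start)[1]))
  featureIntervals(f(1), start, end, f(4), ftype %||% "CDS", f(5))
}

#' Construct rRNA model hits
#'
#' One row per HMM model hit: the domain-of-life model that produced the
#' hit, the rRNA gene type, the location, and the hit's E-value and bit
#' score.
#'
#' @param contig_id,domain_model,rna_type,start,end,strand,evalue,score
#'   parallel vectors.
#' @return data.frame of hits.
#' @export
rrnaHits <- function(contig_id, domain_model, rna_type, start, end,
                     strand = "+", evalue, score = 0) {
  stopifnot(all(evalue > 0), all(is.finite(evalue)), all(start <= end))
  data.frame(contig_id = contig_id, domain_model = domain_model,
             rna_type = rna_type, start = start, end = end,
             strand = rep_len(strand, length(contig_id)),
             evalue = evalue, score = rep_len(score, length(contig_id)),
             stringsAsFactors = FALSE)
}

#' Resolve competing rRNA model hits
#'
#' When HMM models from several domains of life hit the same region of a
#' contig, only the hit(s) with the lowest E-value in the conflicting group
#' survive; exact E-value ties are all kept. Conflict groups are the
#' connected components of the pairwise interval-overlap graph on each
#' contig (two hits conflict when they share at least 1 bp; strand and rRNA
#' type are ignored when forming groups, since transitively overlapping
#' regions must be resolved together). Non-overlapping hits always survive.
#'
#' @param hits data.frame from \code{rrnaHits}.
#' @return the retained hits, sorted by (contig_id, start).
#' @export
resolveModelHits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  keep <- logical(nrow(hits))
  for (ctg in unique(hits$contig_id)) {
    idx <- which(hits$contig_id == ctg)
    ir <- IRanges::IRanges(hits$start[idx], hits$end[idx])
    ## connected components of the 1-D overlap graph are exactly the merged
    ## (reduced) regions
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    for (g in unique(grp)) {
      m <- idx[grp == g]
      keep[m] <- hits$evalue[m] == min(hits$evalue[m])
    }
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[ordC(out$contig_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mask feature regions with Ns
#'
#' Replaces every position covered by the union of the given feature
#' intervals with \code{N}, leaving all other positions untouched. Used to
#' hide detected noncoding features (CRISPR/tRNA/rRNA) before ORF
#' prediction so no artefactual protein gene overlaps them.
#'
#' @param contigs \code{DNAStringSet}.
#' @param features \code{GRanges} on those contigs.
#' @return \code{DNAStringSet} of identical lengths with masked positions.
#' @export
maskContigs <- function(contigs, features) {
  segs <- split(features, factor(as.character(GenomicRanges::seqnames(features)),
                                 levels = names(contigs)))
  out <- as.character(contigs)
  for (ctg in names(contigs)) {
    fr <- segs[[ctg]]
    if (is.null(fr) || length(fr) == 0) next
    if (any(GenomicRanges::end(fr) > nchar(out[[ctg]])) ||
        any(GenomicRanges::start(fr) < 1))
      mStop("outOfBoundsError",
            sprintf("feature exceeds bounds of contig '%s'", ctg))
    red <- IRanges::reduce(GenomicRanges::ranges(fr))
    ch <- strsplit(out[[ctg]], "")[[1]]
    pos <- unlist(Map(seq.int, IRanges::start(red), IRanges::end(red)))
    ch[pos] <- "N"
    out[[ctg]] <- paste(ch, collapse = "")
  }
  Biostrings::DNAStringSet(out)
}

#' Construct ORF calls
#'
#' @param gene_id,contig_id,start,end,strand,partial5,partial3 parallel
#'   vectors describing predicted protein-coding genes.
#' @return data.frame with a derived \code{nt_length} column.
#' @export
orfCalls <- function(gene_id, contig_id, start, end, strand = "+",
                     partial5 = FALSE, partial3 = FALSE) {
  stopifnot(!anyDuplicated(gene_id), all(end >= start))
  n <- length(gene_id)
  data.frame(gene_id = gene_id, contig_id = contig_id, start = start,
             end = end, strand = rep_len(strand, n),
             nt_length = end - start + 1L,
             partial5 = rep_len(partial5, n), partial3 = rep_len(partial3, n),
             stringsAsFactors = FALSE)
}

#' Filter short ORFs
#'
#' ORFs spanning fewer than \code{minNt} nucleotides (stop codon included,
#' partial and complete calls alike) are excluded; the threshold is strict,
#' so an ORF of exactly \code{minNt} nt is kept. Default 180 nt.
#'
#' @param orfs data.frame from \code{orfCalls}.
#' @param minNt minimum nucleotide span.
#' @return the kept ORFs, input order preserved.
#' @export
filterOrfs <- function(orfs, minNt = 180) {
  stopifnot(minNt >= 0)
  orfs[orfs$nt_length >= minNt, , drop = FALSE]
}

#' Classify an rRNA gene from its pairwise hits
#'
#' The detected rRNA gene inherits the lineage of its best pairwise hit
#' against the rRNA reference (lowest E-value, ties broken by bit score then
#' subject id). Returns the empty (unclassified) lineage when there are no
#' hits.
#'
#' @param hits data.frame of pairwise hits for this gene
#'   (see \code{readPairwiseHits}).
#' @param refmap named character: subject_id -> lineage string.
#' @param strict raise \code{missingSubjectError} when the best subject has
#'   no lineage (default TRUE).
#' @return lineage string (possibly \code{""}).
#' @export
classifyRrna <- function(hits, refmap, strict = TRUE) {
  best <- selectBestHit(hits)
  if (is.null(best)) return("")
  lin <- refmap[best$subject_id]
  if (is.na(lin)) {
    if (strict)
      mStop("missingSubjectError",
            sprintf("subject '%s' absent from reference map",
                    best$subject_id))
    return("")
  }
  unname(lin)
}
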