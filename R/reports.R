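## Master-table column order (normalized tag set; fixed for determinism).
MASTER_COLS <- c("id", "contigid", "start", "end", "strand", "product",
                 "allec_ids", "allko_ids", "allko_ontology", "go_terms",
                 "sprot_desc", "sprot_ec", "sprot_kos", "sprot_go",
                 "sprot_target", "genomedb_oc", "genomedb_target",
                 "pfam_id", "pfam_desc", "pfam_target",
                 "tigrfam_id", "tigrfam_desc", "tigrfam_go",
                 "tigrfam_mainrole", "tigrfam_sub1role", "tigrfam_target",
                 "foam_kos", "foam_ecs", "foam_target",
                 "metabolic_target", "casgene_target", "sp", "tm_num",
                 "depth", "total_avg_depth")

#' Write annotated features as GFF3
#'
#' Emits a standards-conformant GFF3 (via rtracklayer, which
#' percent-encodes reserved characters in attribute values) with one line
#' per feature, sorted by (contig, start). CDS features carry the record
#' attribute subset ID, product, allec_ids, allko_ids, genomedb_oc.
#'
#' @param features \code{GRanges} from \code{featureIntervals}, with an
#'   optional \code{ID} metadata column.
#' @param records optional annotation \code{DataFrame}; matched to CDS
#'   features by \code{ID}.
#' @param path output file.
#' @export
writeGff3 <- function(features, records = NULL, path) {
  gr <- features
  mc <- S4Vectors::mcols(gr)
  id <- mc$ID %||% sprintf("feat%05d", seq_along(gr))
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                GenomicRanges::ranges(gr),
                                strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(out)$source <- "metannot"
  S4Vectors::mcols(out)$type <- mc$ftype
  S4Vectors::mcols(out)$phase <- ifelse(mc$ftype == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(out)$ID <- id
  S4Vectors::mcols(out)$Name <- mc$subtype
  if (!is.null(records)) {
    i <- match(id, records$id)
    S4Vectors::mcols(out)$product <- ifelse(is.na(i), NA,
                                            records$product[i])
    for (f in c("allec_ids", "allko_ids", "genomedb_oc"))
      S4Vectors::mcols(out)[[f]] <- ifelse(is.na(i), NA, records[[f]][i])
  }
  o <- ordC(as.character(GenomicRanges::seqnames(out)),
            GenomicRanges::start(out))
  rtracklayer::export(out[o], path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file back into a feature GRanges
#'
#' Inverse of \code{\link{writeGff3}} on its image; foreign attributes are
#' preserved verbatim in the metadata columns.
#'
#' @param path GFF3 file.
#' @return \code{GRanges} with \code{ftype}/\code{subtype} plus any
#'   attribute columns.
#' @export
readGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  mc$ftype <- as.character(mc$type)
  mc$subtype <- as.character(mc$Name %||% rep(NA_character_, length(gr)))
  S4Vectors::mcols(gr) <- mc
  gr
}

#' Write the master annotation table
#'
#' One row per gene, one column per annotation tag, multi-valued fields
#' ";"-joined, rows ordered by (contig, start), depths formatted at 4
#' decimals. Deterministic: identical records give byte-identical files.
#'
#' @param records annotation \code{DataFrame}.
#' @param path output TSV.
#' @export
writeMasterTable <- function(records, path) {
  cols <- intersect(MASTER_COLS, colnames(records))
  o <- ordC(records$contigid, records$start)
  records <- records[o, , drop = FALSE]
  cells <- lapply(cols, function(f) {
    v <- records[[f]]
    if (f == "depth" && is.matrix(v))
      apply(v, 1, function(r) paste(fmtDepth(r), collapse = ";"))
    else if (f == "total_avg_depth") fmtDepth(v)
    else {
      v <- as.character(v)
      ifelse(is.na(v), "", v)
    }
  })
  lines <- c(paste(cols, collapse = "\t"),
             do.call(paste, c(cells, sep = "\t")))
  writeLinesC(lines, path)
  invisible(path)
}

#' Read a master annotation table
#'
#' Parses a TSV written by \code{\link{writeMasterTable}} back into a
#' \code{DataFrame}; empty cells become NA, the depth column becomes a
#' numeric matrix again.
#'
#' @param path master table TSV.
#' @return \code{DataFrame}.
#' @export
readMasterTable <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  parts <- lapply(body, function(l)
    strsplit(paste0(l, "\t\x01"), "\t", fixed = TRUE)[[1]])  # keep trailing
  get <- function(j) {
    v <- vapply(parts, `[`, "", j)
    v[v == ""] <- NA_character_
    v
  }
  out <- S4Vectors::DataFrame(lapply(stats::setNames(seq_along(hdr), hdr),
                                     get))
  for (f in c("start", "end", "tm_num"))
    if (f %in% hdr) out[[f]] <- as.integer(out[[f]])
  if ("total_avg_depth" %in% hdr)
    out$total_avg_depth <- as.numeric(out$total_avg_depth)
  if ("depth" %in% hdr) {
    rows <- lapply(out$depth, function(s)
      if (is.na(s)) numeric() else
        as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
    ncolD <- max(lengths(rows), 0)
    m <- matrix(0, length(rows), ncolD)
    for (i in seq_along(rows))
      if (length(rows[[i]])) m[i, ] <- rows[[i]]
    rownames(m) <- out$id
    out$depth <- m
  }
  rownames(out) <- out$id
  out
}

#' Write a profile matrix as TSV
#'
#' One row per category with per-sample weight and proportion columns at
#' fixed 4-decimal formatting.
#'
#' @param pm \code{ProfileMatrix}.
#' @param path output TSV.
#' @export
writeProfileTable <- function(pm, path) {
  w <- profileWeights(pm); r <- relAbundance(pm)
  samples <- colnames(w)
  hdr <- c("category", paste0(samples, "_weight"),
           paste0(samples, "_proportion"))
  lines <- c(paste(hdr, collapse = "\t"),
             vapply(seq_len(nrow(w)), function(i)
               paste(c(rownames(w)[i], fmtDepth(w[i, ]), fmtDepth(r[i, ])),
                     collapse = "\t"), ""))
  writeLinesC(lines, path)
  invisible(path)
}

#' Write the MAG taxonomy report TSV
#'
#' @param report data.frame from \code{magReport}.
#' @param path output TSV.
#' @export
writeMagReport <- function(report, path) {
  lines <- c("mag_id\trank\tplurality\tdiscordant_fraction\tn_classified\tn_unclassified",
             vapply(seq_len(nrow(report)), function(i)
               paste(c(report$mag_id[i], report$rank[i],
                       report$plurality[i],
                       fmtDepth(report$discordant_fraction[i]),
                       report$n_classified[i], report$n_unclassified[i]),
                     collapse = "\t"), ""))
  writeLinesC(lines, path)
  invisible(path)
}

#' Write the static HTML index page
#'
#' A single static page linking every emitted report and embedding the
#' taxonomy/profile JSON documents as data blocks (no interactive
#' JavaScript).
#'
#' @param outdir output directory containing the reports.
#' @param files named character vector of emitted files (relative paths).
#' @param embedJson named character vector of JSON file paths to embed.
#' @return the path of the written index.html.
#' @export
writeHtmlIndex <- function(outdir, files, embedJson = character()) {
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", x))
  links <- vapply(names(files), function(k)
    sprintf("    <li><a href=\"%s\">%s</a> (%s)</li>", files[[k]],
            files[[k]], esc(k)), "")
  blobs <- unlist(lapply(names(embedJson), function(k) {
    p <- file.path(outdir, embedJson[[k]])
    if (!file.exists(p)) return(character())
    c(sprintf("  <script type=\"application/json\" id=\"%s\">", k),
      readLines(p), "  </script>")
  }))
  lines <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
             "<title>metannot annotation report</title></head><body>",
             "  <h1>metannot annotation report</h1>", "  <ul>", links,
             "  </ul>", blobs, "</body></html>")
  path <- file.path(outdir, "index.html")
  writeLinesC(lines, path)
  invisible(path)
}

#' Build the report manifest
#'
#' Lists every emitted file with its md5 checksum, plus the stage
#' parameter hashes, and writes it as \code{manifest.json}.
#'
#' @param outdir output directory.
#' @param files character vector of file paths relative to outdir.
#' @param stageHashes named character vector of per-stage parameter hashes.
#' @return the manifest as a list (invisibly writes manifest.json).
#' @export
writeManifest <- function(outdir, files, stageHashes = character()) {
  files <- sortC(files)
  sums <- unname(tools::md5sum(file.path(outdir, files)))
  manifest <- list(files = data.frame(path = files, md5 = sums,
                                      stringsAsFactors = FALSE),
                   stages = as.list(stageHashes))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
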