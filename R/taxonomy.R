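#' Parse a rank-prefixed lineage string
#'
#' Lineages follow the GTDB convention: semicolon-separated segments with
#' rank prefixes \code{d__, p__, c__, o__, f__, g__, s__} in canonical
#' order, possibly terminating early (e.g. at genus). Trailing empty
#' segments are dropped; an empty string is the unclassified lineage.
#'
#' @param s lineage string.
#' @return named character vector of taxon names, names = rank prefixes
#'   present (zero-length for unclassified).
#' @export
parseLineage <- function(s) {
  if (is.na(s) || !nzchar(s)) return(stats::setNames(character(), character()))
  segs <- strsplit(s, ";", fixed = TRUE)[[1]]
  segs <- trimws(segs)
  segs <- segs[nzchar(segs)]
  if (!length(segs)) return(stats::setNames(character(), character()))
  pref <- sub("__.*$", "", segs)
  name <- sub("^[a-z]__", "", segs)
  idx <- match(pref, RANK_PREFIXES)
  if (any(is.na(idx)))
    mStop("lineageFormatError",
          sprintf("unknown rank prefix '%s__'", pref[is.na(idx)][1]))
  if (!identical(idx, seq_along(idx)))
    mStop("lineageFormatError",
          sprintf("ranks out of order or gapped in '%s'", s))
  if (any(!nzchar(name)))
    mStop("lineageFormatError",
          sprintf("empty taxon name at rank '%s__'",
                  pref[!nzchar(name)][1]))
  stats::setNames(name, pref)
}

#' Format a parsed lineage back into its string form
#'
#' @param lin named character from \code{parseLineage}.
#' @return lineage string with trailing semicolon (\code{""} if empty).
#' @export
lineageString <- function(lin) {
  if (!length(lin)) return("")
  paste0(paste(paste0(names(lin), "__", lin), collapse = ";"), ";")
}

#' Classify a gene from its best reference hit
#'
#' The gene inherits the lineage of its best significant pairwise hit
#' against the lineage-labelled reference (single best hit, not an LCA).
#'
#' @param bundle \code{evidenceBundle} (its \code{genomedb} hits are used).
#' @param refmap named character subject_id -> lineage string.
#' @param maxEvalue significance cutoff for hits (default 1e-5).
#' @param strict raise \code{missingSubjectError} when the best subject is
#'   absent from \code{refmap} (default TRUE).
#' @return lineage string; \code{""} when no hit survives filtering.
#' @export
classifyGene <- function(bundle, refmap, maxEvalue = 1e-5, strict = TRUE) {
  best <- selectBestHit(significanceFilter(bundle$genomedb, maxEvalue))
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

## Pad a lineage to the full 7-rank depth with the unclassified pseudo-taxon
## so every gene reaches the outermost ring and ring weights partition the
## total.
padLineage <- function(s) {
  lin <- parseLineage(s)
  out <- rep(UNCLASSIFIED, length(RANK_PREFIXES))
  if (length(lin)) out[seq_along(lin)] <- lin
  out
}

#' Build the weighted hierarchical taxonomy tree
#'
#' Aggregates per-gene lineage assignments into a \code{\link{TaxonTree}}:
#' each node's weight (per sample) is the sum of the weights of all genes
#' whose padded lineage passes through it, so parent weights equal the sum
#' of their children and ring proportions are node weight over root weight.
#'
#' @param assignments named character: gene id -> lineage string (\code{""}
#'   = unclassified).
#' @param weights numeric vector or gene-by-sample matrix of non-negative
#'   weights, names/rownames = gene ids; default 1 per gene (count
#'   weighting, sample \code{"count"}).
#' @return \code{TaxonTree}.
#' @export
buildTaxonTree <- function(assignments, weights = NULL) {
  genes <- names(assignments)
  if (is.null(weights)) {
    weights <- matrix(1, length(genes), 1,
                      dimnames = list(genes, "count"))
  } else if (is.null(dim(weights))) {
    weights <- matrix(weights, ncol = 1,
                      dimnames = list(names(weights), "weight"))
  }
  weights <- weights[genes, , drop = FALSE]
  if (any(weights < 0))
    mStop("negativeWeightError", "gene weights must be non-negative")
  padded <- t(vapply(assignments, padLineage,
                     character(length(RANK_PREFIXES))))
  paths <- padded
  for (r in seq_along(RANK_PREFIXES))
    paths[, r] <- if (r == 1) padded[, 1] else
      paste(paths[, r - 1], padded[, r], sep = "|")
  nodes <- data.frame(path = "root", rank = "root", name = "root",
                      parent = NA_character_, stringsAsFactors = FALSE)
  weight <- matrix(colSums(weights), 1, ncol(weights),
                   dimnames = list("root", colnames(weights)))
  for (r in seq_along(RANK_PREFIXES)) {
    w <- rowsum(weights, group = paths[, r], reorder = FALSE)
    w <- w[ordC(rownames(w)), , drop = FALSE]   # locale-independent order
    pth <- rownames(w)
    parent <- if (r == 1) "root" else sub("\\|[^|]*$", "", pth)
    nm <- sub("^.*\\|", "", pth)
    nodes <- rbind(nodes, data.frame(path = pth, rank = RANK_NAMES[r],
                                     name = nm, parent = parent,
                                     stringsAsFactors = FALSE))
    weight <- rbind(weight, w)
  }
  rownames(weight) <- nodes$path
  methods::new("TaxonTree", nodes = nodes, weight = weight)
}

#' Per-ring relative abundances of a taxon tree
#'
#' @param tree \code{TaxonTree}.
#' @param rank one of domain, phylum, class, order, family, genus, species.
#' @return matrix node-by-sample of proportions (node weight over root
#'   weight; zero-total samples give 0).
#' @export
ringProportions <- function(tree, rank) {
  rank <- match.arg(rank, RANK_NAMES)
  w <- treeWeights(tree)
  rows <- treeNodes(tree)$rank == rank
  root <- w["root", ]
  p <- sweep(w[rows, , drop = FALSE], 2, ifelse(root > 0, root, 1), "/")
  p[, root == 0] <- 0
  p
}

rankIndex <- function(rank) {
  if (rank %in% RANK_PREFIXES) return(match(rank, RANK_PREFIXES))
  match(match.arg(rank, RANK_NAMES), RANK_NAMES)
}

#' Taxonomic discordance of one gene set at one rank
#'
#' For the genes of a MAG (or any gene set), finds the plurality taxon at
#' the requested rank and the fraction of classified genes that disagree
#' with it; a high discordant fraction flags a chimeric or contaminated
#' bin. Genes unclassified at the rank are excluded from the denominator;
#' plurality ties break to the lexicographically smallest name.
#'
#' @param lineages character vector of lineage strings (one per gene).
#' @param rank rank name or prefix (e.g. "genus" or "g").
#' @return list: \code{rank}, \code{plurality}, \code{discordant_fraction},
#'   \code{n_classified}, \code{n_unclassified}.
#' @export
contaminationReport <- function(lineages, rank = "genus") {
  ri <- rankIndex(rank)
  nm <- vapply(lineages, function(s) {
    lin <- parseLineage(s)
    if (length(lin) >= ri) lin[[ri]] else NA_character_
  }, "", USE.NAMES = FALSE)
  cls <- nm[!is.na(nm)]
  if (!length(cls))
    mStop("noClassifiedGenesError",
          sprintf("no genes classified at rank '%s'", RANK_NAMES[ri]))
  tab <- table(cls)
  best <- max(tab)
  plurality <- sortC(names(tab)[tab == best])[1]
  list(rank = RANK_NAMES[ri], plurality = plurality,
       discordant_fraction = 1 - best / length(cls),
       n_classified = length(cls),
       n_unclassified = sum(is.na(nm)))
}

#' Per-MAG taxonomy report
#'
#' Runs \code{\link{contaminationReport}} for every MAG at the requested
#' ranks, routing genes to MAGs through the contig bin map.
#'
#' @param records annotation \code{DataFrame} from \code{annotateGenes}
#'   (columns \code{contigid} and \code{genomedb_oc} are used).
#' @param binmap named character contig_id -> mag_id (may be partial).
#' @param ranks ranks to report (default genus).
#' @return data.frame: mag_id, rank, plurality, discordant_fraction,
#'   n_classified, n_unclassified.
#' @export
magReport <- function(records, binmap, ranks = "genus") {
  byMag <- extractMagAnnotations(records, binmap)
  rows <- list()
  for (mag in names(byMag)) {
    lin <- byMag[[mag]]$genomedb_oc
    lin[is.na(lin)] <- ""
    for (rk in ranks) {
      rep <- tryCatch(contaminationReport(lin, rk),
                      noClassifiedGenesError = function(e) NULL)
      if (is.null(rep)) next
      rows[[length(rows) + 1]] <- data.frame(
        mag_id = mag, rank = rep$rank, plurality = rep$plurality,
        discordant_fraction = rep$discordant_fraction,
        n_classified = rep$n_classified,
        n_unclassified = rep$n_unclassified, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows) %||%
    data.frame(mag_id = character(), rank = character(),
               plurality = character(), discordant_fraction = numeric(),
               n_classified = integer(), n_unclassified = integer())
}

#' Partition annotation records by MAG
#'
#' Every record is routed to its contig's MAG, or to \code{"unbinned"} when
#' the contig has no bin assignment; record totals are conserved.
#'
#' @param records annotation \code{DataFrame} (column \code{contigid}).
#' @param binmap named character contig_id -> mag_id.
#' @return named list of record subsets (always includes \code{unbinned},
#'   possibly empty).
#' @export
extractMagAnnotations <- function(records, binmap = character()) {
  mag <- if (length(binmap)) binmap[records$contigid] else
    rep(NA_character_, nrow(records))
  mag[is.na(mag)] <- "unbinned"
  out <- lapply(stats::setNames(nm = sortC(unique(mag))), function(m)
    records[mag == m, , drop = FALSE])
  if (!"unbinned" %in% names(out))
    out$unbinned <- records[0, , drop = FALSE]
  out
}

#' Serialize a taxon tree to a nested document
#'
#' Produces the hierarchical data contract consumed by sunburst/collapsible
#' tree views: nested nodes with name, rank, per-sample weight, and
#' children ordered deterministically (descending total weight, then name).
#'
#' @param tree \code{TaxonTree}.
#' @return nested list.
#' @export
treeToList <- function(tree) {
  nodes <- treeNodes(tree)
  w <- treeWeights(tree)
  build <- function(path) {
    i <- match(path, nodes$path)
    kidIdx <- which(nodes$parent == path)
    if (length(kidIdx)) {
      tot <- rowSums(w[kidIdx, , drop = FALSE])
      o <- ordC(-tot, nodes$name[kidIdx])
      kids <- lapply(nodes$path[kidIdx][o], build)
    } else kids <- list()
    list(name = nodes$name[i], rank = nodes$rank[i],
         weight = as.list(w[i, ]), children = kids)
  }
  build("root")
}

#' Rebuild a taxon tree from its serialized form
#'
#' Inverse of \code{\link{treeToList}} on its image; used to verify the
#' round trip.
#'
#' @param x nested list from \code{treeToList} (or parsed JSON with
#'   \code{simplifyVector = FALSE}).
#' @return \code{TaxonTree}.
#' @export
treeFromList <- function(x) {
  nodes <- list(); weights <- list()
  walk <- function(node, parentPath) {
    path <- if (is.null(parentPath)) "root" else if (parentPath == "root")
      node$name else paste(parentPath, node$name, sep = "|")
    nodes[[length(nodes) + 1]] <<- data.frame(
      path = path, rank = node$rank, name = node$name,
      parent = parentPath %||% NA_character_, stringsAsFactors = FALSE)
    weights[[length(weights) + 1]] <<- unlist(node$weight)
    for (k in node$children) walk(k, path)
  }
  walk(x, NULL)
  nodeDf <- do.call(rbind, nodes)
  w <- do.call(rbind, weights)
  rownames(w) <- nodeDf$path
  ## restore canonical node order (rank depth, then path)
  depth <- match(nodeDf$rank, c("root", RANK_NAMES))
  o <- ordC(depth, nodeDf$path)
  methods::new("TaxonTree", nodes = nodeDf[o, , drop = FALSE],
               weight = w[o, , drop = FALSE])
}

#' Write the taxonomy tree JSON document
#'
#' @param tree \code{TaxonTree}.
#' @param path output file.
#' @export
writeTreeJson <- function(tree, path) {
  jsonlite::write_json(treeToList(tree), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
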