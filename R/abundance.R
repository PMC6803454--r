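#' Read a MetaBat-dialect contig depth table
#'
#' Tab-delimited file with header columns \code{contigName},
#' \code{contigLen}, \code{totalAvgDepth}, followed by one mean-depth
#' column and one variance column per sample (the
#' \code{jgi_summarize_bam_contig_depths} layout). Variance columns are
#' parsed and discarded; sample names come from the depth-column headers.
#'
#' @param path file path.
#' @return list: \code{contigs} (data.frame contig_id, length,
#'   total_avg_depth), \code{depth} (contig-by-sample matrix),
#'   \code{samples}.
#' @export
readDepthTable <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    mStop("parseError", "empty depth file")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 3 || hdr[1] != "contigName")
    mStop("parseError", "depth file must start with contigName/contigLen/totalAvgDepth header")
  extra <- hdr[-(1:3)]
  sampleIdx <- if (length(extra)) seq(1, length(extra), by = 2) else
    integer()                                  # depth, variance pairs
  samples <- sub("\\.bam$", "", extra[sampleIdx])
  body <- lines[-1]
  body <- body[nzchar(body)]
  n <- length(body)
  depth <- matrix(0, n, length(samples))
  contigs <- data.frame(contig_id = character(n), length = integer(n),
                        total_avg_depth = numeric(n),
                        stringsAsFactors = FALSE)
  if (n) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != length(hdr)))
      mStop("parseError",
            sprintf("depth file line %d: column count mismatch",
                    which(lengths(parts) != length(hdr))[1] + 1))
    contigs$contig_id <- vapply(parts, `[`, "", 1)
    contigs$length <- as.integer(vapply(parts, `[`, "", 2))
    contigs$total_avg_depth <- as.numeric(vapply(parts, `[`, "", 3))
    for (j in seq_along(samples))
      depth[, j] <- as.numeric(vapply(parts, `[`, "", 3 + sampleIdx[j]))
    if (any(is.na(depth)) || any(depth < 0))
      mStop("parseError", "invalid (missing or negative) depth value")
  }
  dimnames(depth) <- list(contigs$contig_id, samples)
  list(contigs = contigs, depth = depth, samples = samples)
}

#' Attach per-sample contig depth to gene records
#'
#' Every gene inherits the mean per-sample depth of its contig (depth is
#' reported per contig, not recomputed per base). Adds a gene-by-sample
#' \code{depth} matrix column and a scalar \code{total_avg_depth} column.
#'
#' @param records annotation \code{DataFrame} (column \code{contigid}).
#' @param depth table from \code{readDepthTable}.
#' @param strict error on a contig missing from the depth table (default
#'   TRUE); otherwise its genes get zero depth with a warning.
#' @return updated \code{DataFrame}.
#' @export
attachGeneDepth <- function(records, depth, strict = TRUE) {
  i <- match(records$contigid, depth$contigs$contig_id)
  if (any(is.na(i))) {
    missing <- unique(records$contigid[is.na(i)])
    if (strict)
      mStop("unknownContigError",
            sprintf("contig '%s' absent from depth table", missing[1]))
    warning(sprintf("%d contig(s) absent from depth table; genes set to zero depth",
                    length(missing)))
  }
  m <- matrix(0, nrow(records), length(depth$samples),
              dimnames = list(records$id, depth$samples))
  ok <- !is.na(i)
  m[ok, ] <- depth$depth[i[ok], , drop = FALSE]
  records$depth <- m
  records$total_avg_depth <- ifelse(ok, depth$contigs$total_avg_depth[i], 0)
  records
}

#' Compute a weighted per-sample abundance profile
#'
#' Sums gene weights per category and sample and normalises columns to
#' relative abundances. Genes without a category accumulate under an
#' explicit \code{"unassigned"} row so every column still partitions the
#' total; samples whose total weight is zero are flagged and report zero
#' abundance.
#'
#' @param categories named character: gene id -> category (NA for
#'   unassigned).
#' @param weights gene-by-sample numeric matrix (or vector for one
#'   sample), non-negative, rownames = gene ids.
#' @return \code{\link{ProfileMatrix}}.
#' @export
weightedProfile <- function(categories, weights) {
  genes <- names(categories)
  if (is.null(dim(weights)))
    weights <- matrix(weights, ncol = 1,
                      dimnames = list(names(weights), "weight"))
  weights <- weights[genes, , drop = FALSE]
  if (any(weights < 0))
    mStop("negativeWeightError", "weights must be non-negative")
  cat <- ifelse(is.na(categories) | !nzchar(categories), "unassigned",
                categories)
  w <- rowsum(weights, group = cat, reorder = FALSE)
  w <- w[ordC(rownames(w)), , drop = FALSE]
  tot <- colSums(w)
  zero <- tot == 0
  relab <- sweep(w, 2, ifelse(zero, 1, tot), "/")
  relab[, zero] <- 0
  methods::new("ProfileMatrix", weight = w, relab = relab,
               zeroSamples = unname(zero))
}

#' Read a spectral count table
#'
#' Tab-delimited with a header; the first column is the gene id, all later
#' columns are normalized per-sample protein expression levels. Genes
#' absent from the table are taken to have zero expression downstream.
#'
#' @param path file path.
#' @return gene-by-sample numeric matrix.
#' @export
readSpectralTable <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    mStop("parseError", "empty spectral count file")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- hdr[-1]
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != length(hdr)))
    mStop("parseError",
          sprintf("spectral file line %d: column count mismatch",
                  which(lengths(parts) != length(hdr))[1] + 1))
  genes <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(genes))
    mStop("duplicateGeneError",
          sprintf("duplicated gene id '%s' in spectral table",
                  genes[duplicated(genes)][1]))
  m <- matrix(0, length(genes), length(samples),
              dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1 + j)))
    if (any(is.na(v)))
      mStop("parseError", "non-numeric spectral count")
    m[, j] <- v
  }
  if (any(m < 0)) mStop("parseError", "negative spectral count")
  m
}

#' Expand spectral counts to a full gene set
#'
#' @param spectral matrix from \code{readSpectralTable}.
#' @param geneIds all gene ids; genes absent from the table get zero.
#' @return gene-by-sample matrix over \code{geneIds}.
#' @export
spectralWeights <- function(spectral, geneIds) {
  m <- matrix(0, length(geneIds), ncol(spectral),
              dimnames = list(geneIds, colnames(spectral)))
  common <- intersect(geneIds, rownames(spectral))
  m[common, ] <- spectral[common, , drop = FALSE]
  m
}

#' Per-sample pathway activity profile
#'
#' For each kept pathway, sums the weights of the genes supporting its
#' observed member families (a gene supporting two families of the same
#' pathway is counted once per family) and normalises per sample.
#'
#' @param recon \code{PathwayReconstruction}.
#' @param defs pathway definitions.
#' @param familyObs data.frame from \code{readFamilyMap} (family_id,
#'   gene_ids).
#' @param weights gene-by-sample weight matrix.
#' @return \code{\link{ProfileMatrix}} with one row per kept pathway.
#' @export
pathwayActivity <- function(recon, defs, familyObs, weights) {
  kept <- keptPathways(recon)
  if (is.null(dim(weights)))
    weights <- matrix(weights, ncol = 1,
                      dimnames = list(names(weights), "weight"))
  w <- matrix(0, length(kept), ncol(weights),
              dimnames = list(kept, colnames(weights)))
  for (p in kept) {
    m <- defs$members[[match(p, defs$pathway_id)]]
    for (fi in seq_len(nrow(familyObs))) {
      f <- familyObs$family_id[fi]
      if (!any(vapply(m, familyMatches, TRUE, observed = f))) next
      gs <- intersect(familyObs$gene_ids[[fi]], rownames(weights))
      if (length(gs))
        w[p, ] <- w[p, ] + colSums(weights[gs, , drop = FALSE])
    }
  }
  tot <- colSums(w)
  zero <- tot == 0
  relab <- sweep(w, 2, ifelse(zero, 1, tot), "/")
  if (any(zero)) relab[, zero] <- 0
  methods::new("ProfileMatrix", weight = w, relab = relab,
               zeroSamples = unname(zero))
}
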