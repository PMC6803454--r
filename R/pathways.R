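#' Read pathway definitions
#'
#' TSV with columns \code{pathway_id}, \code{name}, and a comma-separated
#' member list of family ids (KO or EC numbers).
#'
#' @param path file path.
#' @return data.frame with a \code{members} list-column.
#' @export
readPathwayDefs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 3))
    mStop("parseError",
          sprintf("pathway definition line %d: expected 3 columns",
                  which(nc != 3)[1]))
  defs <- data.frame(pathway_id = vapply(parts, `[`, "", 1),
                     name = vapply(parts, `[`, "", 2),
                     stringsAsFactors = FALSE)
  defs$members <- lapply(parts, function(p)
    unique(trimws(strsplit(p[3], ",", fixed = TRUE)[[1]])))
  if (any(lengths(defs$members) == 0))
    mStop("parseError", "pathway with empty member list")
  defs
}

#' Read a gene-to-family mapping file
#'
#' TSV with one \code{gene_id <TAB> family_id} pair per line (the
#' ORF-identifier-to-KO/EC mapping). Duplicate pairs collapse; the result
#' groups the supporting genes per observed family.
#'
#' @param path file path.
#' @return data.frame with \code{family_id} and a \code{gene_ids}
#'   list-column.
#' @export
readFamilyMap <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(family_id = character(),
                      gene_ids = I(list()), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 2))
    mStop("parseError",
          sprintf("family map line %d: expected 2 columns",
                  which(nc != 2)[1]))
  gene <- vapply(parts, `[`, "", 1)
  fam <- vapply(parts, `[`, "", 2)
  keep <- !duplicated(paste0(gene, "\r", fam))
  gene <- gene[keep]; fam <- fam[keep]
  fams <- sortC(unique(fam))
  data.frame(family_id = fams,
             gene_ids = I(lapply(fams, function(f) sortC(gene[fam == f]))),
             stringsAsFactors = FALSE)
}

#' EC wildcard matching
#'
#' An observed EC number may carry \code{-} wildcards in its trailing
#' fields (e.g. \code{7.1.1.-}); it matches a pathway member EC when all
#' its specified fields agree, the wildcard fields matching anything. Plain
#' ids (KOs) match by equality.
#'
#' @param observed observed family id.
#' @param member pathway member id.
#' @return logical.
#' @export
familyMatches <- function(observed, member) {
  if (observed == member) return(TRUE)
  if (!grepl("-", observed, fixed = TRUE)) return(FALSE)
  of <- strsplit(observed, ".", fixed = TRUE)[[1]]
  mf <- strsplit(member, ".", fixed = TRUE)[[1]]
  if (length(of) != length(mf)) return(FALSE)
  all(of == "-" | of == mf)
}

## pathway x observed logical incidence under wildcard matching
coverMatrix <- function(observed, defs) {
  out <- matrix(FALSE, nrow(defs), length(observed),
                dimnames = list(defs$pathway_id, observed))
  for (j in seq_along(observed))
    out[, j] <- vapply(defs$members, function(m)
      any(vapply(m, familyMatches, TRUE, observed = observed[j])), TRUE)
  out
}

## Exact minimum set cover by iterative-deepening DFS in lexicographic
## order with a coverage bound: the first cover found at the smallest
## feasible cardinality is also the lexicographically smallest id-set of
## that cardinality (candidates are scanned in sorted-id order).
exactCover <- function(cov) {
  nFam <- ncol(cov)
  if (nFam == 0) return(integer())
  nP <- nrow(cov)
  sizes <- rowSums(cov)
  for (k in seq_len(nP)) {
    found <- NULL
    dfs <- function(startIdx, chosen, covered) {
      if (!is.null(found)) return()
      if (all(covered)) { found <<- chosen; return() }
      left <- k - length(chosen)
      if (left == 0 || startIdx > nP) return()
      cand <- startIdx:nP
      ## bound: even the `left` largest remaining sets cannot cover
      need <- sum(!covered)
      best <- sort(sizes[cand], decreasing = TRUE)
      if (sum(best[seq_len(min(left, length(best)))]) < need) return()
      for (i in cand) {
        if (!any(cov[i, ] & !covered)) next
        dfs(i + 1L, c(chosen, i), covered | cov[i, ])
        if (!is.null(found)) return()
      }
    }
    dfs(1L, integer(), rep(FALSE, nFam))
    if (!is.null(found)) return(found)
  }
  integer()
}

greedyCover <- function(cov) {
  chosen <- integer()
  covered <- rep(FALSE, ncol(cov))
  while (!all(covered)) {
    gain <- rowSums(cov[, !covered, drop = FALSE])
    gain[chosen] <- -1
    chosen <- c(chosen, which.max(gain))  # rows sorted by id: tie -> smallest
    covered <- covered | cov[chosen[length(chosen)], ]
  }
  chosen
}

#' Reconstruct the minimal pathway set (parsimony)
#'
#' Finds the smallest set of pathways whose members jointly cover every
#' observed family that belongs to at least one pathway (observed families
#' in no pathway are reported as uncovered). Exact mode solves the set
#' cover to optimality, breaking ties toward the lexicographically smallest
#' id-set; greedy mode iteratively picks the pathway covering the most
#' still-uncovered families (ties to the smallest id) and gives a
#' conservative upper bound. Auto mode uses exact when at most
#' \code{exactLimit} candidate pathways intersect the observation, greedy
#' otherwise.
#'
#' @param observed character vector of observed family ids (KOs or ECs,
#'   possibly wildcarded).
#' @param defs pathway definitions from \code{readPathwayDefs}.
#' @param mode "auto", "exact" or "greedy".
#' @param exactLimit candidate-count threshold for auto mode (default 20).
#' @return \code{\link{PathwayReconstruction}}.
#' @export
reconstructMinimal <- function(observed, defs,
                               mode = c("auto", "exact", "greedy"),
                               exactLimit = 20) {
  mode <- match.arg(mode)
  stopifnot(nrow(defs) > 0)
  observed <- sortC(unique(observed))
  defs <- defs[ordC(defs$pathway_id), , drop = FALSE]
  cov <- coverMatrix(observed, defs)
  coverable <- colSums(cov) > 0
  uncovered <- observed[!coverable]
  candidate <- rowSums(cov[, coverable, drop = FALSE]) > 0
  covC <- cov[candidate, coverable, drop = FALSE]
  if (mode == "auto")
    mode <- if (sum(candidate) <= exactLimit) "exact" else "greedy"
  idx <- if (sum(candidate) == 0) integer()
         else if (mode == "exact") exactCover(covC)
         else greedyCover(covC)
  kept <- defs$pathway_id[candidate][idx]
  kept <- sortC(kept)
  fill <- vapply(kept, function(p) {
    m <- defs$members[[match(p, defs$pathway_id)]]
    hit <- vapply(m, function(mm)
      any(vapply(observed, familyMatches, TRUE, member = mm)), TRUE)
    sum(hit) / length(m)
  }, 0)
  methods::new("PathwayReconstruction", kept = kept, uncovered = uncovered,
               fill = fill, mode = mode, observed = observed)
}

#' Per-pathway coverage report
#'
#' One row per kept pathway with its member count, the observed members,
#' and the fill ratio (observed members over all members).
#'
#' @param recon \code{PathwayReconstruction}.
#' @param defs pathway definitions.
#' @return data.frame: pathway_id, name, n_members, n_observed, fill,
#'   observed_members (";"-joined).
#' @export
pathwayReport <- function(recon, defs) {
  kept <- keptPathways(recon)
  observed <- recon@observed
  rows <- lapply(kept, function(p) {
    i <- match(p, defs$pathway_id)
    m <- defs$members[[i]]
    hit <- vapply(m, function(mm)
      any(vapply(observed, familyMatches, TRUE, member = mm)), TRUE)
    data.frame(pathway_id = p, name = defs$name[i],
               n_members = length(m), n_observed = sum(hit),
               fill = sum(hit) / length(m),
               observed_members = paste(sortC(m[hit]), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||%
    data.frame(pathway_id = character(), name = character(),
               n_members = integer(), n_observed = integer(),
               fill = numeric(), observed_members = character())
}
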