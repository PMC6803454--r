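#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

## Canonical GTDB-style rank prefixes, inner ring to outer ring.
RANK_PREFIXES <- c("d", "p", "c", "o", "f", "g", "s")
RANK_NAMES <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")
UNCLASSIFIED <- "unclassified"

#' TaxonTree: weighted hierarchical taxonomy aggregation
#'
#' A tree over rank-prefixed lineage paths in which every node carries one
#' weight per sample, equal to the summed weights of all genes whose lineage
#' passes through that node. Genes lacking a name at some rank are padded
#' with an explicit \code{"unclassified"} pseudo-taxon so that the weights on
#' every ring partition the total: at each rank the node weights sum to the
#' root weight, which makes ring proportions directly comparable to a
#' sunburst display.
#'
#' @slot nodes data.frame with columns \code{path} (pipe-joined names from
#'   the root), \code{rank} (one of domain...species, or \code{"root"}),
#'   \code{name}, and \code{parent} (path of the parent node, \code{NA} for
#'   the root).
#' @slot weight numeric matrix, one row per node (rownames = \code{path}),
#'   one column per sample.
#' @exportClass TaxonTree
setClass("TaxonTree",
  representation(nodes = "data.frame", weight = "matrix"))

setValidity("TaxonTree", function(object) {
  n <- object@nodes
  w <- object@weight
  if (nrow(n) != nrow(w))
    return("nodes and weight row counts differ")
  if (!identical(rownames(w), n$path))
    return("weight rownames must equal node paths")
  if (any(w < 0))
    return("negative node weights")
  ## parent weight == sum of child weights (all genes are padded to full
  ## depth, so internal nodes carry no at-node weight)
  for (i in which(n$rank != "species")) {
    kids <- which(n$parent == n$path[i])
    if (length(kids)) {
      delta <- abs(w[i, ] - colSums(w[kids, , drop = FALSE]))
      if (any(delta > 1e-8 * max(1, max(w))))
        return(sprintf("weight not conserved at node '%s'", n$path[i]))
    }
  }
  TRUE
})

#' ProfileMatrix: per-sample category abundance profile
#'
#' A category-by-sample matrix of weights (gene counts, sequencing depth, or
#' spectral counts summed over the genes assigned to each category) together
#' with the per-sample relative abundances. Within each sample with positive
#' total weight the relative abundances sum to one; samples with zero total
#' weight are flagged and report zero abundance everywhere.
#'
#' @slot weight numeric matrix, categories x samples.
#' @slot relab numeric matrix of the same shape, columns summing to 1 for
#'   samples with positive total.
#' @slot zeroSamples logical, one flag per sample.
#' @exportClass ProfileMatrix
setClass("ProfileMatrix",
  representation(weight = "matrix", relab = "matrix",
                 zeroSamples = "logical"))

setValidity("ProfileMatrix", function(object) {
  if (!identical(dim(object@weight), dim(object@relab)))
    return("weight and relab dimensions differ")
  if (length(object@zeroSamples) != ncol(object@weight))
    return("one zero-total flag per sample required")
  if (any(object@weight < 0))
    return("negative weights")
  ok <- !object@zeroSamples
  if (any(ok)) {
    s <- colSums(object@relab[, ok, drop = FALSE])
    if (any(abs(s - 1) > 1e-9))
      return("relative abundances must sum to 1 per non-empty sample")
  }
  TRUE
})

#' PathwayReconstruction: minimal pathway set explaining observed families
#'
#' Result of the parsimony reconstruction: the smallest set of pathways whose
#' members jointly cover every observed gene family that belongs to at least
#' one pathway, plus coverage diagnostics. \code{uncovered} holds observed
#' families belonging to no pathway at all; \code{fill} is, for each kept
#' pathway, the fraction of its member families that were observed.
#'
#' @slot kept character, ids of the retained pathways.
#' @slot uncovered character, observed families outside every pathway.
#' @slot fill named numeric in [0,1], one entry per kept pathway.
#' @slot mode character, "exact" or "greedy" (the mode actually used).
#' @slot observed character, the observed family ids as supplied.
#' @exportClass PathwayReconstruction
setClass("PathwayReconstruction",
  representation(kept = "character", uncovered = "character",
                 fill = "numeric", mode = "character",
                 observed = "character"))

setValidity("PathwayReconstruction", function(object) {
  if (!object@mode %in% c("exact", "greedy"))
    return("mode must be 'exact' or 'greedy'")
  if (!setequal(names(object@fill), object@kept))
    return("fill must be named by the kept pathways")
  if (length(object@fill) && (any(object@fill < 0) || any(object@fill > 1)))
    return("fill ratios must lie in [0,1]")
  TRUE
})

## ---- generics -------------------------------------------------------------

#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))
#' @export
setGeneric("treeWeights", function(x) standardGeneric("treeWeights"))
#' @export
setGeneric("profileWeights", function(x) standardGeneric("profileWeights"))
#' @export
setGeneric("relAbundance", function(x) standardGeneric("relAbundance"))
#' @export
setGeneric("profileSamples", function(x) standardGeneric("profileSamples"))
#' @export
setGeneric("keptPathways", function(x) standardGeneric("keptPathways"))
#' @export
setGeneric("uncoveredFamilies", function(x) standardGeneric("uncoveredFamilies"))
#' @export
setGeneric("pathwayFill", function(x) standardGeneric("pathwayFill"))

#' @describeIn TaxonTree node table (path, rank, name, parent)
#' @param x a \code{TaxonTree}
#' @export
setMethod("treeNodes", "TaxonTree", function(x) x@nodes)

#' @describeIn TaxonTree node-by-sample weight matrix
#' @export
setMethod("treeWeights", "TaxonTree", function(x) x@weight)

#' @describeIn ProfileMatrix category-by-sample weight matrix
#' @param x a \code{ProfileMatrix}
#' @export
setMethod("profileWeights", "ProfileMatrix", function(x) x@weight)

#' @describeIn ProfileMatrix category-by-sample relative abundances
#' @export
setMethod("relAbundance", "ProfileMatrix", function(x) x@relab)

#' @describeIn ProfileMatrix sample names
#' @export
setMethod("profileSamples", "ProfileMatrix", function(x) colnames(x@weight))

#' @describeIn PathwayReconstruction ids of the retained pathways
#' @param x a \code{PathwayReconstruction}
#' @export
setMethod("keptPathways", "PathwayReconstruction", function(x) x@kept)

#' @describeIn PathwayReconstruction observed families in no pathway
#' @export
setMethod("uncoveredFamilies", "PathwayReconstruction",
          function(x) x@uncovered)

#' @describeIn PathwayReconstruction observed-member fraction per kept pathway
#' @export
setMethod("pathwayFill", "PathwayReconstruction", function(x) x@fill)

## ---- show -----------------------------------------------------------------

setMethod("show", "TaxonTree", function(object) {
  w <- object@weight
  cat(sprintf("TaxonTree: %d nodes, %d sample(s), root weight %s\n",
              nrow(object@nodes), ncol(w),
              paste(fmtDepth(w["root", ]), collapse = ", ")))
  byRank <- table(object@nodes$rank)
  cat("  nodes per rank:",
      paste(sprintf("%s=%d", names(byRank), byRank), collapse = " "), "\n")
})

setMethod("show", "ProfileMatrix", function(object) {
  cat(sprintf("ProfileMatrix: %d categories x %d sample(s)\n",
              nrow(object@weight), ncol(object@weight)))
  if (any(object@zeroSamples))
    cat("  zero-total samples:",
        paste(colnames(object@weight)[object@zeroSamples], collapse = ", "),
        "\n")
})

setMethod("show", "PathwayReconstruction", function(object) {
  cat(sprintf(
    "PathwayReconstruction (%s): %d pathway(s) kept, %d uncovered family(ies)\n",
    object@mode, length(object@kept), length(object@uncovered)))
  if (length(object@kept))
    cat("  kept:", paste(object@kept, collapse = ", "), "\n")
})
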