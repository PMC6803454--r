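# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: overlap groups by explicit pairwise intersection + BFS,
# set cover by exhaustive subset enumeration over bitmasks, best hit by a
# full scan.

# Connected components of the pairwise interval-overlap graph, then keep
# hits at the group-minimum E-value.
oracleResolveHits <- function(hits) {
  n <- nrow(hits)
  if (n == 0) return(hits)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- hits$contig_id[i] == hits$contig_id[j] &&
      hits$start[i] <= hits$end[j] && hits$start[j] <= hits$end[i]
  }
  comp <- rep(NA_integer_, n)
  cur <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  keep <- logical(n)
  for (g in unique(comp)) {
    m <- comp == g
    keep[m] <- hits$evalue[m] == min(hits$evalue[m])
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$contig_id, out$start, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive minimum set cover: pathways as bitmasks over <= 30 families.
# Enumerates every pathway subset (with incrementally computed union masks
# and popcounts) and returns the minimum covering cardinality (NA when
# uncoverable).
oracleMinCoverSize <- function(masks, targetMask) {
  np <- length(masks)
  if (targetMask == 0) return(0L)
  nSub <- 2^np
  orMask <- integer(nSub)
  pc <- integer(nSub)
  best <- NA_integer_
  for (s in seq_len(nSub - 1)) {
    low <- bitwAnd(s, -s)
    orMask[s + 1] <- bitwOr(orMask[s - low + 1],
                            masks[round(log2(low)) + 1])
    pc[s + 1] <- pc[s - low + 1] + 1L
    if ((is.na(best) || pc[s + 1] < best) &&
        bitwAnd(orMask[s + 1], targetMask) == targetMask)
      best <- pc[s + 1]
  }
  best
}

# Full-scan best hit under the (evalue, -bitscore, subject_id) key.
oracleBestHit <- function(hits) {
  if (nrow(hits) == 0) return(NULL)
  best <- 1L
  for (i in seq_len(nrow(hits))[-1]) {
    a <- hits[i, ]; b <- hits[best, ]
    better <- (a$evalue < b$evalue) ||
      (a$evalue == b$evalue && a$bitscore > b$bitscore) ||
      (a$evalue == b$evalue && a$bitscore == b$bitscore &&
         a$subject_id < b$subject_id)
    if (better) best <- i
  }
  hits[best, , drop = FALSE]
}

# Random rRNA hit set on a handful of contigs with deliberate overlaps and
# occasional exact E-value ties.
randomHitSet <- function(n = 8, nContig = 2, tieProb = 0.2) {
  ctg <- sprintf("c%d", sample.int(nContig, n, replace = TRUE))
  start <- sample.int(500, n, replace = TRUE)
  width <- sample(20:120, n, replace = TRUE)
  ev <- 10^runif(n, -40, -5)
  if (n >= 2 && runif(1) < tieProb) ev[2] <- ev[1]
  rrnaHits(ctg, sample(c("Bacteria", "Archaea", "Eukaryota"), n, TRUE),
           sample(c("5S", "16S", "23S"), n, TRUE), start, start + width,
           "+", ev)
}

# Random set-cover instance over at most `maxP` pathways / `maxF` families.
randomCoverInstance <- function(maxP = 12, maxF = 30) {
  np <- sample(2:maxP, 1)
  nf <- sample(4:maxF, 1)
  fams <- sprintf("F%02d", seq_len(nf))
  members <- lapply(seq_len(np), function(i)
    sample(fams, sample(1:min(8, nf), 1)))
  defs <- data.frame(pathway_id = sprintf("P%02d", seq_len(np)),
                     name = sprintf("pathway %d", seq_len(np)),
                     stringsAsFactors = FALSE)
  defs$members <- members
  observed <- sample(fams, sample(1:nf, 1))
  list(defs = defs, observed = observed, fams = fams)
}

localTmpDir <- function(envir = parent.frame()) {
  d <- tempfile("metannot")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = envir)
  d
}
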