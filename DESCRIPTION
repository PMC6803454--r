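Package: metannot
Title: Metagenome Annotation Engine with Taxonomic Profiling and Minimal
    Pathway Reconstruction
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An annotation engine for assembled metagenome contigs and
    metagenome-assembled genomes (MAGs). Validates and cleans input contigs,
    resolves competing rRNA model hits, masks noncoding features before open
    reading frame filtering, merges homology evidence from pairwise
    (BLAST/DIAMOND tabular) and profile (HMMER3 domtblout) searches into
    per-gene annotation records, classifies genes taxonomically from best
    reference hits with hierarchical community and per-MAG profiling and
    contamination detection, reconstructs the minimal set of metabolic
    pathways explaining observed KO/EC families by exact or greedy set cover,
    and computes depth- and spectral-count-weighted relative abundance
    profiles. Includes a deterministic synthetic fixture generator with
    planted ground truth, standard-format readers and writers (FASTA, GFF3,
    tabular hit files, MetaBat depth tables), and a resumable pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
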