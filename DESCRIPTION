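Package: asmgrade
Title: Reference-Based Evaluation of Genome Assemblies with Simulated Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for grading de novo genome assemblies
    against a reference. Simulates platform-specific (454-style and
    Illumina-style) fragment and paired-end read sets with configurable
    error models and ground-truth placement tags; computes the standard
    contig and scaffold statistics block (N50, size-class counts);
    acquires assembly-versus-reference alignments from MUMmer show-coords
    or PAF files, or from a built-in exact-anchor aligner usable at test
    scale; and computes a full reference-alignment fidelity battery
    (representation, mismatch and indel rates, misassembly detection by
    relocation/inversion/translocation breakpoints, gap and captured-gap
    accounting, ambiguity measures), both genome-wide and restricted to
    GFF3-annotated region classes such as genes, repeats, and protein
    families. A fixtures module generates synthetic genomes, annotations,
    and deliberately corrupted assemblies with machine-readable ground
    truth, so every metric is testable without external data or binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    DBI,
    RSQLite,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
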