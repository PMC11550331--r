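Package: t2tqc
Title: Assembly Continuity Inspection from Curated Long-Read Alignment Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses how close a genome assembly is to the telomere-to-telomere
    (gapless) standard at single-base resolution. Long-read alignments (HiFi
    and/or ONT, from one or two aligners per platform, BAM or PAF) are filtered
    on mapping quality, identity and clipping, integrated across aligners with
    a high-mapping-quality rescue rule, and converted into end-trimmed per-base
    coverage. Regions with zero or extremely low curated coverage are reported
    as candidate assembly issues, chromosomes are split into curated contigs at
    those loci, and a 0-100 continuity score combining curated contig N50 and
    contig count is computed per genome and per chromosome. Includes a
    deterministic synthetic-data generator (toy assemblies, tiling alignments
    with controlled defects, gap-injection and structural-issue experiments)
    so the whole pipeline runs without external data or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
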