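#' Sensitivity of contiguity metrics to random gap injection
#'
#' For each gap count, fragments the genome at random breakpoints
#' ([simulate_gaps()]) over several replicates and records the mean scaled
#' contig-N50 score, scaled auN score and continuity score. N50 plateaus once
#' it saturates at the chromosome N50 (many gap layouts leave it untouched),
#' while the continuity score keeps falling through the contig-count ratio —
#' the property that makes it the more sensitive statistic for near-complete
#' assemblies.
#'
#' @param chrom_lengths Integer vector of chromosome lengths.
#' @param gap_counts Integer vector of gap counts to test.
#' @param replicates Replicates per gap count.
#' @param seed Integer seed.
#' @return `data.frame` with one row per gap count: `n_gaps`,
#'   `n50_score`, `aun_score`, `continuity_score` (replicate means).
#' @export
gap_injection_curve <- function(chrom_lengths, gap_counts,
                                replicates = 50L, seed = 1L) {
  exp_n50 <- contig_n50(chrom_lengths)
  exp_aun <- aun(chrom_lengths)
  exp_num <- length(chrom_lengths)
  rows <- lapply(gap_counts, function(g) {
    m <- vapply(seq_len(replicates), function(r) {
      frags <- simulate_gaps(chrom_lengths, g,
                             seed = seed + 1009L * g + r)
      c(scale_score(contig_n50(frags), exp_n50),
        scale_score(aun(frags), exp_aun),
        continuity_score(contig_n50(frags), exp_n50,
                         length(frags), exp_num))
    }, numeric(3))
    data.frame(n_gaps = g, n50_score = mean(m[1L, ]),
               aun_score = mean(m[2L, ]), continuity_score = mean(m[3L, ]))
  })
  do.call(rbind, rows)
}

#' End-to-end simulated-issue detection experiment
#'
#' Generates a clean toy assembly, injects insertions and deletions
#' ([inject_structural_issues()]), regenerates tiling fixture alignments
#' from the mutated assembly with spanning support removed at the event loci
#' ([defects_from_truth()]), runs the full curation and issue-calling
#' pipeline, and scores the detected issue regions against the truth table
#' with locus-level (padded) matching.
#'
#' @param chrom_lengths Chromosome lengths of the clean assembly.
#' @param n_ins,n_del Number of insertion / deletion events.
#' @param seed Integer seed.
#' @param read_length,depth Fixture alignment parameters.
#' @param pad Truth-matching pad passed to [detection_metrics()].
#' @return List with `truth`, `detected` (merged issue regions), `metrics`
#'   ([detection_metrics()] table) and `result` (the continuity result on
#'   the mutated assembly).
#' @export
injection_experiment <- function(chrom_lengths, n_ins = 5L, n_del = 5L,
                                 seed = 1L, read_length = 20000L, depth = 8,
                                 pad = 10000L) {
  base_spec <- fixture_spec(chrom_lengths, read_length = read_length,
                            depth = depth, seed = seed)
  clean <- make_assembly(base_spec)
  inj <- inject_structural_issues(clean, n_ins, n_del, seed = seed + 1L)
  mut_lengths <- stats::setNames(Biostrings::width(inj$assembly),
                                 names(inj$assembly))
  mut_spec <- fixture_spec(mut_lengths, read_length = read_length,
                           depth = depth,
                           defects = defects_from_truth(inj$truth),
                           seed = seed + 2L)
  dir <- tempfile("injection_")
  files <- make_alignments(mut_spec, dir)
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- filter_config()
  cur <- curate_platform(list(A = files$hifi$A$paf, B = files$hifi$B$paf),
                         "hifi", mut_lengths, cfg)
  insp <- inspect_curated(cur$curated, mut_lengths, cfg)
  metrics <- detection_metrics(insp$issues, inj$truth, pad = pad)
  list(truth = inj$truth, detected = insp$issues, metrics = metrics,
       result = insp$result)
}
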