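#' Read an alignment file, dispatching on its extension
#'
#' `.paf` goes to [read_paf()]; `.bam`/`.sam` to [read_bam()].
#'
#' @inheritParams read_paf
#' @return Alignment records.
#' @export
read_alignments <- function(path, aligner_id = "A", platform = "hifi") {
  if (grepl("\\.paf(\\.gz)?$", path, ignore.case = TRUE))
    read_paf(path, aligner_id, platform)
  else if (grepl("\\.(bam|sam)$", path, ignore.case = TRUE))
    read_bam(path, aligner_id, platform)
  else stop("cannot tell alignment format from extension: ", path)
}

#' Inspection run configuration
#'
#' @param assembly Path to the assembly FASTA.
#' @param alignments Named list, one entry per platform ("hifi" and/or
#'   "ont"); each entry a named character vector or list with element `A`
#'   (required) and optionally `B` — the two aligners' BAM or PAF files for
#'   that platform's reads.
#' @param filter A [filter_config()].
#' @param outdir Output directory.
#' @param prefix Output file prefix.
#' @param plot Whether to write per-chromosome depth plots.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(assembly, alignments, filter = filter_config(),
                       outdir = ".", prefix = "continuity", plot = FALSE) {
  if (!file.exists(assembly)) stop("assembly not found: ", assembly)
  if (length(alignments) == 0L) stop("at least one platform is required")
  if (is.null(names(alignments)) ||
      !all(names(alignments) %in% c("hifi", "ont")))
    stop("alignments must be named by platform (hifi, ont)")
  for (p in names(alignments)) {
    al <- alignments[[p]]
    if (!("A" %in% names(al)))
      stop("platform ", p, " needs at least aligner A")
    for (f in unlist(al)) if (!file.exists(f)) stop("alignment file not found: ", f)
  }
  structure(list(assembly = assembly, alignments = alignments,
                 filter = filter, outdir = outdir, prefix = prefix,
                 plot = plot),
            class = "run_config")
}

# curate one platform: read, filter, integrate two aligners
curate_platform <- function(files, platform, target_lengths, cfg) {
  rec_a <- read_alignments(files[["A"]], "A", platform)
  fa <- filter_alignments(rec_a, cfg)
  if (!is.null(files[["B"]])) {
    rec_b <- read_alignments(files[["B"]], "B", platform)
    fb <- filter_alignments(rec_b, cfg)
    curated <- integrate_aligners(fa$kept, fb$kept, cfg, platform)
    stats <- rbind(A = fa$stats, B = fb$stats)
  } else {
    curated <- integrate_aligners(fa$kept, NULL, cfg, platform)
    stats <- rbind(A = fa$stats)
  }
  list(curated = curated, stats = stats)
}

# depth -> issues -> score for one curated set
inspect_curated <- function(curated, target_lengths, cfg) {
  profile <- compute_depth(curated, target_lengths, cfg$trim_len)
  raw <- call_raw_issues(profile, cfg)
  issues <- merge_issues(raw, target_lengths, cfg)
  result <- evaluate_continuity(target_lengths, issues)
  list(profile = profile, raw_issues = raw, issues = issues, result = result)
}

report_rows <- function(result, platform) {
  genome <- data.frame(
    platform = platform, scope = "genome", name = "genome",
    length = sum(as.numeric(result$per_chromosome$length)),
    obs_n50 = result$obs_n50, exp_n50 = result$exp_n50,
    obs_num = result$obs_num, exp_num = result$exp_num,
    obs_aun = result$obs_aun,
    score = result$score, stringsAsFactors = FALSE
  )
  per <- result$per_chromosome
  chrom <- data.frame(
    platform = platform, scope = "chromosome", name = per$target_name,
    length = per$length, obs_n50 = per$obs_n50, exp_n50 = per$length,
    obs_num = per$obs_num, exp_num = 1L, obs_aun = per$obs_aun,
    score = per$score, stringsAsFactors = FALSE
  )
  rbind(genome, chrom)
}

#' Run the full continuity inspection
#'
#' Reads and filters each platform's alignments, integrates the two aligners
#' (consensus + rescue), merges platforms, computes curated depth, calls and
#' merges issue regions, and scores the assembly. Writes, under
#' `outdir/prefix.*`: an issues BED per platform and combined, the combined
#' depth BedGraph, a TSV score report (genome and per-chromosome rows per
#' platform and combined), a log with per-reason filter counts, and optional
#' depth plots. The headline result is the combined profile when two
#' platforms are given, else the single platform's.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with per-platform and combined inspection
#'   results (`$combined$result$score` is the headline genome score), the
#'   report `data.frame`, and the written file paths.
#' @export
run_inspection <- function(config) {
  cfg <- config$filter
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  target_lengths <- Biostrings::fasta.seqlengths(config$assembly)
  target_lengths <- stats::setNames(as.integer(target_lengths),
                                    names(target_lengths))
  out_path <- function(...) file.path(config$outdir,
                                      paste0(config$prefix, ".", ...))

  platforms <- names(config$alignments)
  per_platform <- list()
  log_lines <- character(0)
  for (p in platforms) {
    cur <- curate_platform(config$alignments[[p]], p, target_lengths, cfg)
    insp <- inspect_curated(cur$curated, target_lengths, cfg)
    insp$curated <- cur$curated
    insp$filter_stats <- cur$stats
    per_platform[[p]] <- insp
    write_issues_bed(insp$issues, out_path("issues.", p, ".bed"))
    for (al in rownames(cur$stats))
      log_lines <- c(log_lines, paste0(
        "[", p, "/aligner ", al, "] ",
        paste(names(cur$stats[al, ]), cur$stats[al, ], sep = "=",
              collapse = " ")))
  }

  combined <- if (length(platforms) > 1L) {
    sets <- lapply(per_platform, `[[`, "curated")
    insp <- inspect_curated(do.call(merge_platforms, sets), target_lengths, cfg)
    insp$curated <- do.call(merge_platforms, sets)
    insp
  } else per_platform[[1L]]
  combined_label <- if (length(platforms) > 1L)
    paste(platforms, collapse = "+") else platforms

  write_issues_bed(combined$issues, out_path("issues.combined.bed"))
  write_depth_track(combined$profile, out_path("depth.bedgraph"))

  report <- do.call(rbind, c(
    lapply(platforms, function(p) report_rows(per_platform[[p]]$result, p)),
    if (length(platforms) > 1L) list(report_rows(combined$result,
                                                 combined_label))
  ))
  report_path <- out_path("report.tsv")
  utils::write.table(format(report, digits = 6, scientific = FALSE,
                            trim = TRUE),
                     report_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  log_lines <- c(log_lines, paste0(
    "headline platform(s)=", combined_label,
    " genome_score=", format(combined$result$score, digits = 6),
    " issues=", nrow(combined$issues)))
  writeLines(log_lines, out_path("log"))

  if (isTRUE(config$plot))
    plot_depth(combined$profile, config$outdir,
               paste0(config$prefix, ".depth"), combined$issues)

  invisible(list(per_platform = per_platform, combined = combined,
                 platforms = platforms, report = report,
                 target_lengths = target_lengths,
                 files = list(report = report_path,
                              bedgraph = out_path("depth.bedgraph"),
                              issues_combined = out_path("issues.combined.bed"),
                              log = out_path("log"))))
}

#' Recompute continuity scores from an issues BED
#'
#' Rebuilds curated contigs and scores from a previously written issues BED
#' plus the assembly's sequence lengths, without re-reading alignments.
#'
#' @param issues_bed Path to a BED written by [write_issues_bed()].
#' @param target_lengths Named integer vector of sequence lengths, or a FASTA
#'   path.
#' @return A `"continuity_result"` ([evaluate_continuity()]).
#' @export
score_from_issues <- function(issues_bed, target_lengths) {
  if (is.character(target_lengths) && length(target_lengths) == 1L) {
    target_lengths <- Biostrings::fasta.seqlengths(target_lengths)
    target_lengths <- stats::setNames(as.integer(target_lengths),
                                      names(target_lengths))
  }
  lines <- readLines(issues_bed)
  lines <- lines[!startsWith(lines, "#")]
  issues <- if (length(lines)) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    issue_regions(vapply(f, `[[`, "", 1L),
                  as.integer(vapply(f, `[[`, "", 2L)),
                  as.integer(vapply(f, `[[`, "", 3L)),
                  vapply(f, `[[`, "", 4L),
                  as.integer(vapply(f, `[[`, "", 5L)),
                  as.numeric(vapply(f, `[[`, "", 6L)))
  } else issue_regions()
  evaluate_continuity(target_lengths, issues)
}
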