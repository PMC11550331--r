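#' Contig N50
#'
#' Length of the shortest contig such that contigs of that length or longer
#' cover at least half the total assembly length.
#'
#' @param lengths Positive contig lengths (non-empty).
#' @return The N50 length.
#' @export
contig_n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list")
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Area under the Nx curve (auN / E-size)
#'
#' Length-weighted mean contig size, `sum(l^2) / sum(l)` — the expected
#' length of the contig containing a uniformly random assembly base, a
#' continuous alternative to N50.
#'
#' @inheritParams contig_n50
#' @return The auN value.
#' @export
aun <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list")
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  l <- as.numeric(lengths)
  sum(l^2) / sum(l)
}

#' Scale a contiguity statistic against its theoretical maximum
#'
#' Linear 0-100 scaling: `100 * value / theoretical_max`. Used to put contig
#' N50 and auN on the same footing as the continuity score.
#'
#' @param value Observed statistic, `0 <= value <= theoretical_max`.
#' @param theoretical_max Positive theoretical maximum (e.g. chromosome N50).
#' @return Score in `[0, 100]`.
#' @export
scale_score <- function(value, theoretical_max) {
  if (any(theoretical_max <= 0)) stop("theoretical_max must be positive")
  100 * value / theoretical_max
}

#' Continuity score from curated contig statistics
#'
#' Combines the curated-contig N50 ratio and the contig-count ratio into a
#' single 0-100 score:
#'
#' \deqn{100 \log_2\!\left(1 + \frac{obs_{N50}/exp_{N50} +
#'   exp_{num}/obs_{num}}{2}\right)}
#'
#' The score equals 100 exactly when both ratios are 1 (a truly gapless
#' assembly); it is increasing in `obs_n50`, strictly decreasing in
#' `obs_num`, bounded in `(0, 100]`, and stays sensitive through the count
#' ratio after the N50 ratio saturates.
#'
#' The N50 ratio is capped at 1: because issue bases are removed from the
#' curated assembly, its total length shrinks, and the curated contig N50
#' can then arithmetically exceed the chromosome N50 computed on the
#' full-length assembly (the half-length threshold moved). A curated N50 at
#' or beyond the theoretical maximum simply means the N50 statistic has
#' saturated and carries no further continuity information.
#'
#' @param obs_n50 Curated contig N50.
#' @param exp_n50 Theoretical maximum contig N50 (chromosome N50).
#' @param obs_num Curated contig count.
#' @param exp_num Chromosome / sequence count.
#' @return Score in `(0, 100]`.
#' @export
continuity_score <- function(obs_n50, exp_n50, obs_num, exp_num) {
  if (any(obs_num == 0)) stop("obs_num must be positive")
  if (any(exp_n50 <= 0)) stop("exp_n50 must be positive")
  100 * log2(1 + (pmin(1, obs_n50 / exp_n50) + exp_num / obs_num) / 2)
}

#' Evaluate assembly continuity from merged issues
#'
#' Splits the assembly into curated contigs at the merged issue loci and
#' computes observed versus theoretical contiguity statistics plus the
#' continuity score, for the whole genome and per chromosome. Per-chromosome
#' scoring uses each chromosome's own theoretical maximum: `exp_num = 1` and
#' `exp_n50` equal to the chromosome length. A chromosome left with no
#' curated contig at all (fully unsupported) scores 0.
#'
#' @param target_lengths Named integer vector of assembly sequence lengths.
#' @param merged_issues Disjoint issue regions ([merge_issues()]); may be
#'   empty.
#' @return An object of class `"continuity_result"`: list with `obs_n50`,
#'   `exp_n50`, `obs_num`, `exp_num`, `obs_aun`, `exp_aun`, `score`,
#'   `contigs` and `per_chromosome` (`data.frame`, one row per sequence).
#' @export
evaluate_continuity <- function(target_lengths, merged_issues = NULL) {
  if (length(target_lengths) == 0L) stop("no target sequences")
  if (is.null(merged_issues)) merged_issues <- issue_regions()
  cs <- split_curated_contigs(target_lengths, merged_issues)
  exp_n50 <- contig_n50(target_lengths)
  exp_num <- length(target_lengths)
  obs_n50 <- if (length(cs$lengths)) contig_n50(cs$lengths) else 0
  obs_num <- length(cs$lengths)
  score <- if (obs_num > 0)
    continuity_score(obs_n50, exp_n50, obs_num, exp_num) else 0

  per <- lapply(names(target_lengths), function(t) {
    ctg <- cs$contigs[cs$contigs$target_name == t, , drop = FALSE]
    lens <- ctg$end - ctg$start
    if (length(lens) == 0L)
      return(data.frame(target_name = t,
                        length = as.integer(target_lengths[[t]]),
                        obs_n50 = 0, obs_num = 0L, obs_aun = 0, score = 0,
                        stringsAsFactors = FALSE))
    data.frame(
      target_name = t, length = as.integer(target_lengths[[t]]),
      obs_n50 = contig_n50(lens), obs_num = length(lens),
      obs_aun = aun(lens),
      score = continuity_score(contig_n50(lens), target_lengths[[t]],
                               length(lens), 1L),
      stringsAsFactors = FALSE
    )
  })

  structure(list(
    obs_n50 = obs_n50, exp_n50 = exp_n50,
    obs_num = obs_num, exp_num = exp_num,
    obs_aun = if (obs_num > 0) aun(cs$lengths) else 0,
    exp_aun = aun(target_lengths),
    score = score,
    contigs = cs$contigs,
    per_chromosome = do.call(rbind, per)
  ), class = "continuity_result")
}

#' @export
print.continuity_result <- function(x, ...) {
  cat("Assembly continuity result\n")
  cat(sprintf("  curated contigs: %d (chromosomes: %d)\n", x$obs_num, x$exp_num))
  cat(sprintf("  curated contig N50: %s (theoretical max: %s)\n",
              format(x$obs_n50, big.mark = ","),
              format(x$exp_n50, big.mark = ",")))
  cat(sprintf("  continuity score: %.2f / 100\n", x$score))
  invisible(x)
}

#' Precision / recall / F1 of issue detection against a truth set
#'
#' A truth locus is recovered (TP) when some detected region overlaps its
#' padded interval by at least one base; the pad (default 10 kb on each side)
#' makes the match locus-level rather than base-level, appropriate when exact
#' breakpoint coordinates shift under curation. Detected regions matching no
#' padded truth locus are false positives; unmatched truths are false
#' negatives. When truth loci carry a `region_class` column, metrics are also
#' reported per class.
#'
#' @param detected `data.frame` with `target_name`, `start`, `end` (merged
#'   issue regions).
#' @param truth `data.frame` with `target_name`, `start`, `end` and optional
#'   `region_class`.
#' @param pad Bases added to each side of every truth locus before matching.
#' @return `data.frame` with one row per region class plus `"all"`: columns
#'   `region_class`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
detection_metrics <- function(detected, truth, pad = 10000L) {
  pads <- data.frame(target_name = truth$target_name,
                     start = pmax(0L, truth$start - as.integer(pad)),
                     end = truth$end + as.integer(pad))
  ov_any <- function(a, b) {
    # TRUE per row of a when any row of b on the same target overlaps >= 1 bp
    vapply(seq_len(nrow(a)), function(i) {
      j <- b$target_name == a$target_name[i]
      any(b$start[j] < a$end[i] & b$end[j] > a$start[i])
    }, logical(1))
  }
  truth_hit <- if (nrow(truth)) ov_any(pads, detected) else logical(0)
  det_hit <- if (nrow(detected)) ov_any(detected, pads) else logical(0)

  one <- function(hit_truth, hit_det) {
    tp <- sum(hit_truth); fn <- sum(!hit_truth); fp <- sum(!hit_det)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1)
  }
  rows <- list(all = one(truth_hit, det_hit))
  if (!is.null(truth$region_class) && nrow(truth)) {
    for (cls in unique(truth$region_class)) {
      k <- truth$region_class == cls
      # FPs are not class-attributable; count detections matching no truth of
      # this class only against detections overlapping none at all
      rows[[cls]] <- one(truth_hit[k], det_hit)
    }
  }
  out <- data.frame(region_class = names(rows),
                    do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$region_class != "all", out$region_class), , drop = FALSE]
}
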