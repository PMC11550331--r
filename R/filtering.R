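#' Filtering and calling thresholds
#'
#' Collects every tunable threshold of the curation pipeline with its default:
#'
#' \describe{
#'   \item{min_mapq}{alignments with MAPQ below this are rejected (default 30;
#'     MAPQ 30 itself is kept).}
#'   \item{min_identity}{alignments with mapping identity below this are
#'     rejected (default 0.90; identity 0.90 itself is kept).}
#'   \item{max_clip_frac}{alignments whose clipped fraction exceeds this are
#'     rejected (default 0.10; exactly 0.10 is kept).}
#'   \item{rescue_mapq}{a read supported by only one aligner is still kept if
#'     that aligner reports MAPQ at or above this (default 50); set to `Inf`
#'     to disable the rescue rule.}
#'   \item{min_overlap_frac}{reciprocal overlap (against the longer interval)
#'     required for two aligners' placements of the same read to count as
#'     consistent (default 0.90).}
#'   \item{trim_len}{bases trimmed from both ends of every curated alignment
#'     before depth counting (default 5).}
#'   \item{low_depth_frac}{positions with curated depth below this fraction of
#'     the genome-wide mean are called low-support (default 0.1).}
#'   \item{merge_dist_frac}{issue regions on the same sequence closer than this
#'     fraction of that sequence's length are merged (default 0.005, i.e. 0.5%
#'     of the chromosome length).}
#' }
#'
#' @param min_mapq,min_identity,max_clip_frac,rescue_mapq,min_overlap_frac,trim_len,low_depth_frac,merge_dist_frac
#'   See descriptions above.
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(min_mapq = 30L, min_identity = 0.90,
                          max_clip_frac = 0.10, rescue_mapq = 50,
                          min_overlap_frac = 0.90, trim_len = 5L,
                          low_depth_frac = 0.1, merge_dist_frac = 0.005) {
  cfg <- list(
    min_mapq = as.numeric(min_mapq), min_identity = as.numeric(min_identity),
    max_clip_frac = as.numeric(max_clip_frac),
    rescue_mapq = as.numeric(rescue_mapq),
    min_overlap_frac = as.numeric(min_overlap_frac),
    trim_len = as.integer(trim_len),
    low_depth_frac = as.numeric(low_depth_frac),
    merge_dist_frac = as.numeric(merge_dist_frac)
  )
  fracs <- c(cfg$min_identity, cfg$max_clip_frac, cfg$min_overlap_frac,
             cfg$low_depth_frac, cfg$merge_dist_frac)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$min_mapq > cfg$rescue_mapq) stop("min_mapq must be <= rescue_mapq")
  if (cfg$trim_len < 0L) stop("trim_len must be >= 0")
  structure(cfg, class = "filter_config")
}

filter_reject_reasons <- c("unmapped", "secondary", "supplementary",
                           "low_mapq", "low_identity", "high_clip")

#' Per-alignment rejection decision
#'
#' Applies the rejection rules in fixed precedence: unmapped, secondary,
#' supplementary, MAPQ below `min_mapq`, identity below `min_identity` (when
#' computable), clipped fraction above `max_clip_frac`. Thresholds are strict
#' in the stated orientation: MAPQ 29 is rejected and 30 kept, identity 0.899
#' rejected and 0.90 kept, clip 0.101 rejected and 0.10 kept. Records whose
#' identity cannot be computed pass the identity rule.
#'
#' @param rec Alignment records ([alignment_records()]).
#' @param cfg A [filter_config()].
#' @return Character vector, one element per record: the first failing rule's
#'   reason code, or `NA` for records that pass every rule.
#' @export
passes_filters <- function(rec, cfg = filter_config()) {
  reason <- rep(NA_character_, nrow(rec))
  set <- function(cond, code) {
    hit <- is.na(reason) & cond & !is.na(cond)
    reason[hit] <<- code
  }
  set(rec$is_unmapped, "unmapped")
  set(rec$is_secondary, "secondary")
  set(rec$is_supplementary, "supplementary")
  set(rec$mapping_quality < cfg$min_mapq, "low_mapq")
  open <- which(is.na(reason))
  if (length(open)) {
    sub <- rec[open, , drop = FALSE]
    idy <- alignment_identity(sub)
    low_id <- !is.na(idy) & idy < cfg$min_identity
    reason[open[low_id]] <- "low_identity"
    open2 <- open[!low_id]
    if (length(open2)) {
      cf <- clip_fraction(rec[open2, , drop = FALSE])
      reason[open2[cf > cfg$max_clip_frac]] <- "high_clip"
    }
  }
  reason
}

#' Filter an alignment set
#'
#' Keeps records passing every rule of [passes_filters()], preserving input
#' order, and tallies rejections per reason. Records with unknown identity are
#' additionally counted in `identity_unknown` (they are not rejected for it).
#'
#' @inheritParams passes_filters
#' @return A list with `kept` (alignment records) and `stats` (named integer
#'   vector: total, kept, one count per rejection reason, identity_unknown).
#' @export
filter_alignments <- function(rec, cfg = filter_config()) {
  reason <- passes_filters(rec, cfg)
  kept <- rec[is.na(reason), , drop = FALSE]
  stats <- c(
    total = nrow(rec),
    kept = nrow(kept),
    table(factor(reason, levels = filter_reject_reasons)),
    identity_unknown = sum(is.na(alignment_identity(kept)))
  )
  storage.mode(stats) <- "integer"
  list(kept = kept, stats = stats)
}
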