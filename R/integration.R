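#' Reciprocal overlap of two target intervals
#'
#' Intersection length divided by the length of the longer interval — the
#' stricter, symmetric reading of a reciprocal-overlap requirement, which also
#' prevents a short nested fragment from trivially passing. Intervals on
#' different targets overlap by 0.
#'
#' @param target_a,start_a,end_a First interval (0-based half-open).
#' @param target_b,start_b,end_b Second interval.
#' @return Numeric vector of overlap fractions in `[0, 1]`.
#' @export
overlap_fraction <- function(target_a, start_a, end_a,
                             target_b, start_b, end_b) {
  inter <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  longer <- pmax(end_a - start_a, end_b - start_b)
  out <- ifelse(target_a == target_b, inter / longer, 0)
  out[is.na(out)] <- 0
  out
}

curated_set <- function(target_name = character(0), start = integer(0),
                        end = integer(0), source = character(0),
                        platform = character(0), read_id = character(0)) {
  data.frame(target_name = as.character(target_name),
             start = as.integer(start), end = as.integer(end),
             source = as.character(source), platform = as.character(platform),
             read_id = as.character(read_id), stringsAsFactors = FALSE)
}

# one filtered primary alignment per read; duplicates resolved to best MAPQ
dedupe_primary <- function(rec) {
  if (nrow(rec) <= 1L) return(rec)
  if (anyDuplicated(rec$read_id)) {
    warning("duplicate primary alignments for ",
            sum(duplicated(rec$read_id)), " read(s); keeping highest MAPQ")
    ord <- order(rec$read_id, -rec$mapping_quality)
    rec <- rec[ord, , drop = FALSE]
    rec <- rec[!duplicated(rec$read_id), , drop = FALSE]
  }
  rec
}

#' Integrate filtered alignments from two aligners
#'
#' For each read, the two aligners' filtered placements are compared:
#' \itemize{
#'   \item \emph{consensus}: if both aligners placed the read and the
#'     placements overlap reciprocally by at least `min_overlap_frac`, one
#'     curated interval is emitted — aligner A's interval (taking the
#'     intersection would trim support at both ends on top of the later
#'     end-trimming step, double-penalizing region boundaries);
#'   \item \emph{rescue}: a read whose pair fails (missing partner or
#'     insufficient overlap) is still emitted if either aligner's alignment
#'     has MAPQ at or above `rescue_mapq`, with that aligner's interval —
#'     this recovers support in repetitive regions where one aligner
#'     collapses to MAPQ 0;
#'   \item reads failing both rules are dropped.
#' }
#' Rescue operates on the filtered sets only: an alignment already rejected
#' for clipping or identity is never brought back by MAPQ alone.
#'
#' With `kept_b = NULL` (single-aligner mode) every filtered record of
#' aligner A is emitted with source `"single_aligner"`.
#'
#' @param kept_a,kept_b Filtered alignment records from aligners A and B
#'   ([filter_alignments()]`$kept`); `kept_b` may be `NULL`.
#' @param cfg A [filter_config()].
#' @param platform Platform label stamped on the output.
#' @return A curated alignment set: `data.frame` with columns `target_name`,
#'   `start`, `end`, `source` (consensus / rescued_A / rescued_B /
#'   single_aligner), `platform`, `read_id`.
#' @export
integrate_aligners <- function(kept_a, kept_b = NULL, cfg = filter_config(),
                               platform = "hifi") {
  a <- dedupe_primary(kept_a)
  if (is.null(kept_b)) {
    return(curated_set(a$target_name, a$target_start, a$target_end,
                       rep("single_aligner", nrow(a)),
                       rep(platform, nrow(a)), a$read_id))
  }
  b <- dedupe_primary(kept_b)

  ib <- match(a$read_id, b$read_id)
  has_b <- !is.na(ib)
  ov <- numeric(nrow(a))
  ov[has_b] <- overlap_fraction(
    a$target_name[has_b], a$target_start[has_b], a$target_end[has_b],
    b$target_name[ib[has_b]], b$target_start[ib[has_b]], b$target_end[ib[has_b]]
  )
  consensus <- has_b & ov >= cfg$min_overlap_frac
  resc_a <- !consensus & a$mapping_quality >= cfg$rescue_mapq
  # B can rescue a read A failed to pair, including reads A never kept
  resc_b_paired <- !consensus & !resc_a & has_b &
    b$mapping_quality[ib] >= cfg$rescue_mapq
  b_only <- setdiff(b$read_id, a$read_id)
  jb <- match(b_only, b$read_id)
  jb <- jb[b$mapping_quality[jb] >= cfg$rescue_mapq]

  take_a <- consensus | resc_a
  src_a <- ifelse(consensus, "consensus", "rescued_A")[take_a]
  out_a <- curated_set(a$target_name[take_a], a$target_start[take_a],
                       a$target_end[take_a], src_a,
                       rep(platform, sum(take_a)), a$read_id[take_a])
  kb <- c(ib[resc_b_paired], jb)
  out_b <- curated_set(b$target_name[kb], b$target_start[kb], b$target_end[kb],
                       rep("rescued_B", length(kb)),
                       rep(platform, length(kb)), b$read_id[kb])
  out <- rbind(out_a, out_b)
  out[order(out$target_name, out$start, out$end, out$read_id), , drop = FALSE]
}

#' Merge curated alignment sets across sequencing platforms
#'
#' Multiset union of the intervals: depth counting later counts every interval
#' once, so a region covered by either platform is covered in the combined
#' profile.
#'
#' @param ... Curated alignment sets ([integrate_aligners()]).
#' @return One combined curated alignment set.
#' @export
merge_platforms <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  if (length(sets) == 0L) return(curated_set())
  out <- do.call(rbind, sets)
  out[order(out$target_name, out$start, out$end, out$read_id), , drop = FALSE]
}
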