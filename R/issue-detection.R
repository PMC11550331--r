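issue_regions <- function(target_name = character(0), start = integer(0),
                          end = integer(0), category = character(0),
                          min_depth = integer(0),
                          mean_depth_in_region = numeric(0)) {
  data.frame(target_name = as.character(target_name),
             start = as.integer(start), end = as.integer(end),
             category = as.character(category),
             min_depth = as.integer(min_depth),
             mean_depth_in_region = as.numeric(mean_depth_in_region),
             stringsAsFactors = FALSE)
}

#' Call raw zero/low-support regions from a depth profile
#'
#' Emits maximal runs of positions with depth 0 (category `"zero"`) or with
#' `0 < depth < low_depth_frac * genome_mean` (category `"low"`; the
#' inequality is strict, so depth exactly at the threshold is not called).
#' Adjacent zero and low runs are emitted separately here and unified by
#' [merge_issues()].
#'
#' End-trimming makes the terminal `trim_len` bases of every sequence
#' unassayable — no alignment can ever cover them — so zero runs lying
#' entirely inside those margins are not called: flagging them would penalize
#' every chromosome end regardless of assembly quality.
#'
#' @param profile A [compute_depth()] result.
#' @param cfg A [filter_config()] (uses `low_depth_frac`).
#' @return Issue regions: `data.frame` with columns `target_name`, `start`,
#'   `end` (0-based half-open), `category`, `min_depth`,
#'   `mean_depth_in_region`.
#' @export
call_raw_issues <- function(profile, cfg = filter_config()) {
  thr <- cfg$low_depth_frac * profile$genome_mean
  trim <- profile$trim_len
  out <- lapply(names(profile$depth), function(t) {
    d <- profile$depth[[t]]
    len <- length(d)
    if (len == 0L) return(NULL)
    state <- ifelse(d == 0L, 2L, ifelse(d < thr, 1L, 0L))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    hit <- r$values > 0L
    if (!any(hit)) return(NULL)
    s <- starts[hit]; e <- ends[hit]; cat_ <- r$values[hit]
    # drop zero runs fully inside the unassayable terminal trim margins
    margin <- cat_ == 2L & ((e <= trim) | (s >= len - trim))
    s <- s[margin == FALSE]; e <- e[margin == FALSE]
    cat_ <- cat_[margin == FALSE]
    if (!length(s)) return(NULL)
    stats <- vapply(seq_along(s), function(i) {
      seg <- d[(s[i] + 1L):e[i]]
      c(min(seg), mean(seg))
    }, numeric(2))
    issue_regions(rep(t, length(s)), s, e,
                  ifelse(cat_ == 2L, "zero", "low"),
                  as.integer(stats[1L, ]), stats[2L, ])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) issue_regions() else out
}

#' Merge physically adjacent issue regions
#'
#' Consecutive issues on the same sequence whose gap is smaller than
#' `merge_dist_frac` times that sequence's own length are merged
#' (transitively) into one region spanning both. The merged category is
#' `"zero"` if any constituent was zero-support, else `"low"` — zero support
#' is the stronger claim. Because the threshold scales with each sequence's
#' length, the same gap can merge on a long chromosome and stay split on a
#' short one.
#'
#' @param issues Issue regions ([call_raw_issues()]).
#' @param target_lengths Named integer vector of sequence lengths.
#' @param cfg A [filter_config()] (uses `merge_dist_frac`).
#' @return Merged issue regions, sorted by target then start; `min_depth` and
#'   `mean_depth_in_region` summarize the constituent issue bases only (not
#'   the absorbed gaps).
#' @export
merge_issues <- function(issues, target_lengths, cfg = filter_config()) {
  if (nrow(issues) == 0L) return(issues)
  issues <- issues[order(issues$target_name, issues$start), , drop = FALSE]
  out <- lapply(split(issues, issues$target_name), function(iss) {
    t <- iss$target_name[[1L]]
    max_gap <- cfg$merge_dist_frac * target_lengths[[t]]
    n <- nrow(iss)
    # gap to the running maximum end, so a contained interval cannot reset
    # the chain and let a later issue overlap an earlier merged region
    gap <- iss$start[-1L] - cummax(iss$end)[-n]
    grp <- cumsum(c(0L, as.integer(!(gap < max_gap))))
    agg <- lapply(split(seq_len(n), grp), function(i) {
      w <- iss$end[i] - iss$start[i]
      issue_regions(t, min(iss$start[i]), max(iss$end[i]),
                    if (any(iss$category[i] == "zero")) "zero" else "low",
                    min(iss$min_depth[i]),
                    sum(iss$mean_depth_in_region[i] * w) / sum(w))
    })
    do.call(rbind, agg)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$target_name, out$start), , drop = FALSE]
}

#' Split sequences into curated contigs at issue loci
#'
#' Contigs are the complement of the merged issues within each sequence.
#' Issues abutting a sequence end trim the sequence rather than create an
#' empty contig (a missing telomere should not manufacture a spurious extra
#' contig); zero-length contigs are discarded; a sequence with no issues
#' yields one contig spanning it entirely.
#'
#' @param target_lengths Named integer vector of sequence lengths.
#' @param merged_issues Disjoint, sorted issue regions ([merge_issues()]).
#' @return A list with `contigs` (`data.frame`: `target_name`, `start`,
#'   `end`) and `lengths` (flat integer vector of contig lengths).
#' @export
split_curated_contigs <- function(target_lengths, merged_issues) {
  per <- split(merged_issues, merged_issues$target_name)
  contigs <- lapply(names(target_lengths), function(t) {
    len <- target_lengths[[t]]
    iss <- per[[t]]
    if (is.null(iss) || nrow(iss) == 0L)
      return(data.frame(target_name = t, start = 0L, end = as.integer(len),
                        stringsAsFactors = FALSE))
    iss <- iss[order(iss$start), , drop = FALSE]
    if (any(iss$start[-1L] < iss$end[-nrow(iss)]))
      stop("overlapping issues on ", t)
    s <- c(0L, iss$end)
    e <- c(iss$start, as.integer(len))
    keep <- e > s
    data.frame(target_name = rep(t, sum(keep)), start = s[keep],
               end = e[keep], stringsAsFactors = FALSE)
  })
  contigs <- do.call(rbind, contigs)
  list(contigs = contigs, lengths = as.integer(contigs$end - contigs$start))
}

#' Write issue regions as BED
#'
#' BED4+ output: chrom, start, end, category, min_depth,
#' mean_depth_in_region; 0-based half-open, sorted by chrom then start.
#'
#' @param issues Issue regions.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_issues_bed <- function(issues, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tcategory\tmin_depth\tmean_depth", con)
  if (nrow(issues)) {
    issues <- issues[order(issues$target_name, issues$start), , drop = FALSE]
    writeLines(paste(issues$target_name, issues$start, issues$end,
                     issues$category, issues$min_depth,
                     format(round(issues$mean_depth_in_region, 3),
                            trim = TRUE, scientific = FALSE),
                     sep = "\t"), con)
  }
  invisible(path)
}
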