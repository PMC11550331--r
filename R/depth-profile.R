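#' Trim an alignment interval for depth counting
#'
#' Removes `trim_len` bases from both ends of a target interval; intervals too
#' short to survive trimming become empty. Trimming excludes potentially
#' clipped alignment ends from coverage, sharpening the detection of joins
#' with no spanning support.
#'
#' @param start,end Interval on the target, 0-based half-open (vectors).
#' @param trim_len Non-negative number of bases trimmed from each end.
#' @return A `data.frame` with columns `start`, `end` and logical `empty`
#'   (`TRUE` where nothing survives trimming; such rows carry `start == end`).
#' @export
trim_interval <- function(start, end, trim_len) {
  if (trim_len < 0) stop("trim_len must be >= 0")
  s <- start + trim_len
  e <- end - trim_len
  empty <- e <= s
  e[empty] <- s[empty]
  data.frame(start = as.integer(s), end = as.integer(e), empty = empty)
}

#' Per-base curated depth profile
#'
#' Counts, for every target position, the number of end-trimmed curated
#' intervals covering it. Implemented with difference arrays (one pass per
#' target) but contractually equal to naive per-base counting. The genome
#' mean is the grand mean over all assayed bases, zeros included — the single
#' genome-wide scale the low-depth threshold is applied on.
#'
#' @param curated A curated alignment set ([integrate_aligners()],
#'   [merge_platforms()]).
#' @param target_lengths Named integer vector: assayed sequence lengths.
#' @param trim_len Bases trimmed from each interval end (see
#'   [filter_config()]).
#' @return An object of class `"depth_profile"`: list with `depth` (named list
#'   of integer vectors, one per target), `target_lengths`, `genome_mean`,
#'   `per_target_mean` and `trim_len`.
#' @export
compute_depth <- function(curated, target_lengths, trim_len = 5L) {
  if (is.null(names(target_lengths)) || any(!nzchar(names(target_lengths))))
    stop("target_lengths must be named")
  unknown <- setdiff(unique(curated$target_name), names(target_lengths))
  if (length(unknown))
    stop("curated intervals on unknown target(s): ",
         paste(unknown, collapse = ", "))
  bad <- curated$start < 0L |
    curated$end > target_lengths[curated$target_name]
  if (any(bad))
    stop("interval beyond target bounds for read(s): ",
         paste(utils::head(curated$read_id[bad], 3L), collapse = ", "))

  tr <- trim_interval(curated$start, curated$end, trim_len)
  keep <- !tr$empty
  tn <- curated$target_name[keep]
  ts <- tr$start[keep]
  te <- tr$end[keep]

  # difference-array accumulation (duplicate breakpoints must add up)
  depth <- lapply(names(target_lengths), function(t) {
    len <- as.integer(target_lengths[[t]])
    i <- which(tn == t)
    d <- numeric(len + 1L)
    if (length(i)) {
      add <- tabulate(ts[i] + 1L, nbins = len + 1L)
      sub <- tabulate(te[i] + 1L, nbins = len + 1L)
      d <- add - sub
    }
    as.integer(cumsum(d)[seq_len(len)])
  })
  names(depth) <- names(target_lengths)

  total <- sum(vapply(depth, function(d) sum(as.numeric(d)), numeric(1)))
  lens <- as.numeric(target_lengths)
  structure(list(
    depth = depth,
    target_lengths = as.integer(target_lengths) |> stats::setNames(names(target_lengths)),
    genome_mean = if (sum(lens) > 0) total / sum(lens) else 0,
    per_target_mean = vapply(depth, function(d)
      if (length(d)) mean(d) else 0, numeric(1)),
    trim_len = as.integer(trim_len)
  ), class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("Curated depth profile:", length(x$depth), "target(s),",
      format(sum(as.numeric(x$target_lengths)), big.mark = ","), "bp assayed\n")
  cat("  genome mean depth:", round(x$genome_mean, 2),
      "(trim", x$trim_len, "bp)\n")
  invisible(x)
}

#' Write a depth profile as BedGraph
#'
#' Run-length encodes each target's per-base depth into 4-column BedGraph
#' (0-based half-open).
#'
#' @param profile A [compute_depth()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(profile, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (t in names(profile$depth)) {
    r <- rle(profile$depth[[t]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    writeLines(paste(t, starts, ends, r$values, sep = "\t"), con)
  }
  invisible(path)
}

#' Plot per-target curated depth
#'
#' One PNG per target: the depth track, a dashed horizontal line at the
#' genome-wide mean depth, and shading over zero-support (red) and
#' low-support (orange) issue regions when supplied.
#'
#' @param profile A [compute_depth()] result.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @param issues Optional issue regions ([call_raw_issues()] /
#'   [merge_issues()]) to shade.
#' @param max_points Depth values are binned down to at most this many points
#'   per target before plotting.
#' @return Character vector of written file paths, invisibly.
#' @export
plot_depth <- function(profile, dir, prefix = "depth", issues = NULL,
                       max_points = 5000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (t in names(profile$depth)) {
    d <- profile$depth[[t]]
    len <- length(d)
    bin <- max(1L, ceiling(len / max_points))
    if (bin > 1L) {
      grp <- (seq_len(len) - 1L) %/% bin
      d <- tapply(d, grp, mean)
    }
    x <- (seq_along(d) - 0.5) * bin
    path <- file.path(dir, paste0(prefix, ".", t, ".png"))
    grDevices::png(path, width = 1200, height = 360)
    graphics::plot(x, d, type = "l", col = "steelblue4", lwd = 1,
                   xlab = paste(t, "position (bp)"), ylab = "curated depth",
                   main = t)
    if (!is.null(issues) && nrow(issues)) {
      iss <- issues[issues$target_name == t, , drop = FALSE]
      if (nrow(iss)) {
        col <- ifelse(iss$category == "zero",
                      grDevices::adjustcolor("firebrick", 0.35),
                      grDevices::adjustcolor("darkorange", 0.35))
        graphics::rect(iss$start, graphics::par("usr")[3], iss$end,
                       graphics::par("usr")[4], col = col, border = NA)
      }
    }
    graphics::abline(h = profile$genome_mean, lty = 2, col = "grey30")
    grDevices::dev.off()
    paths <- c(paths, path)
  }
  invisible(paths)
}
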