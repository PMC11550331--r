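# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic assembly and alignment fixture
#'
#' Describes a toy multi-chromosome assembly plus tiling long-read alignments
#' from two simulated aligners, with controlled defects, so the whole
#' curation pipeline runs hermetically (no reads, no aligner). Defects:
#'
#' \describe{
#'   \item{uncovered}{no alignment starts in or spans the interval — curated
#'     depth drops to zero (a hidden join / missing sequence).}
#'   \item{low_coverage}{each overlapping read is kept with probability
#'     `value` — emulates a locally under-sequenced region.}
#'   \item{low_mapq}{overlapping reads get MAPQ drawn below 30 for the
#'     aligner(s) named in `aligners` — a repeat where mappers lose
#'     confidence; with `aligners = "B"` only, aligner A can still rescue.}
#'   \item{discordant}{aligner B relocates overlapping reads to a different
#'     chromosome — divergent mapper behaviour in repeats, exercising the
#'     high-MAPQ rescue path.}
#' }
#'
#' @param chrom_lengths Integer vector of chromosome lengths (named, or names
#'   are generated as chr1, chr2, ...).
#' @param read_length Simulated read length in bases.
#' @param depth Target per-base raw coverage per platform.
#' @param platforms Subset of `c("hifi", "ont")`.
#' @param identity Per-read mapping identity encoded through the NM tag.
#' @param mapq MAPQ assigned outside low-MAPQ defects.
#' @param defects `data.frame` with columns `target_name`, `start`, `end`,
#'   `type`, and optionally `value` (low_coverage fraction) and `aligners`
#'   ("A", "B" or "AB"); `NULL` for a defect-free fixture.
#' @param seed Integer seed; a fixed seed makes every generated file
#'   byte-identical across runs.
#' @return A list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(chrom_lengths, read_length = 20000L, depth = 10,
                         platforms = "hifi", identity = 0.99, mapq = 60L,
                         defects = NULL, seed = 1L) {
  if (length(chrom_lengths) == 0L || any(chrom_lengths <= 0))
    stop("chrom_lengths must be positive and non-empty")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (any(chrom_lengths < 2L * read_length))
    stop("every chromosome must be at least twice the read length")
  if (depth < 1) stop("depth must be >= 1")
  if (!is.null(defects)) {
    need <- c("target_name", "start", "end", "type")
    if (!all(need %in% names(defects)))
      stop("defects must have columns target_name, start, end, type")
    if (is.null(defects$value)) defects$value <- NA_real_
    if (is.null(defects$aligners))
      defects$aligners <- ifelse(defects$type == "discordant", "B", "AB")
    bad <- defects$start < 0L |
      defects$end > chrom_lengths[defects$target_name]
    if (any(bad | is.na(bad))) stop("defect outside chromosome bounds")
  }
  structure(list(
    chrom_lengths = stats::setNames(as.integer(chrom_lengths),
                                    names(chrom_lengths)),
    read_length = as.integer(read_length), depth = depth,
    platforms = match.arg(platforms, c("hifi", "ont"), several.ok = TRUE),
    identity = identity, mapq = as.integer(mapq),
    defects = defects, seed = as.integer(seed)
  ), class = "fixture_spec")
}

#' Generate the synthetic assembly
#'
#' Random-base sequences of the requested lengths, seed-deterministic.
#'
#' @param spec A [fixture_spec()].
#' @param path Optional FASTA path to write.
#' @return A [Biostrings::DNAStringSet] (invisibly written to `path` when
#'   given).
#' @export
make_assembly <- function(spec, path = NULL) {
  seqs <- with_seed(spec$seed, {
    lapply(spec$chrom_lengths, function(len)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""))
  })
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- names(spec$chrom_lengths)
  if (!is.null(path)) Biostrings::writeXStringSet(dss, path)
  invisible(dss)
}

# tiling read table for one platform/one aligner before defect application
tile_reads <- function(spec, platform) {
  rl <- spec$read_length
  recs <- lapply(names(spec$chrom_lengths), function(t) {
    len <- spec$chrom_lengths[[t]]
    spacing <- rl / spec$depth
    phase <- floor(stats::runif(1, 0, spacing))
    starts <- round(seq(0, len - rl, by = spacing) + phase)
    starts <- sort(unique(pmin.int(pmax.int(starts, 0L), len - rl)))
    starts <- sort(unique(c(0L, starts, len - rl)))
    data.frame(
      read_id = sprintf("%s_%s_%06d", platform, t, seq_along(starts)),
      target_name = t, start = as.integer(starts),
      end = as.integer(starts + rl), mapq = spec$mapq,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, recs)
}

apply_defects <- function(reads_a, reads_b, spec) {
  defects <- spec$defects
  if (is.null(defects) || nrow(defects) == 0L)
    return(list(A = reads_a, B = reads_b))
  for (k in seq_len(nrow(defects))) {
    d <- defects[k, ]
    hits <- function(r) r$target_name == d$target_name &
      r$start < d$end & r$end > d$start
    ha <- hits(reads_a); hb <- hits(reads_b)
    if (d$type == "uncovered") {
      drop_ids <- union(reads_a$read_id[ha], reads_b$read_id[hb])
      reads_a <- reads_a[!reads_a$read_id %in% drop_ids, , drop = FALSE]
      reads_b <- reads_b[!reads_b$read_id %in% drop_ids, , drop = FALSE]
    } else if (d$type == "low_coverage") {
      ids <- reads_a$read_id[ha]
      keep <- ids[stats::runif(length(ids)) < d$value]
      drop_ids <- setdiff(ids, keep)
      reads_a <- reads_a[!reads_a$read_id %in% drop_ids, , drop = FALSE]
      reads_b <- reads_b[!reads_b$read_id %in% drop_ids, , drop = FALSE]
    } else if (d$type == "low_mapq") {
      if (grepl("A", d$aligners))
        reads_a$mapq[ha] <- sample(0:29, sum(ha), replace = TRUE)
      if (grepl("B", d$aligners))
        reads_b$mapq[hb] <- sample(0:29, sum(hb), replace = TRUE)
    } else if (d$type == "discordant") {
      others <- setdiff(names(spec$chrom_lengths), d$target_name)
      if (length(others) == 0L) stop("discordant defect needs >= 2 chromosomes")
      dest <- others[[1L]]
      dlen <- spec$chrom_lengths[[dest]]
      n <- sum(hb)
      pos <- sample.int(dlen - spec$read_length, n, replace = TRUE)
      reads_b$target_name[hb] <- dest
      reads_b$start[hb] <- as.integer(pos)
      reads_b$end[hb] <- as.integer(pos + spec$read_length)
    } else stop("unknown defect type: ", d$type)
  }
  list(A = reads_a, B = reads_b)
}

write_fixture_paf <- function(reads, spec, path) {
  rl <- spec$read_length
  nm <- round((1 - spec$identity) * rl)
  tlen <- spec$chrom_lengths[reads$target_name]
  lines <- paste(reads$read_id, rl, 0L, rl, "+", reads$target_name, tlen,
                 reads$start, reads$end, rl - nm, rl, reads$mapq,
                 paste0("NM:i:", nm), "tp:A:P", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

write_fixture_sam <- function(reads, spec, path) {
  rl <- spec$read_length
  nm <- round((1 - spec$identity) * rl)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(spec$chrom_lengths),
                     "\tLN:", spec$chrom_lengths))
  body <- paste(reads$read_id, 0L, reads$target_name, reads$start + 1L,
                reads$mapq, paste0(rl, "M"), "*", 0L, 0L, "*", "*",
                paste0("NM:i:", nm), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate paired synthetic alignment files
#'
#' Emits, per platform, one PAF and one SAM file for each of two simulated
#' aligners ("A" and "B"). Reads tile each chromosome at the target depth
#' with a random phase; outside defects the two aligners agree exactly, and
#' defects perturb coverage, MAPQ or aligner-B placement as described in
#' [fixture_spec()]. The PAF and SAM emissions of one aligner describe the
#' same alignments and parse to identical records.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if absent).
#' @return Nested list `files[[platform]][[aligner]]` with elements `paf` and
#'   `sam`.
#' @export
make_alignments <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (p in spec$platforms) {
    seed_p <- spec$seed + match(p, c("hifi", "ont")) * 1000L
    sets <- with_seed(seed_p, {
      a <- tile_reads(spec, p)
      apply_defects(a, a, spec)
    })
    out[[p]] <- list()
    for (al in c("A", "B")) {
      base <- file.path(dir, paste0(p, ".aligner", al))
      paf <- paste0(base, ".paf"); sam <- paste0(base, ".sam")
      write_fixture_paf(sets[[al]], spec, paf)
      write_fixture_sam(sets[[al]], spec, sam)
      out[[p]][[al]] <- list(paf = paf, sam = sam)
    }
  }
  out
}

#' Fragment an assembly by random gap injection
#'
#' Draws `n_gaps` distinct breakpoints uniformly over the concatenated genome
#' body (never on an existing chromosome boundary) and returns the resulting
#' fragment lengths, for comparing how scaled N50, scaled auN and the
#' continuity score react to increasing fragmentation.
#'
#' @param chrom_lengths Integer vector of chromosome lengths.
#' @param n_gaps Number of breakpoints to inject.
#' @param seed Integer seed.
#' @return Integer vector of fragment lengths (length
#'   `length(chrom_lengths) + n_gaps`).
#' @export
simulate_gaps <- function(chrom_lengths, n_gaps, seed = 1L) {
  if (n_gaps < 0) stop("n_gaps must be >= 0")
  lens <- as.numeric(chrom_lengths)
  if (n_gaps == 0) return(as.integer(lens))
  total <- sum(lens)
  bounds <- cumsum(lens)
  with_seed(seed, {
    breaks <- numeric(0)
    while (length(breaks) < n_gaps) {
      cand <- ceiling(stats::runif(n_gaps - length(breaks)) * (total - 1))
      breaks <- unique(c(breaks, setdiff(cand, bounds)))
    }
    breaks <- sort(breaks)
    starts <- c(0, bounds[-length(bounds)])
    frags <- unlist(lapply(seq_along(lens), function(i) {
      b <- breaks[breaks > starts[i] & breaks < bounds[i]] - starts[i]
      diff(c(0, b, lens[i]))
    }))
    as.integer(frags)
  })
}

#' Inject structural issues into an assembly
#'
#' Introduces insertions (lengths uniform in `ins_range`, sequence copied
#' from a random donor locus elsewhere in the genome) and deletions (lengths
#' uniform in `del_range`) at random loci, avoiding `excluded_regions`,
#' chromosome ends and each other. Returns the mutated assembly together
#' with a truth table in mutated-assembly coordinates: an insertion's locus
#' is the inserted interval, a deletion's locus is its 1-bp breakpoint.
#'
#' @param assembly A [Biostrings::DNAStringSet].
#' @param n_ins,n_del Number of insertion / deletion events.
#' @param seed Integer seed.
#' @param excluded_regions Optional `data.frame` (`target_name`, `start`,
#'   `end`) of loci events must not touch.
#' @param ins_range,del_range Event length ranges in bases.
#' @param end_margin Bases kept clear at each chromosome end.
#' @param min_separation Minimum distance between event footprints.
#' @return List with `assembly` (mutated `DNAStringSet`) and `truth`
#'   (`data.frame`: `target_name`, `start`, `end`, `type`, `length`).
#' @export
inject_structural_issues <- function(assembly, n_ins, n_del, seed = 1L,
                                     excluded_regions = NULL,
                                     ins_range = c(10000L, 50000L),
                                     del_range = c(50000L, 100000L),
                                     end_margin = 30000L,
                                     min_separation = 25000L) {
  lens <- Biostrings::width(assembly)
  names(lens) <- names(assembly)
  with_seed(seed, {
    types <- c(rep("INS", n_ins), rep("DEL", n_del))
    if (length(types) == 0L)
      return(list(assembly = assembly,
                  truth = data.frame(target_name = character(0),
                                     start = integer(0), end = integer(0),
                                     type = character(0),
                                     length = integer(0))))
    sizes <- ifelse(types == "INS",
                    round(stats::runif(length(types), ins_range[1], ins_range[2])),
                    round(stats::runif(length(types), del_range[1], del_range[2])))
    placed <- data.frame(target_name = character(0), start = integer(0),
                         end = integer(0), type = character(0),
                         length = integer(0), stringsAsFactors = FALSE)
    clashes <- function(t, s, e) {
      near <- function(df) any(df$target_name == t &
                                 df$start - min_separation < e &
                                 df$end + min_separation > s)
      near(placed) ||
        (!is.null(excluded_regions) && near(excluded_regions))
    }
    for (i in order(-sizes)) {  # place large events first
      foot <- if (types[i] == "DEL") sizes[i] else 0L
      ok <- FALSE
      for (try in 1:200) {
        t <- sample(names(lens), 1L, prob = lens)
        room <- lens[[t]] - 2L * end_margin - foot
        if (room <= 1L) next
        s <- end_margin + sample.int(room, 1L)
        e <- s + max(foot, 1L)
        if (!clashes(t, s, e)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place event after 200 attempts; ",
                    "assembly too small for the requested events")
      placed <- rbind(placed, data.frame(
        target_name = t, start = as.integer(s), end = as.integer(e),
        type = types[i], length = as.integer(sizes[i]),
        stringsAsFactors = FALSE))
    }

    seq_chr <- stats::setNames(as.character(assembly), names(assembly))
    donor <- function(len) {
      t <- sample(names(lens), 1L, prob = lens)
      s <- sample.int(lens[[t]] - len, 1L)
      substr(seq_chr[[t]], s + 1L, s + len)
    }
    truth <- NULL
    for (t in names(lens)) {
      ev <- placed[placed$target_name == t, , drop = FALSE]
      if (nrow(ev) == 0L) next
      ev <- ev[order(ev$start), , drop = FALSE]
      pieces <- character(0)
      prev <- 0L
      offset <- 0L
      for (i in seq_len(nrow(ev))) {
        pieces <- c(pieces, substr(seq_chr[[t]], prev + 1L, ev$start[i]))
        if (ev$type[i] == "INS") {
          pieces <- c(pieces, donor(ev$length[i]))
          mstart <- ev$start[i] + offset
          truth <- rbind(truth, data.frame(
            target_name = t, start = mstart, end = mstart + ev$length[i],
            type = "INS", length = ev$length[i], stringsAsFactors = FALSE))
          offset <- offset + ev$length[i]
          prev <- ev$start[i]
        } else {
          mstart <- ev$start[i] + offset
          truth <- rbind(truth, data.frame(
            target_name = t, start = mstart, end = mstart + 1L,
            type = "DEL", length = ev$length[i], stringsAsFactors = FALSE))
          offset <- offset - ev$length[i]
          prev <- ev$end[i]
        }
      }
      pieces <- c(pieces, substr(seq_chr[[t]], prev + 1L, lens[[t]]))
      seq_chr[[t]] <- paste(pieces, collapse = "")
    }
    mutated <- Biostrings::DNAStringSet(seq_chr)
    names(mutated) <- names(assembly)
    truth <- truth[order(truth$target_name, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(assembly = mutated, truth = truth)
  })
}

#' Translate an injected-issue truth table into fixture defects
#'
#' Reads simulated from the original genome cannot span an inserted sequence
#' and lose spanning support at a deletion breakpoint; regenerating fixture
#' alignments from the mutated assembly therefore places an `uncovered`
#' defect over each insertion interval and a small padded window around each
#' deletion breakpoint.
#'
#' @param truth Truth table from [inject_structural_issues()].
#' @param del_pad Bases of lost support on each side of a deletion breakpoint.
#' @return A defect `data.frame` suitable for [fixture_spec()].
#' @export
defects_from_truth <- function(truth, del_pad = 200L) {
  is_del <- truth$type == "DEL"
  data.frame(
    target_name = truth$target_name,
    start = as.integer(ifelse(is_del, pmax(0L, truth$start - del_pad),
                              truth$start)),
    end = as.integer(ifelse(is_del, truth$end + del_pad, truth$end)),
    type = "uncovered",
    value = NA_real_,
    aligners = "AB",
    stringsAsFactors = FALSE
  )
}

#' Write a truth table as BED
#'
#' @param truth Truth table from [inject_structural_issues()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  writeLines(paste(truth$target_name, truth$start, truth$end, truth$type,
                   truth$length, sep = "\t"), path)
  invisible(path)
}
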