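#' Normalized alignment records
#'
#' All downstream filtering operates on a flat `data.frame` of alignment
#' records with one row per read-to-assembly alignment, regardless of whether
#' the source was BAM or PAF. Coordinates are 0-based half-open throughout.
#'
#' Columns:
#' \describe{
#'   \item{read_id}{query (read) name.}
#'   \item{target_name}{assembly sequence the read aligns to (`NA` if unmapped).}
#'   \item{target_start, target_end}{0-based half-open interval on the target.}
#'   \item{read_length}{full read length, including soft- and hard-clipped
#'     bases, so the clipped fraction is invariant to the clip encoding.}
#'   \item{mapping_quality}{MAPQ as reported by the aligner.}
#'   \item{is_unmapped, is_secondary, is_supplementary}{SAM flag semantics;
#'     for PAF, `tp:A:S` marks secondary.}
#'   \item{clipped_bases}{soft + hard clipped bases summed over both read ends.}
#'   \item{aligned_read_span}{read bases consumed by the alignment.}
#'   \item{alignment_span}{number of alignment columns (matches + mismatches +
#'     inserted + deleted bases); denominator of the NM-based identity.}
#'   \item{edit_distance}{NM tag when present, else `NA`.}
#'   \item{divergence}{per-alignment divergence (`de:f` tag) when present,
#'     else `NA`; fallback for identity when NM is absent.}
#'   \item{aligner_id}{"A" or "B".}
#'   \item{platform}{"hifi" or "ont".}
#' }
#'
#' @param read_id,target_name,target_start,target_end,read_length,mapping_quality
#'   See column descriptions.
#' @param is_unmapped,is_secondary,is_supplementary Logical flags.
#' @param clipped_bases,aligned_read_span,alignment_span,edit_distance,divergence
#'   See column descriptions.
#' @param aligner_id "A" or "B".
#' @param platform "hifi" or "ont".
#' @return A `data.frame` with the columns above.
#' @export
alignment_records <- function(read_id, target_name, target_start, target_end,
                              read_length, mapping_quality,
                              is_unmapped = FALSE, is_secondary = FALSE,
                              is_supplementary = FALSE,
                              clipped_bases = 0L, aligned_read_span = NA_integer_,
                              alignment_span = NA_integer_,
                              edit_distance = NA_integer_, divergence = NA_real_,
                              aligner_id = "A", platform = "hifi") {
  rec <- data.frame(
    read_id = as.character(read_id),
    target_name = as.character(target_name),
    target_start = as.integer(target_start),
    target_end = as.integer(target_end),
    read_length = as.integer(read_length),
    mapping_quality = as.integer(mapping_quality),
    is_unmapped = as.logical(is_unmapped),
    is_secondary = as.logical(is_secondary),
    is_supplementary = as.logical(is_supplementary),
    clipped_bases = as.integer(clipped_bases),
    aligned_read_span = as.integer(aligned_read_span),
    alignment_span = as.integer(alignment_span),
    edit_distance = as.integer(edit_distance),
    divergence = as.numeric(divergence),
    aligner_id = as.character(aligner_id),
    platform = as.character(platform),
    stringsAsFactors = FALSE
  )
  validate_alignment_records(rec)
  rec
}

validate_alignment_records <- function(rec) {
  mapped <- !rec$is_unmapped
  if (any(mapped & (is.na(rec$target_start) | is.na(rec$target_end))))
    stop("mapped records must carry target coordinates")
  bad <- mapped & (rec$target_start < 0L | rec$target_end <= rec$target_start)
  if (any(bad))
    stop("invalid target interval for record(s): ",
         paste(utils::head(rec$read_id[bad], 3L), collapse = ", "))
  if (any(rec$mapping_quality < 0L, na.rm = TRUE))
    stop("mapping_quality must be >= 0")
  over <- mapped & !is.na(rec$aligned_read_span) &
    (rec$clipped_bases + rec$aligned_read_span > rec$read_length)
  if (any(over))
    stop("clipped_bases + aligned_read_span exceeds read_length for record(s): ",
         paste(utils::head(rec$read_id[over], 3L), collapse = ", "))
  invisible(rec)
}

empty_alignment_records <- function() {
  alignment_records(character(0), character(0), integer(0), integer(0),
                    integer(0), integer(0), logical(0), logical(0), logical(0),
                    integer(0), integer(0), integer(0), integer(0), numeric(0),
                    character(0), character(0))
}

#' Read a PAF alignment file into normalized records
#'
#' Parses the 12 mandatory PAF columns plus the optional `NM:i`, `de:f` and
#' `tp:A` tags. `tp:A:S` marks a secondary alignment. Clipped bases are
#' reconstructed from the query interval: `qstart + (qlen - qend)`.
#'
#' @param path Path to a PAF file (plain text, optionally empty).
#' @param aligner_id Label for the producing aligner ("A" or "B").
#' @param platform Sequencing platform the reads came from ("hifi" or "ont").
#' @return Alignment records as documented in [alignment_records()].
#' @export
read_paf <- function(path, aligner_id = "A", platform = "hifi") {
  if (!file.exists(path)) stop("PAF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_alignment_records())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("malformed PAF: line ", which(nf < 12L)[1L], " has fewer than 12 columns")

  col <- function(i) vapply(fields, `[[`, character(1), i)
  int_col <- function(i) suppressWarnings(as.integer(col(i)))
  qname <- col(1); qlen <- int_col(2)
  qstart <- int_col(3); qend <- int_col(4)
  tname <- col(6)
  tstart <- int_col(8); tend <- int_col(9)
  alnlen <- int_col(11)
  mapq <- int_col(12)

  tag_val <- function(f, prefix) {
    hit <- f[startsWith(f, prefix)]
    if (length(hit)) substring(hit[[1L]], nchar(prefix) + 1L) else NA_character_
  }
  nm <- as.integer(vapply(fields, tag_val, character(1), prefix = "NM:i:"))
  de <- as.numeric(vapply(fields, tag_val, character(1), prefix = "de:f:"))
  tp <- vapply(fields, tag_val, character(1), prefix = "tp:A:")

  if (anyNA(qlen) || anyNA(qstart) || anyNA(qend) || anyNA(tstart) ||
      anyNA(tend) || anyNA(mapq))
    stop("malformed PAF: non-numeric value in a mandatory numeric column")

  alignment_records(
    read_id = qname, target_name = tname,
    target_start = tstart, target_end = tend,
    read_length = qlen, mapping_quality = mapq,
    is_unmapped = FALSE,
    is_secondary = !is.na(tp) & tp == "S",
    is_supplementary = FALSE,
    clipped_bases = qstart + (qlen - qend),
    aligned_read_span = qend - qstart,
    alignment_span = alnlen,
    edit_distance = nm, divergence = de,
    aligner_id = aligner_id, platform = platform
  )
}

#' Read a BAM (or SAM) alignment file into normalized records
#'
#' Flags come from the SAM FLAG field; clipped bases from terminal `S`/`H`
#' CIGAR operations; the read length is reconstructed to include hard-clipped
#' bases. Mapped records lacking a CIGAR are skipped with a warning. No index
#' is required (sequential scan).
#'
#' @inheritParams read_paf
#' @param path Path to a BAM file; a plain-text SAM file is converted on the
#'   fly via [Rsamtools::asBam()].
#' @return Alignment records as documented in [alignment_records()].
#' @export
read_bam <- function(path, aligner_id = "A", platform = "hifi") {
  if (!file.exists(path)) stop("BAM file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = c("NM", "de")
  )
  res <- Rsamtools::scanBam(path, param = param)[[1L]]
  n <- length(res$qname)
  if (n == 0L) return(empty_alignment_records())

  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L
  supplementary <- bitwAnd(flag, 2048L) > 0L

  cigar <- res$cigar
  missing_cig <- !unmapped & (is.na(cigar) | cigar == "*")
  if (any(missing_cig)) {
    warning(sum(missing_cig), " mapped record(s) without CIGAR skipped")
  }
  keep <- !missing_cig
  idx <- which(keep)
  cigar <- cigar[idx]

  um <- unmapped[idx]
  # per-op total widths; S/H only occur at read ends so totals equal end clips.
  # unmapped records carry no CIGAR; a 1M placeholder keeps the table
  # rectangular and every derived field is NA'd or ignored for them below
  cigar[um | is.na(cigar) | cigar == "*"] <- "1M"
  ops <- GenomicAlignments::cigarOpTable(cigar)
  soft <- ops[, "S"]; hard <- ops[, "H"]
  ref_span <- ops[, "M"] + ops[, "D"] + ops[, "N"] + ops[, "="] + ops[, "X"]
  query_span <- ops[, "M"] + ops[, "I"] + ops[, "="] + ops[, "X"]
  aln_span <- ops[, "M"] + ops[, "I"] + ops[, "D"] + ops[, "="] + ops[, "X"]

  tstart <- ifelse(um, NA_integer_, res$pos[idx] - 1L)  # SAM POS is 1-based
  tend <- ifelse(um, NA_integer_, tstart + ref_span)

  nm <- res$tag$NM[idx]
  if (is.null(nm)) nm <- rep(NA_integer_, length(idx))
  de <- res$tag$de[idx]
  if (is.null(de)) de <- rep(NA_real_, length(idx))

  alignment_records(
    read_id = res$qname[idx],
    target_name = as.character(res$rname[idx]),
    target_start = tstart, target_end = tend,
    read_length = query_span + soft + hard,
    mapping_quality = ifelse(is.na(res$mapq[idx]), 0L, res$mapq[idx]),
    is_unmapped = um,
    is_secondary = secondary[idx],
    is_supplementary = supplementary[idx],
    clipped_bases = soft + hard,
    aligned_read_span = query_span,
    alignment_span = ifelse(um, NA_integer_, aln_span),
    edit_distance = as.integer(nm), divergence = as.numeric(de),
    aligner_id = aligner_id, platform = platform
  )
}

#' Mapping identity of alignment records
#'
#' Identity is `1 - edit_distance / alignment_span` (alignment columns:
#' matches, mismatches, inserted and deleted bases). When the edit distance is
#' absent the per-alignment divergence tag is used instead (`1 - divergence`);
#' when neither is available the result is `NA`, a sentinel meaning "unknown"
#' that the identity filter treats as passing.
#'
#' @param rec Alignment records ([alignment_records()]).
#' @return Numeric vector of identities in `[0, 1]`, `NA` where unknown.
#' @export
alignment_identity <- function(rec) {
  if (any(rec$edit_distance < 0L, na.rm = TRUE))
    stop("negative edit distance")
  id <- 1 - rec$edit_distance / rec$alignment_span
  fall <- is.na(id) & !is.na(rec$divergence)
  id[fall] <- 1 - rec$divergence[fall]
  id
}

#' Clipped fraction of alignment records
#'
#' Soft plus hard clipped bases over the full read length. Hard-clipped bases
#' count toward both numerator and denominator, so the value does not depend
#' on how the aligner encoded the clips.
#'
#' @inheritParams alignment_identity
#' @return Numeric vector of clip fractions in `[0, 1]`.
#' @export
clip_fraction <- function(rec) {
  if (any(rec$read_length == 0L, na.rm = TRUE))
    stop("read_length must be positive")
  rec$clipped_bases / rec$read_length
}
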