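# one-line construction of alignment records for filter/integration tests
rec <- function(read_id = "r1", target = "chr1", start = 1000L, end = 11000L,
                read_length = 10000L, mapq = 60L, clipped = 0L,
                nm = 0L, span = NULL, div = NA_real_,
                unmapped = FALSE, secondary = FALSE, supplementary = FALSE,
                aligner = "A", platform = "hifi") {
  if (is.null(span)) span <- end - start
  alignment_records(
    read_id = read_id, target_name = target,
    target_start = start, target_end = end,
    read_length = read_length, mapping_quality = mapq,
    is_unmapped = unmapped, is_secondary = secondary,
    is_supplementary = supplementary,
    clipped_bases = clipped,
    aligned_read_span = read_length - clipped,
    alignment_span = span, edit_distance = nm, divergence = div,
    aligner_id = aligner, platform = platform
  )
}

recs <- function(...) do.call(rbind, list(...))

# naive per-base depth counter: the oracle compute_depth must agree with
naive_depth <- function(curated, target_lengths, trim_len) {
  out <- lapply(names(target_lengths), function(t) {
    d <- integer(target_lengths[[t]])
    sub <- curated[curated$target_name == t, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      s <- sub$start[i] + trim_len
      e <- sub$end[i] - trim_len
      if (e > s) d[(s + 1L):e] <- d[(s + 1L):e] + 1L
    }
    d
  })
  names(out) <- names(target_lengths)
  out
}

# curated-set constructor for depth tests
cur_set <- function(target, start, end) {
  n <- length(start)
  data.frame(target_name = as.character(target), start = as.integer(start),
             end = as.integer(end),
             source = rep("single_aligner", n), platform = rep("hifi", n),
             read_id = if (n) paste0("r", seq_len(n)) else character(0),
             stringsAsFactors = FALSE)
}

# independent N50 oracle: walking distinct lengths from largest to smallest,
# the first whose >=length mass reaches half the total is the N50
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
}

# independent auN oracle: accumulate each contig's length weighted by its
# share of the assembly
oracle_aun <- function(lengths) {
  total <- sum(lengths)
  acc <- 0
  for (l in lengths) acc <- acc + l * (l / total)
  acc
}

# bare issue-region table
issue_df <- function(target = character(0), start = integer(0),
                     end = integer(0), category = "zero") {
  n <- length(target)
  data.frame(target_name = as.character(target), start = as.integer(start),
             end = as.integer(end),
             category = rep(category, length.out = n),
             min_depth = rep(0L, n), mean_depth_in_region = rep(0, n),
             stringsAsFactors = FALSE)
}

# depth profile built directly from per-target depth vectors, with the mean
# overridden when a test needs a specific calling threshold
fake_profile <- function(depth_list, genome_mean = NULL, trim_len = 0L) {
  lens <- vapply(depth_list, length, integer(1))
  total <- sum(vapply(depth_list, function(d) sum(as.numeric(d)), numeric(1)))
  structure(list(
    depth = depth_list,
    target_lengths = lens,
    genome_mean = if (is.null(genome_mean)) total / sum(lens) else genome_mean,
    per_target_mean = vapply(depth_list, mean, numeric(1)),
    trim_len = as.integer(trim_len)
  ), class = "depth_profile")
}
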