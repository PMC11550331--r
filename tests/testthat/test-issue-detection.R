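test_that("zero and low runs are called with a strict low threshold", {
  d <- rep(50L, 500)
  d[101:200] <- 0L           # zero support
  d[301:400] <- 4L           # 4 < 0.1 * 50
  p <- fake_profile(list(c1 = d), genome_mean = 50)
  iss <- call_raw_issues(p, filter_config())
  expect_equal(nrow(iss), 2L)
  expect_equal(iss$category, c("zero", "low"))
  expect_equal(c(iss$start, iss$end), c(100L, 300L, 200L, 400L))
  expect_equal(iss$min_depth, c(0L, 4L))

  # depth exactly at the threshold is not an issue
  p5 <- fake_profile(list(c1 = rep(5L, 500)), genome_mean = 50)
  expect_equal(nrow(call_raw_issues(p5, filter_config())), 0L)
})

test_that("zero runs confined to the unassayable trim margins are not called", {
  d <- rep(10L, 300)
  d[1:5] <- 0L
  d[296:300] <- 0L
  p <- fake_profile(list(c1 = d), trim_len = 5L)
  expect_equal(nrow(call_raw_issues(p, filter_config())), 0L)

  # a genuine terminal gap extending past the margin is kept whole
  d2 <- rep(10L, 300)
  d2[1:40] <- 0L
  p2 <- fake_profile(list(c1 = d2), trim_len = 5L)
  iss <- call_raw_issues(p2, filter_config())
  expect_equal(nrow(iss), 1L)
  expect_equal(c(iss$start, iss$end), c(0L, 40L))
})

test_that("merge distance scales with each chromosome's own length", {
  iss <- issue <- data.frame(
    target_name = "c1", start = c(10000L, 14000L), end = c(11000L, 15000L),
    category = c("zero", "low"), min_depth = c(0L, 3L),
    mean_depth_in_region = c(0, 3), stringsAsFactors = FALSE)
  cfg <- filter_config()
  merged <- merge_issues(iss, c(c1 = 1000000L), cfg)  # gap 3000 < 5000
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(10000L, 15000L))
  expect_equal(merged$category, "zero")  # zero dominates
  expect_equal(merged$min_depth, 0L)

  apart <- merge_issues(iss, c(c1 = 100000L), cfg)    # gap 3000 >= 500
  expect_equal(nrow(apart), 2L)
})

test_that("a contained interval cannot break the merge chain", {
  # the middle issue lies inside the first; the third is within merge
  # distance of the first's end but not of the middle's end
  iss <- issue_df("c1", c(42457L, 44113L, 45582L),
                  c(46079L, 45319L, 47419L))
  merged <- merge_issues(iss, c(c1 = 50000L), filter_config())  # max gap 250
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(42457L, 47419L))
})

test_that("merging is idempotent and order-independent", {
  set.seed(41)
  n <- 30
  s <- sort(sample(0:900000, n))
  iss <- data.frame(target_name = "c1", start = s,
                    end = s + sample(100:2000, n, TRUE),
                    category = sample(c("zero", "low"), n, TRUE),
                    min_depth = 0L, mean_depth_in_region = 0,
                    stringsAsFactors = FALSE)
  iss$end <- pmin(iss$end, c(iss$start[-1], 1000000L))  # keep disjoint
  iss <- iss[iss$end > iss$start, ]
  lens <- c(c1 = 1000000L)
  cfg <- filter_config()
  m1 <- merge_issues(iss, lens, cfg)
  expect_equal(merge_issues(m1, lens, cfg), m1)
  shuffled <- iss[sample(nrow(iss)), ]
  m2 <- merge_issues(shuffled, lens, cfg)
  expect_equal(m2[c("target_name", "start", "end", "category")],
               m1[c("target_name", "start", "end", "category")])
})

test_that("curated contigs complement the issues, trimming at ends", {
  lens <- c(c1 = 1000000L)
  mid <- issue_df("c1", 400000L, 401000L)
  cs <- split_curated_contigs(lens, mid)
  expect_equal(cs$lengths, c(400000L, 599000L))

  start_iss <- issue_df("c1", 0L, 5000L)
  cs2 <- split_curated_contigs(lens, start_iss)
  expect_equal(cs2$lengths, 995000L)  # trimmed, not split

  cs3 <- split_curated_contigs(c(a = 100L, b = 200L), issue_df()[0, ])
  expect_equal(cs3$lengths, c(100L, 200L))

  expect_error(
    split_curated_contigs(lens, issue_df("c1", c(10L, 50L), c(100L, 150L))),
    "overlapping")
})

test_that("contigs and issues tile each target exactly", {
  set.seed(43)
  lens <- c(c1 = 50000L, c2 = 30000L)
  s <- c(sort(sample(seq(0, 45000, by = 5000), 4)), 10000L)
  iss <- issue_df(c(rep("c1", 4), "c2"), s, s + c(rep(1000L, 4), 2000L))
  merged <- merge_issues(iss, lens, filter_config())
  cs <- split_curated_contigs(lens, merged)
  for (t in names(lens)) {
    covered <- logical(lens[[t]])
    ctg <- cs$contigs[cs$contigs$target_name == t, ]
    for (i in seq_len(nrow(ctg)))
      covered[(ctg$start[i] + 1L):ctg$end[i]] <- TRUE
    mi <- merged[merged$target_name == t, ]
    for (i in seq_len(nrow(mi))) {
      expect_false(any(covered[(mi$start[i] + 1L):mi$end[i]]))
      covered[(mi$start[i] + 1L):mi$end[i]] <- TRUE
    }
    expect_true(all(covered))
  }
})

test_that("raising the low-depth threshold never shrinks the issue bases", {
  set.seed(44)
  d <- sample(0:30, 2000, replace = TRUE)
  p <- fake_profile(list(c1 = as.integer(d)), genome_mean = 20)
  n_bases <- function(frac) {
    iss <- call_raw_issues(p, filter_config(low_depth_frac = frac))
    sum(iss$end - iss$start)
  }
  fracs <- c(0.05, 0.1, 0.3, 0.6, 1.0)
  expect_true(all(diff(vapply(fracs, n_bases, numeric(1))) >= 0))
})

test_that("issues BED is sorted, categorized and headed", {
  iss <- issue_df(c("c2", "c1", "c1"), c(10L, 500L, 20L), c(20L, 600L, 40L))
  path <- tempfile(fileext = ".bed")
  write_issues_bed(iss, path)
  lines <- readLines(path)
  expect_match(lines[1], "^#")
  expect_equal(length(lines), 4L)
  parts <- do.call(rbind, strsplit(lines[-1], "\t"))
  expect_equal(parts[, 1], c("c1", "c1", "c2"))
  expect_equal(as.integer(parts[, 2]), c(20L, 500L, 10L))

  write_issues_bed(iss[0, ], path)
  expect_equal(length(readLines(path)), 1L)
})
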