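test_that("overlap fraction is intersection over the longer interval", {
  expect_equal(overlap_fraction("c1", 1000, 2000, "c1", 1000, 2000), 1.0)
  expect_equal(overlap_fraction("c1", 1000, 2000, "c1", 1050, 2050), 0.95)
  expect_equal(overlap_fraction("c1", 1000, 2000, "c2", 1000, 2000), 0.0)
  expect_equal(overlap_fraction("c1", 0, 100, "c1", 500, 600), 0.0)
  # nested short fragment does not trivially pass
  expect_equal(overlap_fraction("c1", 0, 10000, "c1", 4000, 5000), 0.1)
})

test_that("consensus keeps aligner A's interval, rescue fills the gaps", {
  cfg <- filter_config()
  a <- recs(rec("cons", start = 5000L, end = 15000L, mapq = 60L),
            rec("resc", target = "chr1", start = 30000L, end = 40000L,
                mapq = 60L),
            rec("drop", start = 60000L, end = 70000L, mapq = 35L))
  b <- recs(rec("cons", start = 5020L, end = 15010L, mapq = 55L,
                aligner = "B"),
            rec("resc", target = "chr2", start = 1000L, end = 11000L,
                mapq = 60L, aligner = "B"))
  out <- integrate_aligners(a, b, cfg)
  expect_equal(nrow(out), 2L)
  cons <- out[out$read_id == "cons", ]
  expect_equal(cons$source, "consensus")
  expect_equal(c(cons$start, cons$end), c(5000L, 15000L))  # A's interval
  resc <- out[out$read_id == "resc", ]
  expect_equal(resc$source, "rescued_A")
  expect_false("drop" %in% out$read_id)  # 35 < 50 and no consistent partner
})

test_that("aligner B can rescue reads aligner A lost", {
  cfg <- filter_config()
  a <- rec("shared", mapq = 60L)
  b <- recs(rec("shared", mapq = 60L, aligner = "B"),
            rec("bonly", target = "chr2", start = 0L, end = 10000L,
                mapq = 55L, aligner = "B"),
            rec("bweak", target = "chr2", start = 20000L, end = 30000L,
                mapq = 40L, aligner = "B"))
  out <- integrate_aligners(a, b, cfg)
  expect_setequal(out$read_id, c("shared", "bonly"))
  expect_equal(out$source[out$read_id == "bonly"], "rescued_B")
})

test_that("disabling rescue drops single-aligner reads", {
  cfg <- filter_config(rescue_mapq = Inf)
  a <- recs(rec("cons", mapq = 60L),
            rec("lone", start = 50000L, end = 60000L, mapq = 60L))
  b <- rec("cons", mapq = 60L, aligner = "B")
  out <- integrate_aligners(a, b, cfg)
  expect_equal(out$read_id, "cons")
})

test_that("single-aligner mode passes every filtered record through", {
  a <- recs(rec("r1"), rec("r2", start = 20000L, end = 30000L))
  out <- integrate_aligners(a, NULL)
  expect_equal(nrow(out), 2L)
  expect_true(all(out$source == "single_aligner"))
  expect_equal(sort(out$start), c(1000L, 20000L))
})

test_that("identical input from both aligners returns aligner A's set", {
  set.seed(13)
  a <- do.call(rbind, lapply(1:50, function(i) {
    s <- sample(0:900000, 1)
    rec(paste0("r", i), start = s, end = s + 10000L, mapq = 60L)
  }))
  b <- a
  b$aligner_id <- "B"
  out <- integrate_aligners(a, b, filter_config())
  expect_equal(nrow(out), 50L)
  expect_true(all(out$source == "consensus"))
  expect_equal(sort(out$start), sort(a$target_start))
})

test_that("curated output never invents intervals", {
  set.seed(21)
  mk <- function(al) do.call(rbind, lapply(1:40, function(i) {
    s <- sample(0:90000, 1)
    rec(paste0("r", i), start = s, end = s + 5000L,
        mapq = sample(c(20L, 40L, 60L), 1), aligner = al)
  }))
  a <- mk("A"); b <- mk("B")
  out <- integrate_aligners(a, b, filter_config())
  key <- function(df, s, e) paste(df$read_id, s, e)
  pool <- c(key(a, a$target_start, a$target_end),
            key(b, b$target_start, b$target_end))
  expect_true(all(key(out, out$start, out$end) %in% pool))
})

test_that("duplicate primaries resolve to the highest MAPQ with a warning", {
  a <- recs(rec("dup", mapq = 40L),
            rec("dup", start = 50000L, end = 60000L, mapq = 60L))
  expect_warning(out <- integrate_aligners(a, NULL), "duplicate")
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 50000L)
})

test_that("platform merging is multiset union and only adds coverage", {
  hifi <- cur_set("chr1", c(0L, 100L), c(50L, 150L))
  ont <- cur_set("chr1", 40L, 120L)
  ont$platform <- "ont"
  both <- merge_platforms(hifi, ont)
  expect_equal(nrow(both), 3L)
  expect_equal(nrow(merge_platforms(hifi, hifi[0, ])), 2L)
  lens <- c(chr1 = 200L)
  d_hifi <- compute_depth(hifi, lens, trim_len = 0L)$depth$chr1
  d_ont <- compute_depth(ont, lens, trim_len = 0L)$depth$chr1
  d_both <- compute_depth(both, lens, trim_len = 0L)$depth$chr1
  expect_true(all(d_both >= d_hifi) && all(d_both >= d_ont))
  expect_equal(d_both, d_hifi + d_ont)
})

test_that("a platform gap spanned by the other platform is covered", {
  lens <- c(chr1 = 1000L)
  hifi <- cur_set("chr1", c(0L, 600L), c(400L, 1000L))   # gap [400, 600)
  ont <- cur_set("chr1", 300L, 700L)
  ont$platform <- "ont"
  d <- compute_depth(merge_platforms(hifi, ont), lens, trim_len = 0L)
  expect_true(all(d$depth$chr1[401:600] >= 1L))
})
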