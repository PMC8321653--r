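# Segment filtering, per-patient deletion calls and event overlap counting.

test_that("filter_segments keeps strictly sub-threshold segments in order", {
  segs <- seg_tbl(start = c(0, 100, 200, 300), end = c(50, 150, 250, 350),
                  seg_mean = c(-0.05, -0.1, -0.11, -0.45))
  kept <- filter_segments(segs)
  expect_equal(kept$seg_mean, c(-0.11, -0.45)) # boundary -0.1 excluded
  expect_equal(nrow(filter_segments(segs[0, ])), 0)
  expect_equal(nrow(filter_segments(seg_tbl(seg_mean = c(0, 0.5, 0.1),
                                            start = c(0, 100, 200),
                                            end = c(50, 150, 250)))), 0)
  # threshold is a parameter
  expect_equal(nrow(filter_segments(segs, threshold = -0.4)), 1)
})

test_that("call_deletions computes overlap and bp-weighted value per sample", {
  region <- region_tbl(start = 100, end = 200)
  one <- seg_tbl(start = 150, end = 250, seg_mean = -0.4)
  calls <- call_deletions(one, region, samples = c("S1", "S2"))
  s1 <- calls[calls$sample_id == "S1", ]
  expect_true(s1$deleted)
  expect_equal(s1$overlap_bp, 50)
  expect_equal(s1$weighted_seg_value, -0.4)
  s2 <- calls[calls$sample_id == "S2", ]
  expect_false(s2$deleted)
  expect_equal(s2$overlap_bp, 0)
  expect_true(is.na(s2$weighted_seg_value))

  # (50 x -0.2 + 50 x -0.6) / 100 = -0.4
  two <- seg_tbl(start = c(100, 150), end = c(150, 200),
                 seg_mean = c(-0.2, -0.6))
  calls <- call_deletions(two, region, samples = "S1")
  expect_equal(calls$overlap_bp, 100)
  expect_equal(calls$weighted_seg_value, -0.4)

  expect_error(call_deletions(one, region, samples = "OTHER"),
               "absent from `samples`")
})

test_that("overlap_bp matches the per-base brute-force oracle", {
  withr::with_seed(42, {
    for (i in 1:60) {
      n_seg <- sample(1:6, 1)
      starts <- sample(0:9000, n_seg)
      ends <- starts + sample(1:800, n_seg, replace = TRUE)
      rstart <- sample(0:9000, 1)
      rend <- rstart + sample(1:1500, 1)
      segs <- seg_tbl(start = starts, end = ends,
                      seg_mean = runif(n_seg, -1, -0.2),
                      n_markers = rep(1L, n_seg))
      region <- region_tbl(start = rstart, end = rend)
      got <- call_deletions(segs, region, samples = "S1")$overlap_bp
      expect_equal(got, brute_force_overlap(starts, ends, rstart, rend))
    }
  })
})

test_that("calls are invariant to segment order and to splitting a segment", {
  region <- region_tbl(start = 100, end = 300)
  segs <- seg_tbl(sample_id = "S1", start = c(120, 250), end = c(200, 350),
                  seg_mean = c(-0.5, -0.3))
  base <- call_deletions(segs, region, samples = "S1")
  shuffled <- call_deletions(segs[2:1, ], region, samples = "S1")
  expect_equal(as.data.frame(base), as.data.frame(shuffled))
  # split [120,200) at 160 into two abutting segments of equal value
  split <- seg_tbl(sample_id = "S1", start = c(120, 160, 250),
                   end = c(160, 200, 350), seg_mean = c(-0.5, -0.5, -0.3))
  expect_equal(as.data.frame(call_deletions(split, region, samples = "S1")),
               as.data.frame(base))
})

test_that("overlap_bp is monotone as the filter threshold rises toward 0", {
  withr::with_seed(7, {
    starts <- sample(0:5000, 20)
    segs <- seg_tbl(sample_id = rep("S1", 20),
                    start = starts,
                    end = starts + sample(100:500, 20, TRUE),
                    seg_mean = runif(20, -1, 0.2),
                    n_markers = rep(1L, 20))
    region <- region_tbl(start = 1000, end = 4000)
    thresholds <- c(-0.6, -0.4, -0.2, -0.1, -0.05)
    ovs <- vapply(thresholds, function(th) {
      call_deletions(filter_segments(segs, th), region,
                     samples = "S1")$overlap_bp
    }, numeric(1))
    expect_true(all(diff(ovs) >= 0))
  })
})

test_that("classify_gene_deletion applies the 3' > central precedence", {
  portions <- region_tbl(start = c(0, 100, 200), end = c(100, 200, 300),
                         name = c("five_prime", "central", "three_prime"),
                         kind = "gene")
  segs <- seg_tbl(sample_id = c("central_only", "spanning", "five_only"),
                  start = c(120, 150, 10), end = c(180, 260, 60),
                  seg_mean = -0.5)
  calls <- call_deletions(segs, portions,
                          samples = c("central_only", "spanning",
                                      "five_only", "wt"))
  labels <- classify_gene_deletion(calls, portions)
  lab <- function(s) as.character(labels$label[labels$sample_id == s])
  expect_equal(lab("central_only"), "central_deleted")
  expect_equal(lab("spanning"), "three_prime_deleted") # central + 3'
  expect_equal(lab("five_only"), "other")
  expect_equal(lab("wt"), "wild_type")

  overlapping <- region_tbl(start = c(0, 50, 200), end = c(100, 200, 300),
                            name = c("five_prime", "central", "three_prime"),
                            kind = "gene")
  expect_error(classify_gene_deletion(calls, overlapping), "disjoint")
})

test_that("overlap_fraction_events counts half-open overlaps exactly", {
  element <- list(chrom = "chr1", start = 100, end = 200)
  ev <- seg_tbl(sample_id = letters[1:4], start = c(0, 50, 120, 300),
                end = c(40, 110, 160, 400), seg_mean = -0.5)
  out <- overlap_fraction_events(ev, element)
  expect_equal(out$n_events, 4)
  expect_equal(out$n_overlapping, 2)
  expect_equal(out$fraction, 0.5)

  # event ending exactly at element start does not overlap (half-open)
  touch <- seg_tbl(start = 0, end = 100, seg_mean = -0.5)
  expect_equal(overlap_fraction_events(touch, element)$n_overlapping, 0)

  expect_warning(out0 <- overlap_fraction_events(ev[0, ], element),
                 "undefined")
  expect_true(is.na(out0$fraction))

  # random instances vs per-base enumeration
  withr::with_seed(11, {
    for (i in 1:20) {
      starts <- sample(0:900, 5)
      ends <- starts + sample(1:150, 5, TRUE)
      el <- list(chrom = "chr1", start = 400, end = 500)
      ev <- seg_tbl(sample_id = letters[1:5], start = starts,
                    end = ends, seg_mean = -0.5)
      got <- overlap_fraction_events(ev, el)$n_overlapping
      want <- sum(vapply(1:5, function(j) {
        brute_force_overlap(starts[j], ends[j], 400, 500) > 0
      }, logical(1)))
      expect_equal(got, want)
    }
  })
})
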