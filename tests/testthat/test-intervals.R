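test_that("overlap_length matches per-base set intersection", {
  a <- intervals("chr2L", 100, 200)
  expect_equal(overlap_length(a, a), 100)
  expect_equal(overlap_length(a, intervals("chrX", 100, 200)), 0)
  expect_equal(overlap_length(a, intervals("chr2L", 150, 400)), 50)
  set.seed(11)
  for (i in 1:1000) {
    x <- random_interval(); y <- random_interval()
    expect_identical(overlap_length(x, y), overlap_length(y, x))
    expect_equal(overlap_length(x, y), oracle_overlap_length(x, y))
  }
})

test_that("the four overlap rules follow their half-length definitions", {
  a <- intervals("c", 0, 100)
  expect_true(satisfies(a, a, "reciprocal_half"))
  b <- intervals("c", 50, 250)
  # overlap 50 is > 50? no (strict) for a; and 50 not > 100 for b
  expect_false(satisfies(a, b, "reciprocal_half"))
  expect_false(satisfies(a, b, "either_half"))
  expect_true(satisfies(a, b, "one_sided_half"))      # 50 >= 50
  expect_true(satisfies(a, b, "center_within", center_of_b = 60))
  expect_false(satisfies(a, b, "center_within", center_of_b = 100))  # half-open
  expect_error(satisfies(a, b, "center_within"), "center")
})

test_that("reciprocal_half implies either_half", {
  n_recip <- 0
  set.seed(12)
  for (i in 1:300) {
    x <- random_interval(2000, 400); y <- random_interval(2000, 400)
    if (satisfies(x, y, "reciprocal_half")) {
      n_recip <- n_recip + 1
      expect_true(satisfies(x, y, "either_half"))
    }
  }
  expect_gt(n_recip, 0)
})

test_that("odd lengths use exact rational half-lengths", {
  a <- intervals("c", 0, 101)
  b <- intervals("c", 50, 151)
  # overlap 51 > 101/2 = 50.5 on both sides
  expect_true(satisfies(a, b, "reciprocal_half"))
  b2 <- intervals("c", 51, 152)
  expect_false(satisfies(a, b2, "reciprocal_half"))  # overlap 50 < 50.5
})

test_that("merge_peaks merges on the either-half rule, transitively", {
  disjoint <- intervals("c", c(0, 200), c(100, 300))
  expect_equal(nrow(merge_peaks(disjoint)), 2)
  m <- merge_peaks(intervals("c", c(0, 40), c(100, 140)))  # overlap 60 > 50
  expect_equal(m[, c("start", "end")], data.frame(start = 0, end = 140))
  expect_equal(m$members, "1,2")
  # overlap 40: not > 50 and not > 100
  expect_equal(nrow(merge_peaks(intervals("c", c(0, 60), c(100, 260)))), 2)
  # transitive chain: each adjacent pair merges, so all three fuse
  chain <- intervals("c", c(0, 40, 80), c(100, 140, 180))
  expect_equal(nrow(merge_peaks(chain)), 1)
  expect_equal(merge_peaks(chain)$n_members, 3)
})

test_that("merge_peaks is idempotent and order-independent", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(2:15, 1)
    pk <- do.call(rbind, lapply(1:n, function(j) random_interval(2000, 300)))
    m1 <- merge_peaks(pk)
    m2 <- merge_peaks(m1[, c("chrom", "start", "end")])
    expect_equal(m2[, c("chrom", "start", "end")],
                 m1[, c("chrom", "start", "end")])
    shuf <- pk[sample.int(n), , drop = FALSE]
    expect_equal(merge_peaks(shuf)[, c("chrom", "start", "end")],
                 m1[, c("chrom", "start", "end")])
  }
})

test_that("extend_interval widens by a per-side fraction with clamping", {
  expect_equal(extend_interval(intervals("c", 100, 200), 0.5, 10000)[, c("start", "end")],
               data.frame(start = 50, end = 250))
  expect_equal(extend_interval(intervals("c", 100, 200), 0)[, c("start", "end")],
               data.frame(start = 100, end = 200))
  expect_equal(extend_interval(intervals("c", 10, 110), 0.5, 10000)[, c("start", "end")],
               data.frame(start = 0, end = 160))
  # named chromosome lengths clamp the right end
  out <- extend_interval(intervals("c", 9900, 9990), 0.5, c(c = 10000))
  expect_equal(out$end, 10000)
})

test_that("interval validation rejects malformed intervals", {
  expect_error(intervals("c", 10, 10), "start >= end")
  expect_error(intervals("c", -1, 10), "negative")
  expect_error(intervals("", 0, 10), "chromosome")
})
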