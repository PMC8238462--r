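te_hits <- function(start, end, family, te_class = "LTR", chrom = "2L") {
  data.frame(chrom = chrom, start = start, end = end, family = family,
             te_class = te_class, stringsAsFactors = FALSE)
}

test_that("same-family hits merge and short insertions are dropped", {
  m <- clean_te_annotation(te_hits(c(0, 150), c(200, 400), "roo"))
  expect_equal(m[, c("start", "end")], data.frame(start = 0, end = 400))
  short <- clean_te_annotation(te_hits(0, 80, "roo"))
  expect_equal(nrow(short), 0)
})

test_that("cross-family conflicts resolve longest-first with truncation", {
  # B spans 1100 bp, A 1000 bp: the longer insertion is kept whole and the
  # shorter one loses the common region
  raw <- rbind(te_hits(0, 1000, "A"), te_hits(500, 1600, "B"))
  out <- clean_te_annotation(raw)
  expect_equal(out[out$family == "B", c("start", "end")],
               data.frame(start = 500, end = 1600), ignore_attr = TRUE)
  expect_equal(out[out$family == "A", c("start", "end")],
               data.frame(start = 0, end = 500), ignore_attr = TRUE)
  # an insertion fully inside a longer one disappears
  raw2 <- rbind(te_hits(300, 700, "A"), te_hits(0, 1000, "B"))
  out2 <- clean_te_annotation(raw2)
  expect_equal(out2$family, "B")
  expect_equal(out2[, c("start", "end")], data.frame(start = 0, end = 1000))
  # a surviving fragment below 100 bp is dropped
  raw3 <- rbind(te_hits(0, 1000, "A"), te_hits(950, 1080, "B"))
  out3 <- clean_te_annotation(raw3)
  expect_equal(out3$family, "A")
})

test_that("microsatellite-overlapping hits are removed before merging", {
  raw <- te_hits(c(0, 500), c(300, 900), "roo")
  out <- clean_te_annotation(raw, microsatellites = intervals("2L", 100, 150))
  expect_equal(out[, c("start", "end")], data.frame(start = 500, end = 900))
})

test_that("cleaned insertions of different families never overlap", {
  set.seed(51)
  for (rep in 1:10) {
    n <- 40
    s <- sample(0:5000, n, replace = TRUE)
    raw <- te_hits(s, s + sample(50:800, n, replace = TRUE),
                   sample(c("A", "B", "C"), n, replace = TRUE))
    out <- clean_te_annotation(raw)
    if (nrow(out) > 1) {
      out <- out[order(out$start), ]
      expect_true(all(out$start[-1] >= out$end[-nrow(out)]))
      expect_true(all(out$end - out$start >= 100))
    }
  }
})

test_that("TE-derived flags follow the half-overlap and center rules", {
  pk <- data.frame(chrom = "2L", start = 0, end = 100, summit = 75,
                   stringsAsFactors = FALSE)
  ins_half <- te_hits(0, 50, "roo")
  f <- te_derived_flag(pk, ins_half, "half_overlap")
  expect_true(f$te_derived)          # exactly half, boundary inclusive
  expect_equal(f$family, "roo")
  expect_false(te_derived_flag(pk, te_hits(0, 49, "roo"), "half_overlap")$te_derived)
  ctr <- te_derived_flag(pk, te_hits(70, 300, "jockey"), "center_in_te")
  expect_true(ctr$te_derived)
  expect_equal(ctr$family, "jockey")
  expect_false(te_derived_flag(pk, ins_half, "center_in_te")$te_derived)
  none <- te_derived_flag(pk, te_hits(0, 200, "roo")[0, ], "half_overlap")
  expect_false(none$te_derived)
  # largest overlap wins family assignment
  two <- rbind(te_hits(0, 60, "small"), te_hits(20, 100, "big"))
  expect_equal(te_derived_flag(pk, two, "half_overlap")$family, "big")
})

test_that("log2 odds-ratio enrichment follows the density formula", {
  expect_equal(lor_enrichment(10, 1e4, 1000, 1e6)$lor, 0)
  e <- lor_enrichment(8, 1e4, 1000, 1e7)
  expect_equal(e$lor, 3)
  expect_true(e$enriched)
  e2 <- lor_enrichment(1, 1e5, 1000, 1e7)
  expect_equal(e2$lor, log2(0.1))
  expect_false(e2$enriched)
  expect_equal(lor_enrichment(0, 1e4, 1000, 1e7)$lor, -Inf)
  expect_true(is.na(lor_enrichment(5, 0, 1000, 1e7)$lor))
  # invariance to rescaling both densities by the same factor
  expect_equal(lor_enrichment(8, 1e4, 1000, 1e7)$lor,
               lor_enrichment(80, 1e5, 5000, 5e7)$lor)
})

test_that("motif occurrence counts allow overlap and include the reverse strand", {
  expect_equal(unname(motif_count("GAGAGA", "GAGA")), 2L)
  expect_equal(unname(motif_count("GCAGCA", "GCA")), 2L)
  expect_equal(unname(motif_count("", "GAGA")), 0L)
  expect_equal(unname(motif_count("TCTC", "GAGA")), 1L)   # reverse complement
  expect_equal(unname(motif_count("TGTGTG", "CACA")), 2L)
  counts <- motif_count("GAGATGCCACA", c("GAGA", "CACA", "GCA"))
  expect_equal(unname(counts), c(1L, 1L, 1L))  # GCA via reverse complement TGC
})
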