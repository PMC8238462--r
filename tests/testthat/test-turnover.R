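toy_track <- function(values, step = 100, chrom = "c") {
  n <- length(values)
  signal_track(data.frame(chrom = chrom, start = step * (0:(n - 1)),
                          end = step * (1:n), value = values))
}

toy_peak <- function(chrom, start, end, protein = "MOF", species = "A",
                     fe = 10, name = "p1") {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             summit = floor((start + end) / 2), fold_enrichment = fe,
             protein = protein, species = species, stringsAsFactors = FALSE)
}

test_that("max_signal returns the highest step over the region", {
  tr <- toy_track(c(2, 8))
  expect_equal(max_signal(tr, intervals("c", 50, 150)), 8)
  expect_equal(max_signal(tr, intervals("c", 0, 100)), 2)
  empty <- signal_track(data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0), value = numeric(0)))
  expect_equal(max_signal(empty, intervals("c", 0, 100)), 0)
  expect_equal(max_signal(tr, intervals("other", 0, 100)), 0)
})

test_that("the 10-fold reduction boundary is inclusive on the absent side", {
  ident <- ortholog_map("c", 0, 1000, "c", 0, 1000, "+")
  own <- toy_track(c(1, 10, 1), chrom = "c")
  pk <- toy_peak("c", 100, 200)
  other_boundary <- toy_track(c(1, 1, 1), chrom = "c")      # exactly own/10
  tc <- call_turnover(pk, own, ident, other_boundary)
  expect_equal(tc$status, "absent_in_other")
  expect_equal(tc$own_signal, 10)
  expect_equal(tc$other_signal, 1)
  other_above <- toy_track(c(1.01, 1.01, 1.01), chrom = "c")
  expect_equal(call_turnover(pk, own, ident, other_above)$status,
               "present_in_other")
})

test_that("turnover handles unmappable and zero-signal peaks", {
  m <- ortholog_map("c", 500, 1000, "c", 500, 1000, "+")
  own <- toy_track(c(1, 10, 1))
  pk <- toy_peak("c", 100, 200)
  expect_equal(call_turnover(pk, own, m, own)$status, "unmappable")
  ident <- ortholog_map("c", 0, 1000, "c", 0, 1000, "+")
  empty <- signal_track(data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0), value = numeric(0)))
  expect_warning(tc <- call_turnover(pk, empty, ident, own), "zero own signal")
  expect_equal(tc$status, "present_in_other")
})

test_that("raising the partner signal never flips present back to absent", {
  ident <- ortholog_map("c", 0, 1000, "c", 0, 1000, "+")
  own <- toy_track(c(1, 20, 1))
  pk <- toy_peak("c", 100, 200)
  set.seed(31)
  prev <- "absent_in_other"
  for (v in sort(runif(20, 0, 5))) {
    st <- call_turnover(pk, own, ident, toy_track(rep(v, 3)))$status
    if (prev == "present_in_other") expect_equal(st, "present_in_other")
    prev <- st
  }
})

test_that("conservation uses the one-sided at-least-half rule on the projection", {
  ident <- ortholog_map("cA", 0, 1000, "cB", 0, 1000, "+")
  a <- toy_peak("cA", 0, 100)
  b_half <- toy_peak("cB", 0, 50, species = "B")
  expect_equal(call_conservation(a, b_half, ident)$status, "conserved")
  b_short <- toy_peak("cB", 0, 49, species = "B")
  expect_equal(call_conservation(a, b_short, ident)$status, "unconserved")
  # union of partner peaks counts, not single-peak overlap
  b_split <- rbind(toy_peak("cB", 0, 30, species = "B"),
                   toy_peak("cB", 40, 70, species = "B", name = "p2"))
  expect_equal(call_conservation(a, b_split, ident)$status, "conserved")
  no_block <- ortholog_map("cA", 500, 1000, "cB", 500, 1000, "+")
  cc <- call_conservation(a, b_half, no_block)
  expect_equal(cc$status, "unconserved")
  expect_false(cc$mappable)
  expect_error(call_conservation(a, toy_peak("cB", 0, 50, protein = "MSL1",
                                             species = "B"), ident),
               "different proteins")
})

test_that("an identical partner species leaves every peak present and conserved", {
  cfg <- sim_config(seed = 5, n_peaks = c(MOF = 80, MSL1 = 40, MSL2 = 20),
                    gain_fraction = 0, dc_fraction = 0)
  g <- simulate_genomes(cfg)
  ps <- simulate_peaks_and_signal(cfg, g)
  tc <- call_turnover(ps$peaks_a, ps$track_a, g$map, ps$track_b,
                      g$chrom_lengths_b)
  expect_true(all(tc$status == "present_in_other"))
  for (prot in c("MOF", "MSL1", "MSL2")) {
    cc <- call_conservation(ps$peaks_a[ps$peaks_a$protein == prot, ],
                            ps$peaks_b[ps$peaks_b$protein == prot, ], g$map)
    expect_true(all(cc$status == "conserved"))
  }
})

test_that("turnover_summary counts partition the calls", {
  calls <- data.frame(status = c(rep("conserved", 3), rep("unconserved", 2)))
  s <- turnover_summary(calls)
  expect_equal(sum(s$n), 5)
  expect_equal(s$n[s$status == "conserved"], 3)
  expect_equal(nrow(turnover_summary(calls[0, , drop = FALSE])), 0)
})
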