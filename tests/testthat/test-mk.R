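test_that("variant classification follows the allele-count rules", {
  sites <- data.frame(
    chrom = "2L", pos = 1:6,
    A = c(197, 196, 100, 197, 100, 90),
    C = c(0, 1, 97, 0, 96, 90),
    G = c(0, 0, 0, 0, 0, 17),
    T = c(0, 0, 0, 0, 0, 0),
    outgroup = c("G", "A", "A", "A", "N", "A"),
    stringsAsFactors = FALSE)
  expect_warning(cls <- classify_variant(sites), ">2 ingroup alleles")
  expect_equal(cls, c("divergent", "polymorphic_singleton", "polymorphic",
                      "monomorphic_identical", "unusable", "polymorphic"))
})

test_that("site tabulation counts D, P and singleton-excluded P per class", {
  iv <- list(focal = intervals("2L", 0, 1000), outside = intervals("3R", 0, 500))
  sites <- data.frame(
    chrom = c(rep("2L", 6), "2R"), pos = c(10, 20, 30, 40, 50, 60, 10),
    A = c(197, 197, 197, 100, 110, 196, 197),
    C = c(0, 0, 0, 97, 87, 1, 0),
    G = 0, T = 0,
    outgroup = c("G", "G", "G", "A", "A", "A", "G"),
    stringsAsFactors = FALSE)
  tab <- tabulate_site_classes(sites, iv)
  focal <- tab[tab$label == "focal", ]
  expect_equal(c(focal$L, focal$D, focal$P, focal$P_nosingleton),
               c(1000, 3, 3, 2))
  outside <- tab[tab$label == "outside", ]
  expect_equal(c(outside$L, outside$D, outside$P), c(500, 0, 0))
  bad <- list(focal = intervals("2L", c(0, 500), c(600, 1000)))
  expect_error(tabulate_site_classes(sites, bad), "overlapping")
})

test_that("D/P ratios reproduce published values from the printed counts", {
  expect_equal(round(dp_ratio(site_class_counts("tot", 4199054, 164454, 80282, 59102)), 3),
               2.783)
  expect_equal(round(dp_ratio(site_class_counts("ff", 620151, 97105, 70970, 55348)), 3),
               1.754)
  expect_equal(dp_ratio(site_class_counts("z", 10, 0, 5, 4)), 0)
  expect_equal(dp_ratio(site_class_counts("inf", 10, 3, 0, 0)), Inf)
})

test_that("alpha reproduces published values including negative estimates", {
  expect_equal(round(mk_alpha(site_class_counts("s", 2251825, 23903, 1520, 1285),
                              site_class_counts("n", 2835156, 458286, 303736, 243823)), 3),
               0.899)
  expect_equal(round(mk_alpha(site_class_counts("s", 123565, 13057, 5007, 3119),
                              site_class_counts("n", 3396349, 580321, 161318, 115418)), 3),
               -0.201)
  # equal D/P ratios give alpha exactly 0
  expect_equal(mk_alpha(site_class_counts("s", 10, 20, 10, 10),
                        site_class_counts("n", 10, 40, 20, 20)), 0)
  expect_true(is.na(mk_alpha(site_class_counts("s", 10, 0, 10, 10),
                             site_class_counts("n", 10, 40, 20, 20))))
})

test_that("alpha is invariant to rescaling the neutral class and signs with D/P excess", {
  sel <- site_class_counts("s", 100, 30, 12, 10)
  neut <- site_class_counts("n", 100, 50, 30, 25)
  neut2 <- site_class_counts("n", 100, 50 * 7, 30 * 7, 25 * 7)
  expect_equal(mk_alpha(sel, neut), mk_alpha(sel, neut2))
  set.seed(42)
  for (i in 1:50) {
    s <- site_class_counts("s", 100, sample(1:500, 1), 50, sample(1:50, 1))
    n <- site_class_counts("n", 100, sample(1:500, 1), 50, sample(1:50, 1))
    a <- mk_alpha(s, n)
    expect_equal(a > 0, dp_ratio(s) > dp_ratio(n))
    expect_lte(a, 1)
  }
})

test_that("the MK Fisher test matches exhaustive hypergeometric enumeration", {
  expect_equal(mk_fisher(site_class_counts("s", 1, 10, 10, 10),
                         site_class_counts("n", 1, 10, 10, 10)), 1.0)
  p_pkg <- mk_fisher(site_class_counts("s", 1, 20, 1, 1),
                     site_class_counts("n", 1, 1, 20, 20))
  expect_equal(p_pkg, oracle_fisher2x2(20, 1, 1, 20), tolerance = 1e-10)
  set.seed(43)
  for (i in 1:20) {
    m <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      p1 <- mk_fisher(site_class_counts("s", 1, m[1, 1], m[1, 2], m[1, 2]),
                      site_class_counts("n", 1, m[2, 1], m[2, 2], m[2, 2]))
      expect_equal(p1, oracle_fisher2x2(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                   tolerance = 1e-8)
    }
  }
})

test_that("mk_test bundles ratios, alpha and the Fisher p into one fit", {
  fit <- mk_test(site_class_counts("MSL2 DC X", 177823, 17469, 9191, 7329),
                 site_class_counts("4-fold X", 620151, 97105, 70970, 55348))
  expect_s3_class(fit, "mk_test")
  expect_equal(round(fit$alpha, 3), 0.264)
  expect_lt(fit$p.value, 0.001)
  expect_named(coef(fit), c("alpha", "dp_selected", "dp_neutral", "p.value"))
  expect_output(print(fit), "fraction of adaptive fixations")
})

test_that("four-fold degenerate sites match the codon table on both strands", {
  # + strand: GGA (4-fold), ATG (not), CTT (4-fold) -> third positions 2, 8
  seq_plus <- "GGAATGCTT"
  genome <- Biostrings::DNAStringSet(c(chrP = seq_plus,
                                       chrM = revcomp_chr(seq_plus)))
  plus <- fourfold_sites(data.frame(gene = "g1", chrom = "chrP", start = 0,
                                    end = 9, strand = "+", phase = 0), genome)
  expect_equal(plus$pos, c(2, 8))
  minus <- fourfold_sites(data.frame(gene = "g2", chrom = "chrM", start = 0,
                                     end = 9, strand = "-", phase = 0), genome)
  expect_equal(sort(minus$pos), c(0, 6))
  # every codon agrees with direct genetic-code lookup
  set.seed(44)
  rnd <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  g2 <- Biostrings::DNAStringSet(c(chr1 = rnd))
  got <- fourfold_sites(data.frame(gene = "g", chrom = "chr1", start = 0,
                                   end = 300, strand = "+", phase = 0), g2)$pos
  want <- c()
  for (k in seq(1, 300, by = 3)) {
    if (oracle_fourfold_codon(substr(rnd, k, k + 2))) want <- c(want, k + 1)
  }
  expect_equal(got, want)
})

test_that("split CDS segments and unphased genes are handled", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "GGANNNATGCTT"))
  seg <- data.frame(gene = "g1", chrom = "chr1", start = c(0, 6),
                    end = c(3, 12), strand = "+", phase = 0)
  expect_equal(fourfold_sites(seg, genome)$pos, c(2, 11))
  bad <- data.frame(gene = "g2", chrom = "chr1", start = 0, end = 4,
                    strand = "+", phase = 0)
  expect_warning(out <- fourfold_sites(bad, genome), "not a multiple of 3")
  expect_equal(nrow(out), 0)
})

test_that("per-gene MK applies BH correction with monotonicity", {
  one <- gene_mk(data.frame(gene = "g1", Dn = 12, Ds = 2, Pn = 2, Ps = 12))
  expect_equal(one$bh_q, one$fisher_p)
  # hand BH: p = (0.01, 0.02, 0.04), m = 3 -> q = (0.03, 0.03, 0.04)
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  recs <- data.frame(gene = c("a", "b", "c"),
                     Dn = c(20, 1, 0), Ds = c(1, 1, 0),
                     Pn = c(1, 1, 0), Ps = c(20, 1, 0))
  out <- gene_mk(recs)
  expect_true(out$excess[1])
  expect_false(out$excess[2])
  expect_true(is.na(out$fisher_p[3]) && is.na(out$excess[3]))
  expect_true(all(out$bh_q >= out$fisher_p, na.rm = TRUE))
})

test_that("the bundled count table carries internally consistent printed values", {
  tab <- msl_mk_counts()
  expect_equal(nrow(tab), 32)
  expect_true(all(tab$P_nosingleton <= tab$P))
  expect_true(all(tab$L > 0))
  expect_equal(round(tab$D / tab$P_nosingleton, 3), tab$dp_printed)
})
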