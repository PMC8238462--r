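test_that("a fixed seed makes every generator bit-identical across runs", {
  cfg <- sim_config(seed = 9, n_peaks = c(MOF = 40, MSL1 = 20, MSL2 = 10))
  g1 <- simulate_genomes(cfg); g2 <- simulate_genomes(cfg)
  expect_identical(as.data.frame(g1$map), as.data.frame(g2$map))
  p1 <- simulate_peaks_and_signal(cfg, g1)
  p2 <- simulate_peaks_and_signal(cfg, g2)
  expect_identical(p1$peaks_a, p2$peaks_a)
  expect_identical(as.data.frame(p1$track_b), as.data.frame(p2$track_b))
  iv <- intervals("2L", 0, 5e4)
  v1 <- simulate_variants(cfg, iv, intervals("3L", 0, 5e4))
  v2 <- simulate_variants(cfg, iv, intervals("3L", 0, 5e4))
  expect_identical(v1$sites, v2$sites)
  grp <- data.frame(gene = sprintf("g%02d", 1:30),
                    bs_status = rep(names(cfg$expr_group_noise), each = 10))
  expect_identical(simulate_expression(cfg, grp)$records,
                   simulate_expression(cfg, grp)$records)
})

test_that("block coverage bounds mappability", {
  full <- simulate_genomes(sim_config(seed = 2, block_coverage = 1))
  set.seed(1)
  for (i in 1:20) {
    s <- sample(0:9e5, 1)
    q <- intervals(sample(names(full$chrom_lengths_a), 1), s, s + 100)
    expect_false(is.null(project_interval(q, full$map)))
  }
  none <- simulate_genomes(sim_config(seed = 2, block_coverage = 0))
  expect_equal(nrow(none$map), 0)
  expect_null(project_interval(intervals("2L", 100, 200), none$map))
})

test_that("planted gain fraction is recovered by the turnover caller", {
  cfg <- sim_config(seed = 14, n_peaks = c(MOF = 400, MSL1 = 0, MSL2 = 0),
                    gain_fraction = 0.10, dc_fraction = 0)
  g <- simulate_genomes(cfg)
  ps <- simulate_peaks_and_signal(cfg, g)
  tc <- call_turnover(ps$peaks_a, ps$track_a, g$map, ps$track_b,
                      g$chrom_lengths_b)
  expect_identical(tc$status == "absent_in_other", !ps$truth$conserved)
  frac <- mean(!ps$truth$conserved)
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / 400))
})

test_that("MSL2 peaks concentrate on the X at the configured fraction", {
  cfg <- sim_config(seed = 15, n_peaks = c(MOF = 200, MSL1 = 0, MSL2 = 300),
                    msl2_x_fraction = 0.97)
  ps <- simulate_peaks_and_signal(cfg, simulate_genomes(cfg))
  msl2 <- ps$peaks_a[ps$peaks_a$protein == "MSL2", ]
  expect_gt(mean(msl2$chrom == "X"), 0.92)
  mof <- ps$peaks_a[ps$peaks_a$protein == "MOF", ]
  expect_lt(mean(mof$chrom == "X"), 0.5)
})

test_that("planted DC fraction is recovered exactly by classify_dc", {
  cfg <- sim_config(seed = 16, n_peaks = c(MOF = 150, MSL1 = 0, MSL2 = 80),
                    dc_fraction = 0.2, gain_fraction = 0)
  ps <- simulate_peaks_and_signal(cfg, simulate_genomes(cfg))
  mof <- ps$peaks_a[ps$peaks_a$protein == "MOF", ]
  msl2 <- ps$peaks_a[ps$peaks_a$protein == "MSL2", ]
  lab <- classify_dc(mof, msl2)
  truth <- ps$truth[ps$truth$protein == "MOF", ]
  expect_identical(lab$dc_status == "DC", truth$dc)
})

test_that("the variant stream round-trips exactly to its count truth", {
  cfg <- sim_config(seed = 17)
  sel <- intervals("2L", c(0, 60000), c(40000, 90000))
  neut <- intervals("3R", 0, 80000)
  v <- simulate_variants(cfg, sel, neut)
  tab <- tabulate_site_classes(v$sites, list(selected = sel, neutral = neut))
  expect_equal(as.data.frame(tab), as.data.frame(v$truth),
               ignore_attr = TRUE)
  est <- mk_alpha(tab[tab$label == "selected", ], tab[tab$label == "neutral", ])
  expect_lt(abs(est - v$true_alpha), 0.15)
})

test_that("singleton rate zero collapses P onto P_nosingleton", {
  cfg <- sim_config(seed = 18, singleton_fraction = 0)
  cc <- simulate_variant_counts(cfg)
  expect_equal(cc$selected$P, cc$selected$P_nosingleton)
  expect_equal(cc$neutral$P, cc$neutral$P_nosingleton)
})

test_that("expression generator orders group divergence by planted noise", {
  cfg <- sim_config(seed = 19)
  grp <- data.frame(gene = sprintf("g%03d", 1:600),
                    bs_status = rep(c("unconservedBSplus", "BSminus",
                                      "conservedBSplus"), each = 200))
  ex <- simulate_expression(cfg, grp)
  avg <- average_tpm(ex$records)
  div <- sapply(c("unconservedBSplus", "BSminus", "conservedBSplus"),
                function(gname) {
    gs <- grp$gene[grp$bs_status == gname]
    a <- avg[avg$species == "A" & avg$sex == "male" & avg$gene %in% gs, ]
    b <- avg[avg$species == "B" & avg$sex == "male" & avg$gene %in% gs, ]
    expression_divergence(a$tpm[match(gs, a$gene)],
                          b$tpm[match(gs, b$gene)], n_boot = 0)$point
  })
  expect_gt(div["unconservedBSplus"], div["BSminus"])
  expect_gt(div["BSminus"], div["conservedBSplus"])
})

test_that("zero between-species noise gives zero divergence in every group", {
  cfg <- sim_config(seed = 20, expr_replicate_sd = 0,
                    expr_group_noise = c(unconservedBSplus = 0, BSminus = 0,
                                         conservedBSplus = 0))
  grp <- data.frame(gene = sprintf("g%02d", 1:60),
                    bs_status = rep(names(cfg$expr_group_noise), each = 20))
  ex <- simulate_expression(cfg, grp)
  avg <- average_tpm(ex$records)
  a <- avg[avg$species == "A" & avg$sex == "female", ]
  b <- avg[avg$species == "B" & avg$sex == "female", ]
  shared <- intersect(a$gene, b$gene)
  d <- expression_divergence(a$tpm[match(shared, a$gene)],
                             b$tpm[match(shared, b$gene)], n_boot = 0)
  expect_equal(d$point, 0)
})

test_that("written datasets parse cleanly through every reader", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 21, n_peaks = c(MOF = 30, MSL1 = 20, MSL2 = 10))
  paths <- expect_no_warning(write_dataset(cfg, dir))
  expect_no_warning({
    map <- load_ortholog_map(paths$map)
    pk <- read_peaks(paths$peaks_A_MOF, "MOF", "A")
    tr <- read_bedgraph(paths$track_a)
    te <- read_repeat_annotation(paths$te)
    vr <- read_variant_table(paths$variants)
    ex <- read_expression_table(paths$expression)
  })
  expect_s3_class(map, "ortholog_map")
  expect_equal(nrow(pk), 30)
  expect_s3_class(tr, "signal_track")
  expect_true(all(c("family", "te_class") %in% names(te)))
  expect_true(nrow(vr) > 0)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$seed, 21)
  expect_true(is.character(truth$te_planted_family))
})
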