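#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with defaults sized for
#' sub-minute generation: two species, five 1-Mb chromosomes (one "X"),
#' 2,000 binding peaks, ~50k variant sites. One integer seed drives a named
#' substream scheme — each generator derives its own stream from
#' `(seed, generator name)` — so adding a generator never perturbs the draws
#' of the others.
#'
#' @param seed master integer seed.
#' @param chrom_names chromosome names shared by both species; the first is
#'   treated as the X.
#' @param chrom_length length of every chromosome, bp.
#' @param block_length ortholog block tile size, bp.
#' @param block_coverage fraction of each genome covered by ortholog blocks.
#' @param n_peaks named vector of peak counts per protein.
#' @param gain_fraction fraction of focal-species peaks that are
#'   species-specific gains (absent in the partner).
#' @param dc_fraction fraction of MOF/MSL1 peaks planted on MSL2 regions
#'   (DC truth).
#' @param msl2_x_fraction fraction of MSL2 peaks placed on the X.
#' @param peak_width binding peak width, bp.
#' @param fe_meanlog,fe_sdlog log-normal parameters of peak fold enrichment;
#'   draws are clipped to at least `fe_min`.
#' @param fe_min minimum peak fold enrichment (kept above 10x the background
#'   so a background-only ortholog is an unambiguous absence).
#' @param background_fe background fold enrichment of the signal tracks.
#' @param n_te_families,te_insertions_per_family,te_insertion_length TE
#'   landscape: number of families, insertions per family, insertion length
#'   (bp).
#' @param te_planted_family,te_planted_factor one family carries
#'   `te_planted_factor` times the background binding-site density.
#' @param te_site_density genome-wide background binding-site density used by
#'   the TE enrichment generator (sites/bp).
#' @param n_sample number of sampled chromosomes in the ingroup population.
#' @param neutral_d_density,neutral_p_density neutral-class divergent and
#'   polymorphic site densities per bp (polymorphic includes singletons).
#' @param sel_p_density selected-class polymorphic site density per bp.
#' @param singleton_fraction fraction of polymorphic sites that are
#'   singletons.
#' @param true_alpha true fraction of adaptive fixations planted in the
#'   selected class (must be < 1).
#' @param expr_meanlog,expr_sdlog log-normal baseline of gene expression
#'   (shared between species).
#' @param expr_group_noise named vector of between-species log-scale noise
#'   standard deviations per gene group (drives expression divergence).
#' @param expr_replicate_sd log-scale replicate noise.
#' @param n_replicates biological replicates per species and sex.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_names = c("X", "2L", "2R", "3L", "3R"),
                       chrom_length = 1e6,
                       block_length = 2e4,
                       block_coverage = 0.9,
                       n_peaks = c(MOF = 800, MSL1 = 800, MSL2 = 400),
                       gain_fraction = 0.10,
                       dc_fraction = 0.15,
                       msl2_x_fraction = 0.97,
                       peak_width = 300,
                       fe_meanlog = log(20), fe_sdlog = 0.3, fe_min = 12,
                       background_fe = 1.0,
                       n_te_families = 10,
                       te_insertions_per_family = 40,
                       te_insertion_length = 500,
                       te_planted_family = "FAM01",
                       te_planted_factor = 8,
                       te_site_density = 2e-3,
                       n_sample = 197,
                       neutral_d_density = 0.162,
                       neutral_p_density = 0.107,
                       sel_p_density = 0.02,
                       singleton_fraction = 0.2,
                       true_alpha = 0.5,
                       expr_meanlog = 3, expr_sdlog = 1.5,
                       expr_group_noise = c(unconservedBSplus = 1.2,
                                            BSminus = 0.55,
                                            conservedBSplus = 0.15),
                       expr_replicate_sd = 0.1,
                       n_replicates = 2) {
  if (true_alpha >= 1) stop("true_alpha must be < 1")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic substream seed from (master seed, stream name). Internal.
substream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer((seed %% 2147483647) * 48271 %% 2147483647 + h) %% 2147483647L
}

#' Simulate two genome coordinate systems and their ortholog map
#'
#' Tiles every chromosome into blocks of `block_length` bp; each block is
#' orthologous (kept in the map) with probability `block_coverage`. Block
#' destination coordinates accumulate on the partner genome with gaps where
#' blocks were dropped, so the two coordinate systems differ while remaining
#' collinear. Optionally emits random genome sequences.
#'
#' @param cfg a [sim_config()].
#' @param sequences also generate random FASTA-able sequences (default
#'   `FALSE`; sequence generation dominates runtime at Mb scale).
#' @return list: `chrom_lengths_a`, `chrom_lengths_b` (named vectors), `map`
#'   (an `ortholog_map`, species A to B), and optionally `seq_a`, `seq_b`
#'   ([Biostrings::DNAStringSet]).
#' @export
simulate_genomes <- function(cfg, sequences = FALSE) {
  set.seed(substream_seed(cfg$seed, "genomes"))
  blocks <- list()
  lens_b <- stats::setNames(numeric(length(cfg$chrom_names)), cfg$chrom_names)
  for (ch in cfg$chrom_names) {
    starts <- seq(0, cfg$chrom_length - cfg$block_length, by = cfg$block_length)
    keep <- stats::runif(length(starts)) < cfg$block_coverage
    dst_pos <- 0
    for (i in seq_along(starts)) {
      if (keep[i]) {
        blocks[[length(blocks) + 1L]] <- data.frame(
          src_chrom = ch, src_start = starts[i],
          src_end = starts[i] + cfg$block_length,
          dst_chrom = ch, dst_start = dst_pos,
          dst_end = dst_pos + cfg$block_length,
          strand = "+", stringsAsFactors = FALSE)
        dst_pos <- dst_pos + cfg$block_length
      } else {
        dst_pos <- dst_pos + round(cfg$block_length / 2)  # unaligned partner gap
      }
    }
    lens_b[ch] <- max(dst_pos, cfg$block_length)
  }
  b <- do.call(rbind, blocks)
  map <- if (is.null(b)) {
    ortholog_map(character(0), numeric(0), numeric(0),
                 character(0), numeric(0), numeric(0), character(0))
  } else {
    ortholog_map(b$src_chrom, b$src_start, b$src_end,
                 b$dst_chrom, b$dst_start, b$dst_end, b$strand)
  }
  out <- list(chrom_lengths_a = stats::setNames(
    rep(cfg$chrom_length, length(cfg$chrom_names)), cfg$chrom_names),
    chrom_lengths_b = lens_b, map = map)
  if (sequences) {
    rand_genome <- function(lens) {
      s <- Biostrings::DNAStringSet(vapply(lens, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
        character(1)))
      names(s) <- names(lens)
      s
    }
    out$seq_a <- rand_genome(out$chrom_lengths_a)
    out$seq_b <- rand_genome(out$chrom_lengths_b)
  }
  out
}

#' Simulate binding peaks and fold-enrichment signal tracks
#'
#' Peaks are placed on a slot grid inside ortholog blocks of species A (so
#' every peak is cleanly mappable and peaks never interfere with one
#' another's signal search windows). MSL2 peaks concentrate on the X;
#' a configured fraction of MOF/MSL1 peaks is planted on MSL2 intervals (DC
#' truth). A `gain_fraction` of species-A peaks is species-specific: the
#' partner track carries only background there, at least 10-fold below the
#' peak's own signal. Conserved peaks get a matching partner peak whose
#' signal ratio is drawn strictly above the 10-fold boundary.
#'
#' @param cfg a [sim_config()].
#' @param genomes result of [simulate_genomes()].
#' @return list: `peaks_a`, `peaks_b` (peak tables), `track_a`, `track_b`
#'   ([signal_track()]), `truth` (per species-A peak: `conserved`, `dc`).
#' @export
simulate_peaks_and_signal <- function(cfg, genomes) {
  set.seed(substream_seed(cfg$seed, "peaks"))
  w <- cfg$peak_width
  spacing <- 6 * w
  map <- genomes$map
  slots <- do.call(rbind, lapply(seq_len(nrow(map)), function(i) {
    ss <- seq(map$src_start[i] + w, map$src_end[i] - 2 * w, by = spacing)
    if (!length(ss)) return(NULL)
    data.frame(chrom = map$src_chrom[i], start = ss, stringsAsFactors = FALSE)
  }))
  x_chrom <- cfg$chrom_names[1]
  total <- sum(cfg$n_peaks)
  if (total > nrow(slots))
    stop("not enough slots for ", total, " peaks; lower n_peaks or peak_width")
  peaks_a <- list(); peaks_b <- list(); truth <- list()
  used <- rep(FALSE, nrow(slots))
  pick_slot <- function(on_x) {
    cand <- which(!used & ((slots$chrom == x_chrom) == on_x))
    if (!length(cand)) cand <- which(!used)
    s <- cand[sample.int(length(cand), 1)]
    used[s] <<- TRUE
    s
  }
  msl2_rows <- list()
  prot_order <- c(intersect("MSL2", names(cfg$n_peaks)),
                  setdiff(names(cfg$n_peaks), "MSL2"))
  for (prot in prot_order) {
    for (k in seq_len(cfg$n_peaks[[prot]])) {
      on_x <- if (prot == "MSL2") stats::runif(1) < cfg$msl2_x_fraction
      else stats::runif(1) < 1 / length(cfg$chrom_names)
      dc <- FALSE
      if (prot != "MSL2" && length(msl2_rows) > 0 &&
          stats::runif(1) < cfg$dc_fraction) {
        base <- msl2_rows[[sample.int(length(msl2_rows), 1)]]
        chrom <- base$chrom; start <- base$start
        dc <- TRUE
      } else {
        s <- pick_slot(on_x)
        chrom <- slots$chrom[s]; start <- slots$start[s]
      }
      fe <- pmax(cfg$fe_min, stats::rlnorm(1, cfg$fe_meanlog, cfg$fe_sdlog))
      # DC-planted peaks share an MSL2 region that carries partner signal, so
      # they are always conserved; gains are drawn among the rest.
      gained <- !dc && stats::runif(1) < cfg$gain_fraction
      pa <- data.frame(chrom = chrom, start = start, end = start + w,
                       name = sprintf("%s_a_%04d", prot, k),
                       summit = start + floor(w / 2),
                       fold_enrichment = fe, protein = prot, species = "A",
                       stringsAsFactors = FALSE)
      peaks_a[[length(peaks_a) + 1L]] <- pa
      if (prot == "MSL2" && !gained)
        msl2_rows[[length(msl2_rows) + 1L]] <- pa
      if (!gained) {
        proj <- project_interval(pa, map)
        ratio <- stats::runif(1, 0.3, 1.6)  # strictly above the 1/10 boundary
        peaks_b[[length(peaks_b) + 1L]] <- data.frame(
          chrom = proj$chrom, start = proj$start, end = proj$end,
          name = sprintf("%s_b_%04d", prot, k),
          summit = proj$start + floor((proj$end - proj$start) / 2),
          fold_enrichment = fe * ratio, protein = prot, species = "B",
          stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        name = pa$name, protein = prot, conserved = !gained, dc = dc,
        stringsAsFactors = FALSE)
    }
  }
  peaks_a <- do.call(rbind, peaks_a)
  peaks_b <- do.call(rbind, peaks_b)
  truth <- do.call(rbind, truth)
  list(peaks_a = peaks_a, peaks_b = peaks_b,
       track_a = build_track(peaks_a, genomes$chrom_lengths_a, cfg$background_fe),
       track_b = build_track(peaks_b, genomes$chrom_lengths_b, cfg$background_fe),
       truth = truth)
}

# Step track: background value everywhere, peak fold enrichment on the
# (flattened, max-valued) peak segments. Internal.
build_track <- function(peaks, chrom_lengths, background) {
  segs <- list()
  for (ch in names(chrom_lengths)) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    pos <- 0
    if (nrow(p)) for (i in seq_len(nrow(p))) {
      s <- max(pos, p$start[i]); e <- p$end[i]
      if (s > pos)
        segs[[length(segs) + 1L]] <- data.frame(chrom = ch, start = pos,
                                                end = s, value = background)
      if (e > s)
        segs[[length(segs) + 1L]] <- data.frame(chrom = ch, start = s, end = e,
                                                value = p$fold_enrichment[i])
      pos <- max(pos, e)
    }
    if (pos < chrom_lengths[[ch]])
      segs[[length(segs) + 1L]] <- data.frame(chrom = ch, start = pos,
                                              end = chrom_lengths[[ch]],
                                              value = background)
  }
  signal_track(do.call(rbind, segs))
}

#' Simulate site-class counts with a planted true alpha
#'
#' The count layer of the variant generator: Poisson draws of divergent and
#' polymorphic site counts for a neutral class (given densities) and a
#' selected class whose divergence density is inflated so that the planted
#' fraction of adaptive fixations equals `true_alpha`:
#' `D_sel = (D_neut / P_neut) * P_sel / (1 - alpha)` in expectation (all P
#' singleton-excluded).
#'
#' @param cfg a [sim_config()].
#' @param L_sel,L_neut class lengths in bp.
#' @param true_alpha planted alpha; defaults to `cfg$true_alpha`.
#' @param stream substream name (vary to get independent replicates).
#' @return list: `selected`, `neutral` ([site_class_counts()]), `true_alpha`.
#' @export
simulate_variant_counts <- function(cfg, L_sel = 1e6, L_neut = 1e6,
                                    true_alpha = cfg$true_alpha,
                                    stream = "variant_counts") {
  if (true_alpha >= 1) stop("true_alpha must be < 1")
  set.seed(substream_seed(cfg$seed, stream))
  p_neut_ns <- cfg$neutral_p_density * (1 - cfg$singleton_fraction)
  p_sel_ns <- cfg$sel_p_density * (1 - cfg$singleton_fraction)
  d_neut <- cfg$neutral_d_density
  d_sel <- (d_neut / p_neut_ns) * p_sel_ns / (1 - true_alpha)
  draw <- function(L, d_dens, p_dens) {
    D <- stats::rpois(1, d_dens * L)
    P <- stats::rpois(1, p_dens * L)
    n_single <- stats::rbinom(1, P, cfg$singleton_fraction)
    c(D = D, P = P, Pn = P - n_single)
  }
  s <- draw(L_sel, d_sel, cfg$sel_p_density)
  n <- draw(L_neut, d_neut, cfg$neutral_p_density)
  list(selected = site_class_counts("selected", L_sel, s["D"], s["P"], s["Pn"]),
       neutral = site_class_counts("neutral", L_neut, n["D"], n["P"], n["Pn"]),
       true_alpha = true_alpha)
}

#' Simulate a variant-site stream over class intervals
#'
#' Materialises the counts drawn by [simulate_variant_counts()] as individual
#' variant sites at distinct positions inside the provided class intervals:
#' divergent sites are fixed in the ingroup and differ from the outgroup,
#' polymorphic sites carry two alleles with minor count at least 2, singleton
#' sites carry minor count exactly 1.
#'
#' @param cfg a [sim_config()].
#' @param sel_intervals,neut_intervals disjoint interval tables of the
#'   selected and neutral classes.
#' @param true_alpha planted alpha; defaults to `cfg$true_alpha`.
#' @return list: `sites` (variant table, see [classify_variant()]), `truth`
#'   (two-row `site_class_counts`: selected and neutral), `true_alpha`.
#' @export
simulate_variants <- function(cfg, sel_intervals, neut_intervals,
                              true_alpha = cfg$true_alpha) {
  L_sel <- union_length(sel_intervals)
  L_neut <- union_length(neut_intervals)
  counts <- simulate_variant_counts(cfg, L_sel, L_neut, true_alpha,
                                    stream = "variants")
  set.seed(substream_seed(cfg$seed, "variant_sites"))
  bases <- c("A", "C", "G", "T")
  make_sites <- function(iv, cc) {
    flat <- flatten_intervals(iv)
    offs <- c(0, cumsum(flat$end - flat$start))
    L <- offs[length(offs)]
    n_div <- cc$D; n_poly <- cc$P_nosingleton; n_single <- cc$P - cc$P_nosingleton
    n <- n_div + n_poly + n_single
    if (n > L) stop("class too small for requested site count")
    lin <- sort(sample.int(L, n)) - 1
    block <- findInterval(lin, offs, rightmost.closed = FALSE)
    chrom <- flat$chrom[block]
    pos <- flat$start[block] + (lin - offs[block])
    kind <- sample(rep(c("divergent", "polymorphic", "singleton"),
                       c(n_div, n_poly, n_single)))
    cnt <- matrix(0L, n, 4, dimnames = list(NULL, bases))
    outg <- character(n)
    for (i in seq_len(n)) {
      al <- sample(bases, 2)
      if (kind[i] == "divergent") {
        cnt[i, al[1]] <- cfg$n_sample
        outg[i] <- al[2]
      } else {
        minor <- if (kind[i] == "singleton") 1L else
          sample(2:max(2, floor(cfg$n_sample / 2)), 1)
        cnt[i, al[1]] <- cfg$n_sample - minor
        cnt[i, al[2]] <- minor
        outg[i] <- al[1]
      }
    }
    data.frame(chrom = chrom, pos = pos, A = cnt[, "A"], C = cnt[, "C"],
               G = cnt[, "G"], T = cnt[, "T"], outgroup = outg,
               stringsAsFactors = FALSE)
  }
  sites <- rbind(make_sites(sel_intervals, counts$selected),
                 make_sites(neut_intervals, counts$neutral))
  truth <- rbind(counts$selected, counts$neutral)
  class(truth) <- c("site_class_counts", "data.frame")
  list(sites = sites[order(sites$chrom, sites$pos), , drop = FALSE],
       truth = truth, true_alpha = true_alpha)
}

#' Simulate a TE landscape with one enriched family
#'
#' Places non-overlapping insertions for each family on a slot grid, then
#' places binding sites at uniform background density across the genome plus
#' extra sites inside the planted family's insertions so that its site
#' density is `te_planted_factor` times background.
#'
#' @param cfg a [sim_config()].
#' @param chrom_lengths named chromosome length vector; defaults to the
#'   configured layout.
#' @param stream substream name (vary for independent replicates).
#' @return list: `insertions` (cleaned-style TE table), `peaks` (binding
#'   site table), `genome_size`, `planted_family`.
#' @export
simulate_te <- function(cfg, chrom_lengths = NULL, stream = "te") {
  set.seed(substream_seed(cfg$seed, stream))
  if (is.null(chrom_lengths))
    chrom_lengths <- stats::setNames(
      rep(cfg$chrom_length, length(cfg$chrom_names)), cfg$chrom_names)
  G <- sum(chrom_lengths)
  fams <- sprintf("FAM%02d", seq_len(cfg$n_te_families))
  te_cls <- rep(c("LTR", "Non-LTR", "DNA", "Unclassified"),
                length.out = cfg$n_te_families)
  len <- cfg$te_insertion_length
  spacing <- 3 * len
  slots <- do.call(rbind, lapply(names(chrom_lengths), function(ch)
    data.frame(chrom = ch,
               start = seq(0, chrom_lengths[[ch]] - len, by = spacing),
               stringsAsFactors = FALSE)))
  need <- cfg$n_te_families * cfg$te_insertions_per_family
  if (need > nrow(slots)) stop("not enough TE slots")
  sel <- slots[sample.int(nrow(slots), need), , drop = FALSE]
  insertions <- data.frame(chrom = sel$chrom, start = sel$start,
                           end = sel$start + len,
                           family = rep(fams, each = cfg$te_insertions_per_family),
                           te_class = rep(te_cls, each = cfg$te_insertions_per_family),
                           stringsAsFactors = FALSE)
  # background sites uniform over the genome
  n_bg <- stats::rpois(1, cfg$te_site_density * G)
  offs <- c(0, cumsum(chrom_lengths))
  w <- 200
  lin <- sort(stats::runif(n_bg, 0, G - w))
  blk <- findInterval(lin, offs)
  bg <- data.frame(chrom = names(chrom_lengths)[blk],
                   start = floor(lin - offs[blk]), stringsAsFactors = FALSE)
  # extra sites inside the planted family to reach the planted density factor
  planted <- insertions[insertions$family == cfg$te_planted_family, , drop = FALSE]
  L_planted <- sum(planted$end - planted$start)
  n_extra <- stats::rpois(1, (cfg$te_planted_factor - 1) *
                            cfg$te_site_density * L_planted)
  idx <- sample.int(nrow(planted), n_extra, replace = TRUE)
  extra <- data.frame(chrom = planted$chrom[idx],
                      start = planted$start[idx] +
                        floor(stats::runif(n_extra, 0, len - w)),
                      stringsAsFactors = FALSE)
  pk <- rbind(bg, extra)
  peaks <- data.frame(chrom = pk$chrom, start = pk$start, end = pk$start + w,
                      name = sprintf("site_%05d", seq_len(nrow(pk))),
                      summit = pk$start + w / 2,
                      fold_enrichment = 10, protein = "MOF", species = "A",
                      stringsAsFactors = FALSE)
  list(insertions = insertions[order(insertions$chrom, insertions$start), ],
       peaks = peaks, genome_size = G,
       planted_family = cfg$te_planted_family)
}

#' Simulate replicate expression tables with group-level divergence
#'
#' Gene baselines are log-normal and shared between species; species B adds
#' per-gene log-scale noise whose standard deviation is set per gene group
#' (`expr_group_noise`), so groups with larger noise have larger expected
#' `1 - rho` divergence. Replicates add i.i.d. log-scale noise; both sexes
#' are emitted with a shared sex offset.
#'
#' @param cfg a [sim_config()].
#' @param groups data.frame with columns `gene` and `bs_status` (one of the
#'   names of `cfg$expr_group_noise`).
#' @param stream substream name (vary for independent replicates).
#' @return list: `records` (expression table, see [average_tpm()]), `groups`
#'   (the input, the ground truth).
#' @export
simulate_expression <- function(cfg, groups, stream = "expression") {
  set.seed(substream_seed(cfg$seed, stream))
  stopifnot(all(groups$bs_status %in% names(cfg$expr_group_noise)))
  n <- nrow(groups)
  base <- stats::rnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)
  shift <- stats::rnorm(n, 0, cfg$expr_group_noise[groups$bs_status])
  sex_off <- c(male = 0.2, female = -0.2)
  recs <- list()
  for (sp in c("A", "B")) for (sx in c("male", "female"))
    for (r in seq_len(cfg$n_replicates)) {
      mu <- base + if (sp == "B") shift else 0
      tpm <- exp(mu + sex_off[[sx]] +
                   stats::rnorm(n, 0, cfg$expr_replicate_sd))
      recs[[length(recs) + 1L]] <- data.frame(
        gene = groups$gene, species = sp, sex = sx, replicate = r,
        tpm = tpm, stringsAsFactors = FALSE)
    }
  list(records = do.call(rbind, recs), groups = groups)
}

#' Write a complete synthetic dataset to disk
#'
#' Generates genomes, peaks, signal tracks, the TE landscape, a variant
#' stream and expression tables, and writes each in the dialect the pipeline
#' reads (block TSV, narrowPeak, bedGraph, repeat TSV, variant TSV,
#' expression TSV) plus a `truth.json` with the planted ground truth.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named list of file paths written.
#' @export
write_dataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genomes <- simulate_genomes(cfg)
  ps <- simulate_peaks_and_signal(cfg, genomes)
  te <- simulate_te(cfg)
  sel_iv <- ps$peaks_a[ps$peaks_a$protein == "MOF", c("chrom", "start", "end")]
  neut_iv <- data.frame(chrom = cfg$chrom_names[2],
                        start = 0, end = cfg$chrom_length)
  vr <- simulate_variants(cfg, sel_iv, neut_iv)
  groups <- data.frame(gene = sprintf("g%04d", 1:300),
                       bs_status = rep(names(cfg$expr_group_noise), each = 100),
                       stringsAsFactors = FALSE)
  ex <- simulate_expression(cfg, groups)
  paths <- list(
    map = file.path(dir, "ortholog_map.tsv"),
    track_a = file.path(dir, "signal_A.bedGraph"),
    track_b = file.path(dir, "signal_B.bedGraph"),
    te = file.path(dir, "te_annotation.tsv"),
    variants = file.path(dir, "variants.tsv"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.json"))
  write_ortholog_map(genomes$map, paths$map)
  for (sp in c("A", "B")) {
    pk <- if (sp == "A") ps$peaks_a else ps$peaks_b
    for (prot in unique(pk$protein)) {
      key <- paste0("peaks_", sp, "_", prot)
      paths[[key]] <- file.path(dir, paste0(key, ".narrowPeak"))
      write_narrowpeak(pk[pk$protein == prot, , drop = FALSE], paths[[key]])
    }
  }
  write_bedgraph(ps$track_a, paths$track_a)
  write_bedgraph(ps$track_b, paths$track_b)
  con <- file(paths$te, "w")
  writeLines("#chrom\tstart\tend\tfamily\tte_class", con)
  utils::write.table(te$insertions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  con <- file(paths$variants, "w")
  writeLines("#chrom\tpos\tA\tC\tG\tT\toutgroup", con)
  utils::write.table(vr$sites, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  con <- file(paths$expression, "w")
  writeLines("#gene\tspecies\tsex\treplicate\ttpm", con)
  utils::write.table(ex$records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  jsonlite::write_json(list(
    seed = cfg$seed,
    peak_truth = ps$truth,
    variant_truth = as.data.frame(vr$truth),
    true_alpha = vr$true_alpha,
    te_planted_family = te$planted_family,
    expression_groups = ex$groups), paths$truth, dataframe = "columns")
  invisible(paths)
}
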