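#' Validate a pipeline run configuration
#'
#' Checks that referenced input files exist, thresholds are positive, rule
#' names are known and chromosome names are compatible between the peak
#' inputs and the ortholog map. Problems are returned, not thrown; an empty
#' character vector means the configuration is runnable.
#'
#' @param config configuration list (see [run_pipeline()]) or the path to a
#'   YAML file holding one.
#' @return character vector of problems (empty when valid).
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))
  ins <- config$inputs
  paths <- c(unlist(lapply(ins$peaks, `[[`, "path")),
             ins$map, ins$track_a, ins$track_b, ins$te, ins$microsatellites,
             ins$cis_elements, ins$variants, ins$neutral_intervals,
             ins$expression, ins$genes)
  for (p in paths) if (!is.null(p) && !file.exists(p))
    note("missing input file: ", p)
  th <- config$thresholds
  if (!is.null(th$fold) && th$fold <= 0) note("fold threshold must be positive")
  if (!is.null(th$lor) && th$lor <= 0) note("LOR threshold must be positive")
  if (!is.null(th$bh_q) && (th$bh_q <= 0 || th$bh_q > 1))
    note("BH q threshold must be in (0, 1]")
  if (!is.null(config$rules$te_rule) &&
      !config$rules$te_rule %in% c("half_overlap", "center_in_te"))
    note("unknown te_rule: ", config$rules$te_rule)
  if (!is.null(config$rules$cis_rule) &&
      !config$rules$cis_rule %in% c("center_within", "half_overlap"))
    note("unknown cis_rule: ", config$rules$cis_rule)
  if (!is.null(ins$map) && file.exists(ins$map) && length(ins$peaks)) {
    map <- try(load_ortholog_map(ins$map), silent = TRUE)
    if (inherits(map, "try-error")) {
      note("ortholog map failed to load: ", attr(map, "condition")$message)
    } else {
      for (pk in ins$peaks) {
        if (!file.exists(pk$path)) next
        peaks <- read_peaks(pk$path, pk$protein, pk$species)
        side <- if (identical(pk$species, config$species_b)) map$dst_chrom else map$src_chrom
        if (!any(peaks$chrom %in% side))
          note("no shared chromosome names between ", pk$path,
               " and the ortholog map")
      }
    }
  }
  problems
}

#' Run the comparative binding-site pipeline
#'
#' Executes the stages in dependency order — turnover and conservation
#' calling, DC/non-DC classification, TE cleaning/flagging/enrichment,
#' cis-regulatory overlap, MK tabulation and expression divergence — each
#' stage skipped when its inputs are absent from the configuration. Reports
#' are written as TSV/JSON into the output directory together with a run
#' manifest (configuration, package version, seed). With identical
#' configuration and inputs the outputs are byte-identical: every random
#' step is seeded from `config$seed`.
#'
#' @param config configuration list or path to a YAML file. Recognised keys:
#'   `seed`, `output_dir`, `species_a`, `species_b`,
#'   `rules` (`te_rule`, `cis_rule`), `thresholds` (`fold`, `lor`, `bh_q`),
#'   and `inputs`: `peaks` (list of `{path, protein, species}` entries),
#'   `map` (block TSV), `track_a`/`track_b` (bedGraph),
#'   `te` (repeat TSV), `microsatellites` (BED), `cis_elements` (TSV with
#'   `chrom start end category center`), `variants` (variant TSV),
#'   `neutral_intervals` (BED of the neutral class), `expression`
#'   (expression TSV), `genes` (TSV with `gene chrom start end strand`).
#' @return invisibly, a named list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- validate_run_config(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ins <- config$inputs
  th <- config$thresholds %||% list()
  rules <- config$rules %||% list()
  fold <- th$fold %||% 10
  seed <- config$seed %||% 1
  results <- list()
  log_stage <- function(stage, n_in, n_out)
    message(sprintf("[%s] %d records in, %d out", stage, n_in, n_out))

  peaks <- lapply(ins$peaks, function(pk)
    read_peaks(pk$path, pk$protein, pk$species))
  species_a <- config$species_a %||% "A"
  species_b <- config$species_b %||% "B"
  all_peaks <- if (length(peaks)) do.call(rbind, peaks) else NULL
  pa <- if (!is.null(all_peaks)) all_peaks[all_peaks$species == species_a, , drop = FALSE]
  pb <- if (!is.null(all_peaks)) all_peaks[all_peaks$species == species_b, , drop = FALSE]

  map <- if (!is.null(ins$map)) load_ortholog_map(ins$map)

  # --- turnover & conservation -------------------------------------------
  if (!is.null(map) && !is.null(ins$track_a) && !is.null(ins$track_b) &&
      !is.null(pa) && nrow(pa)) {
    track_a <- read_bedgraph(ins$track_a)
    track_b <- read_bedgraph(ins$track_b)
    tc <- call_turnover(pa, track_a, map, track_b, fold = fold)
    turnover <- cbind(pa[, c("chrom", "start", "end", "name", "protein", "species")], tc)
    cons <- do.call(rbind, lapply(unique(pa$protein), function(prot) {
      a <- pa[pa$protein == prot, , drop = FALSE]
      b <- pb[pb$protein == prot, , drop = FALSE]
      cbind(a[, c("chrom", "start", "end", "name", "protein")],
            call_conservation(a, b, map))
    }))
    write_tsv_report(turnover, file.path(out_dir, "turnover.tsv"))
    write_tsv_report(cons, file.path(out_dir, "conservation.tsv"))
    write_tsv_report(turnover_summary(
      data.frame(species = turnover$species, protein = turnover$protein,
                 status = turnover$status)),
      file.path(out_dir, "turnover_summary.tsv"))
    log_stage("turnover", nrow(pa), nrow(turnover))
    results$turnover <- turnover
    results$conservation <- cons
  }

  # --- DC classification --------------------------------------------------
  dc_labels <- NULL
  if (!is.null(pa) && nrow(pa) && "MSL2" %in% pa$protein) {
    msl2 <- pa[pa$protein == "MSL2", , drop = FALSE]
    dc_labels <- do.call(rbind, lapply(c("MOF", "MSL1"), function(prot) {
      tp <- pa[pa$protein == prot, , drop = FALSE]
      if (!nrow(tp)) return(NULL)
      cbind(tp[, c("chrom", "start", "end", "name", "protein")],
            classify_dc(tp, msl2))
    }))
    write_tsv_report(dc_labels, file.path(out_dir, "dc_labels.tsv"))
    part <- overlap_partition(merge_peaks(pa[pa$protein == "MOF", , drop = FALSE]),
                              merge_peaks(pa[pa$protein == "MSL1", , drop = FALSE]),
                              merge_peaks(msl2))
    jsonlite::write_json(as.list(part),
                         file.path(out_dir, "overlap_partition.json"),
                         auto_unbox = TRUE)
    write_tsv_report(chromosome_distribution(pa),
                     file.path(out_dir, "chromosome_distribution.tsv"))
    log_stage("classify", nrow(pa), nrow(dc_labels))
    results$dc_labels <- dc_labels
  }

  # --- TE cleaning, flags, enrichment ------------------------------------
  te_flags <- NULL
  nondc <- if (!is.null(dc_labels)) {
    key <- paste(dc_labels$name, dc_labels$protein)
    sel <- key[dc_labels$dc_status == "nonDC"]
    pa[paste(pa$name, pa$protein) %in% sel, , drop = FALSE]
  } else pa
  if (!is.null(ins$te) && !is.null(nondc) && nrow(nondc)) {
    raw <- read_repeat_annotation(ins$te)
    micro <- if (!is.null(ins$microsatellites)) read_bed6(ins$microsatellites)
    insertions <- clean_te_annotation(raw, micro)
    te_rule <- rules$te_rule %||% "half_overlap"
    flags <- te_derived_flag(nondc, insertions, te_rule)
    te_flags <- cbind(nondc[, c("chrom", "start", "end", "name", "protein")], flags)
    genome_size <- config$genome_size %||%
      sum(tapply(c(raw$end, nondc$end), c(raw$chrom, nondc$chrom), max))
    enrich <- te_family_enrichment(nondc, insertions, genome_size,
                                   te_rule, th$lor %||% 1.5)
    enrich$rule <- te_rule
    write_tsv_report(te_flags, file.path(out_dir, "te_flags.tsv"))
    write_tsv_report(enrich, file.path(out_dir, "te_enrichment.tsv"))
    log_stage("te", nrow(raw), nrow(insertions))
    results$te_insertions <- insertions
    results$te_flags <- te_flags
    results$te_enrichment <- enrich
  }

  # --- cis-regulatory overlap ---------------------------------------------
  if (!is.null(ins$cis_elements) && !is.null(nondc) && nrow(nondc)) {
    ce <- read_dialect_tsv(ins$cis_elements,
                           c("chrom", "start", "end", "category", "center"),
                           "cis elements")
    elements <- cis_elements(ce$chrom, ce$start, ce$end, ce$category, ce$center)
    cis_rule <- rules$cis_rule %||% "center_within"
    td <- if (!is.null(te_flags)) te_flags$te_derived else rep(FALSE, nrow(nondc))
    tab <- cis_overlap_table(nondc, td, elements, cis_rule)
    tab$rule <- cis_rule
    write_tsv_report(tab, file.path(out_dir, "cis_overlap.tsv"))
    log_stage("cis", nrow(nondc), nrow(tab))
    results$cis_overlap <- tab
  }

  # --- MK tabulation -------------------------------------------------------
  if (!is.null(ins$variants) && !is.null(nondc) && nrow(nondc) &&
      !is.null(ins$neutral_intervals)) {
    sites <- read_variant_table(ins$variants)
    neutral_iv <- read_bed6(ins$neutral_intervals)
    classes <- list(neutral = neutral_iv)
    for (prot in unique(nondc$protein))
      classes[[paste0(prot, "_nonDC")]] <-
        flatten_intervals(nondc[nondc$protein == prot, , drop = FALSE])
    counts <- tabulate_site_classes(sites, classes)
    mk <- do.call(rbind, lapply(
      setdiff(counts$label, "neutral"), function(lab) {
        fit <- mk_test(counts[counts$label == lab, ],
                       counts[counts$label == "neutral", ])
        data.frame(label = lab, L = fit$selected$L, D = fit$selected$D,
                   P = fit$selected$P,
                   P_nosingleton = fit$selected$P_nosingleton,
                   dp_ratio = fit$dp_selected, alpha = fit$alpha,
                   fisher_p = fit$p.value, stringsAsFactors = FALSE)
      }))
    write_tsv_report(as.data.frame(counts), file.path(out_dir, "mk_counts.tsv"))
    write_tsv_report(mk, file.path(out_dir, "mk_report.tsv"))
    log_stage("mk", nrow(sites), nrow(mk))
    results$mk <- mk
  }

  # --- expression divergence ----------------------------------------------
  if (!is.null(ins$expression) && !is.null(ins$genes)) {
    records <- read_expression_table(ins$expression)
    genes <- read_dialect_tsv(ins$genes,
                              c("gene", "chrom", "start", "end", "strand"),
                              "gene table")
    nondc_cons <- NULL
    if (!is.null(results$conservation) && !is.null(nondc) && nrow(nondc)) {
      cons <- results$conservation
      key <- paste(nondc$name, nondc$protein)
      ck <- paste(cons$name, cons$protein)
      nondc_cons <- nondc
      nondc_cons$conservation <- cons$status[match(key, ck)]
    }
    groups <- if (!is.null(nondc_cons))
      group_genes(genes, nondc_cons, results$te_insertions)
    else data.frame(gene = genes$gene, bs_status = "BSminus",
                    te_status = "TEminus", stringsAsFactors = FALSE)
    avg <- average_tpm(records)
    div <- do.call(rbind, lapply(unique(avg$sex), function(sx) {
      do.call(rbind, lapply(unique(groups$bs_status), function(grp) {
        gsel <- groups$gene[groups$bs_status == grp]
        a <- avg[avg$species == species_a & avg$sex == sx & avg$gene %in% gsel, ]
        b <- avg[avg$species == species_b & avg$sex == sx & avg$gene %in% gsel, ]
        shared <- intersect(a$gene, b$gene)
        d <- expression_divergence(a$tpm[match(shared, a$gene)],
                                   b$tpm[match(shared, b$gene)],
                                   seed = substream_seed(seed, paste0("div_", sx, "_", grp)))
        data.frame(sex = sx, group = grp, n_genes = d$n_genes,
                   divergence = d$point,
                   boot_lo = if (length(d$bootstrap)) stats::quantile(d$bootstrap, 0.025) else NA,
                   boot_hi = if (length(d$bootstrap)) stats::quantile(d$bootstrap, 0.975) else NA,
                   stringsAsFactors = FALSE)
      }))
    }))
    write_tsv_report(groups, file.path(out_dir, "gene_groups.tsv"))
    write_tsv_report(div, file.path(out_dir, "expression_divergence.tsv"))
    log_stage("expression", nrow(records), nrow(div))
    results$expression <- div
  }

  manifest <- list(
    package = "mslevo",
    version = as.character(utils::packageVersion("mslevo")),
    seed = seed,
    rules = rules, thresholds = th,
    inputs = ins,
    stages_run = names(results))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
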