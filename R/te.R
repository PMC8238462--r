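#' Clean raw repeat annotations into non-redundant TE insertions
#'
#' Cleaning proceeds in four steps:
#' \enumerate{
#'   \item hits overlapping any microsatellite interval are dropped;
#'   \item overlapping hits from the same TE family are union-merged;
#'   \item remaining insertions are sorted by length descending (ties by
#'     chrom, start for determinism) and shorter insertions have regions
#'     overlapping any already-accepted longer insertion removed; when this
#'     splits an insertion, the longest surviving fragment is kept (leftmost
#'     on ties);
#'   \item insertions shorter than `min_length` bp (default 100) are dropped.
#' }
#' After cleaning, insertions of different families never overlap.
#'
#' @param raw_hits data.frame: `chrom`, `start`, `end`, `family`, `te_class`
#'   (one of LTR, Non-LTR, DNA, Unclassified; optional).
#' @param microsatellites interval table of microsatellite regions to exclude
#'   (default none).
#' @param min_length minimum insertion length kept (default 100 bp).
#' @return cleaned insertion table: `chrom`, `start`, `end`, `family`,
#'   `te_class`.
#' @export
clean_te_annotation <- function(raw_hits, microsatellites = NULL,
                                min_length = 100) {
  validate_intervals(raw_hits, "TE hits")
  x <- raw_hits
  if (is.null(x$te_class)) x$te_class <- "Unclassified"
  if (!is.null(microsatellites) && nrow(microsatellites) > 0 && nrow(x) > 0) {
    ms <- flatten_intervals(microsatellites)
    keep <- vapply(seq_len(nrow(x)), function(i)
      overlap_with_set(x$chrom[i], x$start[i], x$end[i], ms) == 0, logical(1))
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end", "family", "te_class")])
  # same-family union merge
  merged <- do.call(rbind, lapply(split(x, x$family), function(fx) {
    flat <- flatten_intervals(fx[, c("chrom", "start", "end")])
    flat$family <- fx$family[1]
    flat$te_class <- fx$te_class[1]
    flat
  }))
  # longest-first cross-family truncation
  merged <- merged[order(-(merged$end - merged$start), merged$chrom,
                         merged$start), , drop = FALSE]
  accepted <- merged[0, , drop = FALSE]
  acc_flat <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(merged))) {
    frags <- subtract_intervals(merged$chrom[i], merged$start[i],
                                merged$end[i], acc_flat)
    if (nrow(frags) == 0) next
    len <- frags$end - frags$start
    best <- frags[order(-len, frags$start)[1], , drop = FALSE]
    row <- data.frame(chrom = best$chrom, start = best$start, end = best$end,
                      family = merged$family[i], te_class = merged$te_class[i],
                      stringsAsFactors = FALSE)
    accepted <- rbind(accepted, row)
    acc_flat <- flatten_intervals(rbind(acc_flat,
                                        row[, c("chrom", "start", "end")]))
  }
  accepted <- accepted[accepted$end - accepted$start >= min_length, ,
                       drop = FALSE]
  accepted <- accepted[order(accepted$chrom, accepted$start), , drop = FALSE]
  rownames(accepted) <- NULL
  accepted
}

#' Flag binding peaks as TE-derived
#'
#' Two selectable rules:
#' \describe{
#'   \item{`half_overlap`}{(default) a peak is TE-derived when at least half
#'     of the binding region overlaps a single TE insertion (non-strict
#'     `>=`).}
#'   \item{`center_in_te`}{a peak is TE-derived when its summit (midpoint if
#'     no summit) falls within a TE insertion.}
#' }
#' The assigned family is that of the qualifying insertion with the largest
#' overlap (first by position on ties).
#'
#' @param peaks peak table.
#' @param insertions cleaned TE insertions (see [clean_te_annotation()]).
#' @param rule `"half_overlap"` or `"center_in_te"`.
#' @return data.frame per peak: `te_derived` logical, `family` (`NA` when
#'   not TE-derived).
#' @export
te_derived_flag <- function(peaks, insertions,
                            rule = c("half_overlap", "center_in_te")) {
  rule <- match.arg(rule)
  n <- nrow(peaks)
  derived <- logical(n); family <- rep(NA_character_, n)
  if (nrow(insertions) > 0) for (i in seq_len(n)) {
    cand <- insertions[insertions$chrom == peaks$chrom[i] &
                         insertions$end > peaks$start[i] &
                         insertions$start < peaks$end[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    if (rule == "half_overlap") {
      ov <- pmax(0, pmin(cand$end, peaks$end[i]) - pmax(cand$start, peaks$start[i]))
      ok <- ov >= (peaks$end[i] - peaks$start[i]) / 2
      if (any(ok)) {
        derived[i] <- TRUE
        family[i] <- cand$family[ok][order(-ov[ok])[1]]
      }
    } else {
      ctr <- if (!is.null(peaks$summit)) peaks$summit[i] else
        floor((peaks$start[i] + peaks$end[i]) / 2)
      ok <- cand$start <= ctr & ctr < cand$end
      if (any(ok)) {
        derived[i] <- TRUE
        family[i] <- cand$family[which(ok)[1]]
      }
    }
  }
  data.frame(te_derived = derived, family = family, stringsAsFactors = FALSE)
}

#' Log2 odds-ratio enrichment of a TE family in binding sites
#'
#' \deqn{LOR = \log_2\frac{n_{family}/L_{family}}{N_{genome}/G}}
#' comparing the density of binding sites derived from one TE family against
#' the genome-wide binding-site density. A family is enriched at
#' `LOR >= threshold` (default 1.5, roughly a 3-fold density excess).
#'
#' @param n_sites_in_family number of (non-DC) sites derived from the family.
#' @param family_length_bp total annotated bp of the family in the genome.
#' @param n_sites_genome total number of (non-DC) sites in the genome.
#' @param genome_size_bp genome size in bp.
#' @param threshold enrichment threshold on the LOR (default 1.5).
#' @return one-row data.frame: `n_sites`, `family_length`, `lor`, `enriched`.
#' @examples
#' lor_enrichment(8, 1e4, 1000, 1e7)  # lor = 3, enriched
#' @export
lor_enrichment <- function(n_sites_in_family, family_length_bp,
                           n_sites_genome, genome_size_bp, threshold = 1.5) {
  stopifnot(genome_size_bp > 0, n_sites_genome > 0)
  lor <- if (family_length_bp == 0) NA_real_
  else if (n_sites_in_family == 0) -Inf
  else log2((n_sites_in_family / family_length_bp) /
              (n_sites_genome / genome_size_bp))
  data.frame(n_sites = n_sites_in_family, family_length = family_length_bp,
             lor = lor, enriched = !is.na(lor) & lor >= threshold)
}

#' Per-family TE enrichment table
#'
#' Applies [te_derived_flag()] and [lor_enrichment()] over all annotated
#' families. Family lengths are computed from the cleaned annotation, never
#' hard-coded.
#'
#' @param peaks (non-DC) peak table.
#' @param insertions cleaned TE insertions.
#' @param genome_size_bp genome size in bp.
#' @param rule TE-derived rule, see [te_derived_flag()].
#' @param threshold LOR enrichment threshold (default 1.5).
#' @return data.frame per family: `family`, `te_class`, `n_sites`,
#'   `family_length`, `lor`, `enriched`, plus attributes `rule` and
#'   `n_sites_genome`.
#' @export
te_family_enrichment <- function(peaks, insertions, genome_size_bp,
                                 rule = c("half_overlap", "center_in_te"),
                                 threshold = 1.5) {
  rule <- match.arg(rule)
  flags <- te_derived_flag(peaks, insertions, rule)
  fams <- unique(insertions[, c("family", "te_class")])
  n_genome <- nrow(peaks)
  out <- do.call(rbind, lapply(seq_len(nrow(fams)), function(i) {
    f <- fams$family[i]
    L <- sum(with(insertions, end - start)[insertions$family == f])
    e <- lor_enrichment(sum(flags$te_derived & flags$family == f, na.rm = TRUE),
                        L, n_genome, genome_size_bp, threshold)
    cbind(data.frame(family = f, te_class = fams$te_class[i],
                     stringsAsFactors = FALSE), e)
  }))
  out <- out[order(-out$lor), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rule") <- rule
  attr(out, "n_sites_genome") <- n_genome
  out
}

#' Count motif occurrences in a consensus sequence
#'
#' Counts exact, possibly overlapping occurrences of each motif on the
#' forward strand plus its reverse complement, deduplicated per start
#' position. This is a simplified occurrence count (no position-weight-matrix
#' p-value model).
#'
#' @param consensus_sequence character DNA string over `A,C,G,T,N`.
#' @param motifs character vector of motifs (default the three MSL-associated
#'   motifs GAGA, CACA, GCA).
#' @return named integer vector of counts per motif.
#' @examples
#' motif_count("GAGAGA", "GAGA")  # 2 (positions 1 and 3 overlap)
#' @export
motif_count <- function(consensus_sequence, motifs = c("GAGA", "CACA", "GCA")) {
  seq <- toupper(consensus_sequence)
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  find_pos <- function(pat) {
    if (!nzchar(seq) || nchar(seq) < nchar(pat)) return(integer(0))
    m <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  vapply(motifs, function(mo) {
    length(union(find_pos(mo), find_pos(revcomp(mo))))
  }, integer(1))
}

#' Read a RepeatMasker-style repeat annotation subset
#'
#' Dialect: headered TSV with columns `chrom start end family te_class`
#' (0-based half-open coordinates).
#'
#' @param path file path.
#' @return raw hit table for [clean_te_annotation()].
#' @export
read_repeat_annotation <- function(path) {
  x <- read_dialect_tsv(path, c("chrom", "start", "end", "family", "te_class"),
                        "repeat annotation")
  x$chrom <- as.character(x$chrom)
  x$family <- as.character(x$family)
  x$te_class <- as.character(x$te_class)
  x
}
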