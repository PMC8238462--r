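#' Classify MOF/MSL1 binding sites as DC or non-DC
#'
#' A MOF or MSL1 binding site is a dosage-compensation (DC) site when it
#' overlaps an MSL2-bound region under the reciprocal-half rule (the common
#' region is larger than half of the region covered by each site); otherwise
#' it is a non-DC site. Both input sets are expected to be pre-merged with
#' [merge_peaks()]. Many-to-one overlaps count once: DC status is boolean.
#'
#' @param target_peaks merged peak table, protein MOF or MSL1.
#' @param msl2_peaks merged peak table, protein MSL2.
#' @param chrom_classes list with entries `X` and `autosome` naming the
#'   chromosomes of each class; anything else (e.g. the 4th chromosome,
#'   unplaced scaffolds) is classed `"other"` and excluded from autosomes.
#' @return data.frame per target peak: `dc_status` (`"DC"`/`"nonDC"`),
#'   `chromosome_class` (`"X"`/`"autosome"`/`"other"`).
#' @export
classify_dc <- function(target_peaks, msl2_peaks,
                        chrom_classes = drosophila_chrom_classes()) {
  tp <- stats::na.omit(unique(target_peaks$protein))
  mp <- stats::na.omit(unique(msl2_peaks$protein))
  if (length(tp) && !all(tp %in% c("MOF", "MSL1")))
    stop("classify_dc: target peaks must be MOF or MSL1, got ",
         paste(tp, collapse = ","))
  if (length(mp) && !all(mp == "MSL2"))
    stop("classify_dc: msl2_peaks must be MSL2, got ", paste(mp, collapse = ","))
  n <- nrow(target_peaks)
  dc <- logical(n)
  if (nrow(msl2_peaks) > 0) {
    for (i in seq_len(n)) {
      cand <- msl2_peaks[msl2_peaks$chrom == target_peaks$chrom[i], , drop = FALSE]
      if (nrow(cand) == 0) next
      dc[i] <- any(satisfies(target_peaks[i, , drop = FALSE], cand,
                             "reciprocal_half"))
    }
  }
  data.frame(dc_status = ifelse(dc, "DC", "nonDC"),
             chromosome_class = class_chromosome(target_peaks$chrom, chrom_classes),
             stringsAsFactors = FALSE)
}

#' Default chromosome classing for Drosophila
#'
#' X vs the major autosome arms; the 4th chromosome and unplaced scaffolds
#' fall into `"other"` and are excluded from the autosome class.
#'
#' @return list with `X` and `autosome` name vectors.
#' @export
drosophila_chrom_classes <- function() {
  list(X = c("X", "chrX"),
       autosome = c("2L", "2R", "3L", "3R", "chr2L", "chr2R", "chr3L", "chr3R"))
}

# Map chromosome names onto {X, autosome, other}. Internal.
class_chromosome <- function(chrom, chrom_classes = drosophila_chrom_classes()) {
  out <- rep("other", length(chrom))
  out[chrom %in% chrom_classes$X] <- "X"
  out[chrom %in% chrom_classes$autosome] <- "autosome"
  unknown <- !(chrom %in% unlist(chrom_classes)) & !(chrom %in% c("4", "chr4"))
  if (any(unknown))
    warning("unknown chromosome name(s) classed 'other': ",
            paste(unique(chrom[unknown]), collapse = ", "))
  out
}

#' Tri-set membership counts of MOF/MSL1/MSL2 binding regions
#'
#' Each protein's peaks are merged within protein; merged regions from the
#' three proteins are then linked whenever a pair satisfies the
#' reciprocal-half rule, and each connected component of this overlap graph is
#' one region, classed by the set of proteins it contains. Counts are of such
#' regions, partitioned over the seven membership classes.
#'
#' @param mof,msl1,msl2 merged peak tables (see [merge_peaks()]).
#' @return named integer vector over
#'   `MOF_only, MSL1_only, MSL2_only, MOF_MSL1, MOF_MSL2, MSL1_MSL2,
#'   MOF_MSL1_MSL2`.
#' @export
overlap_partition <- function(mof, msl1, msl2) {
  sets <- list(MOF = mof, MSL1 = msl1, MSL2 = msl2)
  pool <- do.call(rbind, lapply(names(sets), function(p) {
    x <- sets[[p]]
    if (nrow(x) == 0) return(NULL)
    data.frame(chrom = x$chrom, start = x$start, end = x$end, protein = p,
               stringsAsFactors = FALSE)
  }))
  counts <- stats::setNames(integer(7),
                            c("MOF_only", "MSL1_only", "MSL2_only", "MOF_MSL1",
                              "MOF_MSL2", "MSL1_MSL2", "MOF_MSL1_MSL2"))
  if (is.null(pool) || nrow(pool) == 0) return(counts)
  n <- nrow(pool)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  ord <- order(pool$chrom, pool$start)
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (pool$chrom[j] != pool$chrom[i] || pool$start[j] >= pool$end[i]) break
      if (satisfies(pool[i, , drop = FALSE], pool[j, , drop = FALSE],
                    "reciprocal_half"))
        unite(i, j)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  for (cid in unique(comp)) {
    prot <- sort(unique(pool$protein[comp == cid]))
    key <- if (length(prot) == 1) paste0(prot, "_only") else paste(prot, collapse = "_")
    key <- switch(key,
                  MOF_only = "MOF_only", MSL1_only = "MSL1_only",
                  MSL2_only = "MSL2_only", MOF_MSL1 = "MOF_MSL1",
                  MOF_MSL2 = "MOF_MSL2", MSL1_MSL2 = "MSL1_MSL2",
                  MOF_MSL1_MSL2 = "MOF_MSL1_MSL2")
    counts[key] <- counts[key] + 1L
  }
  counts
}

#' Chromosome distribution of binding sites
#'
#' Fraction of each protein's sites on the X, the major autosomes and other
#' chromosomes. Fractions sum to 1 per protein; empty inputs give `NA`.
#'
#' @param peaks peak table with a `protein` column.
#' @param chrom_classes see [classify_dc()].
#' @return data.frame per protein with columns `frac_X`, `frac_autosome`,
#'   `frac_other`, `n`.
#' @export
chromosome_distribution <- function(peaks,
                                    chrom_classes = drosophila_chrom_classes()) {
  if (nrow(peaks) == 0)
    return(data.frame(protein = character(0), frac_X = numeric(0),
                      frac_autosome = numeric(0), frac_other = numeric(0),
                      n = integer(0)))
  cls <- class_chromosome(peaks$chrom, chrom_classes)
  prot <- if (!is.null(peaks$protein)) peaks$protein else rep("all", nrow(peaks))
  res <- lapply(unique(prot), function(p) {
    sel <- cls[prot == p]
    n <- length(sel)
    data.frame(protein = p,
               frac_X = if (n) mean(sel == "X") else NA_real_,
               frac_autosome = if (n) mean(sel == "autosome") else NA_real_,
               frac_other = if (n) mean(sel == "other") else NA_real_,
               n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
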