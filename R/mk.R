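#' Site-class divergence/polymorphism counts
#'
#' Bundle of counts feeding the extended McDonald-Kreitman test for one class
#' of sites: total class length `L` in bp, divergent site count `D`
#' (fixed in the ingroup and different from the outgroup), polymorphic site
#' count `P` (including singletons) and `P_nosingleton` (minor-allele-count-1
#' variants excluded).
#'
#' @param label class label (e.g. `"MOF nonDC autosome"`).
#' @param L class length in bp (> 0).
#' @param D divergent site count.
#' @param P polymorphic site count including singletons.
#' @param P_nosingleton polymorphic count excluding singletons.
#' @return a one-row data.frame of class `site_class_counts`.
#' @export
site_class_counts <- function(label, L, D, P, P_nosingleton) {
  stopifnot(L > 0, D >= 0, P >= 0, P_nosingleton >= 0, P_nosingleton <= P)
  # doubles: count products in the alpha estimator exceed integer range
  x <- data.frame(label = label, L = as.numeric(L), D = as.numeric(D),
                  P = as.numeric(P),
                  P_nosingleton = as.numeric(P_nosingleton),
                  stringsAsFactors = FALSE)
  class(x) <- c("site_class_counts", "data.frame")
  x
}

#' Divergence-to-polymorphism ratio
#'
#' `D / P_nosingleton`. Returns `Inf` when `D > 0` and the denominator is 0,
#' and `NA` when both are 0.
#'
#' @param counts a [site_class_counts()] (or any data.frame with `D` and
#'   `P_nosingleton`).
#' @return numeric vector of ratios.
#' @export
dp_ratio <- function(counts) {
  r <- counts$D / counts$P_nosingleton
  r[counts$P_nosingleton == 0 & counts$D > 0] <- Inf
  r[counts$P_nosingleton == 0 & counts$D == 0] <- NA_real_
  r
}

#' Fraction of adaptive fixations (alpha)
#'
#' The extended-MK estimator
#' \deqn{\alpha = 1 - \frac{D_{neutral}\,P_{selected}}{D_{selected}\,P_{neutral}}}
#' with `P = P_nosingleton` on both sides (singleton-excluded polymorphism).
#' Alpha is at most 1; negative values indicate an excess of segregating
#' (typically weakly deleterious) variation relative to divergence. Requires
#' all four counts positive, else `NA`.
#'
#' @param selected [site_class_counts()] for the selected class (the binding
#'   sites).
#' @param neutral [site_class_counts()] for the neutral control (four-fold
#'   degenerate sites).
#' @param use_singletons include singleton polymorphisms (use `P` instead of
#'   `P_nosingleton`); default `FALSE`.
#' @return scalar alpha estimate.
#' @examples
#' sel <- site_class_counts("nonDC A", 2251825, 23903, 1520, 1285)
#' neut <- site_class_counts("4-fold A", 2835156, 458286, 303736, 243823)
#' mk_alpha(sel, neut)  # 0.899
#' @export
mk_alpha <- function(selected, neutral, use_singletons = FALSE) {
  p_sel <- as.numeric(if (use_singletons) selected$P else selected$P_nosingleton)
  p_neut <- as.numeric(if (use_singletons) neutral$P else neutral$P_nosingleton)
  d_sel <- as.numeric(selected$D); d_neut <- as.numeric(neutral$D)
  if (any(c(d_sel, p_sel, d_neut, p_neut) == 0)) return(NA_real_)
  1 - (d_neut * p_sel) / (d_sel * p_neut)
}

#' Fisher's exact test on an MK contingency table
#'
#' Two-sided Fisher's exact test on
#' `[[D_selected, P_selected], [D_neutral, P_neutral]]` with
#' singleton-excluded polymorphism counts.
#'
#' @inheritParams mk_alpha
#' @return two-sided p-value (`NA` for an all-zero table).
#' @export
mk_fisher <- function(selected, neutral, use_singletons = FALSE) {
  p_sel <- if (use_singletons) selected$P else selected$P_nosingleton
  p_neut <- if (use_singletons) neutral$P else neutral$P_nosingleton
  m <- matrix(c(selected$D, p_sel, neutral$D, p_neut), nrow = 2, byrow = TRUE)
  if (all(m == 0)) return(NA_real_)
  stats::fisher.test(m)$p.value
}

#' Extended McDonald-Kreitman test of a selected against a neutral site class
#'
#' Fits the extended-MK comparison of one selected site class (binding sites)
#' against a neutral control (four-fold degenerate sites): D/P ratios of both
#' classes, the fraction of adaptive fixations alpha, and a two-sided
#' Fisher's exact test of the 2x2 divergence/polymorphism table.
#'
#' @inheritParams mk_alpha
#' @return an object of class `mk_test` with components `selected`,
#'   `neutral`, `dp_selected`, `dp_neutral`, `alpha`, `p.value`, `table`.
#' @examples
#' sel <- site_class_counts("MSL2 DC X", 177823, 17469, 9191, 7329)
#' neut <- site_class_counts("4-fold X", 620151, 97105, 70970, 55348)
#' mk_test(sel, neut)
#' @export
mk_test <- function(selected, neutral, use_singletons = FALSE) {
  p_sel <- if (use_singletons) selected$P else selected$P_nosingleton
  p_neut <- if (use_singletons) neutral$P else neutral$P_nosingleton
  tab <- matrix(c(selected$D, p_sel, neutral$D, p_neut), nrow = 2, byrow = TRUE,
                dimnames = list(c(selected$label, neutral$label),
                                c("D", "P")))
  out <- list(selected = selected, neutral = neutral,
              dp_selected = dp_ratio(selected), dp_neutral = dp_ratio(neutral),
              alpha = mk_alpha(selected, neutral, use_singletons),
              p.value = mk_fisher(selected, neutral, use_singletons),
              table = tab)
  class(out) <- "mk_test"
  out
}

#' @export
print.mk_test <- function(x, digits = 3, ...) {
  cat("Extended McDonald-Kreitman test\n")
  cat("  selected:", x$selected$label, " D/P =", format(round(x$dp_selected, digits)), "\n")
  cat("  neutral: ", x$neutral$label, " D/P =", format(round(x$dp_neutral, digits)), "\n")
  cat("  alpha (fraction of adaptive fixations):",
      format(round(x$alpha, digits)), "\n")
  cat("  Fisher's exact (two-sided) p:", format.pval(x$p.value, digits), "\n")
  invisible(x)
}

#' @method summary mk_test
#' @export
summary.mk_test <- function(object, ...) {
  cat("2x2 divergence/polymorphism table (singleton-excluded P):\n")
  print(object$table)
  cat("\n")
  print(object)
  invisible(object)
}

#' @method coef mk_test
#' @export
coef.mk_test <- function(object, ...) {
  c(alpha = object$alpha, dp_selected = object$dp_selected,
    dp_neutral = object$dp_neutral, p.value = object$p.value)
}

#' Classify variant sites from ingroup allele counts and an outgroup allele
#'
#' Per-site classification used for MK tabulation:
#' \itemize{
#'   \item missing outgroup allele: `unusable`;
#'   \item one ingroup allele, different from the outgroup: `divergent`;
#'   \item one ingroup allele, equal to the outgroup: `monomorphic_identical`;
#'   \item two ingroup alleles with minor-allele count exactly 1:
#'     `polymorphic_singleton`;
#'   \item two or more ingroup alleles otherwise: `polymorphic` (more than two
#'     alleles are counted once and flagged with a warning).
#' }
#' Divergence therefore requires fixation in the ingroup, keeping D and P
#' disjoint.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based) and allele
#'   counts `A`, `C`, `G`, `T` over the sampled chromosomes, plus `outgroup`
#'   (base or `NA`/`"N"`/`"."` when missing).
#' @return character vector of classes, one per site.
#' @examples
#' classify_variant(data.frame(chrom = "2L", pos = 1, A = 196, C = 1, G = 0,
#'                             T = 0, outgroup = "A"))  # polymorphic_singleton
#' @export
classify_variant <- function(sites) {
  cnt <- as.matrix(sites[, c("A", "C", "G", "T"), drop = FALSE])
  if (any(rowSums(cnt) <= 0)) stop("variant site with no ingroup alleles")
  n_alleles <- rowSums(cnt > 0)
  if (any(n_alleles > 2))
    warning(sum(n_alleles > 2), " site(s) with >2 ingroup alleles counted once as polymorphic")
  outg <- toupper(as.character(sites$outgroup))
  outg[!outg %in% c("A", "C", "G", "T")] <- NA
  major <- c("A", "C", "G", "T")[max.col(cnt, ties.method = "first")]
  minor_count <- apply(cnt, 1, function(r) {
    nz <- r[r > 0]
    if (length(nz) < 2) 0 else min(nz)
  })
  out <- rep("polymorphic", nrow(sites))
  out[which(n_alleles == 2 & minor_count == 1)] <- "polymorphic_singleton"
  out[which(n_alleles == 1 & major == outg)] <- "monomorphic_identical"
  out[which(n_alleles == 1 & major != outg)] <- "divergent"
  out[which(is.na(outg))] <- "unusable"
  out
}

#' Tabulate variant sites into site-class counts
#'
#' Assigns each usable site to the class(es) whose intervals contain its
#' position and accumulates `L` (total class bp), `D`, `P`
#' (polymorphic + singleton) and `P_nosingleton` per class. Intervals within
#' one class must be disjoint.
#'
#' @param sites variant table (see [classify_variant()]).
#' @param class_intervals named list of interval tables, one per class label.
#' @return a `site_class_counts` data.frame, one row per label.
#' @export
tabulate_site_classes <- function(sites, class_intervals) {
  cls <- classify_variant(sites)
  out <- lapply(names(class_intervals), function(label) {
    iv <- class_intervals[[label]]
    validate_intervals(iv, label)
    flat <- flatten_intervals(iv)
    if (sum(flat$end - flat$start) != sum(iv$end - iv$start))
      stop("tabulate_site_classes: overlapping intervals within class ", label)
    inside <- logical(nrow(sites))
    for (k in seq_len(nrow(flat))) {
      inside <- inside | (sites$chrom == flat$chrom[k] &
                            sites$pos >= flat$start[k] & sites$pos < flat$end[k])
    }
    site_class_counts(label,
                      L = sum(flat$end - flat$start),
                      D = sum(inside & cls == "divergent"),
                      P = sum(inside & cls %in% c("polymorphic", "polymorphic_singleton")),
                      P_nosingleton = sum(inside & cls == "polymorphic"))
  })
  res <- do.call(rbind, out)
  class(res) <- c("site_class_counts", "data.frame")
  res
}

#' Read a variant-count TSV
#'
#' Dialect: headered TSV with columns
#' `chrom pos A C G T outgroup` (0-based positions, per-base ingroup allele
#' counts over the sampled chromosomes, outgroup base or `N` when missing).
#'
#' @param path file path.
#' @return variant table suitable for [classify_variant()].
#' @export
read_variant_table <- function(path) {
  x <- read_dialect_tsv(path, c("chrom", "pos", "A", "C", "G", "T", "outgroup"),
                        "variant table")
  x$chrom <- as.character(x$chrom)
  x$outgroup <- as.character(x$outgroup)
  x
}

#' Four-fold degenerate third-codon positions
#'
#' Genomic positions (0-based) of third codon positions whose codon's amino
#' acid is invariant to any third-base substitution under the standard code
#' (codons whose first two bases are one of CT, GT, TC, CC, AC, GC, CG, GG).
#' Strand-aware; genes whose concatenated CDS length is not a multiple of 3
#' are skipped with a warning and codons containing ambiguity codes are
#' skipped.
#'
#' @param gene_models data.frame of CDS segments: `gene`, `chrom`, `start`,
#'   `end`, `strand` (segments of one gene on one chromosome/strand).
#' @param genome a [Biostrings::DNAStringSet] named by chromosome.
#' @return interval-style data.frame of single positions: `chrom`, `pos`
#'   (0-based), `gene`.
#' @export
fourfold_sites <- function(gene_models, genome) {
  fourfold_prefix <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
  out <- list()
  for (g in unique(gene_models$gene)) {
    seg <- gene_models[gene_models$gene == g, , drop = FALSE]
    strand <- seg$strand[1]
    chrom <- seg$chrom[1]
    seg <- seg[order(seg$start), , drop = FALSE]
    # genomic coordinates of CDS bases in translation order
    coords <- unlist(lapply(seq_len(nrow(seg)), function(i)
      seq(seg$start[i], seg$end[i] - 1)))
    if (strand == "-") coords <- rev(coords)
    if (length(coords) %% 3 != 0) {
      warning("gene ", g, ": CDS length not a multiple of 3, skipped")
      next
    }
    chrom_seq <- as.character(genome[[chrom]])
    bases <- substring(chrom_seq, coords + 1, coords + 1)
    if (strand == "-")
      bases <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[bases]
    ncod <- length(coords) / 3
    first2 <- paste0(bases[3 * seq_len(ncod) - 2], bases[3 * seq_len(ncod) - 1])
    third <- bases[3 * seq_len(ncod)]
    ok <- first2 %in% fourfold_prefix & third %in% c("A", "C", "G", "T") &
      !grepl("[^ACGT]", first2)
    if (any(ok))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, pos = coords[3 * which(ok)], gene = g,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), pos = numeric(0),
                      gene = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$pos), , drop = FALSE]
}

#' Per-gene MK tests with Benjamini-Hochberg correction
#'
#' For each gene, a two-sided Fisher's exact test on
#' `[[Dn, Pn], [Ds, Ps]]` (non-synonymous/synonymous divergence vs
#' polymorphism), followed by Benjamini-Hochberg correction over all genes.
#' A gene shows an excess of non-synonymous divergence when `Dn/Ds` exceeds
#' `Pn/Ps` (cross-product comparison, robust to zero denominators) and its
#' q-value is below `q_threshold`.
#'
#' @param records data.frame with columns `gene`, `Dn`, `Ds`, `Pn`, `Ps`.
#' @param q_threshold significance threshold on the BH q-value (default 0.05).
#' @return `records` with added `fisher_p`, `bh_q` and `excess` columns;
#'   all-zero genes get `NA`.
#' @export
gene_mk <- function(records, q_threshold = 0.05) {
  p <- vapply(seq_len(nrow(records)), function(i) {
    m <- matrix(c(records$Dn[i], records$Pn[i],
                  records$Ds[i], records$Ps[i]), nrow = 2, byrow = TRUE)
    if (all(m == 0)) return(NA_real_)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  excess <- records$Dn * records$Ps > records$Pn * records$Ds
  excess[is.na(q)] <- NA
  out <- records
  out$fisher_p <- p
  out$bh_q <- q
  out$excess <- excess & !is.na(q) & q < q_threshold
  out$excess[is.na(q)] <- NA
  out
}

#' Published MSL site-class MK count table
#'
#' The published per-class (length, D, P, P excluding singletons) counts for
#' MOF, MSL1 and MSL2 DC/non-DC binding sites and their four-fold degenerate
#' neutral controls in *D. melanogaster* and *D. simulans*, as shipped with
#' the package. These counts are the worked input for [mk_test()].
#'
#' @return data.frame with columns `species`, `protein`, `chrom_class`,
#'   `site_type`, `L`, `D`, `P`, `P_nosingleton`, `dp_printed`,
#'   `alpha_printed` (printed reference values, `NA` for neutral rows).
#' @export
msl_mk_counts <- function() {
  path <- system.file("extdata", "msl_mk_site_counts.tsv", package = "mslevo",
                      mustWork = TRUE)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  for (col in c("L", "D", "P", "P_nosingleton")) x[[col]] <- as.numeric(x[[col]])
  x
}
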