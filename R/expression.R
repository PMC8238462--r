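#' Average TPM across biological replicates
#'
#' @param records data.frame with columns `gene`, `species`, `sex`,
#'   `replicate`, `tpm` (one row per gene x species x sex x replicate).
#' @return data.frame of mean TPM per gene x species x sex.
#' @export
average_tpm <- function(records) {
  stopifnot(all(c("gene", "species", "sex", "tpm") %in% names(records)))
  if (any(records$tpm < 0)) stop("negative TPM")
  stats::aggregate(list(tpm = records$tpm),
                   by = list(gene = records$gene, species = records$species,
                             sex = records$sex),
                   FUN = mean)
}

#' Z-normalize an expression vector within species
#'
#' `(x - mean) / sd` over the within-species gene vector, with the sample
#' (n-1) standard deviation. Per-gene expression change between species is
#' the difference of these z-scores.
#'
#' @param x numeric vector of per-gene expression (one species).
#' @return z-score vector (mean 0, sd 1).
#' @export
normalize_z <- function(x) {
  if (length(x) < 2) stop("normalize_z: need at least 2 genes")
  s <- stats::sd(x)
  if (s == 0) stop("normalize_z: zero standard deviation")
  (x - mean(x)) / s
}

#' Group genes by binding-site and TE status
#'
#' A gene is `unconservedBSplus` when any unconserved non-DC binding site
#' overlaps its window (2 kb upstream of the transcription start plus the
#' gene body, strand-aware; any overlap of at least 1 bp counts), else
#' `conservedBSplus` when any conserved non-DC site overlaps the window, else
#' `BSminus`. Independently, `TEplus` when any cleaned TE insertion overlaps
#' the window.
#'
#' @param genes data.frame: `gene`, `chrom`, `start`, `end`, `strand`.
#' @param nondc_peaks non-DC peak table with a `conservation` column
#'   (`"conserved"`/`"unconserved"`).
#' @param te_insertions cleaned TE insertions (optional).
#' @param upstream upstream window in bp (default 2000).
#' @return data.frame per gene: `gene`, `bs_status`, `te_status`.
#' @export
group_genes <- function(genes, nondc_peaks, te_insertions = NULL,
                        upstream = 2000) {
  if (any(!genes$strand %in% c("+", "-")))
    stop("group_genes: every gene needs strand '+' or '-'")
  win <- data.frame(chrom = genes$chrom,
                    start = ifelse(genes$strand == "+",
                                   pmax(0, genes$start - upstream), genes$start),
                    end = ifelse(genes$strand == "+",
                                 genes$end, genes$end + upstream),
                    stringsAsFactors = FALSE)
  any_overlap <- function(iv, set) {
    if (is.null(set) || nrow(set) == 0) return(rep(FALSE, nrow(iv)))
    vapply(seq_len(nrow(iv)), function(i)
      any(set$chrom == iv$chrom[i] & set$end > iv$start[i] &
            set$start < iv$end[i]), logical(1))
  }
  unc <- nondc_peaks[nondc_peaks$conservation == "unconserved", , drop = FALSE]
  con <- nondc_peaks[nondc_peaks$conservation == "conserved", , drop = FALSE]
  has_unc <- any_overlap(win, unc)
  has_con <- any_overlap(win, con)
  bs <- ifelse(has_unc, "unconservedBSplus",
               ifelse(has_con, "conservedBSplus", "BSminus"))
  te <- ifelse(any_overlap(win, te_insertions), "TEplus", "TEminus")
  data.frame(gene = genes$gene, bs_status = bs, te_status = te,
             stringsAsFactors = FALSE)
}

#' Expression divergence of a gene group between species
#'
#' Divergence is `1 - rho`, one minus Spearman's rank correlation between the
#' two species' mean-TPM vectors over the genes of the group (ties get
#' average ranks). The sampling distribution is estimated by resampling genes
#' with replacement `n_boot` times.
#'
#' @param tpm_a,tpm_b mean TPM vectors over the same genes in species A and B.
#' @param n_boot number of bootstrap draws (default 1000).
#' @param seed optional integer seed fixing the bootstrap.
#' @return object of class `divergence_estimate`: `point`, `rho`,
#'   `bootstrap` (vector of draws), `n_genes`. Groups of fewer than 3 genes
#'   give an `NA` point estimate and no bootstrap.
#' @examples
#' d <- expression_divergence(1:10, c(2:10, 1) + 0.5, n_boot = 100, seed = 1)
#' d$point
#' @export
expression_divergence <- function(tpm_a, tpm_b, n_boot = 1000, seed = NULL) {
  stopifnot(length(tpm_a) == length(tpm_b))
  n <- length(tpm_a)
  if (n < 3) {
    out <- list(point = NA_real_, rho = NA_real_, bootstrap = numeric(0),
                n_genes = n)
    class(out) <- "divergence_estimate"
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  rho <- stats::cor(tpm_a, tpm_b, method = "spearman")
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    1 - stats::cor(tpm_a[idx], tpm_b[idx], method = "spearman")
  }, numeric(1))
  out <- list(point = 1 - rho, rho = rho, bootstrap = boot, n_genes = n)
  class(out) <- "divergence_estimate"
  out
}

#' @export
print.divergence_estimate <- function(x, digits = 3, ...) {
  cat("Expression divergence (1 - Spearman rho)\n")
  cat("  genes:", x$n_genes, "\n")
  cat("  point estimate:", format(round(x$point, digits)), "\n")
  if (length(x$bootstrap))
    cat("  bootstrap (n = ", length(x$bootstrap), "): mean ",
        format(round(mean(x$bootstrap), digits)), ", 95% CI [",
        format(round(stats::quantile(x$bootstrap, 0.025), digits)), ", ",
        format(round(stats::quantile(x$bootstrap, 0.975), digits)), "]\n",
        sep = "")
  invisible(x)
}

#' Compare two divergence estimates
#'
#' Two-sided Mann-Whitney U test between the bootstrap distributions of two
#' gene groups. Bootstrap draws are resamples, not independent observations,
#' so the p-value describes the separation of the two bootstrap
#' distributions rather than a formal test of the group difference.
#'
#' @param d1,d2 `divergence_estimate` objects.
#' @return `htest` object from [stats::wilcox.test()].
#' @export
compare_divergence <- function(d1, d2) {
  stopifnot(inherits(d1, "divergence_estimate"),
            inherits(d2, "divergence_estimate"))
  stats::wilcox.test(d1$bootstrap, d2$bootstrap, alternative = "two.sided",
                     exact = FALSE)
}

#' Read a replicate expression TSV
#'
#' Dialect: headered TSV with columns `gene species sex replicate tpm`.
#'
#' @param path file path.
#' @return expression record table for [average_tpm()].
#' @export
read_expression_table <- function(path) {
  x <- read_dialect_tsv(path, c("gene", "species", "sex", "replicate", "tpm"),
                        "expression table")
  x$gene <- as.character(x$gene)
  x$species <- as.character(x$species)
  x$sex <- as.character(x$sex)
  x
}
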