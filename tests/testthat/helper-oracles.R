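# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's interval arithmetic: overlaps are computed by per-base
# set membership on small toy chromosomes.

oracle_positions <- function(iv) {
  if (iv$end <= iv$start) return(integer(0))
  paste(iv$chrom, seq(iv$start, iv$end - 1), sep = ":")
}

oracle_overlap_length <- function(a, b) {
  length(intersect(oracle_positions(a), oracle_positions(b)))
}

oracle_satisfies <- function(a, b, rule, center_of_b = NULL) {
  ov <- oracle_overlap_length(a, b)
  la <- a$end - a$start
  lb <- b$end - b$start
  switch(rule,
         reciprocal_half = ov > la / 2 && ov > lb / 2,
         either_half = ov > la / 2 || ov > lb / 2,
         one_sided_half = ov >= la / 2,
         center_within = a$chrom == b$chrom &&
           center_of_b %in% seq(a$start, a$end - 1))
}

random_interval <- function(chrom_len = 10000, max_len = 200, chroms = "toy") {
  len <- sample.int(max_len, 1)
  start <- sample.int(chrom_len - len, 1) - 1
  data.frame(chrom = sample(chroms, 1), start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# Two-sided Fisher's exact p for a 2x2 table by exhaustive hypergeometric
# enumeration (probabilities computed from choose(), independent of
# stats::fisher.test / stats::dhyper).
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  total <- choose(m + n, k)
  prob <- function(x) choose(m, x) * choose(n, k - x) / total
  xs <- max(0, k - n):min(k, m)
  p_obs <- prob(a)
  sum(vapply(xs, prob, numeric(1))[vapply(xs, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}

# Four-fold degeneracy by direct codon-table lookup: a third position is
# four-fold iff all four third-base substitutions translate identically.
oracle_fourfold_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  subs <- paste0(substr(codon, 1, 2), c("A", "C", "G", "T"))
  length(unique(gc[subs])) == 1
}

# Closed-form Spearman rho for tie-free vectors.
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}
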