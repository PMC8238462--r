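#' Construct a cis-regulatory element table
#'
#' @param chrom,start,end element coordinates (0-based half-open).
#' @param category one of `promoter`, `enhancer`, `insulator` per element.
#' @param center center/summit position; defaults to the interval midpoint.
#' @return validated element table.
#' @export
cis_elements <- function(chrom, start, end, category, center = NULL) {
  x <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), category = as.character(category),
                  stringsAsFactors = FALSE)
  validate_intervals(x, "cis elements")
  bad <- setdiff(unique(x$category), c("promoter", "enhancer", "insulator"))
  if (length(bad)) stop("unknown cis-element category: ", paste(bad, collapse = ", "))
  x$center <- if (is.null(center)) floor((x$start + x$end) / 2) else as.numeric(center)
  if (any(x$center < x$start | x$center >= x$end))
    stop("cis elements: center outside interval")
  x
}

#' Assign cis-regulatory elements to binding sites
#'
#' Two selectable overlap rules:
#' \describe{
#'   \item{`center_within`}{(default) an element hits a peak when its
#'     center/summit lies within the peak interval (half-open).}
#'   \item{`half_overlap`}{an element hits a peak when the common region
#'     accounts for at least half of the length of the binding site or of the
#'     element (either-half rule, non-strict `>=`).}
#' }
#' A peak may hit several categories; per-category counts are redundant and
#' the total counts each peak once.
#'
#' @param peaks peak table (typically non-DC sites).
#' @param elements element table (see [cis_elements()]).
#' @param rule `"center_within"` or `"half_overlap"`.
#' @return list with `hits` (logical peak x category matrix plus
#'   `any` column) and `counts` (named vector: per-category redundant counts
#'   and deduplicated `total`), plus the rule used.
#' @export
assign_cis <- function(peaks, elements, rule = c("center_within", "half_overlap")) {
  rule <- match.arg(rule)
  cats <- c("promoter", "enhancer", "insulator")
  bad <- setdiff(unique(elements$category), cats)
  if (length(bad)) stop("unknown cis-element category: ", paste(bad, collapse = ", "))
  hits <- matrix(FALSE, nrow(peaks), length(cats),
                 dimnames = list(NULL, cats))
  for (i in seq_len(nrow(peaks))) {
    cand <- elements[elements$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    hit <- if (rule == "center_within") {
      peaks$start[i] <= cand$center & cand$center < peaks$end[i]
    } else {
      satisfies(peaks[i, , drop = FALSE], cand, "either_half", strict = FALSE)
    }
    for (cat in unique(cand$category[hit])) hits[i, cat] <- TRUE
  }
  any_hit <- rowSums(hits) > 0
  counts <- c(colSums(hits), total = sum(any_hit))
  list(hits = cbind(as.data.frame(hits), any = any_hit),
       counts = counts, rule = rule)
}

#' Cis-regulatory overlap table stratified by TE-derived status
#'
#' Rows are TE-derived, non-TE-derived and their sum, per protein; columns
#' are the number of sites, redundant per-category overlap counts and the
#' deduplicated total. The sum row equals the column-wise sum of the two
#' subsets.
#'
#' @param peaks non-DC peak table with `protein` column.
#' @param te_derived logical vector per peak (see [te_derived_flag()]).
#' @param elements element table.
#' @param rule overlap rule, see [assign_cis()].
#' @return data.frame with columns `protein`, `subset`, `n_sites`,
#'   `promoter`, `enhancer`, `insulator`, `total`; attribute `rule` records
#'   the rule used.
#' @export
cis_overlap_table <- function(peaks, te_derived, elements,
                              rule = c("center_within", "half_overlap")) {
  rule <- match.arg(rule)
  prot <- if (!is.null(peaks$protein)) peaks$protein else rep("all", nrow(peaks))
  out <- list()
  for (p in unique(prot)) {
    rows <- list(`TE-derived` = prot == p & te_derived,
                 `non-TE-derived` = prot == p & !te_derived,
                 Sum = prot == p)
    for (s in names(rows)) {
      sel <- peaks[rows[[s]], , drop = FALSE]
      cnt <- if (nrow(sel)) assign_cis(sel, elements, rule)$counts else
        c(promoter = 0L, enhancer = 0L, insulator = 0L, total = 0L)
      out[[length(out) + 1L]] <- data.frame(
        protein = p, subset = s, n_sites = nrow(sel),
        promoter = cnt[["promoter"]], enhancer = cnt[["enhancer"]],
        insulator = cnt[["insulator"]], total = cnt[["total"]],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "rule") <- rule
  res
}
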