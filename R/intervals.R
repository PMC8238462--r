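#' Construct a table of genomic intervals
#'
#' Intervals follow the BED convention throughout the package: coordinates are
#' 0-based, half-open `[start, end)`. All readers convert to this convention on
#' ingest and all writers convert back.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start positions.
#' @param end integer vector, 0-based exclusive end positions.
#' @param ... further equal-length columns carried along (e.g. `name`, `score`).
#' @return a `data.frame` with at least columns `chrom`, `start`, `end`.
#' @examples
#' intervals("chr2L", 100, 200)
#' @export
intervals <- function(chrom, start, end, ...) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  ...,
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

#' Validate an interval table
#'
#' Checks the interval invariants: non-empty chromosome names, non-negative
#' starts and strictly positive lengths.
#'
#' @param x a data.frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, what = "intervals") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop(what, ": empty chromosome name")
  if (any(x$start < 0)) stop(what, ": negative start coordinate")
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop(what, ": start >= end at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  invisible(x)
}

#' Interval lengths in bp
#' @param x interval table.
#' @return numeric vector `end - start`.
#' @export
interval_width <- function(x) x$end - x$start

#' Pairwise overlap length between two intervals
#'
#' Length in bp of the intersection of `[a.start, a.end)` and
#' `[b.start, b.end)`; 0 when the chromosomes differ. Vectorised over rows
#' (recycled to equal length).
#'
#' @param a,b interval tables (single rows or equal-length).
#' @return non-negative numeric vector of overlap lengths.
#' @examples
#' overlap_length(intervals("chr2L", 100, 200), intervals("chr2L", 150, 400))
#' @export
overlap_length <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ca <- rep_len(a$chrom, n); cb <- rep_len(b$chrom, n)
  sa <- rep_len(a$start, n); sb <- rep_len(b$start, n)
  ea <- rep_len(a$end, n);   eb <- rep_len(b$end, n)
  ov <- pmax(0, pmin(ea, eb) - pmax(sa, sb))
  ov[ca != cb] <- 0
  ov
}

#' Overlap rules used in the analysis
#'
#' Four criteria decide whether two intervals "overlap":
#' \describe{
#'   \item{`reciprocal_half`}{the common region is larger than half of the
#'     region covered by *each* interval (strict `>` on both sides); used to
#'     call DC vs non-DC sites.}
#'   \item{`either_half`}{the common region is larger than half of *either*
#'     interval (strict `>` on at least one side); used when merging adjacent
#'     binding peaks.}
#'   \item{`one_sided_half`}{at least half of interval `a` is covered
#'     (non-strict `>=`, one direction only); used for cross-species
#'     conservation of binding sites.}
#'   \item{`center_within`}{the center/summit of `b` lies inside `a`
#'     (half-open containment); used for cis-regulatory element overlap.}
#' }
#' @return character vector of the four rule names.
#' @export
overlap_rules <- function() c("reciprocal_half", "either_half", "one_sided_half", "center_within")

#' Test an overlap rule on interval pairs
#'
#' Half-lengths are kept as exact rationals (`len / 2`, no integer truncation)
#' and compared against the integer overlap, so odd lengths carry no
#' off-by-one asymmetry.
#'
#' @param a,b interval tables (recycled to equal length). For
#'   `one_sided_half`, `a` is the side whose half-coverage is required.
#' @param rule one of [overlap_rules()].
#' @param center_of_b numeric vector of center/summit positions of `b`;
#'   required for `center_within`.
#' @param strict logical; override the rule's default strictness of the
#'   half-length comparison (`>` when `TRUE`, `>=` when `FALSE`). Defaults:
#'   strict for `reciprocal_half` and `either_half` ("larger than half"),
#'   non-strict for `one_sided_half` ("at least half").
#' @return logical vector.
#' @examples
#' a <- intervals("c", 0, 100); b <- intervals("c", 50, 250)
#' satisfies(a, b, "reciprocal_half")       # FALSE: 50 not > 100
#' satisfies(a, b, "center_within", center_of_b = 60)
#' @export
satisfies <- function(a, b, rule = overlap_rules(), center_of_b = NULL,
                      strict = NULL) {
  rule <- match.arg(rule)
  n <- max(nrow(a), nrow(b))
  if (rule == "center_within") {
    if (is.null(center_of_b))
      stop("center_within rule requires center_of_b")
    ca <- rep_len(a$chrom, n); cb <- rep_len(b$chrom, n)
    s <- rep_len(a$start, n); e <- rep_len(a$end, n)
    ctr <- rep_len(center_of_b, n)
    return(ca == cb & s <= ctr & ctr < e)
  }
  ov <- overlap_length(a, b)
  ha <- rep_len(a$end - a$start, n) / 2
  hb <- rep_len(b$end - b$start, n) / 2
  if (is.null(strict)) strict <- rule != "one_sided_half"
  cmp <- if (strict) `>` else `>=`
  switch(rule,
         reciprocal_half = cmp(ov, ha) & cmp(ov, hb),
         either_half     = cmp(ov, ha) | cmp(ov, hb),
         one_sided_half  = cmp(ov, ha))
}

#' Merge adjacent binding peaks
#'
#' Peaks are sorted by genomic position (chrom, start, end; remaining ties by
#' input order) and merged in one left-to-right pass whenever the common
#' region between adjacent peaks is larger than half of the region of either
#' peak (the `either_half` rule). Merging is transitive within the pass: a
#' merged interval is compared against the next peak.
#'
#' @param peaks interval table.
#' @param strict logical, strictness of the half comparison (default strict
#'   `>`).
#' @return interval table of merged regions with a `members` column giving the
#'   1-based input row indices merged into each region (comma-separated) and
#'   `n_members`, the number of constituent peaks.
#' @examples
#' merge_peaks(intervals("c", c(0, 40), c(100, 140)))  # one region [0,140)
#' @export
merge_peaks <- function(peaks, strict = TRUE) {
  validate_intervals(peaks, "peaks")
  n <- nrow(peaks)
  if (n == 0)
    return(cbind(peaks[0, c("chrom", "start", "end")],
                 data.frame(members = character(0), n_members = integer(0))))
  ord <- order(peaks$chrom, peaks$start, peaks$end)
  p <- peaks[ord, c("chrom", "start", "end")]
  idx <- ord
  out_chrom <- character(0); out_start <- numeric(0); out_end <- numeric(0)
  out_members <- list()
  cur <- list(chrom = p$chrom[1], start = p$start[1], end = p$end[1],
              members = idx[1])
  flush <- function() {
    out_chrom <<- c(out_chrom, cur$chrom)
    out_start <<- c(out_start, cur$start)
    out_end <<- c(out_end, cur$end)
    out_members[[length(out_members) + 1L]] <<- cur$members
  }
  if (n > 1) for (i in 2:n) {
    same <- p$chrom[i] == cur$chrom
    ov <- if (same) max(0, min(cur$end, p$end[i]) - max(cur$start, p$start[i])) else 0
    cmp <- if (strict) `>` else `>=`
    hit <- same && (cmp(ov, (cur$end - cur$start) / 2) ||
                    cmp(ov, (p$end[i] - p$start[i]) / 2))
    if (hit) {
      cur$start <- min(cur$start, p$start[i])
      cur$end <- max(cur$end, p$end[i])
      cur$members <- c(cur$members, idx[i])
    } else {
      flush()
      cur <- list(chrom = p$chrom[i], start = p$start[i], end = p$end[i],
                  members = idx[i])
    }
  }
  flush()
  data.frame(chrom = out_chrom, start = out_start, end = out_end,
             members = vapply(out_members, function(m)
               paste(sort(m), collapse = ","), character(1)),
             n_members = lengths(out_members),
             stringsAsFactors = FALSE)
}

#' Extend an interval by a fraction of its length on each side
#'
#' Used to widen an orthologous region by half its length on each side before
#' searching for the highest binding signal. Clamped to `[0, chrom_length)`.
#'
#' @param a interval table.
#' @param factor fraction of the interval length added on each side
#'   (default 0.5).
#' @param chrom_length chromosome length(s) in bp used for clamping
#'   (default `Inf`); either a single value, a vector recycled over rows, or a
#'   named vector indexed by chromosome.
#' @return extended interval table.
#' @examples
#' extend_interval(intervals("c", 100, 200))  # [50, 250)
#' @export
extend_interval <- function(a, factor = 0.5, chrom_length = Inf) {
  stopifnot(factor >= 0)
  len <- a$end - a$start
  cl <- if (!is.null(names(chrom_length))) {
    unname(chrom_length[a$chrom])
  } else rep_len(chrom_length, nrow(a))
  cl[is.na(cl)] <- Inf
  out <- a
  out$start <- pmax(0, a$start - factor * len)
  out$end <- pmin(cl, a$end + factor * len)
  out
}

# Total bp covered by the union of a set of intervals (used for class lengths
# and flattening). Internal.
union_length <- function(x) {
  if (nrow(x) == 0) return(0)
  s <- flatten_intervals(x)
  sum(s$end - s$start)
}

# Flatten possibly overlapping intervals into a disjoint sorted set. Internal.
flatten_intervals <- function(x) {
  if (nrow(x) <= 1) return(x[, c("chrom", "start", "end")])
  x <- x[order(x$chrom, x$start, x$end), c("chrom", "start", "end")]
  keep_chrom <- character(0); keep_start <- numeric(0); keep_end <- numeric(0)
  cc <- x$chrom[1]; cs <- x$start[1]; ce <- x$end[1]
  for (i in 2:nrow(x)) {
    if (x$chrom[i] == cc && x$start[i] <= ce) {
      ce <- max(ce, x$end[i])
    } else {
      keep_chrom <- c(keep_chrom, cc); keep_start <- c(keep_start, cs)
      keep_end <- c(keep_end, ce)
      cc <- x$chrom[i]; cs <- x$start[i]; ce <- x$end[i]
    }
  }
  data.frame(chrom = c(keep_chrom, cc), start = c(keep_start, cs),
             end = c(keep_end, ce), stringsAsFactors = FALSE)
}

# Overlap of one interval (chrom, start, end scalars) against a flattened
# interval set; returns total overlapped bp. Internal.
overlap_with_set <- function(chrom, start, end, set) {
  if (nrow(set) == 0) return(0)
  s <- set[set$chrom == chrom, , drop = FALSE]
  if (nrow(s) == 0) return(0)
  sum(pmax(0, pmin(s$end, end) - pmax(s$start, start)))
}

# Subtract a flattened interval set from one interval; returns the surviving
# fragments as an interval table. Internal.
subtract_intervals <- function(chrom, start, end, set) {
  s <- set[set$chrom == chrom & set$end > start & set$start < end, , drop = FALSE]
  if (nrow(s) == 0)
    return(data.frame(chrom = chrom, start = start, end = end,
                      stringsAsFactors = FALSE))
  s <- s[order(s$start), , drop = FALSE]
  frag_s <- numeric(0); frag_e <- numeric(0)
  pos <- start
  for (i in seq_len(nrow(s))) {
    if (s$start[i] > pos) { frag_s <- c(frag_s, pos); frag_e <- c(frag_e, s$start[i]) }
    pos <- max(pos, s$end[i])
  }
  if (pos < end) { frag_s <- c(frag_s, pos); frag_e <- c(frag_e, end) }
  if (!length(frag_s))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  data.frame(chrom = chrom, start = frag_s, end = frag_e,
             stringsAsFactors = FALSE)
}
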