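#' Construct a step-function signal track
#'
#' A signal track holds per-chromosome ordered, non-overlapping step segments
#' of linear fold enrichment (ChIP/input). Positions not covered by any
#' segment have value 0.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`, `value`.
#' @return the validated track (class `signal_track`).
#' @export
signal_track <- function(x) {
  validate_intervals(x, "signal track")
  if (is.null(x$value)) stop("signal track: missing value column")
  if (any(x$value < 0)) stop("signal track: negative fold enrichment")
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  if (nrow(x) > 1) {
    bad <- which(x$chrom[-1] == x$chrom[-nrow(x)] & x$start[-1] < x$end[-nrow(x)])
    if (length(bad)) stop("signal track: overlapping segments near row ", bad[1])
  }
  rownames(x) <- NULL
  class(x) <- c("signal_track", "data.frame")
  x
}

#' Highest binding signal over a region
#'
#' Maximum step value among segments intersecting the region; 0 when the
#' region is uncovered.
#'
#' @param track a [signal_track()].
#' @param region single-row interval table.
#' @return scalar linear fold enrichment.
#' @examples
#' tr <- signal_track(data.frame(chrom = "c", start = c(0, 100),
#'                               end = c(100, 200), value = c(2, 8)))
#' max_signal(tr, intervals("c", 50, 150))  # 8
#' @export
max_signal <- function(track, region) {
  hit <- track$chrom == region$chrom[1] &
    track$end > region$start[1] & track$start < region$end[1]
  if (!any(hit)) return(0)
  max(track$value[hit])
}

#' Call cross-species presence/absence of a binding site
#'
#' The highest binding signal is searched within the peak in its own species
#' and within its orthologous region in the other species, the latter widened
#' by half its length on each side. The site is called absent in the other
#' species when the orthologous signal is reduced 10-fold or more
#' (`other <= own / fold`, boundary inclusive); unmappable peaks are reported
#' as such. A peak whose own signal is 0 is degenerate (any signal trivially
#' satisfies the reduction) and is flagged `present_in_other` with a warning.
#'
#' @param peaks peak table (see [read_peaks()]).
#' @param own_track [signal_track()] in the peak's species.
#' @param map `ortholog_map` from the peak's species to the other.
#' @param other_track [signal_track()] in the other species.
#' @param other_chrom_lengths named vector of destination chromosome lengths
#'   (used to clamp the extension), or `Inf`.
#' @param fold reduction threshold (default 10).
#' @param extend_factor half-length extension per side of the orthologous
#'   region (default 0.5).
#' @return data.frame with one row per peak: `status` in
#'   `{present_in_other, absent_in_other, unmappable}`, `own_signal`,
#'   `other_signal`.
#' @export
call_turnover <- function(peaks, own_track, map, other_track,
                          other_chrom_lengths = Inf, fold = 10,
                          extend_factor = 0.5) {
  validate_peaks(peaks)
  n <- nrow(peaks)
  status <- character(n); own <- numeric(n); other <- rep(NA_real_, n)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    pk <- peaks[i, , drop = FALSE]
    own[i] <- max_signal(own_track, pk)
    ortho <- project_interval(pk, map)
    if (is.null(ortho)) { status[i] <- "unmappable"; next }
    reg <- extend_interval(ortho, extend_factor, other_chrom_lengths)
    other[i] <- max_signal(other_track, reg)
    if (own[i] == 0) { status[i] <- "present_in_other"; degenerate <- TRUE; next }
    status[i] <- if (other[i] <= own[i] / fold) "absent_in_other" else "present_in_other"
  }
  if (degenerate)
    warning("peak(s) with zero own signal: absence is vacuous, called present_in_other")
  data.frame(status = status, own_signal = own, other_signal = other,
             stringsAsFactors = FALSE)
}

#' Call cross-species conservation of binding sites
#'
#' A binding site is conserved when at least half of its binding region,
#' projected into the other species' coordinates, overlaps a region bound by
#' the same protein there (non-strict `>=`, the one-sided-half rule applied to
#' the projected region against the union of same-protein peaks). Unmappable
#' sites are unconserved and flagged.
#'
#' @param peaks_a peak table of the focal species.
#' @param peaks_b peak table of the partner species (same protein).
#' @param map_a_to_b `ortholog_map` from species A coordinates to species B.
#' @return data.frame per A peak: `status` in `{conserved, unconserved}`,
#'   `mappable` logical.
#' @export
call_conservation <- function(peaks_a, peaks_b, map_a_to_b) {
  pa <- unique(peaks_a$protein); pb <- unique(peaks_b$protein)
  if (length(pa) && length(pb) && !all(is.na(c(pa, pb))) &&
      !identical(sort(pa), sort(pb)))
    stop("conservation: peak sets are from different proteins (",
         paste(pa, collapse = ","), " vs ", paste(pb, collapse = ","), ")")
  bset <- flatten_intervals(peaks_b[, c("chrom", "start", "end")])
  proj <- project_intervals(peaks_a, map_a_to_b)
  status <- rep("unconserved", nrow(peaks_a))
  ok <- which(proj$mappable)
  for (i in ok) {
    ov <- overlap_with_set(proj$chrom[i], proj$start[i], proj$end[i], bset)
    if (ov >= (proj$end[i] - proj$start[i]) / 2) status[i] <- "conserved"
  }
  data.frame(status = status, mappable = proj$mappable,
             stringsAsFactors = FALSE)
}

#' Aggregate turnover / conservation calls into a count table
#'
#' @param calls data.frame with a `status` column and optional `species` /
#'   `protein` columns to stratify by.
#' @return data.frame of counts per (species, protein, status); counts sum to
#'   the number of input calls.
#' @export
turnover_summary <- function(calls) {
  if (nrow(calls) == 0)
    return(data.frame(species = character(0), protein = character(0),
                      status = character(0), n = integer(0)))
  by <- list(
    species = if (!is.null(calls$species)) calls$species else rep("all", nrow(calls)),
    protein = if (!is.null(calls$protein)) calls$protein else rep("all", nrow(calls)),
    status = calls$status)
  agg <- stats::aggregate(list(n = rep(1L, nrow(calls))), by = by, FUN = sum)
  agg[order(agg$species, agg$protein, agg$status), , drop = FALSE]
}
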