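#' Build a one-to-one ortholog block map
#'
#' A map is a set of reciprocal-best alignment blocks linking intervals in a
#' source coordinate system (`src_*`) to intervals in a destination system
#' (`dst_*`). Blocks must be non-overlapping on both sides (one-to-one
#' orthology); `strand` is the orientation of the destination block relative
#' to the source.
#'
#' @param src_chrom,src_start,src_end source block coordinates (0-based
#'   half-open).
#' @param dst_chrom,dst_start,dst_end destination block coordinates.
#' @param strand `"+"` or `"-"` per block.
#' @return an object of class `ortholog_map` (a validated data.frame).
#' @export
ortholog_map <- function(src_chrom, src_start, src_end,
                         dst_chrom, dst_start, dst_end, strand = "+") {
  x <- data.frame(src_chrom = as.character(src_chrom),
                  src_start = as.numeric(src_start),
                  src_end = as.numeric(src_end),
                  dst_chrom = as.character(dst_chrom),
                  dst_start = as.numeric(dst_start),
                  dst_end = as.numeric(dst_end),
                  strand = rep_len(as.character(strand), length(src_chrom)),
                  stringsAsFactors = FALSE)
  validate_ortholog_map(x)
  class(x) <- c("ortholog_map", "data.frame")
  x
}

#' Validate an ortholog map
#'
#' Enforces the one-to-one invariants: valid block intervals on both sides,
#' strand in `{+,-}`, and no overlap among blocks on the source side or on the
#' destination side. Violations are reported with the offending row numbers.
#'
#' @param x data.frame of blocks.
#' @return `x`, invisibly.
#' @export
validate_ortholog_map <- function(x) {
  validate_intervals(data.frame(chrom = x$src_chrom, start = x$src_start,
                                end = x$src_end), "ortholog map (src)")
  validate_intervals(data.frame(chrom = x$dst_chrom, start = x$dst_start,
                                end = x$dst_end), "ortholog map (dst)")
  if (any(!x$strand %in% c("+", "-")))
    stop("ortholog map: strand must be '+' or '-'")
  check_disjoint <- function(chrom, start, end, side) {
    o <- order(chrom, start)
    ch <- chrom[o]; s <- start[o]; e <- end[o]
    if (length(s) > 1) {
      bad <- which(ch[-1] == ch[-length(ch)] & s[-1] < e[-length(e)])
      if (length(bad))
        stop("ortholog map: overlapping blocks on ", side, " at rows ",
             o[bad[1]], " and ", o[bad[1] + 1])
    }
  }
  check_disjoint(x$src_chrom, x$src_start, x$src_end, "src")
  check_disjoint(x$dst_chrom, x$dst_start, x$dst_end, "dst")
  invisible(x)
}

#' Load an ortholog map from a block TSV
#'
#' The native format is a 7-column TSV with header line
#' `#src_chrom src_start src_end dst_chrom dst_start dst_end strand`.
#'
#' @param path file path.
#' @return an `ortholog_map`.
#' @export
load_ortholog_map <- function(path) {
  cols <- c("src_chrom", "src_start", "src_end",
            "dst_chrom", "dst_start", "dst_end", "strand")
  if (!length(readLines(path, n = 1L)))
    return(ortholog_map(character(0), numeric(0), numeric(0),
                        character(0), numeric(0), numeric(0), character(0)))
  x <- read_dialect_tsv(path, cols, "ortholog map")
  ortholog_map(x$src_chrom, x$src_start, x$src_end,
               x$dst_chrom, x$dst_start, x$dst_end, x$strand)
}

#' Write an ortholog map to the block TSV format
#'
#' @param map an `ortholog_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#src_chrom\tsrc_start\tsrc_end\tdst_chrom\tdst_start\tdst_end\tstrand", con)
  utils::write.table(as.data.frame(map), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Invert an ortholog map
#'
#' Swaps the source and destination sides; block strands are preserved (the
#' orientation relation is symmetric).
#'
#' @param map an `ortholog_map`.
#' @return the reverse `ortholog_map`.
#' @export
invert_ortholog_map <- function(map) {
  ortholog_map(map$dst_chrom, map$dst_start, map$dst_end,
               map$src_chrom, map$src_start, map$src_end, map$strand)
}

#' Convert a UCSC chain file into an ortholog block map
#'
#' Collapses the gapless aligned blocks of each chain into block-TSV
#' semantics. Chain coordinates on a negative-strand target are converted to
#' forward-strand coordinates. Per-block indels inside a chain become separate
#' blocks; overlapping blocks (not expected in reciprocal-best chains) are
#' rejected by validation.
#'
#' @param path chain file path.
#' @return an `ortholog_map`.
#' @export
chain_to_ortholog_map <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "chain")) {
      f <- strsplit(ln, "\\s+")[[1]]
      tName <- f[3]; tStart <- as.numeric(f[6])
      qName <- f[8]; qSize <- as.numeric(f[9]); qStrand <- f[10]
      qStart <- as.numeric(f[11])
      i <- i + 1L
      tPos <- tStart; qPos <- qStart
      while (i <= length(lines) && nzchar(trimws(lines[i]))) {
        b <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
        size <- b[1]
        dst_s <- qPos; dst_e <- qPos + size
        if (qStrand == "-") { tmp <- dst_s; dst_s <- qSize - dst_e; dst_e <- qSize - tmp }
        out[[length(out) + 1L]] <- data.frame(
          src_chrom = tName, src_start = tPos, src_end = tPos + size,
          dst_chrom = qName, dst_start = dst_s, dst_end = dst_e,
          strand = if (qStrand == "-") "-" else "+", stringsAsFactors = FALSE)
        if (length(b) >= 3) { tPos <- tPos + size + b[2]; qPos <- qPos + size + b[3] }
        i <- i + 1L
      }
    }
    i <- i + 1L
  }
  x <- do.call(rbind, out)
  ortholog_map(x$src_chrom, x$src_start, x$src_end,
               x$dst_chrom, x$dst_start, x$dst_end, x$strand)
}

#' Project an interval through an ortholog map
#'
#' Intersects the query with the source blocks, maps each intersected piece
#' linearly (proportional position within the block, strand-aware) into
#' destination coordinates, and returns the minimal destination interval
#' spanning all projected pieces on one destination chromosome. When pieces
#' land on several destination chromosomes, the chromosome carrying the
#' largest projected length wins (ties broken lexicographically). A query
#' intersecting no block is unmappable.
#'
#' @param query single-row interval table (or vector-free list with `chrom`,
#'   `start`, `end`).
#' @param map an `ortholog_map`.
#' @return single-row interval table in destination coordinates with a
#'   `mapped_bp` column, or `NULL` when unmappable.
#' @examples
#' m <- ortholog_map("cA", 0, 1000, "cB", 5000, 6000, "+")
#' project_interval(intervals("cA", 100, 200), m)  # [cB, 5100, 5200)
#' @export
project_interval <- function(query, map) {
  b <- map[map$src_chrom == query$chrom[1] &
             map$src_end > query$start[1] & map$src_start < query$end[1], ,
           drop = FALSE]
  if (nrow(b) == 0) return(NULL)
  qs <- pmax(query$start[1], b$src_start)
  qe <- pmin(query$end[1], b$src_end)
  scale <- (b$dst_end - b$dst_start) / (b$src_end - b$src_start)
  plus <- b$strand == "+"
  ps <- ifelse(plus,
               b$dst_start + (qs - b$src_start) * scale,
               b$dst_start + (b$src_end - qe) * scale)
  pe <- ifelse(plus,
               b$dst_start + (qe - b$src_start) * scale,
               b$dst_start + (b$src_end - qs) * scale)
  ps <- floor(ps); pe <- ceiling(pe)
  pe <- pmax(pe, ps + 1)  # a non-empty piece never projects to zero length
  len_by_chrom <- tapply(pe - ps, b$dst_chrom, sum)
  best <- names(len_by_chrom)[order(-len_by_chrom, names(len_by_chrom))][1]
  keep <- b$dst_chrom == best
  data.frame(chrom = best, start = min(ps[keep]), end = max(pe[keep]),
             mapped_bp = sum(qe[keep] - qs[keep]), stringsAsFactors = FALSE)
}

#' Project many intervals through an ortholog map
#'
#' @param queries interval table.
#' @param map an `ortholog_map`.
#' @return data.frame with one row per query: `chrom`, `start`, `end`,
#'   `mapped_bp`, `mappable`; unmappable queries carry `NA` coordinates.
#' @export
project_intervals <- function(queries, map) {
  res <- lapply(seq_len(nrow(queries)), function(i)
    project_interval(queries[i, , drop = FALSE], map))
  ok <- !vapply(res, is.null, logical(1))
  out <- data.frame(chrom = NA_character_, start = NA_real_, end = NA_real_,
                    mapped_bp = 0, mappable = ok, stringsAsFactors = FALSE)[rep(1, nrow(queries)), ]
  rownames(out) <- NULL
  out$mappable <- ok
  if (any(ok)) {
    hit <- do.call(rbind, res[ok])
    out$chrom[ok] <- hit$chrom
    out$start[ok] <- hit$start
    out$end[ok] <- hit$end
    out$mapped_bp[ok] <- hit$mapped_bp
  }
  out
}
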