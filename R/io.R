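#' Read a BED6 file
#'
#' @param path file path.
#' @return interval table (0-based half-open) with `name`, `score`, `strand`
#'   columns; intervals without strand get `"."`.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  x <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr),
                  name = if (!is.null(gr$name)) as.character(gr$name) else ".",
                  score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
                  strand = as.character(GenomicRanges::strand(gr)),
                  stringsAsFactors = FALSE)
  x$strand[x$strand == "*"] <- "."
  validate_intervals(x, path)
  x
}

#' Write a BED6 file
#'
#' @param x interval table; optional `name`, `score`, `strand` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path) {
  validate_intervals(x)
  strand <- if (!is.null(x$strand)) ifelse(x$strand %in% c("+", "-"), x$strand, "*") else "*"
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$start + 1L, x$end),
                               strand = strand)
  gr$name <- if (!is.null(x$name)) x$name else paste0("region_", seq_len(nrow(x)))
  gr$score <- if (!is.null(x$score)) x$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read binding peaks from a narrowPeak or BED file
#'
#' The summit is taken from the 10th narrowPeak column (offset from peak
#' start) when present and non-negative, otherwise the interval midpoint.
#' Fold enrichment is the narrowPeak `signalValue` (7th column) when present,
#' else the BED score.
#'
#' @param path file path.
#' @param protein protein label attached to every peak (e.g. "MOF").
#' @param species species label attached to every peak.
#' @param format `"narrowPeak"` or `"BED"`; guessed from the file extension
#'   by default.
#' @return peak table: `chrom`, `start`, `end`, `name`, `summit`,
#'   `fold_enrichment`, `protein`, `species`.
#' @export
read_peaks <- function(path, protein = NA_character_, species = NA_character_,
                       format = c("auto", "narrowPeak", "BED")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("narrowPeak$", path)) "narrowPeak" else "BED"
  if (format == "narrowPeak") {
    gr <- rtracklayer::import(path, format = "BED",
                              extraCols = c(signalValue = "numeric",
                                            pValue = "numeric",
                                            qValue = "numeric",
                                            peak = "integer"))
    x <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    name = if (!is.null(gr$name)) as.character(gr$name) else ".",
                    fold_enrichment = gr$signalValue,
                    summit_offset = gr$peak,
                    stringsAsFactors = FALSE)
    x$summit <- ifelse(!is.na(x$summit_offset) & x$summit_offset >= 0,
                       x$start + x$summit_offset,
                       floor((x$start + x$end) / 2))
    x$summit_offset <- NULL
  } else {
    x <- read_bed6(path)
    x$fold_enrichment <- x$score
    x$summit <- floor((x$start + x$end) / 2)
    x$score <- NULL; x$strand <- NULL
  }
  x$protein <- protein
  x$species <- species
  validate_peaks(x)
  x
}

#' Validate a peak table
#'
#' @param x peak table with `summit` and `fold_enrichment` columns.
#' @return `x`, invisibly.
#' @export
validate_peaks <- function(x) {
  validate_intervals(x, "peaks")
  if (!is.null(x$summit)) {
    bad <- which(x$summit < x$start | x$summit >= x$end)
    if (length(bad)) stop("peaks: summit outside interval at row(s) ",
                          paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(x$fold_enrichment) && any(x$fold_enrichment < 0, na.rm = TRUE))
    stop("peaks: negative fold enrichment")
  invisible(x)
}

#' Read a bedGraph signal track
#'
#' Values are linear fold enrichments (ChIP/input); uncovered positions are
#' implicitly 0.
#'
#' @param path file path.
#' @return signal track (see [signal_track()]).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  signal_track(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr) - 1L,
                          end = GenomicRanges::end(gr),
                          value = as.numeric(gr$score),
                          stringsAsFactors = FALSE))
}

#' Write a bedGraph signal track
#'
#' @param track signal track table (`chrom`, `start`, `end`, `value`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end),
                               score = track$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read gene models (CDS segments) from a GFF3 file
#'
#' Returns the CDS segments with their parent transcript/gene id, strand and
#' phase, in the package's 0-based convention, plus the transcript spans of
#' `gene`-/`mRNA`-typed records for gene-body windows.
#'
#' @param path GFF3 file path.
#' @return list with `cds` (gene, chrom, start, end, strand, phase) and
#'   `genes` (gene, chrom, start, end, strand).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  typ <- as.character(gr$type)
  ids <- function(g) {
    id <- if (!is.null(g$Parent)) vapply(g$Parent, function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1)) else NA
    fallback <- if (!is.null(g$ID)) as.character(g$ID) else NA_character_
    ifelse(is.na(id), fallback, id)
  }
  cds <- gr[typ == "CDS"]
  genes <- gr[typ %in% c("gene", "mRNA", "transcript")]
  list(
    cds = data.frame(gene = ids(cds),
                     chrom = as.character(GenomicRanges::seqnames(cds)),
                     start = GenomicRanges::start(cds) - 1L,
                     end = GenomicRanges::end(cds),
                     strand = as.character(GenomicRanges::strand(cds)),
                     phase = if (!is.null(cds$phase)) as.integer(cds$phase) else 0L,
                     stringsAsFactors = FALSE),
    genes = data.frame(gene = if (!is.null(genes$ID)) as.character(genes$ID) else ids(genes),
                       chrom = as.character(GenomicRanges::seqnames(genes)),
                       start = GenomicRanges::start(genes) - 1L,
                       end = GenomicRanges::end(genes),
                       strand = as.character(GenomicRanges::strand(genes)),
                       stringsAsFactors = FALSE))
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write peaks as a narrowPeak file
#'
#' Ten columns: chrom, start, end, name, score (0), strand (`.`),
#' signalValue (fold enrichment), pValue (-1), qValue (-1), peak (summit
#' offset from start).
#'
#' @param peaks peak table with `summit` and `fold_enrichment` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_peaks(peaks)
  x <- data.frame(peaks$chrom, peaks$start, peaks$end,
                  if (!is.null(peaks$name)) peaks$name else ".",
                  0L, ".",
                  peaks$fold_enrichment, -1, -1,
                  peaks$summit - peaks$start)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a TSV report
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a headered TSV dialect, tolerating a leading "#" on the header line.
# Internal.
read_dialect_tsv <- function(path, required, what) {
  header <- readLines(path, n = 1L)
  if (!length(header)) {
    x <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(required))),
                         required)
    return(x)
  }
  cols <- strsplit(sub("^#\\s*", "", header), "\\s+")[[1]]
  x <- utils::read.table(path, header = FALSE, skip = 1L, sep = "",
                         col.names = cols, stringsAsFactors = FALSE,
                         comment.char = "")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "), " in ", path)
  x
}
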