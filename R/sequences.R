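#' Load a genome from a FASTA file
#'
#' Reads a (possibly line-wrapped) FASTA file into an in-memory genome.
#' Record identifiers are the first whitespace-delimited token of each
#' header and must be unique; empty records are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` named by chromosome; lengths are available via
#'   [genome_lengths()].
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("genome FASTA not found: ", path))
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) {
    abort(paste0("duplicate FASTA record id(s): ",
                 paste(unique(names(g)[duplicated(names(g))]), collapse = ", ")))
  }
  if (any(Biostrings::width(g) == 0)) {
    abort(paste0("empty FASTA record(s): ",
                 paste(names(g)[Biostrings::width(g) == 0], collapse = ", ")))
  }
  g
}

#' @rdname load_genome
#' @param genome A genome from [load_genome()].
#' @return `genome_lengths()` returns a named integer vector of
#'   chromosome lengths.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Extract peak sequences with flanks from a genome
#'
#' For each peak, fetches the forward-strand genome substring over
#' `[start - upstream, end + downstream]`, silently clipped to
#' `[1, chromosome length]` (clipped peaks are reported via a message).
#' Peaks are treated as unstranded; no reverse complementing is applied.
#'
#' @param peaks A region-set tibble.
#' @param genome A genome from [load_genome()].
#' @param upstream,downstream Flank widths in bases (>= 0).
#' @return A tibble with columns `name`, `chrom`, `fetch_start`,
#'   `fetch_end`, `sequence`; `nchar(sequence) == fetch_end - fetch_start + 1`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", strrep("ACGT", 50)), fa)
#' g <- load_genome(fa)
#' get_peak_sequences(region_set("c1", 10, 20, "p"), g, 5, 5)
#' @export
get_peak_sequences <- function(peaks, genome, upstream = 0L, downstream = 0L) {
  peaks <- validate_regions(peaks)
  if (upstream < 0 || downstream < 0) abort("flank widths must be >= 0")
  missing_chr <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chr) > 0) {
    abort(paste0(
      "peak chromosome(s) absent from genome: ",
      paste(missing_chr, collapse = ", "), " (peaks: ",
      paste(head(peaks$name[peaks$chrom %in% missing_chr], 5), collapse = ", "), ")"))
  }
  len <- genome_lengths(genome)[peaks$chrom]
  fetch_start <- pmax(peaks$start - as.integer(upstream), 1L)
  fetch_end <- pmin(peaks$end + as.integer(downstream), unname(len))
  clipped <- peaks$name[peaks$start - upstream < 1L | peaks$end + downstream > len]
  if (length(clipped) > 0) {
    inform(paste0("clipped at chromosome boundary: ", paste(clipped, collapse = ", ")))
  }
  seqs <- vapply(seq_len(nrow(peaks)), function(i) {
    as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                    start = fetch_start[i], end = fetch_end[i]))
  }, "")
  tibble(name = peaks$name, chrom = peaks$chrom,
         fetch_start = as.integer(fetch_start), fetch_end = as.integer(fetch_end),
         sequence = toupper(seqs))
}

#' Write peak sequences as wrapped FASTA
#'
#' One record per sequence with header `<name> <chrom>:<start>-<end>` and
#' the sequence wrapped at exactly `width` characters per line (last line
#' possibly shorter). The output re-parses with [load_genome()].
#'
#' @param seqs A tibble from [get_peak_sequences()].
#' @param path Output file path.
#' @param width Line width in characters (>= 1; default 50).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 50L) {
  if (width < 1) abort("width must be >= 1")
  x <- Biostrings::DNAStringSet(seqs$sequence)
  names(x) <- paste0(seqs$name, " ", seqs$chrom, ":", seqs$fetch_start,
                     "-", seqs$fetch_end)
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}
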