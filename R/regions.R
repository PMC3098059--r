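#' Build and validate a region set
#'
#' A region set is an ordinary tibble with one row per genomic interval and
#' columns `name`, `chrom`, `start`, `end`, `strand`, `score`. Coordinates
#' are 1-based and closed (both ends included), matching GFF; BED input is
#' converted at the boundary by [read_bed()]. Strand is one of `"+"`, `"-"`
#' or `"*"` (unstranded). `validate_regions()` checks the invariants and
#' returns the tibble (with columns completed and per-chromosome sorted
#' order) or aborts with an informative error.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 1-based closed, `end >= start >= 1`.
#' @param name Unique region identifiers; auto-generated as `peak_<k>` when
#'   omitted.
#' @param strand Strand tokens; accepted on input: `+`, `-`, `.`, `*`, `1`,
#'   `-1`; canonicalized to `+`, `-`, `*`.
#' @param score Optional numeric score (`NA` when absent).
#' @param label Optional set label, stored in the `label` attribute and used
#'   for Venn labeling.
#' @return A tibble with columns `name`, `chrom`, `start`, `end`, `strand`,
#'   `score`, rows sorted by `(chrom, start, end, name)`.
#' @examples
#' region_set(chrom = "chr1", start = 100, end = 300, name = "peak1")
#' @export
region_set <- function(chrom, start, end, name = NULL, strand = "*",
                       score = NA_real_, label = NULL) {
  n <- length(chrom)
  if (is.null(name)) name <- paste0("peak_", seq_len(max(n, length(start))))
  x <- tibble(
    name = as.character(name),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = canonical_strand(rep_len(as.character(strand), length(name))),
    score = rep_len(as.double(score), length(name))
  )
  validate_regions(x, label = label)
}

#' @rdname region_set
#' @param x A data frame with at least `chrom`, `start`, `end` columns.
#' @export
validate_regions <- function(x, label = NULL) {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("region set lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"name" %in% names(x)) x$name <- paste0("peak_", seq_len(nrow(x)))
  if (!"strand" %in% names(x)) x$strand <- "*"
  if (!"score" %in% names(x)) x$score <- NA_real_
  x <- select(x, "name", "chrom", "start", "end", "strand", "score")
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$strand <- canonical_strand(as.character(x$strand))
  if (anyNA(x$start) || anyNA(x$end)) abort("non-integer start/end coordinates")
  if (any(x$start < 1L)) abort("start coordinates must be >= 1 (1-based closed)")
  bad <- which(x$end < x$start)
  if (length(bad) > 0) {
    abort(paste0("end < start for region(s): ",
                 paste(head(x$name[bad], 5), collapse = ", ")))
  }
  if (any(!nzchar(x$name)) || anyNA(x$name)) abort("region names must be non-empty")
  dup <- unique(x$name[duplicated(x$name)])
  if (length(dup) > 0) {
    abort(paste0("duplicate region name(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  x <- arrange(x, .data$chrom, .data$start, .data$end, .data$name)
  if (!is.null(label)) attr(x, "label") <- label
  x
}

canonical_strand <- function(s) {
  s[is.na(s)] <- "*"
  map <- c("+" = "+", "-" = "-", "." = "*", "*" = "*", "1" = "+", "-1" = "-")
  out <- unname(map[s])
  if (anyNA(out)) {
    abort(paste0("unknown strand symbol(s): ",
                 paste(unique(s[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Read a BED file as a region set
#'
#' BED is 0-based half-open; coordinates are converted to the internal
#' 1-based closed convention (`start = chromStart + 1`, `end = chromEnd`).
#' `track`, `browser` and `#` comment lines are skipped. Missing names are
#' auto-generated as `peak_<k>` in file order.
#'
#' @param path Path to a BED file with >= 3 tab-separated columns.
#' @param label Optional set label.
#' @return A region-set tibble (see [region_set()]).
#' @export
read_bed <- function(path, label = NULL) {
  lines <- read_region_lines(path)
  keep <- !grepl("^(track|browser|#)", lines$text) & nzchar(trimws(lines$text))
  lines <- lines[keep, , drop = FALSE]
  if (nrow(lines) == 0) {
    return(validate_regions(tibble(name = character(), chrom = character(),
                                   start = integer(), end = integer()),
                            label = label))
  }
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("BED line ", lines$lineno[which(nf < 3)[1]],
                 ": fewer than 3 tab-separated columns"))
  }
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, "")
  cs <- suppressWarnings(as.integer(col(2)))
  ce <- suppressWarnings(as.integer(col(3)))
  bad <- which(is.na(cs) | is.na(ce))
  if (length(bad) > 0) {
    abort(paste0("BED line ", lines$lineno[bad[1]], ": non-integer coordinates"))
  }
  bad <- which(ce <= cs)
  if (length(bad) > 0) {
    abort(paste0("BED line ", lines$lineno[bad[1]],
                 ": chromEnd must exceed chromStart (0-based half-open)"))
  }
  nm <- col(4)
  auto <- is.na(nm) | !nzchar(nm) | nm == "."
  nm[auto] <- paste0("peak_", which(auto))
  sc <- suppressWarnings(as.double(col(5)))
  st <- col(6)
  st[is.na(st) | !nzchar(st)] <- "*"
  validate_regions(tibble(name = nm, chrom = col(1), start = cs + 1L, end = ce,
                          strand = st, score = sc), label = label)
}

#' Read a GFF/GTF file as a region set
#'
#' GFF coordinates are already 1-based closed and are taken verbatim.
#' Strand tokens `+`, `-`, `.`, `1`, `-1` are accepted (`.` becomes `*`).
#' The region name is taken from the first attribute key found among
#' `name_attr`, then `gene_id`; rows with neither get `peak_<k>`.
#'
#' @param path Path to a 9-column GFF/GTF file.
#' @param name_attr Attribute key holding the region name (default `"ID"`).
#' @param label Optional set label.
#' @return A region-set tibble (see [region_set()]).
#' @export
read_gff <- function(path, name_attr = "ID", label = NULL) {
  lines <- read_region_lines(path)
  keep <- !grepl("^#", lines$text) & nzchar(trimws(lines$text))
  lines <- lines[keep, , drop = FALSE]
  if (nrow(lines) == 0) {
    return(validate_regions(tibble(name = character(), chrom = character(),
                                   start = integer(), end = integer()),
                            label = label))
  }
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8)) {
    abort(paste0("GFF line ", lines$lineno[which(nf < 8)[1]],
                 ": fewer than 8 tab-separated columns"))
  }
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, "")
  start <- suppressWarnings(as.integer(col(4)))
  end <- suppressWarnings(as.integer(col(5)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(paste0("GFF line ", lines$lineno[bad[1]], ": non-integer coordinates"))
  }
  bad <- which(end < start)
  if (length(bad) > 0) {
    abort(paste0("GFF line ", lines$lineno[bad[1]], ": end < start"))
  }
  attrs <- col(9)
  nm <- gff_attr(attrs, name_attr)
  fallback <- gff_attr(attrs, "gene_id")
  nm[is.na(nm)] <- fallback[is.na(nm)]
  nm[is.na(nm)] <- paste0("peak_", which(is.na(nm)))
  sc <- suppressWarnings(as.double(col(6)))
  validate_regions(tibble(name = nm, chrom = col(1), start = start, end = end,
                          strand = col(7), score = sc), label = label)
}

gff_attr <- function(attrs, key) {
  # handles both GFF3 'ID=x;...' and GTF 'gene_id "x"; ...'
  pat3 <- paste0("(^|;)\\s*", key, "=([^;]+)")
  patg <- paste0("(^|;)\\s*", key, "\\s+\"([^\"]+)\"")
  m3 <- regmatches(attrs, regexec(pat3, attrs))
  mg <- regmatches(attrs, regexec(patg, attrs))
  pick <- function(m) if (length(m) >= 3) m[[3]] else NA_character_
  out <- vapply(m3, pick, "")
  alt <- vapply(mg, pick, "")
  out[is.na(out) | !nzchar(out)] <- alt[is.na(out) | !nzchar(out)]
  out[!nzchar(out)] <- NA_character_
  trimws(out)
}

read_region_lines <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  txt <- readLines(path, warn = FALSE)
  data.frame(lineno = seq_along(txt), text = txt, stringsAsFactors = FALSE)
}

#' Read and write the package's TSV region dialect
#'
#' The TSV dialect is a header row `name chrom start end strand score`
#' followed by one tab-separated row per region, coordinates 1-based
#' closed. `read_regions_tsv(write_regions_tsv(x, p), p)` is the identity.
#'
#' @param x A region-set tibble.
#' @param path Output (or input) file path.
#' @return `write_regions_tsv()` returns `path` invisibly;
#'   `read_regions_tsv()` returns a region-set tibble.
#' @export
write_regions_tsv <- function(x, path) {
  x <- validate_regions(x)
  out <- x
  out$score <- ifelse(is.na(out$score), "", format(out$score, trim = TRUE))
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' @rdname write_regions_tsv
#' @param label Optional set label.
#' @export
read_regions_tsv <- function(path, label = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    strand = readr::col_character(), score = readr::col_double()
  ), progress = FALSE)
  validate_regions(x, label = label)
}

#' Write a region set as BED
#'
#' Converts the internal 1-based closed coordinates back to BED's 0-based
#' half-open convention (`chromStart = start - 1`, `chromEnd = end`).
#'
#' @param x A region-set tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_regions(x)
  lines <- paste(x$chrom, x$start - 1L, x$end, x$name,
                 ifelse(is.na(x$score), "0", format(x$score, trim = TRUE)),
                 ifelse(x$strand == "*", ".", x$strand),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a region set as GFF3
#'
#' Coordinates are written verbatim (both GFF and the internal model are
#' 1-based closed); unstranded regions get `.`, names go into the `ID=`
#' attribute.
#'
#' @param x A region-set tibble.
#' @param path Output file path.
#' @param source,type The GFF source and type columns (defaults
#'   `"peakannot"` / `"region"`).
#' @return `path`, invisibly.
#' @export
write_gff <- function(x, path, source = "peakannot", type = "region") {
  x <- validate_regions(x)
  lines <- paste(x$chrom, source, type, x$start, x$end,
                 ifelse(is.na(x$score), ".", format(x$score, trim = TRUE)),
                 ifelse(x$strand == "*", ".", x$strand), ".",
                 paste0("ID=", x$name), sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Gap between two genomic intervals
#'
#' The gap is the number of bases strictly between two closed intervals:
#' 0 when they intersect or abut, `Inf` when they lie on different
#' chromosomes. Two regions overlap under `maxgap = g` iff their gap is
#' `<= g`, so `maxgap = 0` includes abutting intervals. Vectorized over
#' paired rows.
#'
#' @param a,b Region-set tibbles (or single-row regions) of equal length
#'   (shorter recycled).
#' @return Numeric vector of gaps (`Inf` across chromosomes).
#' @examples
#' a <- region_set("chr1", 100, 200, "a")
#' b <- region_set("chr1", 205, 300, "b")
#' region_gap(a, b)  # 4
#' @export
region_gap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  gap_bases(a$chrom[idx_a], a$start[idx_a], a$end[idx_a],
            b$chrom[idx_b], b$start[idx_b], b$end[idx_b])
}

gap_bases <- function(chrom1, start1, end1, chrom2, start2, end2) {
  g <- pmax(pmax(start1, start2) - pmin(end1, end2) - 1, 0)
  g[chrom1 != chrom2] <- Inf
  g
}
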