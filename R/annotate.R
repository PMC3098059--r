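#' Strand-aware transcription start site of features
#'
#' The TSS is the 5' boundary of a stranded feature: the `start` coordinate
#' on the `+` strand and the `end` coordinate on the `-` strand.
#' Unstranded (`*`) features are rejected, since a TSS is undefined
#' without an orientation.
#'
#' @param features A region-set tibble with `strand` in `+`/`-`.
#' @return The input tibble with an added integer `tss` column.
#' @examples
#' f <- region_set("chr1", 967659, 967869, "t1", strand = "+")
#' feature_tss(f)$tss  # 967659
#' @export
feature_tss <- function(features) {
  features <- validate_regions(features)
  if (any(features$strand == "*")) {
    abort(paste0(
      "TSS is undefined for unstranded features: ",
      paste(head(features$name[features$strand == "*"], 5), collapse = ", "),
      ". Supply stranded features (+/-)."))
  }
  mutate(features, tss = ifelse(.data$strand == "+", .data$start, .data$end))
}

#' Signed distance from peak start to a feature's TSS
#'
#' The distance is measured from the peak start to the feature TSS in the
#' feature's orientation: `peak_start - TSS` on the `+` strand and
#' `TSS - peak_start` on the `-` strand. Negative values mean the peak
#' start lies 5' (upstream) of the TSS; positive values 3' (downstream).
#' Vectorized over paired rows (shorter input recycled).
#'
#' @param peaks,features Region-set tibbles paired row-by-row; features
#'   must be stranded.
#' @return Integer vector of signed distances.
#' @export
signed_distance <- function(peaks, features) {
  check_stranded(features)
  n <- max(nrow(peaks), nrow(features))
  p <- peaks$start[rep_len(seq_len(nrow(peaks)), n)]
  f <- features[rep_len(seq_len(nrow(features)), n), ]
  tss <- ifelse(f$strand == "+", f$start, f$end)
  as.integer(ifelse(f$strand == "+", p - tss, tss - p))
}

check_stranded <- function(features) {
  if (any(features$strand == "*")) {
    abort(paste0(
      "unstranded feature(s): ",
      paste(head(features$name[features$strand == "*"], 5), collapse = ", "),
      ". Supply stranded features (+/-)."))
  }
  invisible(features)
}

#' Classify a peak's position relative to a stranded feature
#'
#' Assigns exactly one of six mutually exclusive classes: `upstream`
#' (no intersection, peak wholly on the feature's 5' side), `downstream`
#' (wholly 3'), `includeFeature` (peak covers the entire feature),
#' `overlapStart` (covers the 5' boundary only), `overlapEnd` (covers the
#' 3' boundary only) and `inside` (intersects but covers neither
#' boundary, i.e. the peak lies within the feature body). Boundaries are
#' strand-aware: the 5' boundary is `start` on `+` and `end` on `-`.
#' Vectorized over paired rows.
#'
#' @inheritParams signed_distance
#' @return Character vector of class labels.
#' @export
classify_relative_position <- function(peaks, features) {
  check_stranded(features)
  n <- max(nrow(peaks), nrow(features))
  ip <- rep_len(seq_len(nrow(peaks)), n)
  jf <- rep_len(seq_len(nrow(features)), n)
  ps <- peaks$start[ip]; pe <- peaks$end[ip]
  fs <- features$start[jf]; fe <- features$end[jf]
  plus <- features$strand[jf] == "+"
  five_p <- ifelse(plus, fs, fe)
  three_p <- ifelse(plus, fe, fs)
  intersects <- ps <= fe & fs <= pe
  covers5 <- ps <= five_p & five_p <= pe
  covers3 <- ps <= three_p & three_p <= pe
  left_of <- pe < fs   # peak entirely left of feature in genome coordinates
  right_of <- ps > fe
  wholly5 <- ifelse(plus, left_of, right_of)
  dplyr::case_when(
    !intersects & wholly5 ~ "upstream",
    !intersects ~ "downstream",
    covers5 & covers3 ~ "includeFeature",
    covers5 ~ "overlapStart",
    covers3 ~ "overlapEnd",
    TRUE ~ "inside"
  )
}

#' Annotate peaks with nearest and/or overlapping features
#'
#' For each peak, finds the feature whose TSS is nearest to the peak start
#' (`output = "nearest"`, rows tagged `NearestStart`), the features within
#' `maxgap` bases (`output = "overlapping"`, tagged `Overlapping`), or the
#' union of nearest rows and those overlapping rows whose feature is not
#' the peak's nearest feature (`output = "both"`). With
#' `multiple = FALSE`, only the overlapping feature with the smallest
#' absolute signed distance is kept per peak. Ties (nearest and
#' overlapping alike) break by smallest absolute distance, then upstream
#' (negative distance) before downstream, then feature name. Peaks are
#' treated as unstranded; peaks with no qualifying feature yield a row
#' with `NA` feature fields.
#'
#' @param peaks A region-set tibble of peaks (non-empty).
#' @param features A stranded region-set tibble (e.g. gene models from
#'   [read_gff()]).
#' @param output One of `"nearest"`, `"overlapping"`, `"both"`.
#' @param maxgap Maximum gap (bases strictly between) for two regions to
#'   count as overlapping; `0` includes abutting regions.
#' @param multiple Keep all overlapping features per peak (`TRUE`) or only
#'   the closest (`FALSE`).
#' @return A tibble with columns `peak`, `chrom`, `peak_start`,
#'   `peak_end`, `feature`, `feature_start`, `feature_end`,
#'   `feature_strand`, `insideFeature`, `distancetoFeature`,
#'   `fromOverlappingOrNearest`.
#' @examples
#' myexp <- region_set(chrom = c("1", "2", "3"),
#'                     start = c(967654, 2010897, 2496704),
#'                     end = c(967754, 2010997, 2496804),
#'                     name = c("Site1", "Site2", "Site3"))
#' lit <- region_set(chrom = c("1", "2", "3", "1", "2"),
#'                   start = c(967659, 2010898, 2496700, 3075866, 3123260),
#'                   end = c(967869, 2011108, 2496920, 3076166, 3123470),
#'                   name = c("t1", "t2", "t3", "t4", "t5"),
#'                   strand = c("1", "1", "-1", "-1", "1"))
#' annotate_peaks(myexp, lit, output = "overlapping")
#' @export
annotate_peaks <- function(peaks, features, output = c("nearest", "overlapping", "both"),
                           maxgap = 0L, multiple = FALSE) {
  output <- rlang::arg_match(output)
  peaks <- validate_regions(peaks)
  features <- validate_regions(features)
  if (nrow(peaks) == 0) abort("no peaks to annotate")
  if (nrow(features) == 0) abort("empty feature set")
  features <- feature_tss(features)
  if (maxgap < 0) abort("maxgap must be >= 0")

  nearest <- if (output %in% c("nearest", "both")) nearest_rows(peaks, features) else NULL
  overl <- if (output %in% c("overlapping", "both")) {
    overlap_rows(peaks, features, maxgap = maxgap, multiple = multiple)
  } else NULL

  res <- switch(output,
    nearest = nearest,
    overlapping = fill_unmatched(overl, peaks),
    both = {
      nearest_of <- stats::setNames(nearest$feature, nearest$peak)
      extra <- filter(overl, .data$feature != nearest_of[.data$peak])
      bind_rows(nearest, extra)
    })
  arrange(res, .data$chrom, .data$peak_start, .data$peak,
          .data$fromOverlappingOrNearest, .data$feature)
}

# one row per peak: feature with TSS nearest to peak start, via binary
# search over the per-chromosome sorted distinct TSS values (the nearest
# |peak_start - tss| is achieved at one of the two flanking values)
nearest_rows <- function(peaks, features) {
  out <- vector("list", length(unique(peaks$chrom)))
  chroms <- unique(peaks$chrom)
  for (i in seq_along(chroms)) {
    cc <- chroms[i]
    p <- filter(peaks, .data$chrom == cc)
    f <- filter(features, .data$chrom == cc)
    if (nrow(f) == 0) {
      out[[i]] <- unmatched_rows(p, "NearestStart")
      next
    }
    tss_vals <- sort(unique(f$tss))
    lo <- findInterval(p$start, tss_vals)
    cand_vals <- lapply(seq_len(nrow(p)), function(k) {
      v <- c(if (lo[k] >= 1) tss_vals[lo[k]], if (lo[k] < length(tss_vals)) tss_vals[lo[k] + 1])
      unique(v)
    })
    rows <- lapply(seq_len(nrow(p)), function(k) {
      cand <- filter(f, .data$tss %in% cand_vals[[k]])
      pick_closest(p[k, ], cand)
    })
    out[[i]] <- bind_rows(rows)
  }
  bind_rows(out) |> mutate(fromOverlappingOrNearest = "NearestStart")
}

overlap_rows <- function(peaks, features, maxgap, multiple) {
  hits <- overlap_hits(peaks, features, maxgap = maxgap)
  if (nrow(hits) == 0) {
    return(annotation_tibble(peaks[0, ], features[0, ], "Overlapping"))
  }
  p <- peaks[hits$qi, ]
  f <- features[hits$si, ]
  rows <- annotation_tibble(p, f, "Overlapping")
  if (!multiple) {
    rows <- rows |>
      group_by(.data$peak) |>
      arrange(abs(.data$distancetoFeature), .data$distancetoFeature, .data$feature,
              .by_group = TRUE) |>
      dplyr::slice(1) |>
      ungroup()
  }
  rows
}

# per-chromosome IRanges overlap query honouring the closed-interval gap rule
overlap_hits <- function(a, b, maxgap) {
  shared <- intersect(unique(a$chrom), unique(b$chrom))
  res <- list()
  for (cc in shared) {
    ia <- which(a$chrom == cc)
    ib <- which(b$chrom == cc)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(a$start[ia], a$end[ia]),
      IRanges::IRanges(b$start[ib], b$end[ib]),
      maxgap = maxgap)
    res[[cc]] <- tibble(qi = ia[S4Vectors::queryHits(hits)],
                        si = ib[S4Vectors::subjectHits(hits)])
  }
  if (length(res) == 0) tibble(qi = integer(), si = integer()) else bind_rows(res)
}

pick_closest <- function(peak, cand) {
  d <- signed_distance(peak[rep(1, nrow(cand)), ], cand)
  ord <- order(abs(d), d, cand$name)
  annotation_tibble(peak, cand[ord[1], ], "NearestStart")
}

annotation_tibble <- function(p, f, tag) {
  tibble(
    peak = p$name, chrom = p$chrom, peak_start = p$start, peak_end = p$end,
    feature = f$name, feature_start = f$start, feature_end = f$end,
    feature_strand = f$strand,
    insideFeature = if (nrow(p) == 0) character() else classify_relative_position(p, f),
    distancetoFeature = if (nrow(p) == 0) integer() else signed_distance(p, f),
    fromOverlappingOrNearest = rep_len(tag, nrow(p))
  )
}

unmatched_rows <- function(p, tag) {
  tibble(
    peak = p$name, chrom = p$chrom, peak_start = p$start, peak_end = p$end,
    feature = NA_character_, feature_start = NA_integer_,
    feature_end = NA_integer_, feature_strand = NA_character_,
    insideFeature = NA_character_, distancetoFeature = NA_integer_,
    fromOverlappingOrNearest = rep_len(tag, nrow(p))
  )
}

fill_unmatched <- function(rows, peaks) {
  missed <- filter(peaks, !.data$name %in% rows$peak)
  bind_rows(rows, unmatched_rows(missed, "Overlapping"))
}

#' Histogram bins of nearest-TSS distances
#'
#' Bins the signed distances of `NearestStart` rows (rows with undefined
#' distances are dropped first) into half-open bins `[edge_i, edge_{i+1})`.
#' Values falling outside the break range are counted in separate
#' `underflow`/`overflow` rows so that total counts always equal the
#' number of binned rows.
#'
#' @param rows An annotation tibble from [annotate_peaks()].
#' @param breaks Strictly increasing numeric vector of bin edges.
#' @return A tibble with columns `type` (`bin`, `underflow`, `overflow`),
#'   `lower`, `upper`, `count`.
#' @export
distance_histogram <- function(rows, breaks) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    abort("breaks must be strictly increasing")
  }
  if (length(breaks) < 2) abort("need at least two bin edges")
  d <- rows$distancetoFeature[rows$fromOverlappingOrNearest == "NearestStart" &
                                !is.na(rows$distancetoFeature)]
  k <- length(breaks) - 1
  idx <- findInterval(d, breaks, left.open = FALSE)  # [edge_i, edge_{i+1})
  counts <- tabulate(idx[idx >= 1 & idx <= k & d < breaks[k + 1]], nbins = k)
  bind_rows(
    tibble(type = "underflow", lower = -Inf, upper = breaks[1],
           count = sum(d < breaks[1])),
    tibble(type = "bin", lower = breaks[-(k + 1)], upper = breaks[-1],
           count = counts),
    tibble(type = "overflow", lower = breaks[k + 1], upper = Inf,
           count = sum(d >= breaks[k + 1]))
  )
}

#' Count peaks by relative-position class
#'
#' Each peak is counted once per kept row: `Overlapping` rows are always
#' kept, while `NearestStart` rows are kept only for peaks that have no
#' `Overlapping` row. Counts are keyed by the `insideFeature` class. With
#' `multiple = TRUE` annotations a peak can contribute several
#' `Overlapping` rows, so the total may exceed the number of distinct
#' peaks.
#'
#' @param rows An annotation tibble from one [annotate_peaks()] call.
#' @return A tibble with columns `insideFeature`, `count`.
#' @export
relative_position_counts <- function(rows) {
  overlapping_peaks <- unique(rows$peak[rows$fromOverlappingOrNearest == "Overlapping"])
  kept <- filter(rows, .data$fromOverlappingOrNearest == "Overlapping" |
                   (.data$fromOverlappingOrNearest == "NearestStart" &
                      !.data$peak %in% overlapping_peaks))
  kept <- filter(kept, !is.na(.data$insideFeature))
  count(kept, .data$insideFeature, name = "count")
}
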