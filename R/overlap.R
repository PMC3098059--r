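#' Find overlapping peak pairs between two region sets
#'
#' Returns every pair of regions (one from each set) whose gap is at most
#' `maxgap`, together with the merged peak spanning both. With
#' `multiple = FALSE`, only the pair with the smallest gap is kept per
#' set-1 peak (ties: leftmost set-2 start, then set-2 name).
#'
#' @param set1,set2 Region-set tibbles.
#' @param maxgap Maximum gap (bases strictly between) to still count as
#'   overlapping; `0` includes abutting regions.
#' @param multiple Keep all pairs per set-1 peak (`TRUE`) or only the
#'   closest (`FALSE`).
#' @return A tibble with columns `peak1`, `peak2`, `chrom`,
#'   `merged_start`, `merged_end`, `merged_name` (`"<peak1>;<peak2>"`),
#'   `gap`.
#' @examples
#' a <- region_set("chr1", 100, 200, "a1")
#' b <- region_set("chr1", 150, 250, "b1")
#' find_overlapping_pairs(a, b)
#' @export
find_overlapping_pairs <- function(set1, set2, maxgap = 0L, multiple = TRUE) {
  set1 <- validate_regions(set1)
  set2 <- validate_regions(set2)
  hits <- overlap_hits(set1, set2, maxgap = maxgap)
  p1 <- set1[hits$qi, ]
  p2 <- set2[hits$si, ]
  out <- tibble(
    peak1 = p1$name, peak2 = p2$name, chrom = p1$chrom,
    merged_start = pmin(p1$start, p2$start),
    merged_end = pmax(p1$end, p2$end),
    merged_name = paste(p1$name, p2$name, sep = ";"),
    gap = gap_bases(p1$chrom, p1$start, p1$end, p2$chrom, p2$start, p2$end)
  )
  if (!multiple && nrow(out) > 0) {
    out <- out |>
      group_by(.data$peak1) |>
      arrange(.data$gap, .data$merged_start, .data$peak2, .by_group = TRUE) |>
      dplyr::slice(1) |>
      ungroup()
  }
  arrange(out, .data$chrom, .data$merged_start, .data$peak1)
}

#' Merge regions across sets into connected components
#'
#' Builds the graph over all regions of all sets with an edge wherever
#' the gap is at most `maxgap`, and returns its connected components.
#' Each component carries the minimal spanning region covering all its
#' members and the membership pattern recording which sets contribute at
#' least one region (e.g. `"110"` for sets 1 and 2 of 3). Overlap is
#' transitive through chains: regions that never directly touch can share
#' a component.
#'
#' @param sets A named list of >= 1 region-set tibbles; names (or `label`
#'   attributes) become the pattern digits' set labels.
#' @param maxgap Maximum gap for two regions to be connected.
#' @return A list with `components` (tibble: `component`, `chrom`,
#'   `start`, `end`, `pattern`, `n_members`) and `members` (tibble:
#'   `component`, `set`, `name`, `chrom`, `start`, `end`).
#' @export
merge_connected <- function(sets, maxgap = 0L) {
  sets <- as_labelled_sets(sets)
  labels <- names(sets)
  pooled <- bind_rows(lapply(labels, function(l) mutate(sets[[l]], set = l)))
  if (nrow(pooled) == 0) {
    return(list(components = tibble(component = integer(), chrom = character(),
                                    start = integer(), end = integer(),
                                    pattern = character(), n_members = integer()),
                members = tibble(component = integer(), set = character(),
                                 name = character(), chrom = character(),
                                 start = integer(), end = integer())))
  }
  # on one chromosome the components of the interval graph are exactly the
  # clusters of reduce() with min.gapwidth = maxgap + 1
  pooled <- arrange(pooled, .data$chrom, .data$start, .data$end, .data$name)
  comp <- integer(nrow(pooled))
  offset <- 0L
  for (cc in unique(pooled$chrom)) {
    i <- which(pooled$chrom == cc)
    ir <- IRanges::IRanges(pooled$start[i], pooled$end[i])
    red <- IRanges::reduce(ir, min.gapwidth = maxgap + 1L)
    hit <- IRanges::findOverlaps(ir, red, maxgap = maxgap)
    stopifnot(length(hit) >= length(ir))
    cl <- S4Vectors::subjectHits(hit)[match(seq_along(ir), S4Vectors::queryHits(hit))]
    comp[i] <- cl + offset
    offset <- offset + length(red)
  }
  pooled$component <- comp
  components <- pooled |>
    group_by(.data$component) |>
    summarise(chrom = .data$chrom[1],
              start = min(.data$start), end = max(.data$end),
              pattern = paste0(as.integer(labels %in% .data$set), collapse = ""),
              n_members = n(), .groups = "drop") |>
    arrange(.data$chrom, .data$start)
  members <- select(pooled, "component", "set", "name", "chrom", "start", "end")
  list(components = components, members = members)
}

as_labelled_sets <- function(sets) {
  if (is.data.frame(sets)) sets <- list(sets)
  labels <- names(sets) %||% rep("", length(sets))
  for (i in seq_along(sets)) {
    if (!nzchar(labels[i])) {
      labels[i] <- attr(sets[[i]], "label") %||% paste0("set", i)
    }
    sets[[i]] <- validate_regions(sets[[i]])
  }
  if (anyDuplicated(labels)) abort("set labels must be unique")
  stats::setNames(sets, labels)
}

#' Hypergeometric upper-tail overlap p-value
#'
#' Significance of observing at least `k` shared peaks between two sets of
#' `n1` and `n2` peaks drawn from a universe of `total_test` potential
#' peaks: `P(X >= k)` with `X ~ Hypergeometric(total_test, n1, n2)`,
#' computed as an exact tail.
#'
#' @param n1,n2 Number of peaks in each set.
#' @param k Observed overlap count.
#' @param total_test Universe size (number of potential peak locations);
#'   a required study parameter, not estimated from the data.
#' @return The p-value in `[0, 1]`.
#' @examples
#' hypergeom_overlap_pvalue(n1 = 4, n2 = 5, k = 4, total_test = 10)  # 6/252
#' @export
hypergeom_overlap_pvalue <- function(n1, n2, k, total_test) {
  if (k < 0 || k > min(n1, n2)) abort("need 0 <= k <= min(n1, n2)")
  if (n1 > total_test || n2 > total_test) abort("set sizes cannot exceed total_test")
  phyper(k - 1, m = n1, n = total_test - n1, k = n2, lower.tail = FALSE)
}

#' Venn cell counts and pairwise overlap significance
#'
#' Pools 2 or 3 region sets, forms connected components under `maxgap`
#' ([merge_connected()]), and counts components per membership pattern
#' (the Venn cells). For each pair of sets, the two sets are re-merged
#' alone and an upper-tail hypergeometric p-value is computed from the
#' pair's component counts: `n_i` components involving set i, `n_j`
#' likewise, `k` components containing both, universe `total_test`. A
#' component counts once per cell regardless of how many regions it holds
#' (`count_mode = "component"`); `count_mode = "set1"` counts the first
#' set's member peaks instead.
#'
#' @param sets A named list of 2 or 3 region-set tibbles.
#' @param maxgap Maximum gap for two regions to be connected.
#' @param total_test Universe size for the hypergeometric test; must be at
#'   least the largest per-pair component count.
#' @param count_mode `"component"` (default) or `"set1"`.
#' @return An object of class `venn_report`: a list with `labels`,
#'   `cell_counts` (tibble `pattern`, `count`), `pairwise` (tibble
#'   `set1`, `set2`, `n1`, `n2`, `k`, `p_value`), `total_test`, and the
#'   `merge` result.
#' @export
venn_report <- function(sets, maxgap = 0L, total_test, count_mode = c("component", "set1")) {
  count_mode <- rlang::arg_match(count_mode)
  sets <- as_labelled_sets(sets)
  if (length(sets) < 2 || length(sets) > 3) {
    abort("venn_report supports 2 or 3 sets")
  }
  labels <- names(sets)
  merged <- merge_connected(sets, maxgap = maxgap)
  cell_counts <- if (count_mode == "component") {
    count(merged$components, .data$pattern, name = "count")
  } else {
    merged$members |>
      left_join(select(merged$components, "component", "pattern"), by = "component") |>
      filter(.data$set == labels[1]) |>
      count(.data$pattern, name = "count")
  }
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  pairwise <- bind_rows(lapply(pairs, function(pr) {
    m <- merge_connected(sets[pr], maxgap = maxgap)
    pat <- m$components$pattern
    n1 <- sum(substr(pat, 1, 1) == "1")
    n2 <- sum(substr(pat, 2, 2) == "1")
    k <- sum(pat == "11")
    if (total_test < max(n1, n2)) {
      abort("total_test must be at least the per-pair component counts")
    }
    tibble(set1 = pr[1], set2 = pr[2], n1 = n1, n2 = n2, k = k,
           p_value = hypergeom_overlap_pvalue(n1, n2, k, total_test))
  }))
  structure(
    list(labels = labels, cell_counts = cell_counts, pairwise = pairwise,
         total_test = total_test, merge = merged),
    class = "venn_report")
}

#' @export
print.venn_report <- function(x, ...) {
  cat("Venn overlap report for sets:", paste(x$labels, collapse = ", "),
      "(totalTest =", x$total_test, ")\n\nCell counts:\n")
  print(as.data.frame(x$cell_counts), row.names = FALSE)
  cat("\nPairwise hypergeometric tests:\n")
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}

#' Tidy a Venn overlap report
#'
#' `tidy()` returns the pairwise hypergeometric tests, one row per set
#' pair; `glance()` returns a one-row summary.
#'
#' @param x A `venn_report` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.venn_report <- function(x, ...) {
  x$pairwise
}

#' @rdname tidy.venn_report
#' @export
glance.venn_report <- function(x, ...) {
  tibble(
    n_sets = length(x$labels),
    n_components = nrow(x$merge$components),
    n_shared_all = sum(x$merge$components$pattern == strrep("1", length(x$labels))),
    total_test = x$total_test,
    min_p_value = suppressWarnings(min(x$pairwise$p_value))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
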