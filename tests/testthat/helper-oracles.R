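# Brute-force oracles and fixture builders, independent of the package
# internals: gaps, distances and classes are recomputed inline from first
# principles so the tests check two separate derivations.

# the three-peak experiment and five literature sites used throughout
toy_peaks <- function() {
  region_set(chrom = c("1", "2", "3"),
             start = c(967654, 2010897, 2496704),
             end = c(967754, 2010997, 2496804),
             name = c("Site1", "Site2", "Site3"))
}

toy_features <- function() {
  region_set(chrom = c("1", "2", "3", "1", "2"),
             start = c(967659, 2010898, 2496700, 3075866, 3123260),
             end = c(967869, 2011108, 2496920, 3076166, 3123470),
             name = c("t1", "t2", "t3", "t4", "t5"),
             strand = c("1", "1", "-1", "-1", "1"))
}

oracle_gap <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(Inf)
  if (s1 <= e2 && s2 <= e1) return(0)          # intersect
  max(max(s1, s2) - min(e1, e2) - 1, 0)        # bases strictly between
}

oracle_tss <- function(f) if (f$strand == "+") f$start else f$end

oracle_signed_distance <- function(p, f) {
  tss <- oracle_tss(f)
  if (f$strand == "+") p$start - tss else tss - p$start
}

# per peak: argmin of |d| over same-chromosome features, ties by
# (|d|, d, feature name); NA row when no feature shares the chromosome
oracle_nearest <- function(peaks, features) {
  lapply(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    f <- features[features$chrom == p$chrom, ]
    if (nrow(f) == 0) return(list(peak = p$name, feature = NA_character_, d = NA_integer_))
    d <- vapply(seq_len(nrow(f)), function(j) oracle_signed_distance(p, f[j, ]), 1)
    ord <- order(abs(d), d, f$name)
    list(peak = p$name, feature = f$name[ord[1]], d = d[ord[1]])
  })
}

# all (peak, feature) pairs with gap <= maxgap
oracle_overlap_pairs <- function(peaks, features, maxgap) {
  out <- list()
  for (i in seq_len(nrow(peaks))) for (j in seq_len(nrow(features))) {
    g <- oracle_gap(peaks$chrom[i], peaks$start[i], peaks$end[i],
                    features$chrom[j], features$start[j], features$end[j])
    if (g <= maxgap) out[[length(out) + 1]] <- c(peaks$name[i], features$name[j])
  }
  out
}

# union-find over the full pairwise gap matrix of pooled regions
oracle_components <- function(pooled, maxgap) {
  n <- nrow(pooled)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      g <- oracle_gap(pooled$chrom[i], pooled$start[i], pooled$end[i],
                      pooled$chrom[j], pooled$start[j], pooled$end[j])
      if (g <= maxgap) parent[find(i)] <- find(j)
    }
  }
  vapply(seq_len(n), find, 1L)
}

# exact upper hypergeometric tail by summation over choose()
oracle_hyper_tail <- function(N, K, n, k) {
  j <- seq(k, min(K, n))
  if (length(j) == 0 || k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Benjamini-Hochberg step-up computed from its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# naive FASTA reader: concatenate lines per record, no Biostrings
naive_read_fasta <- function(path) {
  lines <- readLines(path)
  idx <- grepl("^>", lines)
  rec <- cumsum(idx)
  ids <- sub("^>(\\S+).*$", "\\1", lines[idx])
  seqs <- vapply(split(lines[!idx], rec[!idx]), paste, "", collapse = "")
  stats::setNames(unname(seqs), ids)
}

random_regions <- function(n, max_coord = 2000, chroms = c("c1", "c2"),
                           stranded = FALSE, prefix = "r") {
  start <- sample.int(max_coord, n, replace = TRUE)
  width <- sample.int(max(max_coord %/% 10, 1), n, replace = TRUE)
  region_set(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width - 1L,
             name = paste0(prefix, seq_len(n)),
             strand = if (stranded) sample(c("+", "-"), n, replace = TRUE) else "*")
}
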