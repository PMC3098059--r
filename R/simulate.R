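#' Deterministic synthetic genomes, gene models, peak sets and GO maps
#'
#' These generators stand in for real annotation data in tests and
#' examples. One seed drives everything; each generator draws from its
#' own deterministic substream (derived from the seed and a fixed
#' per-generator tag) so adding a generator never shifts the output of
#' another. Identical arguments and seed give byte-identical output.
#'
#' `simulate_genome()` draws uniform A/C/G/T bases; chromosomes are named
#' `chr1`, `chr2`, ....
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bases (recycled).
#' @param seed Integer seed.
#' @return `simulate_genome()`: a `DNAStringSet` usable wherever
#'   [load_genome()] output is.
#' @name simulate
#' @export
simulate_genome <- function(n_chroms = 1L, chrom_length = 10000L, seed = 1L) {
  if (any(chrom_length < 1)) abort("chromosome lengths must be >= 1")
  len <- rep_len(as.integer(chrom_length), n_chroms)
  with_substream(seed, "genome", {
    seqs <- vapply(len, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
    g <- Biostrings::DNAStringSet(seqs)
    names(g) <- paste0("chr", seq_len(n_chroms))
    g
  })
}

#' @rdname simulate
#' @param n_genes Number of genes to place (spread across chromosomes).
#' @param gene_length Length range `c(min, max)` for each gene.
#' @param prob_plus Probability of the `+` strand.
#' @param genome_lengths Named integer vector of chromosome lengths (e.g.
#'   [genome_lengths()] of a simulated genome).
#' @param min_gap Minimum number of bases strictly between consecutive
#'   genes (default 1).
#' @return `simulate_genes()`: a stranded region-set tibble of
#'   non-overlapping genes named `g0001`, `g0002`, ....
#' @export
simulate_genes <- function(n_genes = 20L, gene_length = c(200L, 500L),
                           prob_plus = 0.5, genome_lengths = c(chr1 = 10000L),
                           min_gap = 1L, seed = 1L) {
  with_substream(seed, "genes", {
    chroms <- rep_len(names(genome_lengths), n_genes)
    rows <- lapply(names(genome_lengths), function(cc) {
      n_here <- sum(chroms == cc)
      if (n_here == 0) return(NULL)
      L <- genome_lengths[[cc]]
      widths <- sample_range(gene_length[1], gene_length[2], n_here)
      # place left to right with >= min_gap bases between consecutive genes
      slack <- L - sum(widths) - (n_here - 1L) * min_gap
      if (slack < 0) {
        abort(paste0("cannot pack ", n_here, " genes of total width ",
                     sum(widths), " into ", cc, " (length ", L, ")"))
      }
      gaps <- if (slack > 0) {
        cuts <- sort(sample.int(slack + 1L, n_here, replace = TRUE) - 1L)
        diff(c(0L, cuts))
      } else rep(0L, n_here)
      starts <- 1L + c(0L, cumsum(widths[-n_here])) +
        (seq_len(n_here) - 1L) * min_gap + cumsum(gaps)
      tibble(chrom = cc, start = as.integer(starts),
             end = as.integer(starts + widths - 1L))
    })
    genes <- bind_rows(rows)
    genes$strand <- ifelse(stats::runif(nrow(genes)) < prob_plus, "+", "-")
    genes$name <- sprintf("g%04d", seq_len(nrow(genes)))
    validate_regions(genes)
  })
}

#' @rdname simulate
#' @param n_peaks Number of peaks.
#' @param peak_width Peak width range `c(min, max)`.
#' @param mode Placement mode: `"uniform"` samples non-overlapping slots
#'   on a slot grid of width `max(peak_width)` (the grid defines the
#'   `totalTest` universe of potential peak locations, see
#'   [n_slots()]); `"planted_offset"` places each peak start exactly
#'   `offset` bases 5' of a randomly chosen gene's TSS (strand-aware), so
#'   nearest-TSS annotation recovers `distancetoFeature == -offset`
#'   exactly; `"planted_overlap"` makes a fraction `overlap_fraction` of
#'   the peaks intersect a member of `partner` and places the rest
#'   disjointly from it.
#' @param genes Stranded region set (required for `planted_offset`).
#' @param offset Planted 5' offset in bases.
#' @param partner Region set to overlap (required for `planted_overlap`).
#' @param overlap_fraction Fraction of peaks that must intersect `partner`.
#' @param label Optional set label.
#' @return `simulate_peaks()`: a region-set tibble of peaks named
#'   `peak_1`, `peak_2`, ....
#' @export
simulate_peaks <- function(n_peaks = 50L, peak_width = c(100L, 100L),
                           mode = c("uniform", "planted_offset", "planted_overlap"),
                           genome_lengths = c(chr1 = 10000L),
                           genes = NULL, offset = 0L,
                           partner = NULL, overlap_fraction = 0.8,
                           seed = 1L, label = NULL) {
  mode <- rlang::arg_match(mode)
  wmax <- as.integer(max(peak_width))
  with_substream(seed, paste0("peaks_", mode), {
    peaks <- switch(mode,
      uniform = {
        chroms <- rep_len(names(genome_lengths), n_peaks)
        stride <- wmax + 1L  # one spacer base so distinct slots never abut
        rows <- lapply(names(genome_lengths), function(cc) {
          n_here <- sum(chroms == cc)
          if (n_here == 0) return(NULL)
          slots <- genome_lengths[[cc]] %/% stride
          if (slots < n_here) abort(paste0("not enough slots on ", cc))
          slot <- sort(sample.int(slots, n_here))
          w <- sample_range(peak_width[1], peak_width[2], n_here)
          start <- (slot - 1L) * stride + 1L
          tibble(chrom = cc, start = as.integer(start),
                 end = as.integer(start + w - 1L))
        })
        bind_rows(rows)
      },
      planted_offset = {
        if (is.null(genes) || nrow(genes) == 0) {
          abort("planted_offset mode needs gene models")
        }
        g <- feature_tss(genes)
        g <- g[g$strand == "-" | g$tss - offset >= 1L, ]  # keep starts >= 1
        if (nrow(g) == 0) abort("no gene admits the requested planted offset")
        pick <- g[sample.int(nrow(g), n_peaks, replace = TRUE), ]
        w <- sample_range(peak_width[1], peak_width[2], n_peaks)
        start <- ifelse(pick$strand == "+", pick$tss - offset, pick$tss + offset)
        tibble(chrom = pick$chrom, start = as.integer(start),
               end = as.integer(start + w - 1L))
      },
      planted_overlap = {
        if (is.null(partner) || nrow(partner) == 0) {
          abort("planted_overlap mode needs a partner set")
        }
        partner <- validate_regions(partner)
        n_hit <- round(n_peaks * overlap_fraction)
        pick <- partner[sample.int(nrow(partner), n_hit, replace = TRUE), ]
        w <- sample_range(peak_width[1], peak_width[2], n_peaks)
        # overlapping peaks start inside the chosen partner region
        hit_start <- pick$start + vapply(pick$end - pick$start + 1L, function(u)
          sample.int(u, 1L) - 1L, 1L)
        hit <- tibble(chrom = pick$chrom, start = as.integer(hit_start),
                      end = as.integer(hit_start + w[seq_len(n_hit)] - 1L))
        n_free <- n_peaks - n_hit
        free <- if (n_free > 0) {
          place_disjoint(n_free, w[n_hit + seq_len(n_free)], genome_lengths, partner)
        }
        bind_rows(hit, free)
      })
    peaks$name <- paste0("peak_", seq_len(nrow(peaks)))
    validate_regions(peaks, label = label)
  })
}

# rejection-sample peaks that neither intersect `avoid` nor leave the genome
place_disjoint <- function(n, widths, genome_lengths, avoid) {
  out <- vector("list", n)
  chroms <- rep_len(names(genome_lengths), n)
  for (i in seq_len(n)) {
    cc <- chroms[i]
    L <- genome_lengths[[cc]]
    av <- filter(avoid, .data$chrom == cc)
    for (try in 1:10000) {
      s <- sample.int(L - widths[i] + 1L, 1L)
      e <- s + widths[i] - 1L
      if (nrow(av) == 0 || all(e < av$start | s > av$end)) break
      if (try == 10000) abort("could not place a disjoint peak")
    }
    out[[i]] <- tibble(chrom = cc, start = as.integer(s), end = as.integer(e))
  }
  bind_rows(out)
}

#' @rdname simulate
#' @param chrom_length_one Length of the chromosome carrying the slot grid.
#' @param width Slot (maximum peak) width; slots are separated by one
#'   spacer base so peaks in distinct slots never overlap or abut.
#' @return `n_slots()`: the number of placeable peak slots, suitable as
#'   `total_test` for [venn_report()] on uniformly simulated sets.
#' @export
n_slots <- function(chrom_length_one, width) {
  as.integer(chrom_length_one %/% (width + 1L))
}

#' @rdname simulate
#' @param n_terms Number of GO terms per aspect split (terms are assigned
#'   round-robin to aspects BP/MF/CC).
#' @param annotation_prob Probability that a given gene carries a given
#'   term.
#' @param gene_ids Gene identifiers for the universe.
#' @return `simulate_go_map()`: a `go_map` object.
#' @export
simulate_go_map <- function(gene_ids, n_terms = 30L, annotation_prob = 0.1,
                            seed = 1L) {
  with_substream(seed, "gomap", {
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    aspects <- rep_len(c("BP", "MF", "CC"), n_terms)
    pairs <- expand.grid(gene = gene_ids, j = seq_len(n_terms),
                         stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(pairs)) < annotation_prob
    mapping <- tibble(gene = pairs$gene[keep],
                      term = terms[pairs$j[keep]],
                      aspect = aspects[pairs$j[keep]])
    # guarantee every gene is in each aspect's universe
    anchor <- tidyr::crossing(gene = gene_ids,
                              tibble(term = terms[1:3], aspect = aspects[1:3]))
    go_map(bind_rows(mapping, anchor))
  })
}

# uniform draw from an integer range; safe when lo == hi (unlike sample())
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else sample(seq(lo, hi), n, replace = TRUE)
}

# deterministic substream: a generator tag hashed with the seed; keeps
# independent generators independent under one global seed
with_substream <- function(seed, tag, code) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 10000L
  withr::with_seed(as.integer(seed) %% 100000000L * 10L + h %% 10L + h, code)
}
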