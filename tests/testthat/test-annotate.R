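test_that("the TSS is the strand-aware 5' boundary", {
  f <- region_set(chrom = c("chr1", "chr3", "c"), start = c(967659, 2496700, 7),
                  end = c(967869, 2496920, 7), name = c("t1", "t3", "w1"),
                  strand = c("+", "-", "+"))
  tss <- feature_tss(f)
  expect_equal(tss$tss[tss$name == "t1"], 967659)
  expect_equal(tss$tss[tss$name == "t3"], 2496920)
  expect_equal(tss$tss[tss$name == "w1"], 7)  # width-1: start == end
  expect_error(feature_tss(region_set("c", 1, 5, "u")), "unstranded")
})

test_that("signed distances follow the feature orientation", {
  site1 <- toy_peaks()[toy_peaks()$name == "Site1", ]
  site3 <- toy_peaks()[toy_peaks()$name == "Site3", ]
  t1 <- toy_features()[toy_features()$name == "t1", ]
  t3 <- toy_features()[toy_features()$name == "t3", ]
  expect_equal(signed_distance(site1, t1), -5L)
  expect_equal(signed_distance(site3, t3), 216L)
  # peak start at the TSS gives 0 on either strand
  p <- region_set("c", 500, 600, "p")
  expect_equal(signed_distance(p, region_set("c", 500, 800, "fp", strand = "+")), 0L)
  expect_equal(signed_distance(p, region_set("c", 200, 500, "fm", strand = "-")), 0L)
  expect_error(signed_distance(p, region_set("c", 1, 5, "u")), "unstranded")
})

test_that("relative-position classes match the worked coordinates", {
  expect_equal(classify_relative_position(
    region_set("1", 967654, 967754, "Site1"),
    region_set("1", 967659, 967869, "t1", strand = "+")), "overlapStart")
  expect_equal(classify_relative_position(
    region_set("3", 2496704, 2496804, "Site3"),
    region_set("3", 2496700, 2496920, "t3", strand = "-")), "inside")
  expect_equal(classify_relative_position(
    region_set("c", 1, 1000, "p"),
    region_set("c", 400, 600, "f", strand = "+")), "includeFeature")
  # on the minus strand a peak left of the feature is past its 3' end
  expect_equal(classify_relative_position(
    region_set("c", 100, 200, "p"),
    region_set("c", 300, 400, "f", strand = "-")), "downstream")
})

test_that("classification is exhaustive and exclusive over all small pairs", {
  iv <- expand.grid(s = 1:10, e = 1:10)
  iv <- iv[iv$s <= iv$e, ]
  classes <- c("upstream", "downstream", "inside", "overlapStart",
               "overlapEnd", "includeFeature")
  for (strand in c("+", "-")) {
    peaks <- region_set("c", iv$s, iv$e, paste0("p", seq_len(nrow(iv))))
    for (j in seq_len(nrow(iv))) {
      f <- region_set("c", iv$s[j], iv$e[j], "f", strand = strand)
      cl <- classify_relative_position(peaks, f[rep(1, nrow(iv)), ])
      expect_true(all(cl %in% classes))
      intersects <- peaks$start <= f$end & f$start <= peaks$end
      expect_equal(cl %in% c("upstream", "downstream"), !intersects)
      expect_equal(cl == "includeFeature",
                   peaks$start <= f$start & peaks$end >= f$end)
    }
  }
})

test_that("mirror reflection with strand flip preserves classes and distances", {
  withr::local_seed(42)
  for (rep in 1:25) {
    p <- random_regions(8, max_coord = 500, chroms = "c", prefix = "p")
    f <- random_regions(8, max_coord = 500, chroms = "c", stranded = TRUE,
                        prefix = "f")
    M <- 2000L
    mirror <- function(x) {
      y <- x
      y$start <- M - x$end
      y$end <- M - x$start
      y$strand <- c("+" = "-", "-" = "+", "*" = "*")[x$strand]
      validate_regions(y)[match(x$name, validate_regions(y)$name), ]
    }
    pm <- mirror(p); fm <- mirror(f)
    expect_equal(classify_relative_position(pm, fm),
                 classify_relative_position(p, f))
    # for width-1 peaks the signed distance is exactly mirror-invariant
    # (for wider peaks the anchor moves from start to end under reflection)
    pt <- p; pt$end <- pt$start
    expect_equal(signed_distance(mirror(pt), fm), signed_distance(pt, f))
  }
})

test_that("nearest annotation matches the brute-force argmin oracle", {
  withr::local_seed(7)
  for (rep in 1:60) {
    peaks <- random_regions(sample(1:30, 1), prefix = "p")
    features <- random_regions(sample(1:30, 1), stranded = TRUE, prefix = "f")
    got <- annotate_peaks(peaks, features, output = "nearest")
    expect_equal(nrow(got), nrow(peaks))
    want <- oracle_nearest(peaks, features)
    for (w in want) {
      row <- got[got$peak == w$peak, ]
      expect_equal(row$feature, w$feature)
      expect_equal(row$distancetoFeature, as.integer(w$d))
    }
  }
})

test_that("overlap annotation matches brute-force gap filtering", {
  withr::local_seed(8)
  for (rep in 1:60) {
    maxgap <- sample(c(0L, 5L, 50L), 1)
    peaks <- random_regions(sample(1:25, 1), prefix = "p")
    features <- random_regions(sample(1:25, 1), stranded = TRUE, prefix = "f")
    got <- annotate_peaks(peaks, features, output = "overlapping",
                          maxgap = maxgap, multiple = TRUE)
    want <- oracle_overlap_pairs(peaks, features, maxgap)
    got_pairs <- got[!is.na(got$feature), c("peak", "feature")]
    expect_setequal(paste(got_pairs$peak, got_pairs$feature),
                    vapply(want, paste, "", collapse = " "))
    # peaks with no qualifying overlap keep a row with empty feature fields
    expect_setequal(got$peak, peaks$name)
  }
})

test_that("multiple = FALSE keeps the closest overlapping feature only", {
  peaks <- region_set("c", 500, 600, "p")
  features <- region_set("c", c(480, 550, 590), c(520, 650, 820),
                         c("far", "near", "mid"), strand = c("+", "+", "+"))
  # |d| to TSSs 480, 550, 590 from peak start 500: 20, 50, 90
  got <- annotate_peaks(peaks, features, output = "overlapping", multiple = FALSE)
  expect_equal(nrow(got), 1L)
  expect_equal(got$feature, "far")
  all3 <- annotate_peaks(peaks, features, output = "overlapping", multiple = TRUE)
  expect_setequal(all3$feature, c("far", "near", "mid"))
})

test_that("output = 'both' unions nearest rows with non-nearest overlaps", {
  # identical peak and feature: single NearestStart row, d = 0, includeFeature
  p <- region_set("c", 100, 200, "p")
  f <- region_set("c", 100, 200, "f", strand = "+")
  got <- annotate_peaks(p, f, output = "both")
  expect_equal(nrow(got), 1L)
  expect_equal(got$fromOverlappingOrNearest, "NearestStart")
  expect_equal(got$distancetoFeature, 0L)
  expect_equal(got$insideFeature, "includeFeature")
  # a second overlapping feature that is not the nearest appears as Overlapping
  f2 <- region_set("c", c(100, 150), c(200, 400), c("f", "g"), strand = "+")
  got2 <- annotate_peaks(p, f2, output = "both", multiple = TRUE)
  expect_equal(nrow(got2), 2L)
  expect_equal(got2$feature[got2$fromOverlappingOrNearest == "Overlapping"], "g")
})

test_that("annotation handles peaks on chromosomes absent from features", {
  peaks <- region_set(c("c1", "cX"), c(100, 100), c(200, 200), c("a", "b"))
  features <- region_set("c1", 150, 400, "f", strand = "+")
  got <- annotate_peaks(peaks, features, output = "nearest")
  expect_equal(nrow(got), 2L)
  expect_true(is.na(got$feature[got$peak == "b"]))
  expect_error(annotate_peaks(peaks, features[0, ], output = "nearest"), "empty")
})

test_that("distance histogram bins are half-open with separate overflow", {
  # distances {-5, 216} with breaks (-100, 0, 100, 300) bin as (1, 0, 1)
  two <- tibble::tibble(distancetoFeature = c(-5L, 216L),
                        fromOverlappingOrNearest = "NearestStart")
  expect_equal(distance_histogram(two, c(-100, 0, 100, 300))$count,
               c(0L, 1L, 0L, 1L, 0L))
  rows <- annotate_peaks(toy_peaks(), toy_features(), output = "nearest")
  h <- distance_histogram(rows, breaks = c(-100, 0, 100, 300))
  bins <- h[h$type == "bin", ]
  d <- rows$distancetoFeature
  expect_equal(bins$count, c(sum(d >= -100 & d < 0), sum(d >= 0 & d < 100),
                             sum(d >= 100 & d < 300)))
  expect_equal(sum(h$count), length(d))
  # interior-edge values land in the bin starting at that edge
  fake <- rows[c(1, 1), ]
  fake$distancetoFeature <- c(0L, 0L)
  h2 <- distance_histogram(fake, breaks = c(-10, 0, 10))
  expect_equal(h2$count[h2$type == "bin"], c(0L, 2L))
  expect_error(distance_histogram(rows, breaks = c(5, 1)), "increasing")
  # empty input: all-zero counts
  h3 <- distance_histogram(rows[0, ], breaks = c(0, 10, 20))
  expect_true(all(h3$count == 0))
})

test_that("relative-position counts apply the overlap-precedence rule", {
  rows <- tibble::tibble(
    peak = c("A", "A", "B"),
    insideFeature = c("inside", "upstream", "upstream"),
    fromOverlappingOrNearest = c("Overlapping", "NearestStart", "NearestStart"))
  got <- relative_position_counts(rows)
  expect_equal(got$count[got$insideFeature == "inside"], 1L)
  expect_equal(got$count[got$insideFeature == "upstream"], 1L)
  # all-NearestStart input degenerates to a plain tally
  rows2 <- rows
  rows2$fromOverlappingOrNearest <- "NearestStart"
  expect_equal(relative_position_counts(rows2)$count, c(1L, 2L))
  # multiple=TRUE: one peak can contribute several Overlapping rows
  rows3 <- tibble::tibble(
    peak = c("A", "A"), insideFeature = c("inside", "overlapStart"),
    fromOverlappingOrNearest = c("Overlapping", "Overlapping"))
  got3 <- relative_position_counts(rows3)
  expect_equal(sum(got3$count), 2L)
})
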