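#' Read a gene-to-GO-term mapping
#'
#' The mapping TSV has columns `gene`, `term`, `aspect` (one of `BP`,
#' `MF`, `CC`); an optional term-name TSV has columns `term`, `name`; an
#' optional edges TSV (`child`, `parent`) supplies is-a links for
#' [propagate_terms()]. Term ids must look like `GO:` followed by seven
#' digits; duplicate gene/term/aspect rows are collapsed.
#'
#' @param path Mapping TSV path (or a data frame with the same columns).
#' @param names_path,edges_path Optional TSV paths.
#' @return A `go_map` list with `mapping` (tibble `gene`, `term`,
#'   `aspect`), `term_names` (tibble or `NULL`), `edges` (tibble or
#'   `NULL`).
#' @export
read_go_map <- function(path, names_path = NULL, edges_path = NULL) {
  mapping <- if (is.data.frame(path)) as_tibble(path) else {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  go_map(mapping,
         term_names = if (!is.null(names_path)) {
           readr::read_tsv(names_path,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
         },
         edges = if (!is.null(edges_path)) {
           readr::read_tsv(edges_path,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
         })
}

#' @rdname read_go_map
#' @param mapping A data frame with columns `gene`, `term`, `aspect`.
#' @param term_names,edges Optional data frames (see `read_go_map`).
#' @export
go_map <- function(mapping, term_names = NULL, edges = NULL) {
  mapping <- as_tibble(mapping)
  need <- c("gene", "term", "aspect")
  if (!all(need %in% names(mapping))) {
    abort("GO mapping needs columns gene, term, aspect")
  }
  mapping <- distinct(select(mapping, "gene", "term", "aspect"))
  bad <- !grepl("^GO:\\d{7}$", mapping$term)
  if (any(bad)) {
    abort(paste0("malformed GO term id(s): ",
                 paste(head(unique(mapping$term[bad]), 5), collapse = ", ")))
  }
  bad_aspect <- setdiff(unique(mapping$aspect), c("BP", "MF", "CC"))
  if (length(bad_aspect) > 0) {
    abort(paste0("unknown aspect(s): ", paste(bad_aspect, collapse = ", ")))
  }
  structure(list(mapping = mapping,
                 term_names = if (!is.null(term_names)) as_tibble(term_names),
                 edges = if (!is.null(edges)) as_tibble(edges)),
            class = "go_map")
}

#' Extract the deduplicated gene sample from annotated peaks
#'
#' Takes the distinct feature (gene) identifiers from an annotation
#' tibble, skipping rows with empty feature fields. One gene hit by
#' several peaks counts once.
#'
#' @param rows An annotation tibble from [annotate_peaks()].
#' @return Character vector of gene ids.
#' @export
extract_gene_sample <- function(rows) {
  genes <- unique(rows$feature[!is.na(rows$feature) & nzchar(rows$feature)])
  if (length(genes) == 0) abort("no genes to test: all feature fields are empty")
  genes
}

#' Close gene annotations under is-a ancestor edges
#'
#' Adds, for every gene, all ancestors (within the same aspect) of its
#' directly annotated terms. Idempotent; a cycle among the edges is an
#' error. With no edges the map is returned unchanged.
#'
#' @param map A `go_map` object.
#' @return A `go_map` with the closed mapping.
#' @export
propagate_terms <- function(map) {
  if (is.null(map$edges) || nrow(map$edges) == 0) return(map)
  edges <- distinct(select(map$edges, "child", "parent"))
  ancestors <- ancestor_closure(edges)
  extra <- map$mapping |>
    inner_join(ancestors, by = c(term = "child"), relationship = "many-to-many") |>
    select(gene = "gene", term = "parent", aspect = "aspect")
  map$mapping <- distinct(bind_rows(map$mapping, extra))
  map
}

# transitive closure child -> all ancestors; aborts on a cycle
ancestor_closure <- function(edges) {
  parents <- split(edges$parent, edges$child)
  memo <- new.env(parent = emptyenv())
  visit <- function(node, stack) {
    if (node %in% stack) abort(paste0("cycle in term hierarchy at ", node))
    if (!is.null(memo[[node]])) return(memo[[node]])
    ps <- parents[[node]]
    anc <- unique(c(ps, unlist(lapply(ps, visit, stack = c(stack, node)))))
    memo[[node]] <- anc %||% character()
    memo[[node]]
  }
  res <- lapply(unique(edges$child), function(ch) {
    tibble(child = ch, parent = visit(ch, character()))
  })
  bind_rows(res)
}

#' Hypergeometric GO-term enrichment of a gene sample
#'
#' Tests, per ontology aspect, whether GO terms are over-represented in a
#' gene sample relative to the annotation universe (all genes with at
#' least one term in that aspect). For each candidate term (those
#' annotating at least `min_go_term` genes in the universe) the raw
#' p-value is the upper hypergeometric tail `P(X >= k)` with universe
#' size `N`, term count `K` and sample size `n`; Benjamini-Hochberg
#' adjustment is applied across the candidate terms within each aspect.
#' Rows are kept when the adjusted p (raw p when `adjust = "none"`) is at
#' most `max_p`. Sample genes absent from an aspect's universe are
#' dropped from `n` for that aspect.
#'
#' @param sample Character vector of gene ids (e.g. from
#'   [extract_gene_sample()]).
#' @param map A `go_map` object.
#' @param max_p Maximum (adjusted) p-value to report (default 0.01).
#' @param min_go_term Minimum genome-wide gene count for a term to be
#'   tested (default 10).
#' @param adjust `"BH"` (default) or `"none"`.
#' @return A tibble with columns `term`, `term_name`, `aspect`, `K`
#'   (universe genes with term), `k` (sample genes with term), `N`
#'   (universe size), `n` (sample size in universe), `p_raw`,
#'   `p_adjusted`, sorted by `p_raw` then `term` within aspect.
#' @export
enrich_go <- function(sample, map, max_p = 0.01, min_go_term = 10L,
                      adjust = c("BH", "none")) {
  adjust <- rlang::arg_match(adjust)
  if (min_go_term < 1) abort("min_go_term must be >= 1")
  sample <- unique(as.character(sample))
  res <- lapply(c("BP", "MF", "CC"), function(aspect) {
    m <- filter(map$mapping, .data$aspect == !!aspect)
    if (nrow(m) == 0) return(NULL)
    universe <- unique(m$gene)
    in_univ <- intersect(sample, universe)
    dropped <- setdiff(sample, universe)
    if (length(dropped) > 0) {
      inform(paste0(aspect, ": ", length(dropped),
                    " sample gene(s) absent from universe, dropped"))
    }
    N <- length(universe)
    n <- length(in_univ)
    term_stats <- m |>
      group_by(.data$term) |>
      summarise(K = dplyr::n_distinct(.data$gene),
                k = dplyr::n_distinct(intersect(.data$gene, in_univ)),
                .groups = "drop") |>
      filter(.data$K >= min_go_term)
    if (nrow(term_stats) == 0) return(NULL)
    term_stats |>
      mutate(aspect = aspect, N = N, n = n,
             p_raw = phyper(.data$k - 1, m = .data$K, n = N - .data$K,
                            k = n, lower.tail = FALSE),
             p_adjusted = if (adjust == "BH") p.adjust(.data$p_raw, method = "BH")
                          else .data$p_raw)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(term = character(), term_name = character(), aspect = character(),
                  K = integer(), k = integer(), N = integer(), n = integer(),
                  p_raw = double(), p_adjusted = double()))
  }
  out <- filter(out, .data$p_adjusted <= max_p)
  nm <- map$term_names
  out$term_name <- if (!is.null(nm)) nm$name[match(out$term, nm$term)] else NA_character_
  out |>
    select("term", "term_name", "aspect", "K", "k", "N", "n", "p_raw", "p_adjusted") |>
    arrange(.data$aspect, .data$p_raw, .data$term)
}
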