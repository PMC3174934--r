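#' Upper tail of the hypergeometric distribution
#'
#' Exact `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes
#' from a universe of `N` that contains `K` annotated genes, the chance of
#' seeing `k` or more annotated ones. This is the enrichment test used both
#' for individual GeneTerm-sets and for whole metagroups.
#'
#' @param k Observed successes, `0 <= k <= min(n, K)`.
#' @param n Sample size (query size), `n <= N`.
#' @param K Population successes (annotated genes), `K <= N`.
#' @param N Population size (universe).
#' @return The exact tail probability, in `(0, 1]`.
#' @examples
#' hypergeometric_tail(3, 5, 4, 10) # 66/252
#' @export
hypergeometric_tail <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (any(!is.finite(vals)) || any(vals != round(vals)))
    stop("k, n, K, N must be finite integers")
  if (k < 0 || k > min(n, K) || n > N || K > N || n < 0 || K < 0)
    stop(sprintf("invalid hypergeometric bounds: k=%d n=%d K=%d N=%d",
                 k, n, K, N))
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Query context for enrichment and element vectors
#'
#' Fixes the ordered query gene list (which defines the axes of the
#' element vectors), its size `M`, and the universe size `N` used as
#' hypergeometric population. Duplicate query genes are dropped with a
#' warning.
#'
#' @param query_genes Character vector of query gene ids (order kept).
#' @param universe_size Integer population size `N >= M`.
#' @return A `QueryContext`: list with `query_genes`, `M`, `universe_size`.
#' @export
query_context <- function(query_genes, universe_size) {
  query_genes <- trimws(as.character(query_genes))
  query_genes <- query_genes[nzchar(query_genes)]
  if (!length(query_genes)) stop("empty query")
  if (anyDuplicated(query_genes)) {
    warning(sum(duplicated(query_genes)),
            " duplicated query gene(s) removed")
    query_genes <- unique(query_genes)
  }
  universe_size <- as.integer(universe_size)
  if (is.na(universe_size) || universe_size < length(query_genes))
    stop("universe_size must be >= number of query genes")
  structure(list(query_genes = query_genes, M = length(query_genes),
                 universe_size = universe_size),
            class = "QueryContext")
}

#' Construct a GeneTerm-set element
#'
#' The atomic unit of the whole pipeline: a set of genes, the terms they
#' are all annotated with, and the enrichment p-value tying them together.
#'
#' @param element_id Label.
#' @param genes Non-empty character vector of gene ids.
#' @param terms Non-empty character vector of source-prefixed term ids.
#' @param p_value Number in `(0, 1]`.
#' @return A `GeneTermSet`.
#' @export
gene_term_set <- function(element_id, genes, terms, p_value) {
  genes <- unique(trimws(as.character(genes)))
  terms <- unique(trimws(as.character(terms)))
  if (!length(genes) || any(!nzchar(genes))) stop("genes must be non-empty")
  if (!length(terms) || any(!nzchar(terms))) stop("terms must be non-empty")
  if (!is.numeric(p_value) || length(p_value) != 1L || is.na(p_value) ||
      p_value <= 0 || p_value > 1)
    stop("p_value must be a single number in (0, 1]")
  structure(list(element_id = as.character(element_id), genes = genes,
                 terms = terms, p_value = as.numeric(p_value)),
            class = "GeneTermSet")
}

#' @export
print.GeneTermSet <- function(x, ...) {
  cat(sprintf("<GeneTermSet> %s: %d gene(s), %d term(s), p = %.3g\n",
              x$element_id, length(x$genes), length(x$terms), x$p_value))
  invisible(x)
}

# named list space_id -> AnnotationSpace; accepts a bare space too
as_space_list <- function(spaces) {
  if (inherits(spaces, "AnnotationSpace")) spaces <- list(spaces)
  stopifnot(all(vapply(spaces, inherits, TRUE, "AnnotationSpace")))
  stats::setNames(spaces, vapply(spaces, `[[`, "", "source_id"))
}

# genes annotated with EVERY term of `terms` (prefixed ids), within the
# spaces' universes
genes_with_all_terms <- function(terms, spaces) {
  spaces <- as_space_list(spaces)
  parts <- split_term(terms)
  sets <- mapply(function(s, t) {
    sp <- spaces[[s]]
    if (is.null(sp)) stop("unknown annotation space: ", s)
    g <- sp$term_to_genes[[t]]
    if (is.null(g)) stop("unknown term ", t, " in space ", s)
    g
  }, parts$space, parts$term, SIMPLIFY = FALSE)
  Reduce(intersect, sets)
}

enrichment_population <- function(spaces, population) {
  spaces <- as_space_list(spaces)
  if (population == "annotated")
    sort(unique(unlist(lapply(spaces, function(s)
      unlist(s$term_to_genes, use.names = FALSE)), use.names = FALSE)))
  else
    sort(unique(unlist(lapply(spaces, `[[`, "universe"), use.names = FALSE)))
}

finalize_elements <- function(cand, p_max) {
  cand <- Filter(function(e) e$p <= p_max, cand)
  if (!length(cand)) return(list())
  ord <- order(vapply(cand, `[[`, 0, "p"),
               vapply(cand, function(e) paste(sort(e$terms), collapse = ";"), ""))
  cand <- cand[ord]
  lapply(seq_along(cand), function(i)
    gene_term_set(sprintf("E%03d", i), cand[[i]]$genes, cand[[i]]$terms,
                  cand[[i]]$p))
}

#' Singular enrichment analysis (one term per element)
#'
#' For every term with at least `min_support` query genes, tests the overlap
#' between the query and the term's gene set with the exact hypergeometric
#' tail and emits one GeneTerm-set per significant term.
#'
#' @param query A [query_context()].
#' @param spaces `AnnotationSpace` or list thereof.
#' @param min_support Minimum number of query genes carrying the term.
#' @param p_max Keep elements with `p <= p_max`.
#' @param population `"universe"` (default: the spaces' full gene universe)
#'   or `"annotated"` (only genes with at least one annotation).
#' @return List of `GeneTermSet`, sorted by increasing p-value; ids `E001...`
#' @export
singular_enrichment <- function(query, spaces, min_support = 3, p_max = 0.05,
                                population = c("universe", "annotated")) {
  stopifnot(inherits(query, "QueryContext"))
  population <- match.arg(population)
  spaces <- as_space_list(spaces)
  pop <- enrichment_population(spaces, population)
  N <- length(pop)
  M <- sum(query$query_genes %in% pop)
  cand <- list()
  for (sp in spaces) {
    for (t in names(sp$term_to_genes)) {
      tg <- intersect(sp$term_to_genes[[t]], pop)
      g <- intersect(query$query_genes, tg)
      if (length(g) < min_support) next
      p <- hypergeometric_tail(length(g), M, length(tg), N)
      cand[[length(cand) + 1L]] <-
        list(genes = g, terms = prefix_terms(sp, t), p = p)
    }
  }
  finalize_elements(cand, p_max)
}

#' Concurrent (modular) enrichment analysis via closed itemsets
#'
#' Treats each query gene as a transaction over its annotation terms (all
#' loaded spaces pooled, term ids source-prefixed) and enumerates the closed
#' frequent itemsets with support `>= min_support`. Each closed itemset `A`
#' becomes a GeneTerm-set: its genes are the query genes carrying every term
#' of `A`, and its p-value is the hypergeometric tail of that count against
#' the universe genes carrying every term of `A`. Closedness means two terms
#' annotated to exactly the same query genes always travel together in one
#' element rather than spawning duplicates.
#'
#' @inheritParams singular_enrichment
#' @return List of `GeneTermSet`, sorted by increasing p-value.
#' @export
concurrent_enrichment <- function(query, spaces, min_support = 3,
                                  p_max = 0.05,
                                  population = c("universe", "annotated")) {
  stopifnot(inherits(query, "QueryContext"))
  population <- match.arg(population)
  spaces <- as_space_list(spaces)
  pop <- enrichment_population(spaces, population)
  N <- length(pop)
  qg <- intersect(query$query_genes, pop)
  M <- length(qg)
  # tidlists: term -> indices of query genes annotated with it
  tidlists <- list()
  for (sp in spaces) {
    for (t in names(sp$term_to_genes)) {
      tids <- which(qg %in% sp$term_to_genes[[t]])
      if (length(tids))
        tidlists[[prefix_terms(sp, t)]] <- tids
    }
  }
  closed <- mine_closed_itemsets(tidlists, min_support)
  cand <- lapply(closed, function(cs) {
    K <- length(intersect(genes_with_all_terms(cs$items, spaces), pop))
    g <- qg[cs$tids]
    list(genes = g, terms = cs$items,
         p = hypergeometric_tail(length(g), M, K, N))
  })
  finalize_elements(cand, p_max)
}

split_id_list <- function(x) {
  out <- strsplit(x, "[,;]")
  lapply(out, function(v) unique(trimws(v[nzchar(trimws(v))])))
}

#' Read GeneTerm-sets from a TSV file
#'
#' Expected columns (with header): `element_id`, `genes`, `terms`,
#' `p_value`; the two list columns are `;`- or `,`-separated. When
#' annotation spaces are supplied the co-annotation invariant (every gene
#' annotated with every term) is verified; otherwise the file is trusted
#' with a warning.
#'
#' @param path Path to the TSV.
#' @param spaces Optional `AnnotationSpace` list for validation.
#' @return List of `GeneTermSet`.
#' @export
read_genetermsets <- function(path, spaces = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("element_id", "genes", "terms", "p_value")
  if (!all(need %in% names(df)))
    stop("GeneTerm-set TSV must have columns: ", paste(need, collapse = ", "))
  if (!nrow(df)) stop("no GeneTerm-set rows in ", path)
  p <- suppressWarnings(as.numeric(df$p_value))
  bad <- which(is.na(p) | p <= 0 | p > 1)
  if (length(bad))
    stop("invalid p_value in row ", bad[1L], " of ", path, ": '",
         df$p_value[bad[1L]], "' (must be a number in (0,1])")
  genes <- split_id_list(df$genes)
  terms <- split_id_list(df$terms)
  out <- lapply(seq_len(nrow(df)), function(i)
    gene_term_set(df$element_id[i], genes[[i]], terms[[i]], p[i]))
  if (is.null(spaces)) {
    warning("no annotation spaces supplied; co-annotation of the loaded ",
            "GeneTerm-sets is trusted, not verified")
  } else {
    for (i in seq_along(out)) {
      carriers <- genes_with_all_terms(out[[i]]$terms, spaces)
      extra <- setdiff(out[[i]]$genes, carriers)
      if (length(extra))
        stop("row ", i, ": gene(s) not annotated with every term: ",
             paste(utils::head(extra, 3L), collapse = ", "))
    }
  }
  out
}

#' Write GeneTerm-sets to TSV
#'
#' Inverse of [read_genetermsets()]; gene and term lists are `;`-joined in
#' sorted order so output is byte-stable.
#'
#' @param elements List of `GeneTermSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genetermsets <- function(elements, path) {
  rows <- vapply(elements, function(e) paste(
    e$element_id,
    paste(sort(e$genes), collapse = ";"),
    paste(sort(e$terms), collapse = ";"),
    format(e$p_value, digits = 15),
    sep = "\t"), "")
  writeLines(c("element_id\tgenes\tterms\tp_value", rows), path,
             useBytes = TRUE)
  invisible(path)
}
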