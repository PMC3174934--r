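#' Construct a metagroup
#'
#' A metagroup is a set of GeneTerm-set elements linked by shared genes
#' and/or terms; its gene and term unions are recomputed from the elements,
#' and scores are `NA` until [score_metagroups()] fills them.
#'
#' @param metagroup_id Label.
#' @param elements Non-empty list of `GeneTermSet`.
#' @return A `Metagroup`.
#' @export
metagroup <- function(metagroup_id, elements) {
  if (!length(elements)) stop("a metagroup needs at least one element")
  stopifnot(all(vapply(elements, inherits, TRUE, "GeneTermSet")))
  structure(
    list(metagroup_id = as.character(metagroup_id), elements = elements,
         union_genes = sort(unique(unlist(lapply(elements, `[[`, "genes")))),
         union_terms = sort(unique(unlist(lapply(elements, `[[`, "terms")))),
         raw_p = NA_real_, adjusted_p = NA_real_, silhouette = NA_real_,
         diameter = NA_real_, similarity_coefficient = NA_real_),
    class = "Metagroup")
}

#' @export
print.Metagroup <- function(x, ...) {
  cat(sprintf(
    "<Metagroup> %s: %d element(s), %d gene(s), %d term(s), adj p = %s\n",
    x$metagroup_id, length(x$elements), length(x$union_genes),
    length(x$union_terms),
    if (is.na(x$adjusted_p)) "NA" else format(x$adjusted_p, digits = 3)))
  invisible(x)
}

#' Step 1: drop elements annotated only with generic terms
#'
#' Removes exactly the GeneTerm-sets whose entire term set consists of
#' tagged generic (promiscuous) terms. An element mixing generic and
#' specific terms is kept intact, generic terms included — generic
#' annotations stay informative in co-occurrence.
#'
#' @param elements List of `GeneTermSet`.
#' @param policies `GenericTermPolicy` or list of them, covering every
#'   annotation space referenced by the elements (unknown space = error).
#' @return Filtered list of `GeneTermSet`, order and contents untouched.
#' @export
filter_generic_only <- function(elements, policies) {
  if (!length(elements)) return(elements)
  keep <- vapply(elements, function(e)
    !all(is_generic_term(e$terms, policies)), TRUE)
  elements[keep]
}

shared_specific_terms <- function(terms_a, terms_b, generic) {
  length(setdiff(intersect(terms_a, terms_b), generic))
}

#' Step 2b: greedy merge of pre-metagroups by shared terms
#'
#' Starting from the clusters of the tree cut, repeatedly merges the pair
#' of groups sharing the largest number of non-generic terms (ties go to
#' the smallest pair of group indices) until no two groups share any
#' non-generic term. Generic terms never count toward sharing.
#'
#' @param pre_groups List of lists of `GeneTermSet` (e.g. the clusters of
#'   [cut_pre_metagroups()] mapped back to elements).
#' @param policies Generic-term policies covering all referenced spaces.
#' @return List of unscored `Metagroup`s, ids `MG01`, `MG02`, ...
#' @export
greedy_term_merge <- function(pre_groups, policies) {
  pre_groups <- Filter(length, pre_groups)
  if (!length(pre_groups)) return(list())
  terms_of <- lapply(pre_groups, function(g)
    unique(unlist(lapply(g, `[[`, "terms"))))
  all_terms <- unique(unlist(terms_of))
  generic <- all_terms[is_generic_term(all_terms, policies)]
  repeat {
    k <- length(pre_groups)
    if (k < 2L) break
    best <- NULL; best_n <- 0L
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      s <- shared_specific_terms(terms_of[[i]], terms_of[[j]], generic)
      if (s > best_n) { best_n <- s; best <- c(i, j) }
    }
    if (best_n == 0L) break
    i <- best[1L]; j <- best[2L]
    pre_groups[[i]] <- c(pre_groups[[i]], pre_groups[[j]])
    terms_of[[i]] <- unique(c(terms_of[[i]], terms_of[[j]]))
    pre_groups[[j]] <- NULL
    terms_of[[j]] <- NULL
  }
  lapply(seq_along(pre_groups), function(i)
    metagroup(sprintf("MG%02d", i), pre_groups[[i]]))
}

#' Step 3: complete-cover redundancy removal within a metagroup
#'
#' Visits elements from least to most significant (decreasing p-value;
#' ties visited in decreasing element-id order, so lexicographically
#' smaller ids are preferentially retained) and removes an element iff
#' both its genes and its terms are already covered by the union of the
#' other retained elements. The metagroup's gene and term unions are
#' provably unchanged, and no single retained element can still be removed
#' without losing a gene or a term.
#'
#' @param group A `Metagroup`.
#' @return The metagroup with redundant elements removed (scores reset).
#' @export
complete_cover <- function(group) {
  stopifnot(inherits(group, "Metagroup"))
  els <- group$elements
  if (length(els) > 1L) {
    p <- vapply(els, `[[`, 0, "p_value")
    ids <- vapply(els, `[[`, "", "element_id")
    visit <- rev(order(p, xtfrm(ids)))   # decreasing p, then decreasing id
    retained <- rep(TRUE, length(els))
    for (i in visit) {
      others <- which(retained)
      others <- others[others != i]
      if (!length(others)) next
      og <- unique(unlist(lapply(els[others], `[[`, "genes")))
      ot <- unique(unlist(lapply(els[others], `[[`, "terms")))
      if (all(els[[i]]$genes %in% og) && all(els[[i]]$terms %in% ot))
        retained[i] <- FALSE
    }
    els <- els[retained]
  }
  out <- metagroup(group$metagroup_id, els)
  stopifnot(identical(out$union_genes, group$union_genes),
            identical(out$union_terms, group$union_terms))
  out
}

#' Step 4: score and rank metagroups
#'
#' Computes, per metagroup: (i) the exact hypergeometric tail p-value of
#' its gene union against the universe genes annotated with at least one of
#' its terms; (ii) Benjamini-Hochberg adjusted p-values across the
#' metagroups; (iii) silhouette width, diameter and similarity coefficient
#' from cosine distances over gene-only element vectors (the p-value
#' component is excluded from this geometry). Groups are ranked by
#' adjusted p (ascending), then silhouette (descending), then id.
#'
#' Conventions: a single-element metagroup has diameter 0 and similarity 1
#' and its element contributes silhouette 0; when only one metagroup exists
#' the silhouette is `NA` (no between-group distance exists).
#'
#' @param groups List of `Metagroup`.
#' @param query The [query_context()] the elements were built against.
#' @param spaces Annotation spaces (for the term-carrier population `K`).
#' @param population `"union"` (default; `K` = genes with >= 1 metagroup
#'   term) or `"intersection"` (genes carrying all terms).
#' @return The scored metagroups, ranked.
#' @export
score_metagroups <- function(groups, query, spaces,
                             population = c("union", "intersection")) {
  stopifnot(length(groups) >= 1L,
            all(vapply(groups, inherits, TRUE, "Metagroup")),
            inherits(query, "QueryContext"))
  population <- match.arg(population)
  spaces <- as_space_list(spaces)
  N <- query$universe_size
  M <- query$M

  raw_p <- vapply(groups, function(g) {
    K <- term_carrier_count(g$union_terms, spaces, population)
    k <- length(g$union_genes)
    if (k > M)
      stop("metagroup ", g$metagroup_id, " has genes outside the query")
    hypergeometric_tail(k, M, max(K, k), N)
  }, 0)
  adj_p <- stats::p.adjust(raw_p, method = "BH")

  # gene-only geometry over all elements of all groups
  all_el <- unlist(lapply(groups, `[[`, "elements"), recursive = FALSE)
  gidx <- rep(seq_along(groups),
              vapply(groups, function(g) length(g$elements), 0L))
  V <- build_element_vectors(all_el, query, p_weight_mode = "off")
  D <- cosine_distance_matrix(V)

  for (gi in seq_along(groups)) {
    own <- which(gidx == gi)
    if (length(own) == 1L) {
      diam <- 0; simc <- 1
    } else {
      sub <- D[own, own, drop = FALSE]
      w <- sub[upper.tri(sub)]
      diam <- max(w); simc <- 1 - mean(w)
    }
    if (length(groups) == 1L) {
      sil <- NA_real_
    } else {
      s <- vapply(own, function(i) {
        a <- if (length(own) == 1L) 0 else mean(D[i, setdiff(own, i)])
        b <- min(vapply(setdiff(seq_along(groups), gi), function(gj)
          mean(D[i, which(gidx == gj)]), 0))
        if (length(own) == 1L) return(0)
        if (max(a, b) == 0) 0 else (b - a) / max(a, b)
      }, 0)
      sil <- mean(s)
    }
    groups[[gi]]$raw_p <- raw_p[gi]
    groups[[gi]]$adjusted_p <- adj_p[gi]
    groups[[gi]]$silhouette <- sil
    groups[[gi]]$diameter <- diam
    groups[[gi]]$similarity_coefficient <- simc
  }
  sil_key <- vapply(groups, function(g)
    if (is.na(g$silhouette)) 0 else g$silhouette, 0)
  ids <- vapply(groups, `[[`, "", "metagroup_id")
  groups[order(adj_p, -sil_key, xtfrm(ids))]
}

term_carrier_count <- function(terms, spaces, population) {
  if (population == "intersection")
    return(length(genes_with_all_terms(terms, spaces)))
  parts <- split_term(terms)
  sets <- mapply(function(s, t) {
    sp <- spaces[[s]]
    if (is.null(sp)) stop("unknown annotation space: ", s)
    sp$term_to_genes[[t]]
  }, parts$space, parts$term, SIMPLIFY = FALSE)
  length(unique(unlist(sets, use.names = FALSE)))
}

#' Run the full linker (steps 1-4) on a list of GeneTerm-sets
#'
#' Filters generic-only elements, clusters the survivors by Ward linkage on
#' cosine distances over p-weighted gene-occurrence vectors, cuts the tree
#' at a fraction of its depth (escalating until a metagroup forms), merges
#' clusters sharing non-generic terms, removes intra-metagroup redundancy
#' by complete cover, and scores/ranks the metagroups.
#'
#' @param elements List of `GeneTermSet` (e.g. from
#'   [concurrent_enrichment()] or [read_genetermsets()]).
#' @param query A [query_context()]. Queries below 7 genes trigger a
#'   warning: reciprocal linkage needs enough genes to anchor terms.
#' @param spaces Annotation spaces backing the elements.
#' @param policies Optional generic-term policies; computed from `spaces`
#'   at `n_factor` when omitted (spaces with < 2 terms get an empty policy).
#' @param n_factor Deviation factor for [detect_generic_terms()].
#' @param depth_fraction,step,min_elements See [cut_pre_metagroups()].
#' @param p_weight_mode Vector weighting for the clustering stage
#'   (`"literal"` = p * M component, the default; `"off"` for gene-only).
#' @param population See [score_metagroups()].
#' @return List with `metagroups` (scored, ranked), `elements` (the
#'   post-filter elements) and `counts` (per-step element/group tallies).
#' @export
link_metagroups <- function(elements, query, spaces, policies = NULL,
                            n_factor = 4, depth_fraction = 0.20,
                            step = 0.10, min_elements = 2L,
                            p_weight_mode = c("literal", "off"),
                            population = c("union", "intersection")) {
  stopifnot(inherits(query, "QueryContext"))
  p_weight_mode <- match.arg(p_weight_mode)
  population <- match.arg(population)
  spaces <- as_space_list(spaces)
  if (query$M < 7)
    warning("query has only ", query$M,
            " genes; below seven genes reciprocal linkage is unreliable")
  if (is.null(policies))
    policies <- lapply(spaces, function(sp) {
      if (length(sp$term_to_genes) < 2L)
        structure(list(space_id = sp$source_id, mean_ng = NA_real_,
                       sigma_ng = NA_real_, n_factor = n_factor,
                       threshold = Inf, generic_terms = character(0)),
                  class = "GenericTermPolicy")
      else detect_generic_terms(sp, n_factor = n_factor)
    })
  counts <- list(elements_in = length(elements))
  kept <- filter_generic_only(elements, policies)
  counts$after_generic_filter <- length(kept)
  if (!length(kept))
    return(list(metagroups = list(), elements = kept, counts = counts))
  V <- build_element_vectors(kept, query, p_weight_mode = p_weight_mode)
  tree <- ward_tree(cosine_distance_matrix(V))
  clusters <- cut_pre_metagroups(tree, depth_fraction = depth_fraction,
                                 step = step, min_elements = min_elements)
  counts$pre_metagroups <- length(clusters)
  by_id <- stats::setNames(kept, vapply(kept, `[[`, "", "element_id"))
  groups <- greedy_term_merge(lapply(clusters, function(ids) by_id[ids]),
                              policies)
  counts$merged_metagroups <- length(groups)
  groups <- lapply(groups, complete_cover)
  counts$elements_after_cover <-
    sum(vapply(groups, function(g) length(g$elements), 0L))
  scored <- score_metagroups(groups, query, spaces, population = population)
  counts$final_metagroups <- length(scored)
  list(metagroups = scored, elements = kept, counts = counts)
}
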