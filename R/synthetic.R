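#' Design for a synthetic annotation benchmark
#'
#' Describes an artificial organism whose annotation catalogs emulate the
#' features the pipeline must cope with: disjoint planted gene modules
#' annotated by small specific terms, the same specific terms duplicated
#' across pseudo-databases (synonymous cross-source annotation), and a few
#' promiscuous generic terms covering a large random slice of the
#' universe. Defaults give 5 modules of 10 genes with 4 specific terms
#' each, 2 synonym sources, and 1 generic term covering half of a
#' 1000-gene universe — small specific terms plus rare heavy outliers,
#' the skew that makes the Z-score outlier rule work.
#'
#' @param n_universe Total genes in the organism.
#' @param modules Data frame (or list coercible to one) with columns
#'   `size` and `n_specific_terms`, one row per planted module.
#' @param n_synonym_sources Number of pseudo-databases each specific term
#'   is duplicated into (`SRC1`, `SRC2`, ...).
#' @param n_generic_terms Generic terms added to the first source.
#' @param generic_coverage Fraction of the universe each generic term
#'   annotates, in `(0, 1]`.
#' @param seed Integer seed; the whole construction is deterministic in it.
#' @return A `SyntheticDesign`.
#' @export
synthetic_design <- function(n_universe = 1000L,
                             modules = data.frame(
                               size = rep(10L, 5L),
                               n_specific_terms = rep(4L, 5L)),
                             n_synonym_sources = 2L,
                             n_generic_terms = 1L,
                             generic_coverage = 0.5,
                             seed = 1L) {
  modules <- as.data.frame(modules)
  stopifnot(all(c("size", "n_specific_terms") %in% names(modules)),
            nrow(modules) >= 1L, all(modules$size >= 1L),
            all(modules$n_specific_terms >= 1L),
            n_synonym_sources >= 1L, n_generic_terms >= 0L,
            generic_coverage > 0, generic_coverage <= 1)
  if (sum(modules$size) > n_universe)
    stop("module sizes exceed the universe")
  structure(list(n_universe = as.integer(n_universe), modules = modules,
                 n_synonym_sources = as.integer(n_synonym_sources),
                 n_generic_terms = as.integer(n_generic_terms),
                 generic_coverage = generic_coverage,
                 seed = as.integer(seed)),
            class = "SyntheticDesign")
}

#' Generate annotation spaces with planted modules
#'
#' Realises a [synthetic_design()]: module genes are sampled from the
#' universe; each module's specific terms annotate exactly its genes and
#' are replicated in every synonym source; generic terms annotate a random
#' `generic_coverage` slice of the universe (first source only). Returns
#' the spaces, the reference partition of modules, and a truth table
#' recording every term's provenance.
#'
#' @param design A `SyntheticDesign`.
#' @return List with `spaces` (named list of `AnnotationSpace`),
#'   `reference` (`ReferencePartition` of the planted modules), and
#'   `truth` (data.frame: term, source, module, type).
#' @export
generate_space <- function(design) {
  stopifnot(inherits(design, "SyntheticDesign"))
  with_seed(design$seed, {
    universe <- sprintf("g%04d", seq_len(design$n_universe))
    n_mod <- nrow(design$modules)
    picked <- sample(universe, sum(design$modules$size))
    stops <- cumsum(design$modules$size)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    module_genes <- lapply(seq_len(n_mod), function(m)
      sort(picked[starts[m]:stops[m]]))
    names(module_genes) <- sprintf("M%d", seq_len(n_mod))

    truth <- list()
    spaces <- lapply(seq_len(design$n_synonym_sources), function(s) {
      src <- sprintf("SRC%d", s)
      tg <- list()
      for (m in seq_len(n_mod)) {
        for (j in seq_len(design$modules$n_specific_terms[m])) {
          id <- sprintf("M%dT%d", m, j)
          tg[[id]] <- module_genes[[m]]
          truth[[length(truth) + 1L]] <<-
            data.frame(term = paste0(src, ":", id), source = src,
                       module = names(module_genes)[m], type = "specific",
                       stringsAsFactors = FALSE)
        }
      }
      if (s == 1L && design$n_generic_terms > 0L) {
        n_cov <- max(1L, round(design$generic_coverage * design$n_universe))
        for (k in seq_len(design$n_generic_terms)) {
          id <- sprintf("GEN%d", k)
          tg[[id]] <- sort(sample(universe, n_cov))
          truth[[length(truth) + 1L]] <<-
            data.frame(term = paste0(src, ":", id), source = src,
                       module = NA_character_, type = "generic",
                       stringsAsFactors = FALSE)
        }
      }
      annotation_space(src, tg, organism = "synthetic", universe = universe)
    })
    names(spaces) <- vapply(spaces, `[[`, "", "source_id")
    list(spaces = spaces,
         reference = reference_partition("planted_modules", module_genes,
                                         universe = universe),
         truth = do.call(rbind, truth))
  })
}
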