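#' Reference partition of genes into (possibly overlapping) groups
#'
#' @param name Label.
#' @param groups Named list of character vectors, each non-empty.
#' @param universe Optional gene universe; must cover every group gene.
#'   Defaults to the union of the groups.
#' @return A `ReferencePartition`.
#' @export
reference_partition <- function(name, groups, universe = NULL) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (is.null(names(groups)))
    names(groups) <- sprintf("G%02d", seq_along(groups))
  groups <- lapply(groups, function(g) unique(trimws(as.character(g))))
  if (any(lengths(groups) == 0L)) stop("every group needs at least one gene")
  genes <- unique(unlist(groups, use.names = FALSE))
  if (is.null(universe)) universe <- sort(genes)
  else {
    universe <- unique(trimws(as.character(universe)))
    if (length(setdiff(genes, universe)))
      stop("universe does not cover all group genes")
  }
  structure(list(name = name, groups = groups, universe = universe),
            class = "ReferencePartition")
}

#' Read a reference partition from a GMT file
#'
#' @param path GMT path (set id, description, genes...).
#' @param name Partition label; defaults to the file name.
#' @return A `ReferencePartition`.
#' @export
read_reference_gmt <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop("malformed GMT line ", bad[1L], " in ", path)
  groups <- stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                            vapply(fields, `[[`, "", 1L))
  reference_partition(name, groups)
}

as_group_list <- function(x) {
  if (inherits(x, "ReferencePartition")) return(x$groups)
  if (inherits(x, "Metagroup")) return(list(x$union_genes))
  if (is.list(x) && length(x) && all(vapply(x, inherits, TRUE, "Metagroup")))
    return(lapply(x, `[[`, "union_genes"))
  if (is.character(x)) return(list(x))
  stopifnot(is.list(x))
  x
}

# n x n logical co-membership over `genes` given a (possibly overlapping)
# group list: TRUE iff the pair appears together in >= 1 group
co_membership <- function(groups, genes) {
  n <- length(genes)
  co <- matrix(FALSE, n, n)
  for (g in groups) {
    idx <- which(genes %in% g)
    if (length(idx) >= 2L) co[idx, idx] <- TRUE
  }
  diag(co) <- FALSE
  co
}

#' Gene-pair confusion matrix between a found grouping and a reference
#'
#' Classifies all `C(n, 2)` unordered pairs of the evaluated genes by
#' co-membership (a pair is co-grouped when both genes share at least one
#' group — groupings may overlap): TP co-grouped in both, FP in the found
#' grouping only, FN in the reference only, TN in neither.
#'
#' @param found Found grouping: list of gene-id vectors, list of
#'   `Metagroup`s, or a `ReferencePartition`.
#' @param reference Reference grouping, same forms.
#' @param genes Genes to evaluate (`n >= 2`); defaults to the union of all
#'   genes in `found` and `reference` — pass the query list to let noise
#'   genes count toward TN/FP.
#' @return A `PairConfusion`: list with `tp`, `fp`, `fn`, `tn`,
#'   `total_pairs`.
#' @export
pair_confusion <- function(found, reference, genes = NULL) {
  fg <- as_group_list(found)
  rg <- as_group_list(reference)
  if (is.null(genes))
    genes <- unique(unlist(c(fg, rg), use.names = FALSE))
  genes <- unique(as.character(genes))
  n <- length(genes)
  if (n < 2L) stop("need at least two evaluated genes")
  cf <- co_membership(fg, genes)
  cr <- co_membership(rg, genes)
  up <- upper.tri(cf)
  tp <- sum(cf[up] & cr[up]); fp <- sum(cf[up] & !cr[up])
  fn <- sum(!cf[up] & cr[up]); tn <- sum(!cf[up] & !cr[up])
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 total_pairs = choose(n, 2)),
            class = "PairConfusion")
}

#' Rand accuracy and Jaccard coefficient of a pair confusion
#'
#' `accuracy = (TP + TN) / total pairs` (the Rand statistic);
#' `jaccard = TP / (TP + FN + FP)`, 0 by convention when the denominator
#' is 0.
#'
#' @param conf A `PairConfusion` (or list with tp/fp/fn/tn/total_pairs).
#' @return List with `accuracy` and `jaccard`.
#' @examples
#' partition_accuracy_jaccard(
#'   structure(list(tp = 320, fp = 0, fn = 82, tn = 1309,
#'                  total_pairs = 1711), class = "PairConfusion"))
#' @export
partition_accuracy_jaccard <- function(conf) {
  stopifnot(conf$total_pairs > 0)
  denom <- conf$tp + conf$fn + conf$fp
  list(accuracy = (conf$tp + conf$tn) / conf$total_pairs,
       jaccard = if (denom == 0) 0 else conf$tp / denom)
}

#' Gene-level precision, recall and F-score (in percent)
#'
#' Information-retrieval statistics of a retrieved gene set against the
#' relevant (reference) set: precision = fraction of retrieved genes that
#' are relevant, recall = fraction of relevant genes retrieved, F-score =
#' their harmonic mean. Reported in percent. An empty retrieved set yields
#' `NA` precision (undefined) and 0 recall/F.
#'
#' @param retrieved Character vector of retrieved genes (may be empty).
#' @param relevant Non-empty character vector of relevant genes.
#' @return List with `precision`, `recall`, `f_score`, each in `[0, 100]`.
#' @export
precision_recall_f <- function(retrieved, relevant) {
  retrieved <- unique(as.character(retrieved))
  relevant <- unique(as.character(relevant))
  if (!length(relevant)) stop("relevant set must be non-empty")
  hit <- length(intersect(retrieved, relevant))
  r <- 100 * hit / length(relevant)
  if (!length(retrieved))
    return(list(precision = NA_real_, recall = r, f_score = 0))
  p <- 100 * hit / length(retrieved)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f_score = f)
}

#' Add random noise genes to a reference gene set
#'
#' Implements the benchmarking noise protocol: `round(fraction * |ref|)`
#' genes (round half up) are drawn uniformly without replacement from the
#' pool minus the reference and appended to it, so a 10-gene reference at
#' 20% noise becomes a 12-gene query. Deterministic given `seed`.
#'
#' @param reference_genes Character vector of reference genes.
#' @param pool Gene universe to draw noise from; must properly contain the
#'   reference when noise is requested.
#' @param fraction Non-negative noise fraction.
#' @param seed Integer RNG seed.
#' @return Character vector: reference genes followed by the noise genes.
#' @export
inject_noise <- function(reference_genes, pool, fraction, seed) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L, fraction >= 0)
  reference_genes <- unique(as.character(reference_genes))
  k <- floor(fraction * length(reference_genes) + 0.5)  # round half up
  candidates <- sort(setdiff(unique(as.character(pool)), reference_genes))
  if (k > length(candidates))
    stop("pool too small: need ", k, " noise genes, have ",
         length(candidates))
  noise <- with_seed(seed, sample(candidates, k))
  c(reference_genes, noise)
}

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
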