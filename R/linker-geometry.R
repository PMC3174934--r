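#' Build element vectors over the query gene axes
#'
#' Each GeneTerm-set element becomes a numeric vector of length `M + 1`:
#' the first `M` components are 1/0 occurrence indicators of the query
#' genes (in query order), and the extra component carries the element's
#' p-value weighted by `M`, representing the strength of the gene/term
#' relationship. The extra component is zeroed in `"off"` mode, which is
#' used for the score-stage geometry that is based on the genes only.
#'
#' @param elements List of `GeneTermSet`.
#' @param query A [query_context()]; every element gene must be a query gene.
#' @param p_weight_mode `"literal"` (extra component `p * M`) or `"off"` (0).
#' @return Numeric matrix, one row per element (rownames = element ids),
#'   `M + 1` columns.
#' @export
build_element_vectors <- function(elements, query,
                                  p_weight_mode = c("literal", "off")) {
  stopifnot(inherits(query, "QueryContext"))
  p_weight_mode <- match.arg(p_weight_mode)
  M <- query$M
  V <- matrix(0, nrow = length(elements), ncol = M + 1L,
              dimnames = list(vapply(elements, `[[`, "", "element_id"),
                              c(query$query_genes, ".p_weight")))
  for (i in seq_along(elements)) {
    e <- elements[[i]]
    idx <- match(e$genes, query$query_genes)
    if (anyNA(idx))
      stop("element ", e$element_id, " has gene(s) outside the query list: ",
           paste(utils::head(e$genes[is.na(idx)], 3L), collapse = ", "))
    V[i, idx] <- 1
    if (p_weight_mode == "literal") V[i, M + 1L] <- e$p_value * M
  }
  V
}

#' Pairwise cosine distance matrix
#'
#' `1 - cosine similarity` between the rows of a non-negative matrix; for
#' such vectors the distance lies in `[0, 1]`, the generalisation of the
#' Jaccard coefficient to weighted attributes.
#'
#' @param vectors Numeric matrix (rows = elements); every row norm must be
#'   positive.
#' @return Symmetric matrix with zero diagonal.
#' @export
cosine_distance_matrix <- function(vectors) {
  V <- as.matrix(vectors)
  if (!nrow(V)) stop("need at least one vector")
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0)) stop("zero vector(s): cosine distance undefined")
  S <- (V %*% t(V)) / outer(nrm, nrm)
  D <- 1 - S
  D[D < 0] <- 0
  if (all(V >= 0)) D[D > 1] <- 1
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Agglomerative Ward clustering on a precomputed dissimilarity
#'
#' The Lance-Williams recurrence in the classical `ward.D` convention,
#' applied directly to the supplied dissimilarities (cosine distances here
#' are not guaranteed Euclidean-embeddable, so no squaring is imposed).
#' Ties are broken by the smallest pair of cluster indices, making the tree
#' a pure function of the matrix. Handles `n = 1` (no merges).
#'
#' @param dist A `dist` object or symmetric matrix.
#' @return An object of class `c("ward_tree", "hclust")` with the usual
#'   `merge`, `height`, `order`, `labels` components.
#' @export
ward_tree <- function(dist) {
  D <- as.matrix(dist)
  n <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 0L) stop("empty distance matrix")
  if (!isTRUE(all.equal(D, t(D))) || any(diag(D) != 0))
    stop("dissimilarity matrix must be symmetric with zero diagonal")
  merge <- matrix(0L, max(n - 1L, 0L), 2L)
  height <- numeric(max(n - 1L, 0L))
  if (n > 1L) {
    size <- rep(1L, n)
    id <- -seq_len(n)          # hclust coding: negatives are singletons
    active <- seq_len(n)
    W <- D
    for (m in seq_len(n - 1L)) {
      best <- c(NA_integer_, NA_integer_); bh <- Inf
      for (a in seq_along(active)) {
        i <- active[a]
        for (b in seq_along(active)) {
          if (b <= a) next
          j <- active[b]
          if (W[i, j] < bh - 1e-12) { bh <- W[i, j]; best <- c(i, j) }
        }
      }
      i <- best[1L]; j <- best[2L]
      height[m] <- W[i, j]
      merge[m, ] <- sort(c(id[i], id[j]))
      # Lance-Williams update (ward.D): new cluster stored in slot i
      ni <- size[i]; nj <- size[j]
      for (k in active) {
        if (k == i || k == j) next
        nk <- size[k]
        w <- ((ni + nk) * W[i, k] + (nj + nk) * W[j, k] - nk * W[i, j]) /
          (ni + nj + nk)
        W[i, k] <- W[k, i] <- w
      }
      size[i] <- ni + nj
      id[i] <- m
      active <- setdiff(active, j)
    }
  }
  order <- tree_leaf_order(merge, n)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "ward.D",
                 dist.method = "cosine", call = match.call()),
            class = c("ward_tree", "hclust"))
}

tree_leaf_order <- function(merge, n) {
  if (n == 1L) return(1L)
  leaves <- function(m) {
    if (m < 0) return(-m)
    c(leaves(merge[m, 1L]), leaves(merge[m, 2L]))
  }
  leaves(nrow(merge))
}

#' Cut a Ward tree into preliminary metagroups
#'
#' Cuts at `depth_fraction` of the tree depth (the maximum merge height):
#' clusters are the connected components formed by all merges at or below
#' the cut. If no component holds at least `min_elements` elements the
#' cutoff escalates in `step` absolute increments (20% -> 30% -> ...) until
#' one does or the fraction reaches 1, at which point the whole tree is a
#' single pre-metagroup. Singletons below the cut are kept as candidate
#' singletons for the subsequent term-merge stage.
#'
#' @param tree A [ward_tree()].
#' @param depth_fraction Initial cut, in `(0, 1]`.
#' @param step Escalation step in absolute fraction points, `> 0`.
#' @param min_elements A cut qualifies once some cluster reaches this size.
#' @return List of character vectors of element labels (clusters ordered by
#'   their first leaf).
#' @export
cut_pre_metagroups <- function(tree, depth_fraction = 0.20, step = 0.10,
                               min_elements = 2L) {
  stopifnot(inherits(tree, "hclust"))
  if (!is.numeric(depth_fraction) || depth_fraction <= 0 || depth_fraction > 1)
    stop("depth_fraction must be in (0, 1]")
  if (!is.numeric(step) || step <= 0) stop("step must be > 0")
  n <- length(tree$labels)
  if (n == 1L) return(list(tree$labels))
  maxh <- max(tree$height)
  f <- depth_fraction
  repeat {
    groups <- components_below(tree, f * maxh + 1e-12)
    if (f >= 1 - 1e-12) {
      groups <- list(tree$labels[tree$order])
      break
    }
    if (any(lengths(groups) >= min_elements)) break
    f <- min(1, f + step)
  }
  groups
}

# union-find over merges with height <= cut
components_below <- function(tree, cut) {
  n <- length(tree$labels)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  cl_rep <- integer(nrow(tree$merge))  # representative leaf of each merge
  rep_of <- function(m) if (m < 0) -m else cl_rep[m]
  for (m in seq_along(tree$height)) {
    a <- find(rep_of(tree$merge[m, 1L]))
    b <- find(rep_of(tree$merge[m, 2L]))
    if (tree$height[m] <= cut) parent[b] <- a
    cl_rep[m] <- a
  }
  comp <- vapply(seq_len(n), find, 0L)
  idx <- split(seq_len(n), comp)
  idx <- idx[order(vapply(idx, min, 0L))]
  lapply(idx, function(i) tree$labels[i])
}
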