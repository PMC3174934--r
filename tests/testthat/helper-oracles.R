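# Independent brute-force oracles and small fixture builders.

# P(X >= k) by exhaustive enumeration of all C(N, n) draws from a
# population of N with K successes.
enum_hyper_tail <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)  # successes are items 1..K
  mean(succ >= k)
}

# All closed frequent itemsets by power-set enumeration (<= ~15 items).
# Returns a sorted character vector of "item1+item2|support" signatures.
enum_closed_itemsets <- function(tidlists, min_support) {
  items <- names(tidlists)
  n <- length(items)
  out <- character(0)
  sets <- list()
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    tids <- Reduce(intersect, tidlists[idx])
    if (length(tids) >= min_support)
      sets[[length(sets) + 1L]] <- list(idx = idx, tids = sort(tids))
  }
  for (a in sets) {
    closed <- TRUE
    for (b in sets) {
      if (length(b$idx) > length(a$idx) && all(a$idx %in% b$idx) &&
          identical(a$tids, b$tids)) { closed <- FALSE; break }
    }
    if (closed)
      out <- c(out, paste0(paste(sort(items[a$idx]), collapse = "+"),
                           "|", length(a$tids)))
  }
  sort(unique(out))
}

itemset_signatures <- function(closed) {
  sort(vapply(closed, function(cs)
    paste0(paste(sort(cs$items), collapse = "+"), "|", length(cs$tids)),
    ""))
}

# Benjamini-Hochberg step-up, written from the definition.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}

# Pair confusion by an explicit double loop over all unordered pairs.
loop_pair_confusion <- function(found, reference, genes) {
  co <- function(groups, x, y)
    any(vapply(groups, function(g) x %in% g && y %in% g, TRUE))
  tp <- fp <- fn <- tn <- 0L
  n <- length(genes)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    f <- co(found, genes[i], genes[j])
    r <- co(reference, genes[i], genes[j])
    if (f && r) tp <- tp + 1L else if (f) fp <- fp + 1L
    else if (r) fn <- fn + 1L else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn, total_pairs = choose(n, 2))
}

# quick GeneTermSet builder
el <- function(id, genes, terms, p)
  gene_term_set(id, genes, terms, p)

# random metagroup over a small alphabet, for cover stress tests
random_metagroup <- function(n_elements, genes = letters[1:6],
                             terms = paste0("S:t", 1:6)) {
  els <- lapply(seq_len(n_elements), function(i)
    el(sprintf("E%02d", i),
       sample(genes, sample.int(length(genes), 1L)),
       sample(terms, sample.int(length(terms), 1L)),
       stats::runif(1, 1e-8, 1)))
  metagroup("MG01", els)
}

# two-space toy annotation world used across linker tests
toy_world <- function() {
  universe <- sprintf("g%02d", 1:20)
  sp <- annotation_space(
    "GO-BP",
    list(t1 = universe[1:4], t2 = universe[1:4], t3 = universe[5:8],
         gen = universe[1:18]),
    universe = universe)
  kegg <- annotation_space("KEGG", list(k1 = universe[5:8]),
                           universe = universe)
  list(spaces = list(`GO-BP` = sp, KEGG = kegg), universe = universe)
}
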