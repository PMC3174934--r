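# Closed frequent-itemset mining (LCM-style prefix-preserving closure
# extension). Items are term ids, transactions are genes. Small inputs by
# construction (terms frequent within one query gene list), so clarity is
# preferred over bitset tricks.

# tidlists: named list item -> sorted integer vector of transaction indices.
# Returns list of list(items = character, tids = integer).
mine_closed_itemsets <- function(tidlists, min_support) {
  stopifnot(min_support >= 1)
  items <- names(tidlists)
  keep <- lengths(tidlists) >= min_support
  tidlists <- tidlists[keep]
  items <- items[keep]
  n <- length(items)
  out <- list()
  if (!n) return(out)

  closure_of <- function(tids) {
    # all frequent items present in every supporting transaction
    which(vapply(tidlists, function(tl) all(tids %in% tl), TRUE))
  }

  recurse <- function(closed_idx, tids, last) {
    out[[length(out) + 1L]] <<- list(items = items[closed_idx],
                                     tids = tids)
    for (j in seq_len(n)) {
      if (j <= last || j %in% closed_idx) next
      t2 <- intersect(tids, tidlists[[j]])
      if (length(t2) < min_support) next
      cl <- closure_of(t2)
      # prefix-preserving check: extension j may not pull in an item that
      # precedes it and is not already part of the current closed set
      if (any(cl < j & !(cl %in% closed_idx))) next
      recurse(cl, t2, j)
    }
  }

  all_tids <- sort(unique(unlist(tidlists, use.names = FALSE)))
  root <- closure_of(all_tids)   # items present in every transaction
  if (length(all_tids) >= min_support && length(root)) {
    recurse(root, all_tids, 0L)
  } else {
    recurse(integer(0), all_tids, 0L)
    # drop the empty root itemset emitted by the recursion above
    out <- Filter(function(e) length(e$items) > 0L, out)
  }
  out
}
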