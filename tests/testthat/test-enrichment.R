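test_that("hypergeometric tail matches hand and enumeration values", {
  expect_equal(hypergeometric_tail(0, 5, 4, 10), 1)
  expect_equal(hypergeometric_tail(4, 4, 4, 4), 1)   # certain event
  expect_equal(hypergeometric_tail(3, 5, 4, 10), 66 / 252)
  expect_equal(hypergeometric_tail(3, 5, 4, 10),
               enum_hyper_tail(3, 5, 4, 10))
  expect_error(hypergeometric_tail(5, 4, 10, 10), "bounds")
  expect_error(hypergeometric_tail(2, 5, 4, 3), "bounds")
  expect_error(hypergeometric_tail(1.5, 5, 4, 10), "integer")
})

test_that("query_context deduplicates with a warning and validates sizes", {
  expect_warning(qc <- query_context(c("a", "b", "a"), 10), "duplicated")
  expect_identical(qc$query_genes, c("a", "b"))
  expect_identical(qc$M, 2L)
  expect_error(query_context(character(0), 5), "empty query")
  expect_error(query_context(c("a", "b"), 1), "universe_size")
})

test_that("singular enrichment reproduces the hypergeometric worked case", {
  universe <- sprintf("u%02d", 1:10)
  sp <- annotation_space("S", list(t1 = universe[1:4], t0 = universe[9:10]),
                         universe = universe)
  qc <- query_context(c(universe[1:3], universe[5:6]), 10)
  els <- singular_enrichment(qc, sp, min_support = 3, p_max = 1)
  expect_length(els, 1L)  # t0 shares no query gene -> nothing emitted
  expect_identical(els[[1]]$terms, "S:t1")
  expect_setequal(els[[1]]$genes, universe[1:3])
  expect_equal(els[[1]]$p_value, 66 / 252, tolerance = 1e-12)
})

test_that("a term covering the whole query yields G = query", {
  universe <- sprintf("u%02d", 1:10)
  sp <- annotation_space("S", list(all = universe), universe = universe)
  qc <- query_context(universe[1:5], 10)
  els <- singular_enrichment(qc, sp, min_support = 1, p_max = 1)
  expect_setequal(els[[1]]$genes, qc$query_genes)
})

test_that("closed itemsets collapse synonymous terms into one element", {
  universe <- sprintf("u%02d", 1:12)
  sp <- annotation_space("S", list(t1 = universe[1:4], t2 = universe[1:4]),
                         universe = universe)
  qc <- query_context(universe[1:4], 12)
  els <- concurrent_enrichment(qc, sp, min_support = 2, p_max = 1)
  expect_length(els, 1L)
  expect_setequal(els[[1]]$terms, c("S:t1", "S:t2"))
})

test_that("the three-transaction worked lattice is enumerated", {
  # g1:{t1,t2}, g2:{t1,t2}, g3:{t1}; support 2 -> {t1}(3) and {t1,t2}(2)
  universe <- c("g1", "g2", "g3", "g4")
  sp <- annotation_space("S", list(t1 = c("g1", "g2", "g3"),
                                   t2 = c("g1", "g2")),
                         universe = universe)
  qc <- query_context(c("g1", "g2", "g3"), 4)
  els <- concurrent_enrichment(qc, sp, min_support = 2, p_max = 1)
  sig <- vapply(els, function(e)
    paste0(paste(sort(e$terms), collapse = "+"), "|", length(e$genes)), "")
  expect_setequal(sig, c("S:t1|3", "S:t1+S:t2|2"))
  expect_length(concurrent_enrichment(qc, sp, min_support = 4, p_max = 1),
                0L)  # unattainable support
})

test_that("closed-itemset mining agrees with power-set enumeration", {
  set.seed(3)
  for (rep in 1:8) {
    n_items <- sample(3:8, 1)
    n_trans <- sample(4:12, 1)
    tidlists <- lapply(seq_len(n_items), function(i)
      sort(sample(seq_len(n_trans), sample(seq_len(n_trans), 1))))
    names(tidlists) <- sprintf("t%d", seq_len(n_items))
    minsup <- sample(1:3, 1)
    got <- itemset_signatures(mine_closed_itemsets(tidlists, minsup))
    want <- enum_closed_itemsets(tidlists, minsup)
    expect_identical(got, want)
  }
})

random_enrichment_world <- function(seed) {
  set.seed(seed)
  universe <- sprintf("g%03d", 1:40)
  tg <- lapply(1:8, function(i) sample(universe, sample(3:15, 1)))
  names(tg) <- sprintf("T%d", 1:8)
  sp <- annotation_space("S", tg, universe = universe)
  qc <- query_context(sample(universe, 12), 40)
  list(sp = sp, qc = qc)
}

test_that("MEA singletons agree with SEA, and emitted sets co-annotate", {
  for (seed in 1:5) {
    w <- random_enrichment_world(seed)
    mea <- concurrent_enrichment(w$qc, w$sp, min_support = 2, p_max = 1)
    sea <- singular_enrichment(w$qc, w$sp, min_support = 2, p_max = 1)
    sea_by_term <- setNames(sea, vapply(sea, `[[`, "", "terms"))
    for (e in mea) {
      # co-annotation invariant: every gene carries every term
      carriers <- Reduce(intersect,
                         w$sp$term_to_genes[sub("^S:", "", e$terms)])
      expect_true(all(e$genes %in% carriers))
      if (length(e$terms) == 1L) {
        twin <- sea_by_term[[e$terms]]
        expect_setequal(e$genes, twin$genes)
        expect_equal(e$p_value, twin$p_value)
      }
    }
    # every SEA term appears somewhere in the MEA output (inside its closure)
    mea_terms <- unlist(lapply(mea, `[[`, "terms"))
    expect_true(all(vapply(sea, `[[`, "", "terms") %in% mea_terms))
    # anti-monotone support over all nested emitted pairs
    for (a in mea) for (b in mea) {
      if (length(a$terms) < length(b$terms) && all(a$terms %in% b$terms))
        expect_gte(length(a$genes), length(b$genes))
    }
  }
})

test_that("GeneTerm-set TSVs load, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("element_id\tgenes\tterms\tp_value",
               "E1\ta,b\tGO:1;KEGG:2\t0.001"), path)
  expect_warning(els <- read_genetermsets(path), "trusted")
  expect_length(els[[1]]$genes, 2L)
  expect_length(els[[1]]$terms, 2L)

  writeLines(c("element_id\tgenes\tterms\tp_value",
               "E1\ta\tGO:1\t0.5", "E2\ta\tGO:1\t1.5"), path)
  expect_error(read_genetermsets(path), "row 2")

  orig <- list(el("E1", c("b", "a"), c("S:t2", "S:t1"), 0.012345),
               el("E2", "c", "S:t3", 1e-9))
  write_genetermsets(orig, path)
  expect_warning(back <- read_genetermsets(path), "trusted")
  for (i in 1:2) {
    expect_setequal(back[[i]]$genes, orig[[i]]$genes)
    expect_setequal(back[[i]]$terms, orig[[i]]$terms)
    expect_equal(back[[i]]$p_value, orig[[i]]$p_value)
    expect_identical(back[[i]]$element_id, orig[[i]]$element_id)
  }
})

test_that("loading against spaces enforces co-annotation", {
  w <- toy_world()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("element_id\tgenes\tterms\tp_value",
               sprintf("E1\t%s;%s\tGO-BP:t1\t0.01", "g01", "g09")), path)
  expect_error(read_genetermsets(path, w$spaces), "not annotated")
})
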