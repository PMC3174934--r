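policy_for <- function(space_id, generic = character(0))
  structure(list(space_id = space_id, mean_ng = 0, sigma_ng = 0,
                 n_factor = 4, threshold = Inf, generic_terms = generic),
            class = "GenericTermPolicy")

test_that("step 1 removes exactly the all-generic elements", {
  pol <- policy_for("S", generic = c("gen1", "gen2"))
  e_all <- el("E1", "a", c("S:gen1", "S:gen2"), 0.01)
  e_mix <- el("E2", "b", c("S:gen1", "S:spec1"), 0.01)
  e_spec <- el("E3", "c", "S:spec2", 0.01)
  out <- filter_generic_only(list(e_all, e_mix, e_spec), pol)
  expect_identical(vapply(out, `[[`, "", "element_id"), c("E2", "E3"))
  # survivors keep their full term sets, generic included
  expect_setequal(out[[1]]$terms, c("S:gen1", "S:spec1"))
  expect_identical(filter_generic_only(list(), pol), list())
  expect_error(filter_generic_only(list(el("E4", "a", "X:t", 0.1)), pol),
               "no generic-term policy")
})

test_that("greedy term merge reaches its fixed point transitively", {
  pol <- policy_for("S", generic = "gen")
  A <- list(el("E1", "a", c("S:t1"), 0.01))
  B <- list(el("E2", "b", c("S:t1", "S:t2"), 0.02))
  C <- list(el("E3", "c", c("S:t2"), 0.03))
  D <- list(el("E4", "d", c("S:t9"), 0.04))
  merged <- greedy_term_merge(list(A, B, C, D), pol)
  expect_length(merged, 2L)  # A-B share t1, B-C share t2 -> one group + D
  sizes <- sort(vapply(merged, function(g) length(g$elements), 0L))
  expect_identical(sizes, c(1L, 3L))
  # no shared terms anywhere: untouched
  lone <- greedy_term_merge(list(A, C, D), pol)
  expect_length(lone, 3L)
  # generic terms never count toward sharing
  g1 <- list(el("E1", "a", c("S:gen", "S:t1"), 0.01))
  g2 <- list(el("E2", "b", c("S:gen", "S:t2"), 0.02))
  expect_length(greedy_term_merge(list(g1, g2), pol), 2L)
})

test_that("complete cover reproduces the worked removals", {
  g <- metagroup("M", list(
    el("E1", c("a", "b"), c("S:t1", "S:t2"), 1e-5),
    el("E2", "a", "S:t1", 1e-3)))
  out <- complete_cover(g)
  expect_identical(vapply(out$elements, `[[`, "", "element_id"), "E1")

  g3 <- metagroup("M", list(
    el("E1", c("a", "b"), c("S:t1", "S:t2"), 1e-4),
    el("E2", "a", "S:t1", 1e-3),
    el("E3", "b", "S:t2", 1e-2)))
  out3 <- complete_cover(g3)
  expect_identical(vapply(out3$elements, `[[`, "", "element_id"), "E1")
  expect_identical(out3$union_genes, g3$union_genes)
  expect_identical(out3$union_terms, g3$union_terms)

  # every element owns a unique gene: nothing can be removed
  un <- metagroup("M", list(el("E1", "a", "S:t1", 0.1),
                            el("E2", "b", "S:t1", 0.2)))
  expect_length(complete_cover(un)$elements, 2L)
})

test_that("complete cover preserves unions and is single-removal minimal", {
  set.seed(13)
  for (rep in 1:100) {
    g <- random_metagroup(sample(2:7, 1))
    out <- complete_cover(g)
    expect_identical(out$union_genes, g$union_genes)
    expect_identical(out$union_terms, g$union_terms)
    els <- out$elements
    for (i in seq_along(els)) {
      rest <- els[-i]
      if (!length(rest)) next
      og <- unique(unlist(lapply(rest, `[[`, "genes")))
      ot <- unique(unlist(lapply(rest, `[[`, "terms")))
      expect_false(all(els[[i]]$genes %in% og) &&
                     all(els[[i]]$terms %in% ot))
    }
  }
})

test_that("complete cover is input-order independent and id-tie-broken", {
  set.seed(29)
  for (rep in 1:20) {
    g <- random_metagroup(5)
    ids0 <- sort(vapply(complete_cover(g)$elements, `[[`, "",
                        "element_id"))
    perm <- metagroup(g$metagroup_id, sample(g$elements))
    ids1 <- sort(vapply(complete_cover(perm)$elements, `[[`, "",
                        "element_id"))
    expect_identical(ids0, ids1)
  }
  # equal p-values: the lexicographically smaller id is retained
  tie <- metagroup("M", list(el("E2", "a", "S:t1", 0.5),
                             el("E1", "a", "S:t1", 0.5)))
  expect_identical(vapply(complete_cover(tie)$elements, `[[`, "",
                          "element_id"), "E1")
})

scored_toy <- function() {
  w <- toy_world()
  qc <- query_context(w$universe[1:8], 20)
  g1 <- metagroup("MG01", list(
    el("E1", w$universe[1:4], c("GO-BP:t1", "GO-BP:t2"), 1e-4),
    el("E2", w$universe[1:4], "GO-BP:t1", 1e-3)))
  g2 <- metagroup("MG02", list(
    el("E3", w$universe[5:8], c("GO-BP:t3", "KEGG:k1"), 1e-2),
    el("E4", w$universe[5:8], "GO-BP:t3", 2e-2)))
  score_metagroups(list(g1, g2), qc, w$spaces)
}

test_that("score stage: geometry conventions and BH adjustment", {
  scored <- scored_toy()
  by_id <- setNames(scored, vapply(scored, `[[`, "", "metagroup_id"))
  # within-distances 0, between-distances 1 -> silhouette 1 for both
  expect_equal(by_id$MG01$silhouette, 1)
  expect_equal(by_id$MG02$silhouette, 1)
  expect_equal(by_id$MG01$diameter, 0)
  expect_equal(by_id$MG01$similarity_coefficient, 1)
  for (g in scored) {
    expect_gte(g$adjusted_p, g$raw_p)
    expect_true(g$diameter >= 0 && g$diameter <= 1)
    expect_true(g$similarity_coefficient >= 0 &&
                  g$similarity_coefficient <= 1)
    expect_true(is.na(g$silhouette) ||
                  (g$silhouette >= -1 && g$silhouette <= 1))
  }
  # ranked by adjusted p
  expect_equal(order(vapply(scored, `[[`, 0, "adjusted_p")),
               seq_along(scored))
})

test_that("a singleton-element group scores silhouette 0, diameter 0", {
  w <- toy_world()
  qc <- query_context(w$universe[1:8], 20)
  g1 <- metagroup("MG01", list(
    el("E1", w$universe[1:4], "GO-BP:t1", 1e-4),
    el("E2", w$universe[1:4], "GO-BP:t2", 1e-3)))
  g2 <- metagroup("MG02", list(
    el("E3", w$universe[5:8], "GO-BP:t3", 1e-2)))
  scored <- score_metagroups(list(g1, g2), qc, w$spaces)
  by_id <- setNames(scored, vapply(scored, `[[`, "", "metagroup_id"))
  expect_equal(by_id$MG02$silhouette, 0)
  expect_equal(by_id$MG02$diameter, 0)
  expect_equal(by_id$MG02$similarity_coefficient, 1)
})

test_that("a lone metagroup has undefined silhouette", {
  w <- toy_world()
  qc <- query_context(w$universe[1:4], 20)
  g <- metagroup("MG01", list(el("E1", w$universe[1:4], "GO-BP:t1", 1e-3)))
  scored <- score_metagroups(list(g), qc, w$spaces)
  expect_true(is.na(scored[[1]]$silhouette))
  expect_equal(scored[[1]]$diameter, 0)
})

test_that("score errors when metagroup genes leave the query", {
  w <- toy_world()
  qc <- query_context(w$universe[1:3], 20)
  g <- metagroup("MG01", list(el("E1", w$universe[1:4], "GO-BP:t1", 1e-3)))
  expect_error(score_metagroups(list(g), qc, w$spaces), "outside the query")
})

test_that("BH adjustment matches the hand example and the step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  set.seed(17)
  for (rep in 1:20) {
    p <- runif(sample(2:6, 1))
    expect_equal(p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }
  # and through the score stage itself: raw -> adjusted obeys the oracle
  scored <- scored_toy()
  raw <- vapply(scored, `[[`, 0, "raw_p")
  adj <- vapply(scored, `[[`, 0, "adjusted_p")
  expect_equal(adj, bh_stepup(raw), tolerance = 1e-12)
})

test_that("end-to-end linking conserves elements and is deterministic", {
  sim <- generate_space(synthetic_design(seed = 3))
  universe <- sim$reference$universe
  qc <- query_context(unlist(sim$reference$groups), length(universe))
  els <- concurrent_enrichment(qc, sim$spaces)
  res <- link_metagroups(els, qc, sim$spaces)
  # every non-filtered element lands in exactly one metagroup before cover;
  # after cover the unions per metagroup must still be recomputable
  for (g in res$metagroups) {
    expect_identical(g$union_genes,
                     sort(unique(unlist(lapply(g$elements, `[[`,
                                               "genes")))))
    expect_identical(g$union_terms,
                     sort(unique(unlist(lapply(g$elements, `[[`,
                                               "terms")))))
  }
  expect_length(res$metagroups, 5L)
  for (m in names(sim$reference$groups)) {
    hit <- any(vapply(res$metagroups, function(g)
      all(sim$reference$groups[[m]] %in% g$union_genes), TRUE))
    expect_true(hit, label = paste("module", m, "recovered"))
  }
  # byte-identical reports across reruns: no RNG anywhere in the linker
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_metagroup_report(res$metagroups, p1)
  res2 <- link_metagroups(els, qc, sim$spaces)
  write_metagroup_report(res2$metagroups, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("small queries warn instead of failing", {
  w <- toy_world()
  qc <- query_context(w$universe[1:4], 20)
  els <- list(el("E1", w$universe[1:2], "GO-BP:t1", 1e-3),
              el("E2", w$universe[3:4], "GO-BP:t2", 1e-3))
  expect_warning(res <- link_metagroups(els, qc, w$spaces),
                 "seven genes")
  expect_gte(length(res$metagroups), 1L)
})
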