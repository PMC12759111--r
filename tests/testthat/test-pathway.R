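test_that("hypergeometric ORA matches exhaustive subset enumeration", {
  universe <- paste0("g", 1:10)
  term <- universe[1:4]

  # saturated draw
  expect_equal(ora_hypergeometric(universe, term, universe)$p, 1)

  # the 6/252 case: N=10, K=4, n=5, k=4
  query <- universe[c(1:4, 10)]
  o <- ora_hypergeometric(query, term, universe)
  expect_equal(o$k, 4)
  expect_equal(o$p, 6 / 252, tolerance = 1e-12)
  expect_equal(o$p, ora_p_oracle(10, 4, 5, 4), tolerance = 1e-12)

  # zero overlap is vacuous
  expect_equal(ora_hypergeometric(universe[9:10], universe[1:4], universe)$p, 1)

  # random configurations vs enumeration at N <= 12
  set.seed(60)
  for (i in 1:20) {
    N <- sample(6:12, 1)
    uni <- paste0("g", seq_len(N))
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    q <- sample(uni, n)
    tm <- uni[seq_len(K)]
    k <- length(intersect(q, tm))
    expect_equal(ora_hypergeometric(q, tm, uni)$p, ora_p_oracle(N, K, n, k),
                 tolerance = 1e-10)
  }

  expect_error(ora_hypergeometric(character(0), term, universe), "empty query")
  expect_error(ora_hypergeometric(query, term, character(0)), "empty universe")
})

test_that("enrich_terms applies BH within the collection", {
  set.seed(61)
  universe <- paste0("g", 1:100)
  sets <- list(A = universe[1:20], B = universe[21:25], C = sample(universe, 30))
  res <- enrich_terms(universe[1:15], sets, universe, source = "KEGG")
  expect_equal(nrow(res), 3)
  expect_true(all(res$adj_p >= res$raw_p))
  expect_equal(res$adj_p, p.adjust(res$raw_p, "BH"), tolerance = 1e-12)
})

test_that("Jaccard similarity basics", {
  expect_equal(jaccard_similarity(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(jaccard_similarity(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard_similarity(c("a", "b", "c"), c("a", "b", "d", "e")), 0.4)
  expect_warning(z <- jaccard_similarity(character(0), character(0)), "empty")
  expect_equal(z, 0)
})

test_that("Wang similarity: hand-recursion oracle and structural properties", {
  edges <- data.frame(child = c("A", "B"), parent = c("R", "R"),
                      relation = c("is_a", "is_a"))
  g <- ontology_graph(edges)
  expect_equal(wang_similarity("A", "A", g), 1)
  # T_A = {A, R}, S_A(R) = 0.8; shared ancestor {R}:
  # (0.8 + 0.8) / (1.8 + 1.8) = 4/9
  expect_equal(wang_similarity("A", "B", g), 4 / 9, tolerance = 1e-12)
  expect_equal(wang_similarity("A", "B", g), wang_similarity("B", "A", g))

  # disconnected components share no ancestors
  edges2 <- rbind(edges, data.frame(child = "X", parent = "Y", relation = "part_of"))
  g2 <- ontology_graph(edges2)
  expect_equal(wang_similarity("A", "X", g2), 0)

  # deeper DAG with mixed relations, against a direct recursive evaluation
  edges3 <- data.frame(
    child = c("C", "C", "D", "E", "F"),
    parent = c("D", "E", "R", "R", "R"),
    relation = c("is_a", "part_of", "is_a", "is_a", "part_of"))
  g3 <- ontology_graph(edges3)
  # S_C: C=1, D=0.8, E=0.6, R=max(0.8*0.8, 0.6*0.8)=0.64 ; SV=3.04
  # S_F: F=1, R=0.6 ; SV=1.6 ; shared {R}: (0.64+0.6)/(3.04+1.6)
  expect_equal(wang_similarity("C", "F", g3), (0.64 + 0.6) / (3.04 + 1.6),
               tolerance = 1e-12)

  expect_error(wang_similarity("A", "nope", g), "absent")
  cyc <- data.frame(child = c("A", "B"), parent = c("B", "A"),
                    relation = c("is_a", "is_a"))
  expect_error(ontology_graph(cyc), "cycle")
})

test_that("reduce_terms: collapse, components oracle, determinism", {
  # two identical gene sets collapse to the smaller adjusted p
  sets <- list(t1 = c("a", "b", "c"), t2 = c("a", "b", "c"))
  terms <- data.frame(term = c("t1", "t2"), source = "KEGG",
                      raw_p = c(0.005, 0.02), adj_p = c(0.01, 0.03))
  red <- reduce_terms(terms, sets)
  expect_equal(length(unique(red$community)), 1)
  expect_equal(red$term[red$is_representative], "t1")

  # all similarities at/below threshold: every term is its own representative
  sets2 <- list(u1 = c("a", "b"), u2 = c("c", "d"), u3 = c("e", "f"))
  terms2 <- data.frame(term = names(sets2), source = "Reactome",
                       raw_p = c(0.1, 0.2, 0.3), adj_p = c(0.1, 0.2, 0.3))
  red2 <- reduce_terms(terms2, sets2)
  expect_true(all(red2$is_representative))

  # 9-term fixture: two cliques plus an isolate -> 3 representatives,
  # agreeing with a brute-force component count
  pool1 <- paste0("x", 1:10)
  pool2 <- paste0("y", 1:10)
  sets9 <- c(
    lapply(1:4, function(i) pool1[-i]),          # clique 1: Jaccard 8/10
    lapply(1:4, function(i) pool2[-i]),          # clique 2
    list(paste0("z", 1:10))                      # isolate
  )
  names(sets9) <- paste0("T", 1:9)
  terms9 <- data.frame(term = names(sets9), source = "KEGG",
                       raw_p = seq(0.001, 0.009, by = 0.001),
                       adj_p = seq(0.01, 0.09, by = 0.01))
  red9 <- reduce_terms(terms9, sets9)
  sim <- outer(names(sets9), names(sets9),
               Vectorize(function(i, j) jaccard_similarity(sets9[[i]], sets9[[j]])))
  expect_equal(sum(red9$is_representative), components_oracle(sim, 0.5))
  expect_equal(sum(red9$is_representative), 3)
  expect_true(all(c("T1", "T5", "T9") %in% red9$term[red9$is_representative]))

  # representative count bounded by term count; input order irrelevant
  shuffled <- terms9[c(5, 9, 1, 7, 3, 2, 8, 6, 4), ]
  red9b <- reduce_terms(shuffled, sets9)
  expect_identical(red9[order(red9$term), c("term", "community", "is_representative")],
                   red9b[order(red9b$term), c("term", "community", "is_representative")])

  # GO terms need an ontology unless the fallback is requested
  terms_go <- data.frame(term = c("t1", "t2"), source = "GO",
                         raw_p = c(0.01, 0.02), adj_p = c(0.01, 0.02))
  expect_error(reduce_terms(terms_go, sets), "ontology")
  red_go <- reduce_terms(terms_go, sets, go_jaccard = TRUE)
  expect_equal(sum(red_go$is_representative), 1)
})

test_that("GMT files round-trip", {
  sets <- list(S1 = c("a", "b", "c"), S2 = c("d", "e"))
  path <- tempfile(fileext = ".gmt")
  on.exit(unlink(path))
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back$S1, sets$S1)
  expect_equal(back$S2, sets$S2)
})
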