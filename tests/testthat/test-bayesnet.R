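# Hand-built network helper: parents is a named list over `nodes`.
make_net <- function(nodes, parents = list()) {
  par <- stats::setNames(rep(list(character()), length(nodes)), nodes)
  for (nd in names(parents)) par[[nd]] <- parents[[nd]]
  edges <- do.call(rbind, c(list(
    data.frame(parent = character(), child = character(),
               strength = numeric(), log10_strength = numeric())),
    lapply(names(par), function(v)
      if (length(par[[v]]))
        data.frame(parent = par[[v]], child = v, strength = NA_real_,
                   log10_strength = NA_real_))))
  structure(list(nodes = nodes, parents = par, edges = edges,
                 score = NA_real_, score_trace = numeric(),
                 learn_meta = list(penalty_weight = 1)),
            class = "directed_network")
}

test_that("mdl score matches the closed multinomial form", {
  # exactly uniform single column: -loglik = N log 4, penalty = 1.5 log N
  N <- 400L
  aln <- make_aln(rep(c("a", "c", "g", "u"), N / 4),
                  ids = sprintf("q%03d", 1:N), column_labels = "X")
  expect_equal(mdl_score(aln, list(X = character())),
               N * log(4) + 0.5 * 3 * log(N))
  # doubling the penalty weight doubles only the penalty term
  expect_equal(mdl_score(aln, list(X = character()), penalty_weight = 2),
               N * log(4) + 3 * log(N))
})

test_that("a copy parent zeroes the likelihood term at a known penalty", {
  set.seed(20)
  N <- 200L
  x <- sample(c("a", "c", "g", "u"), N, replace = TRUE)
  aln <- make_aln(paste0(x, x), ids = sprintf("q%03d", 1:N),
                  column_labels = c("X", "Y"))
  tab <- tabulate(factor(x, c("a", "c", "g", "u")), 4)
  ll_marg <- sum(tab * log(tab / N))
  s_with <- mdl_score(aln, list(Y = "X"))       # family Y | X only
  s_without <- mdl_score(aln, list(Y = character()))
  expect_equal(s_with, 0.5 * 3 * 4 * log(N))    # -loglik == 0, 12 params
  expect_equal(s_without, -ll_marg + 0.5 * 3 * log(N))
  # the edge pays off exactly when N H(X) beats the extra penalty
  expect_lt(s_with, s_without)
  # edge strength equals the exponentiated closed-form delta
  net <- make_net(c("X", "Y"), list(Y = "X"))
  expect_equal(edge_strength(aln, net, "X", "Y"),
               exp(s_without - s_with))
  expect_equal(edge_strength(aln, net, "X", "Y", log10 = TRUE),
               (s_without - s_with) / log(10))
  expect_error(edge_strength(aln, net, "Y", "X"), "not present")
})

test_that("the score is decomposable over families", {
  aln <- make_chain_aln(n = 500, seed = 3)
  full <- mdl_score(aln, list(X = character(), Y = "X", Z = "Y"))
  fam <- mdl_score(aln, list(X = character())) +
    mdl_score(aln, list(Y = "X")) + mdl_score(aln, list(Z = "Y"))
  expect_equal(full, fam)
  # removing an edge changes only its child's family score
  no_edge <- mdl_score(aln, list(X = character(), Y = "X", Z = character()))
  expect_equal(full - no_edge,
               mdl_score(aln, list(Z = "Y")) - mdl_score(aln, list(Z = character())))
})

test_that("families with zero complete-case rows are an error", {
  # complementary missingness: no row observes both columns
  aln <- make_aln(c("a-", "c-", "-g", "-u"))
  expect_error(mdl_score(aln, list(`2` = "1"), gap_threshold = 1),
               "zero complete-case rows")
})

test_that("independent uniform columns yield the empty graph", {
  sim <- generate_alignment(plain_spec(n_per_class = 400, n_columns = 3,
                                       seed = 14))
  net <- learn_structure(sim$alignment, restarts = 3, seed = 2)
  expect_equal(nrow(net$edges), 0L)
  # the empty graph is also the exhaustive optimum over all 25 DAGs
  best <- exhaustive_best_score(sim$alignment)
  expect_equal(attr(best, "n_dags"), 25L)
  expect_equal(net$score, as.numeric(best))
})

test_that("chain data is recovered without a shortcut edge", {
  aln <- make_chain_aln(n = 2000, rho = 0.9, seed = 5)
  net <- learn_structure(aln, restarts = 5, seed = 1)
  expect_setequal(skeleton_of(net), c("X|Y", "Y|Z"))
  # matches the exhaustive search optimum
  expect_equal(net$score, as.numeric(exhaustive_best_score(aln)))
})

test_that("planted complementary pairs are recovered as skeleton edges", {
  spec <- synthetic_spec(n_per_class = 500,
                         classes = list(c("Gly", "Bac"), c("Ala", "Bac")),
                         n_columns = 8,
                         stems = list(list(col_a = 1, col_b = 8,
                                           complementarity = 0.95),
                                      list(col_a = 2, col_b = 7,
                                           complementarity = 0.95)),
                         invariant_columns = c(), determinants = list(),
                         gap_columns = c(), seed = 21)
  sim <- generate_alignment(spec)
  net <- learn_structure(sim$alignment, restarts = 3, seed = 4)
  sk <- skeleton_of(net)
  expect_true(all(c("1|8", "2|7") %in% sk))
  # every retained edge improves the score: strength >= 1
  expect_true(all(net$edges$strength >= 1))
  expect_true(all(net$edges$log10_strength >= 0))
})

test_that("hill climbing is monotone and deterministic", {
  sim <- generate_alignment(synthetic_spec(n_per_class = 250,
                                           classes = list(c("Gly", "Bac"),
                                                          c("Ala", "Bac")),
                                           n_columns = 6,
                                           stems = list(list(col_a = 1,
                                                             col_b = 6,
                                                             complementarity = 0.9)),
                                           invariant_columns = c(),
                                           determinants = list(),
                                           gap_columns = c(), seed = 31))
  a <- learn_structure(sim$alignment, restarts = 4, seed = 7)
  b <- learn_structure(sim$alignment, restarts = 4, seed = 7)
  expect_identical(a$edges, b$edges)
  expect_identical(a$score, b$score)
  expect_true(all(diff(a$score_trace) < 0))
  expect_equal(a$score, sum(vapply(a$nodes, function(v)
    mdl_score(sim$alignment, stats::setNames(list(a$parents[[v]]), v)), 0)))
})

test_that("degenerate and gap-heavy inputs are handled as documented", {
  const <- make_aln(rep("aaaa", 50))
  expect_message(net <- learn_structure(const, restarts = 1, seed = 1),
                 "constant")
  expect_equal(nrow(net$edges), 0L)
  # a >50% gap column is dropped from the node set
  gappy <- make_aln(c(rep("a-cg", 30), rep("aacg", 10)))
  expect_message(net2 <- learn_structure(gappy, restarts = 1, seed = 1),
                 "gap fraction")
  expect_false("2" %in% net2$nodes)
})

test_that("the class variable can enter as an ordinary node", {
  sim <- generate_alignment(synthetic_spec(
    n_per_class = 400, classes = list(c("Gly", "Bac"), c("Ala", "Bac")),
    n_columns = 4, stems = list(), invariant_columns = c(),
    determinants = list(list(column = 2, aa_class = "Gly",
                             life_domain = "Bac",
                             shift = c(0.97, 0.01, 0.01, 0.01))),
    gap_columns = c(), seed = 41))
  net <- learn_structure(sim$alignment, restarts = 3, seed = 2,
                         include_class_node = TRUE)
  expect_true("100" %in% net$nodes)
  # the determinant column must attach to the class node
  expect_true("100|2" %in% skeleton_of(net))
})

test_that("local models are conditional frequency tables", {
  sim <- generate_alignment(synthetic_spec(
    n_per_class = 1000, classes = list(c("Gly", "Bac")), n_columns = 4,
    stems = list(list(col_a = 1, col_b = 2, complementarity = 1)),
    invariant_columns = c(), determinants = list(), gap_columns = c(),
    seed = 51))
  # no parents: the marginal
  lm0 <- fit_local_model(sim$alignment, "3")
  expect_equal(nrow(lm0$table), 1L)
  expect_equal(sum(lm0$table), 1)
  # perfect complementarity: indicator rows a->u, c->g, g->c, u->a
  lm1 <- fit_local_model(sim$alignment, "2", "1")
  expect_equal(unname(lm1$table["a", ]), c(0, 0, 0, 1))
  expect_equal(unname(lm1$table["c", ]), c(0, 0, 1, 0))
  expect_equal(unname(lm1$table["g", ]), c(0, 1, 0, 0))
  expect_equal(unname(lm1$table["u", ]), c(1, 0, 0, 0))
  expect_true(all(abs(rowSums(lm1$table) - 1) < 1e-12))
  # 90% pair: diagonal-complement entries near 0.9
  spec2 <- synthetic_spec(n_per_class = 4000, classes = list(c("Gly", "Bac")),
                          n_columns = 4,
                          stems = list(list(col_a = 1, col_b = 2,
                                            complementarity = 0.9)),
                          invariant_columns = c(), determinants = list(),
                          gap_columns = c(), seed = 52)
  sim2 <- generate_alignment(spec2)
  lm2 <- fit_local_model(sim2$alignment, "2", "1")
  p_wc <- 0.9 + 0.1 * 0.25
  n_a <- sum(sim2$alignment$mat[, 1] == "a")
  expect_lt(abs(lm2$table["a", "u"] - p_wc), 3 * sqrt(p_wc * (1 - p_wc) / n_a))
  # unobserved parent combinations are flagged and uniform
  tiny <- make_aln(c("aa", "aa", "ac"))
  lm3 <- fit_local_model(tiny, "2", "1")
  expect_false(lm3$observed[["c"]])
  expect_equal(unname(lm3$table["c", ]), rep(0.25, 4))
})

test_that("markov blankets follow the parents/children/co-parents rule", {
  nodes <- c("W", "X", "Y", "Z")
  chain <- make_net(nodes, list(Y = "X", Z = "Y"))
  expect_equal(markov_blanket(chain, "Y"), c("X", "Z"))
  expect_equal(markov_blanket(chain, "W"), character())   # isolated node
  collider <- make_net(nodes, list(Y = c("X", "Z")))
  expect_equal(markov_blanket(collider, "X"), c("Y", "Z"))  # co-parent
  expect_error(markov_blanket(chain, "Q"), "unknown node")
})

test_that("cpdag conversion marks compelled and reversible edges", {
  nodes <- c("X", "Y", "Z")
  chain <- to_cpdag(make_net(nodes, list(Y = "X", Z = "Y")))
  expect_equal(nrow(chain), 2L)
  expect_false(any(chain$directed))          # no v-structure: all reversible
  collider <- to_cpdag(make_net(nodes, list(Y = c("X", "Z"))))
  expect_true(all(collider$directed))        # v-structure: both compelled
  single <- to_cpdag(make_net(c("X", "Y"), list(Y = "X")))
  expect_false(single$directed)
  # orientation propagation: X -> Y <- Z plus Y - W compels Y -> W
  ext <- to_cpdag(make_net(c("X", "Y", "Z", "W"),
                           list(Y = c("X", "Z"), W = "Y")))
  expect_true(ext$directed[ext$parent == "Y" & ext$child == "W"])
})

test_that("dot / edge-list / cpt exports are written and well formed", {
  sim <- generate_alignment(synthetic_spec(
    n_per_class = 300, classes = list(c("Gly", "Bac")), n_columns = 4,
    stems = list(list(col_a = 1, col_b = 4, complementarity = 0.95)),
    invariant_columns = c(), determinants = list(), gap_columns = c(),
    seed = 61))
  net <- learn_structure(sim$alignment, restarts = 2, seed = 3)
  d <- withr::local_tempdir()
  write_dot(net, file.path(d, "net.dot"))
  dot <- readLines(file.path(d, "net.dot"))
  expect_equal(dot[1], "digraph bn {")
  expect_true(any(grepl("->", dot, fixed = TRUE)))
  write_edges_tsv(net, file.path(d, "edges.tsv"))
  edges <- utils::read.delim(file.path(d, "edges.tsv"),
                             colClasses = c(parent = "character",
                                            child = "character"))
  expect_equal(nrow(edges), nrow(net$edges))
  write_cpts(sim$alignment, net, file.path(d, "cpts"))
  expect_true(all(file.exists(file.path(d, "cpts",
                                        paste0("cpt_", net$nodes, ".tsv")))))
})
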