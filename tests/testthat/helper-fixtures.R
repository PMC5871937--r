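# In-code fixtures shared across the suite.

# Build a labeled_alignment from residue strings.
make_aln <- function(seqs, ids = NULL, column_labels = NULL, classes = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(seqs))
  mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(ids, NULL))
  labeled_alignment(mat, column_labels = column_labels, classes = classes)
}

# Spec with no planted structure: i.i.d. background columns only.
plain_spec <- function(n_per_class, n_columns, seed,
                       classes = list(c("Gly", "Bac"), c("Ala", "Bac"),
                                      c("Asp", "Bac"), c("His", "Bac"),
                                      c("Ser", "Bac"))) {
  synthetic_spec(n_per_class = n_per_class, classes = classes,
                 n_columns = n_columns, stems = list(),
                 invariant_columns = c(), determinants = list(),
                 gap_columns = c(), seed = seed)
}

# Random probability vector over k states (Dirichlet(1) via normalized
# exponentials).
rand_probs <- function(k = 5L) {
  x <- stats::rexp(k)
  x / sum(x)
}

# Alignment with columns drawn from a 3-node chain X -> Y -> Z:
# Y is the Watson-Crick complement of X with prob rho, else uniform;
# Z likewise from Y. X, Z are conditionally independent given Y.
make_chain_aln <- function(n = 2000L, rho = 0.9, seed = 1L) {
  set.seed(seed)
  nt <- c("a", "c", "g", "u")
  wc <- c(a = "u", c = "g", g = "c", u = "a")
  x <- sample(nt, n, replace = TRUE)
  y <- ifelse(stats::runif(n) < rho, wc[x], sample(nt, n, replace = TRUE))
  z <- ifelse(stats::runif(n) < rho, wc[y], sample(nt, n, replace = TRUE))
  mat <- cbind(x, y, z)
  rownames(mat) <- sprintf("s%05d", seq_len(n))
  colnames(mat) <- NULL
  labeled_alignment(mat, column_labels = c("X", "Y", "Z"))
}

# Collider X -> Y <- Z: X and Z independent uniform; Y deterministic-ish in
# (X, Z) jointly so the v-structure is identifiable.
make_collider_aln <- function(n = 2000L, seed = 1L) {
  set.seed(seed)
  nt <- c("a", "c", "g", "u")
  wc <- c(a = "u", c = "g", g = "c", u = "a")
  x <- sample(nt, n, replace = TRUE)
  z <- sample(nt, n, replace = TRUE)
  y <- ifelse(z %in% c("a", "g"), wc[x], x)
  noise <- stats::runif(n) < 0.1
  y[noise] <- sample(nt, sum(noise), replace = TRUE)
  mat <- cbind(x, y, z)
  rownames(mat) <- sprintf("s%05d", seq_len(n))
  colnames(mat) <- NULL
  labeled_alignment(mat, column_labels = c("X", "Y", "Z"))
}

# Exhaustive structure-search oracle for <= 4 nodes: enumerate every DAG as
# a combination of per-node parent sets, keep the acyclic ones, and score
# each with mdl_score. Returns the optimal score.
exhaustive_best_score <- function(aln, penalty_weight = 1) {
  nodes <- aln$column_labels
  p <- length(nodes)
  stopifnot(p <= 4L)
  subsets <- function(v) {
    out <- list(character())
    for (x in v) out <- c(out, lapply(out, c, x))
    out
  }
  per_node <- lapply(nodes, function(nd) subsets(setdiff(nodes, nd)))
  is_acyclic <- function(par) {
    remaining <- nodes
    repeat {
      free <- remaining[vapply(remaining, function(nd)
        !length(intersect(par[[nd]], remaining)), TRUE)]
      if (!length(free)) return(length(remaining) == 0L)
      remaining <- setdiff(remaining, free)
      if (!length(remaining)) return(TRUE)
    }
  }
  grid <- expand.grid(lapply(per_node, seq_along))
  best <- Inf
  n_dags <- 0L
  for (i in seq_len(nrow(grid))) {
    par <- lapply(seq_len(p), function(j) per_node[[j]][[grid[i, j]]])
    names(par) <- nodes
    if (!is_acyclic(par)) next
    n_dags <- n_dags + 1L
    s <- mdl_score(aln, par, penalty_weight = penalty_weight)
    if (s < best) best <- s
  }
  attr(best, "n_dags") <- n_dags
  best
}

# Undirected skeleton of a network as a sorted "a|b" character vector.
skeleton_of <- function(net) {
  if (!nrow(net$edges)) return(character())
  sort(unique(apply(net$edges[, c("parent", "child")], 1L, function(e)
    paste(sort(e), collapse = "|"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
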