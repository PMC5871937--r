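# Discrete Bayesian network structure learning over alignment columns.
#
# Columns are multinomial variables with four nucleotide states (gaps are
# treated as missing: each family is fit on its complete-case rows, so
# sparse insertions act as rare events in correspondingly reduced
# datasets). The network score is an MDL / penalized log-likelihood:
#   score(G) = sum_families [ -max log-lik + w * (k_free / 2) * log N_fam ]
# (natural log; lower is better; w = penalty_weight tunes towards
# underfitting). The score is decomposable, so greedy hill-climbing with
# single-edge add/delete/reverse moves and random restarts only ever
# re-scores the one or two families a move touches.

# ---- data encoding -------------------------------------------------------

# Integer matrix over 1..4 (a,c,g,u) with NA for gaps; optional class node
# appended as an extra column. Columns whose gap fraction exceeds
# `gap_threshold` are excluded from the node set.
.bn_encode <- function(aln, gap_threshold = 0.5, include_class_node = FALSE,
                       class_node = "100") {
  E <- .encode_alignment(aln)
  E[E == .GAP] <- NA_integer_
  gap_frac <- colMeans(is.na(E))
  keep <- gap_frac <= gap_threshold
  if (any(!keep))
    message("excluding ", sum(!keep), " column(s) with gap fraction > ",
            gap_threshold, ": ",
            paste(aln$column_labels[!keep], collapse = ", "))
  X <- E[, keep, drop = FALSE]
  nodes <- aln$column_labels[keep]
  sizes <- rep(4L, ncol(X))
  states <- rep(list(c("a", "c", "g", "u")), ncol(X))
  if (include_class_node) {
    cls <- factor(aln$classes$aa_class)
    X <- cbind(X, as.integer(cls))
    nodes <- c(nodes, class_node)
    sizes <- c(sizes, nlevels(cls))
    states <- c(states, list(levels(cls)))
  }
  colnames(X) <- nodes
  list(X = X, nodes = nodes, sizes = sizes, states = states)
}

# ---- family scoring ------------------------------------------------------

# MDL score of one family (child given parents), complete cases only.
# Returns +Inf when the family has no complete-case rows.
.family_score <- function(X, sizes, child, parents, penalty_weight) {
  fam <- c(child, parents)
  sub <- X[, fam, drop = FALSE]
  ok <- !rowSums(is.na(sub))
  n <- sum(ok)
  if (n == 0L) return(Inf)
  r <- sizes[child]
  x <- sub[ok, 1L]
  if (length(parents)) {
    cfg <- integer(n)
    mult <- 1L
    for (j in seq_along(parents)) {
      cfg <- cfg + (sub[ok, j + 1L] - 1L) * mult
      mult <- mult * sizes[parents[j]]
    }
    tab <- tabulate(x + r * cfg, nbins = r * mult)
    dim(tab) <- c(r, mult)
    ncfg <- rep(colSums(tab), each = r)
    pos <- tab > 0
    ll <- sum(tab[pos] * log(tab[pos] / ncfg[pos]))
    q <- mult
  } else {
    tab <- tabulate(x, nbins = r)
    pos <- tab > 0
    ll <- sum(tab[pos] * log(tab[pos] / n))
    q <- 1L
  }
  -ll + penalty_weight * 0.5 * (r - 1) * q * log(n)
}

# Cached family score keyed by (child, sorted parent set).
.fscore <- function(cache, X, sizes, child, parents, penalty_weight) {
  key <- paste0(child, "|", paste(sort(parents), collapse = ","))
  v <- cache[[key]]
  if (is.null(v)) {
    v <- .family_score(X, sizes, child, parents, penalty_weight)
    cache[[key]] <- v
  }
  v
}

#' MDL score of a network
#'
#' Penalized-likelihood (MDL) score of a directed acyclic graph over
#' alignment columns: for every family, the negative maximized multinomial
#' log-likelihood (natural log, complete-case rows) plus
#' `penalty_weight * (free parameters / 2) * log(N_family)`. Lower is
#' better; the score is decomposable over families.
#'
#' @param aln a [labeled_alignment()].
#' @param network a `directed_network` (see [learn_structure()]), or a
#'   named list of parent character vectors.
#' @param penalty_weight complexity-penalty multiplier (default 1 =
#'   BIC-equivalent; larger underfits more).
#' @param gap_threshold columns with gap fraction above this are not
#'   modeled (default 0.5).
#' @param include_class_node add the subclass variable as an ordinary
#'   multinomial node (conventionally labeled `"100"`).
#' @param class_node name of the class node.
#' @export
mdl_score <- function(aln, network, penalty_weight = 1,
                      gap_threshold = 0.5, include_class_node = FALSE,
                      class_node = "100") {
  enc <- .bn_encode(aln, gap_threshold, include_class_node, class_node)
  parents <- .network_parents(network)
  if (!all(names(parents) %in% enc$nodes))
    stop("network node(s) not among modeled alignment columns: ",
         paste(setdiff(names(parents), enc$nodes), collapse = ", "))
  idx <- match(names(parents), enc$nodes)
  total <- 0
  for (i in seq_along(parents)) {
    s <- .family_score(enc$X, enc$sizes, idx[i],
                       match(parents[[i]], enc$nodes), penalty_weight)
    if (!is.finite(s))
      stop("family for node '", names(parents)[i],
           "' has zero complete-case rows")
    total <- total + s
  }
  total
}

.network_parents <- function(network) {
  if (inherits(network, "directed_network")) return(network$parents)
  stopifnot(is.list(network), !is.null(names(network)))
  network
}

# ---- graph utilities (integer adjacency on parent lists) -----------------

# TRUE if `to` is reachable from `from` following child edges.
.reachable <- function(children, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(length(children))
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    ch <- children[[v]]
    if (to %in% ch) return(TRUE)
    stack <- c(stack, ch[!seen[ch]])
  }
  FALSE
}

.children_from_parents <- function(par) {
  p <- length(par)
  children <- rep(list(integer()), p)
  for (v in seq_len(p))
    for (u in par[[v]]) children[[u]] <- c(children[[u]], v)
  children
}

# ---- hill climbing -------------------------------------------------------

# One greedy climb from an initial parent-list state. Best-improvement
# moves (add / delete / reverse), deterministic tie-break by enumeration
# order: move type, then parent index, then child index.
.hill_climb <- function(X, sizes, par, max_parents, penalty_weight, cache) {
  p <- length(par)
  fs <- vapply(seq_len(p), function(v)
    .fscore(cache, X, sizes, v, par[[v]], penalty_weight), 0)
  children <- .children_from_parents(par)
  eps <- 1e-9
  trace <- sum(fs)
  repeat {
    best <- NULL
    best_delta <- -eps
    for (u in seq_len(p)) {
      for (v in seq_len(p)) {
        if (u == v) next
        has_uv <- u %in% par[[v]]
        if (!has_uv) {
          # add u -> v
          if (v %in% par[[u]]) next  # reverse handles the flip
          if (length(par[[v]]) >= max_parents) next
          if (.reachable(children, v, u)) next
          new <- .fscore(cache, X, sizes, v, c(par[[v]], u), penalty_weight)
          delta <- new - fs[v]
          if (is.finite(new) && delta < best_delta) {
            best_delta <- delta
            best <- list(type = "add", u = u, v = v)
          }
        } else {
          # delete u -> v
          new <- .fscore(cache, X, sizes, v, setdiff(par[[v]], u), penalty_weight)
          delta <- new - fs[v]
          if (is.finite(new) && delta < best_delta) {
            best_delta <- delta
            best <- list(type = "delete", u = u, v = v)
          }
          # reverse u -> v  (becomes v -> u)
          if (length(par[[u]]) < max_parents) {
            ch2 <- children
            ch2[[u]] <- setdiff(ch2[[u]], v)
            if (!.reachable(ch2, u, v)) {
              new_v <- .fscore(cache, X, sizes, v, setdiff(par[[v]], u),
                               penalty_weight)
              new_u <- .fscore(cache, X, sizes, u, c(par[[u]], v),
                               penalty_weight)
              delta <- (new_v - fs[v]) + (new_u - fs[u])
              if (is.finite(new_v) && is.finite(new_u) && delta < best_delta) {
                best_delta <- delta
                best <- list(type = "reverse", u = u, v = v)
              }
            }
          }
        }
      }
    }
    if (is.null(best)) break
    u <- best$u; v <- best$v
    if (best$type == "add") {
      par[[v]] <- c(par[[v]], u)
      children[[u]] <- c(children[[u]], v)
    } else if (best$type == "delete") {
      par[[v]] <- setdiff(par[[v]], u)
      children[[u]] <- setdiff(children[[u]], v)
    } else {
      par[[v]] <- setdiff(par[[v]], u)
      children[[u]] <- setdiff(children[[u]], v)
      par[[u]] <- c(par[[u]], v)
      children[[v]] <- c(children[[v]], u)
      fs[u] <- .fscore(cache, X, sizes, u, par[[u]], penalty_weight)
    }
    fs[v] <- .fscore(cache, X, sizes, v, par[[v]], penalty_weight)
    trace <- c(trace, sum(fs))
  }
  list(par = par, score = sum(fs), trace = trace)
}

# Random DAG: random topological order, forward edges kept with probability
# 2/(p-1), parent count capped.
.random_dag <- function(p, max_parents) {
  ord <- sample.int(p)
  par <- rep(list(integer()), p)
  prob <- min(1, 2 / max(1L, p - 1L))
  for (j in seq_len(p)[-1L]) {
    cand <- ord[seq_len(j - 1L)]
    pick <- cand[stats::runif(length(cand)) < prob]
    if (length(pick) > max_parents) pick <- pick[seq_len(max_parents)]
    par[[ord[j]]] <- pick
  }
  par
}

#' Learn network structure by hill-climbing with restarts
#'
#' Greedy best-improvement search over single-edge additions, deletions and
#' reversals, minimizing the MDL score of [mdl_score()], from an empty
#' graph (restart 1) and seeded random DAGs (later restarts); the best
#' local optimum over all restarts is returned. Acyclicity is maintained at
#' every step and the result is deterministic for a fixed seed.
#'
#' @inheritParams mdl_score
#' @param restarts number of climbs (>= 1).
#' @param max_parents parent-count cap per node (default 4; bounds table
#'   sizes, an artifact constraint of the implementation).
#' @param seed integer seed for the restart initial graphs.
#' @return a `directed_network`: list with `nodes`, `parents` (named list),
#'   `edges` (data.frame `parent`, `child`, `strength`), `score`,
#'   `score_trace` (per-move score of the winning climb) and `learn_meta`.
#'   Edge strengths are exponentiated score deltas (see [edge_strength()]).
#' @export
learn_structure <- function(aln, restarts = 5L, max_parents = 4L,
                            penalty_weight = 1, seed = 1L,
                            include_class_node = FALSE, class_node = "100",
                            gap_threshold = 0.5) {
  stopifnot(restarts >= 1L, max_parents >= 1L)
  enc <- .bn_encode(aln, gap_threshold, include_class_node, class_node)
  p <- length(enc$nodes)
  if (p < 2L) stop("need at least 2 modeled columns")
  constant <- vapply(seq_len(p), function(j) {
    v <- enc$X[, j]
    length(unique(v[!is.na(v)])) <= 1L
  }, TRUE)
  if (all(constant)) {
    message("all modeled columns are constant; returning the empty graph")
    return(.make_network(enc, rep(list(integer()), p), NA_real_, numeric(),
                         restarts, max_parents, penalty_weight, seed, cache = NULL))
  }
  cache <- new.env(parent = emptyenv())
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- if (r == 1L) rep(list(integer()), p) else .random_dag(p, max_parents)
    res <- .hill_climb(enc$X, enc$sizes, init, max_parents, penalty_weight, cache)
    if (is.null(best) || res$score < best$score - 1e-9) best <- res
  }
  .make_network(enc, best$par, best$score, best$trace,
                restarts, max_parents, penalty_weight, seed, cache)
}

.make_network <- function(enc, par, score, trace, restarts, max_parents,
                          penalty_weight, seed, cache = NULL) {
  nodes <- enc$nodes
  names(par) <- nodes
  parents <- lapply(par, function(ix) nodes[ix])
  edges <- data.frame(parent = character(), child = character(),
                      strength = numeric(), log10_strength = numeric(),
                      stringsAsFactors = FALSE)
  if (any(lengths(par) > 0)) {
    if (is.null(cache)) cache <- new.env(parent = emptyenv())
    rows <- list()
    for (v in seq_along(par)) {
      for (u in par[[v]]) {
        with_e <- .fscore(cache, enc$X, enc$sizes, v, par[[v]], penalty_weight)
        without <- .fscore(cache, enc$X, enc$sizes, v, setdiff(par[[v]], u),
                           penalty_weight)
        delta <- without - with_e
        rows[[length(rows) + 1L]] <-
          data.frame(parent = nodes[u], child = nodes[v],
                     strength = exp(delta), log10_strength = delta / log(10),
                     stringsAsFactors = FALSE)
      }
    }
    edges <- do.call(rbind, rows)
    edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, parents = parents, edges = edges,
                 score = score, score_trace = trace,
                 learn_meta = list(restarts = restarts,
                                   max_parents = max_parents,
                                   penalty_weight = penalty_weight,
                                   seed = as.integer(seed))),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat("directed_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges, score =", format(x$score), "\n")
  if (nrow(x$edges)) {
    e <- x$edges[order(-x$edges$log10_strength), ]
    show <- utils::head(e, 8L)
    cat("strongest edges (log10 ratio):",
        paste0(show$parent, "->", show$child, " (",
               format(show$log10_strength, digits = 3), ")", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Strength of one edge
#'
#' Exponentiated score delta: the network score without the edge (all other
#' edges fixed) minus the score with it, exponentiated — a likelihood-ratio
#' style measure of how much the edge improves fit. Values above 1 favor
#' keeping the edge; edges retained by [learn_structure()] always have
#' strength >= 1. Strengths are comparable within one network, not across
#' networks.
#'
#' @inheritParams mdl_score
#' @param from,to parent and child node names; the edge must be present.
#' @param log10 return the strength as a log10 ratio instead of the raw
#'   ratio (which overflows to `Inf` for strong edges at large N).
#' @export
edge_strength <- function(aln, network, from, to,
                          penalty_weight = NULL, gap_threshold = 0.5,
                          include_class_node = FALSE, class_node = "100",
                          log10 = FALSE) {
  stopifnot(inherits(network, "directed_network"))
  if (is.null(penalty_weight))
    penalty_weight <- network$learn_meta$penalty_weight %||% 1
  if (!(from %in% network$parents[[to]] %||% character()))
    stop("edge ", from, " -> ", to, " not present in network")
  enc <- .bn_encode(aln, gap_threshold, include_class_node, class_node)
  v <- match(to, enc$nodes)
  pv <- match(network$parents[[to]], enc$nodes)
  with_e <- .family_score(enc$X, enc$sizes, v, pv, penalty_weight)
  without <- .family_score(enc$X, enc$sizes, v,
                           setdiff(pv, match(from, enc$nodes)), penalty_weight)
  if (log10) (without - with_e) / log(10) else exp(without - with_e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the local conditional probability table of one family
#'
#' Maximum-likelihood multinomial table of a child given its parents,
#' complete-case rows only, with optional pseudocount. Parent-state
#' combinations never observed in the data are filled with the uniform
#' distribution and flagged.
#'
#' @inheritParams mdl_score
#' @param child child node name.
#' @param parents character vector of parent node names (may be empty:
#'   the table is then the marginal distribution).
#' @param pseudocount added to every cell before normalization (default 0).
#' @return a `local_model`: list with `child`, `parents`, `table` (matrix,
#'   one row per parent-state combination, columns are child states),
#'   `observed` (logical per row), `n` (complete-case rows).
#' @export
fit_local_model <- function(aln, child, parents = character(),
                            pseudocount = 0, gap_threshold = 0.5,
                            include_class_node = FALSE, class_node = "100") {
  enc <- .bn_encode(aln, gap_threshold, include_class_node, class_node)
  ci <- match(child, enc$nodes)
  pi_ <- match(parents, enc$nodes)
  if (anyNA(c(ci, pi_)))
    stop("unknown node(s): ",
         paste(setdiff(c(child, parents), enc$nodes), collapse = ", "))
  sub <- enc$X[, c(ci, pi_), drop = FALSE]
  ok <- !rowSums(is.na(sub))
  n <- sum(ok)
  if (n == 0L) stop("family for node '", child, "' has zero complete-case rows")
  r <- enc$sizes[ci]
  x <- sub[ok, 1L]
  if (length(pi_)) {
    mult <- 1L
    cfg <- integer(n)
    for (j in seq_along(pi_)) {
      cfg <- cfg + (sub[ok, j + 1L] - 1L) * mult
      mult <- mult * enc$sizes[pi_[j]]
    }
    tab <- tabulate(x + r * cfg, nbins = r * mult)
    dim(tab) <- c(r, mult)
    tab <- t(tab)
    grid <- expand.grid(lapply(pi_, function(j) enc$states[[j]]),
                        stringsAsFactors = FALSE)
    rownames(tab) <- do.call(paste, c(grid, sep = ","))
  } else {
    tab <- matrix(tabulate(x, nbins = r), nrow = 1L,
                  dimnames = list("(marginal)", NULL))
  }
  colnames(tab) <- enc$states[[ci]]
  observed <- rowSums(tab) > 0
  tab <- tab + pseudocount
  probs <- tab / pmax(rowSums(tab), .Machine$double.eps)
  probs[!observed & rowSums(tab) == 0, ] <- 1 / r
  structure(list(child = child, parents = parents, table = probs,
                 observed = observed, n = n),
            class = "local_model")
}

#' @export
print.local_model <- function(x, ...) {
  cat("local_model:", x$child,
      if (length(x$parents)) paste("|", paste(x$parents, collapse = ", "))
      else "(no parents)", " n =", x$n, "\n")
  print(round(x$table, 3))
  invisible(x)
}

#' Markov blanket of a node
#'
#' Parents, children, and the children's other parents.
#'
#' @param network a `directed_network`.
#' @param node node name.
#' @return character vector (possibly empty), sorted.
#' @export
markov_blanket <- function(network, node) {
  stopifnot(inherits(network, "directed_network"))
  if (!(node %in% network$nodes)) stop("unknown node: ", node)
  par <- network$parents[[node]] %||% character()
  kids <- names(Filter(function(p) node %in% p, network$parents))
  cop <- unlist(network$parents[kids], use.names = FALSE)
  sort(setdiff(unique(c(par, kids, cop)), node))
}

# ---- CPDAG ---------------------------------------------------------------

#' Equivalence-class (CPDAG) form of a network
#'
#' Marks every edge as compelled (directed) or reversible (undirected)
#' within the network's Markov equivalence class: edges taking part in
#' v-structures are compelled, the orientation is propagated by the
#' standard closure rules, and everything else is reversible.
#'
#' @param network a `directed_network` (acyclic).
#' @return data.frame with columns `parent`, `child`, `directed`
#'   (undirected edges keep the input orientation with `directed = FALSE`).
#' @export
to_cpdag <- function(network) {
  stopifnot(inherits(network, "directed_network"))
  nodes <- network$nodes
  p <- length(nodes)
  D <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))  # input DAG
  for (v in nodes)
    for (u in network$parents[[v]]) D[u, v] <- TRUE
  A <- D | t(D)                                            # skeleton
  C <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))  # compelled
  # v-structures: u -> v <- w with u, w non-adjacent
  for (v in seq_len(p)) {
    pa <- which(D[, v])
    if (length(pa) < 2L) next
    for (i in seq_along(pa)[-length(pa)]) {
      for (j in seq.int(i + 1L, length(pa))) {
        u <- pa[i]; w <- pa[j]
        if (!A[u, w]) { C[u, v] <- TRUE; C[w, v] <- TRUE }
      }
    }
  }
  # Closure rules; the sweep restarts after every orientation so the
  # undirected view is never stale.
  repeat {
    changed <- FALSE
    U <- A & !(C | t(C))
    for (b in seq_len(p)) {
      if (changed) break
      for (cx in seq_len(p)) {
        if (!U[b, cx]) next
        # R1: a -> b, b - c, a and c non-adjacent  =>  b -> c
        if (any(C[, b] & !A[, cx] & seq_len(p) != cx)) {
          C[b, cx] <- TRUE; changed <- TRUE; break
        }
        # R2: b -> . -> c with b - c  =>  b -> c
        if (any(C[b, ] & C[, cx])) {
          C[b, cx] <- TRUE; changed <- TRUE; break
        }
        # R3: b - d1, b - d2, d1 -> c, d2 -> c, d1 and d2 non-adjacent
        ds <- which(U[b, ] & C[, cx])
        if (length(ds) >= 2L) {
          ok <- FALSE
          for (i in seq_along(ds)[-length(ds)])
            for (j in seq.int(i + 1L, length(ds)))
              if (!A[ds[i], ds[j]]) ok <- TRUE
          if (ok) { C[b, cx] <- TRUE; changed <- TRUE; break }
        }
      }
    }
    if (!changed) break
  }
  out <- list()
  for (v in seq_len(p)) {
    for (u in which(D[, v])) {
      out[[length(out) + 1L]] <- data.frame(
        parent = nodes[u], child = nodes[v],
        directed = C[u, v] && !C[v, u], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(parent = character(), child = character(),
                      directed = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$parent, res$child), , drop = FALSE]
}

# ---- exports -------------------------------------------------------------

#' Export a network as Graphviz DOT
#'
#' Edge labels carry the edge strength rounded to one decimal, on the
#' log10 likelihood-ratio scale (the raw ratio overflows double precision
#' for strongly coupled columns at realistic sample sizes, so the log is
#' the only faithfully printable form); when the node labels belong to the
#' standard tRNA numbering, nodes are colored by cloverleaf arm (acceptor
#' stem, D-arm, anticodon arm, T-arm, variable region).
#'
#' @param network a `directed_network`.
#' @param path output path.
#' @param color_by_arm color nodes by tRNA arm when labels permit.
#' @export
write_dot <- function(network, path, color_by_arm = TRUE) {
  stopifnot(inherits(network, "directed_network"))
  arm_fill <- c(acceptor = "indianred1", D = "palegreen", anticodon = "skyblue",
                T = "khaki", variable = "plum", other = "white")
  lines <- c("digraph bn {", "  node [style=filled, fillcolor=white];")
  for (nd in network$nodes) {
    fill <- if (color_by_arm) arm_fill[[.trna_arm(nd)]] else "white"
    lines <- c(lines, sprintf("  \"%s\" [fillcolor=%s];", nd, fill))
  }
  if (nrow(network$edges)) {
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%.1f\"];",
                              network$edges$parent, network$edges$child,
                              network$edges$log10_strength))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Export the edge list as TSV
#'
#' @param network a `directed_network`.
#' @param path output path.
#' @export
write_edges_tsv <- function(network, path) {
  stopifnot(inherits(network, "directed_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Dump conditional probability tables for every node
#'
#' One TSV per node (named `cpt_<node>.tsv`) under `dir`, using the
#' network's parent sets.
#'
#' @inheritParams mdl_score
#' @param dir output directory (created if needed).
#' @export
write_cpts <- function(aln, network, dir, include_class_node = FALSE,
                       class_node = "100", gap_threshold = 0.5) {
  stopifnot(inherits(network, "directed_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nd in network$nodes) {
    lm <- fit_local_model(aln, nd, network$parents[[nd]] %||% character(),
                          gap_threshold = gap_threshold,
                          include_class_node = include_class_node,
                          class_node = class_node)
    df <- data.frame(parent_config = rownames(lm$table), lm$table,
                     observed = lm$observed, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, paste0("cpt_", nd, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
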