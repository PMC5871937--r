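# Per-column distributions, the Jensen-Shannon importance statistic, its
# permutation null, second-order conditioning, and determinant classification.
#
# For a column i and a sequence subclass j, the statistic is
#   l_ij = 1/2 d(p_ij, m_ij) + 1/2 d(q_i, m_ij),  m_ij = (p_ij + q_i) / 2,
# where q_i is the pooled distribution of states at column i, p_ij the
# distribution within the subclass, and d the relative entropy
# d(x, y) = sum_k x(k) log x(k)/y(k). In log base 2 (the package default)
# l_ij lies in [0, 1] bits; sqrt(l) is a proper metric.

# Encode the character matrix as integers 1..5 over (a,c,g,u,-).
.encode_alignment <- function(aln) {
  E <- match(aln$mat, .ALPHABET)
  dim(E) <- dim(aln$mat)
  E
}

# State counts per column: 5 x L matrix from integer-encoded rows `idx`.
.col_counts <- function(E, idx = seq_len(nrow(E))) {
  L <- ncol(E)
  off <- rep(seq.int(0L, by = 5L, length.out = L), each = length(idx))
  cnt <- tabulate(E[idx, , drop = FALSE] + off, nbins = 5L * L)
  dim(cnt) <- c(5L, L)
  cnt
}

# Counts -> probabilities; optionally drop the gap state and renormalize
# over non-gap rows. Columns with zero support give NaN (caller decides).
.counts_to_probs <- function(cnt, include_gap = TRUE, pseudocount = 0) {
  if (!include_gap) cnt[5L, ] <- 0
  k <- if (include_gap) 5L else 4L
  if (pseudocount > 0) cnt[seq_len(k), ] <- cnt[seq_len(k), ] + pseudocount
  sweep(cnt, 2L, colSums(cnt), "/")
}

#' Empirical state distribution at one column
#'
#' Tallies the states `a, c, g, u, gap` at a column. With
#' `include_gap = FALSE` the gap frequency is forced to zero and the
#' nucleotide frequencies are renormalized over the non-gap rows.
#'
#' @param aln a [labeled_alignment()].
#' @param column_label which column.
#' @param include_gap count the gap symbol as a fifth state (default TRUE;
#'   the gap state is a bookkeeping convenience that makes variable-region
#'   columns visible to the divergence statistic).
#' @return a `position_distribution`: list with `probs` (named length-5
#'   vector summing to 1), `support_count`, `column_label`.
#' @export
position_distribution <- function(aln, column_label, include_gap = TRUE) {
  stopifnot(inherits(aln, "labeled_alignment"))
  ci <- match(column_label, aln$column_labels)
  if (is.na(ci)) stop("no column labeled '", column_label, "'")
  x <- aln$mat[, ci]
  cnt <- tabulate(match(x, .ALPHABET), nbins = 5L)
  if (!include_gap) cnt[5L] <- 0L
  support <- sum(cnt)
  if (support == 0L)
    stop("empty support at column '", column_label,
         "' under the chosen gap policy")
  probs <- cnt / support
  names(probs) <- c("a", "c", "g", "u", "gap")
  structure(list(probs = probs, support_count = support,
                 column_label = column_label),
            class = "position_distribution")
}

#' @export
print.position_distribution <- function(x, ...) {
  cat("position", x$column_label, "(n =", x$support_count, "):",
      paste(names(x$probs), round(x$probs, 3), sep = "=", collapse = " "), "\n")
  invisible(x)
}

.as_probs <- function(x) {
  if (inherits(x, "position_distribution")) x <- x$probs
  stopifnot(is.numeric(x), all(x >= 0))
  if (abs(sum(x) - 1) > 1e-9) stop("distribution does not sum to 1")
  x
}

#' Relative entropy d(x, y)
#'
#' `sum_k x(k) log(x(k)/y(k))` with the convention `0 log(0/.) = 0`.
#' Undefined (error) when x puts mass where y has none — which cannot
#' happen for the mixture arguments used by [jsd()].
#'
#' @param x,y distributions over the same state set (numeric vectors or
#'   `position_distribution` objects).
#' @param base logarithm base; 2 (bits) by default.
#' @export
relative_entropy_d <- function(x, y, base = 2) {
  x <- .as_probs(x); y <- .as_probs(y)
  stopifnot(length(x) == length(y))
  pos <- x > 0
  if (any(y[pos] == 0))
    stop("relative entropy undefined: x has support where y is zero")
  sum(x[pos] * log(x[pos] / y[pos], base = base))
}

#' Jensen-Shannon divergence
#'
#' The symmetrised, mixture-smoothed relative entropy
#' `1/2 d(p, m) + 1/2 d(q, m)` with `m = (p + q)/2`. Symmetric, bounded by
#' `[0, 1]` in bits (base 2), zero iff `p == q`, maximal iff the supports
#' are disjoint; its square root is a metric.
#'
#' @inheritParams relative_entropy_d
#' @param p,q distributions over the same state set.
#' @export
jsd <- function(p, q, base = 2) {
  p <- .as_probs(p); q <- .as_probs(q)
  stopifnot(length(p) == length(q))
  m <- (p + q) / 2
  relative_entropy_d(p, m, base = base) / 2 +
    relative_entropy_d(q, m, base = base) / 2
}

# Vectorized column-wise JSD between two 5 x L probability matrices.
.jsd_cols <- function(P, Q, base = 2) {
  M <- (P + Q) / 2
  t1 <- P * log(P / M, base = base)
  t2 <- Q * log(Q / M, base = base)
  t1[P == 0] <- 0
  t2[Q == 0] <- 0
  (colSums(t1) + colSums(t2)) / 2
}

#' Per-column importance profile with permutation null
#'
#' For every column i, computes `l_i = JSD(p_i, q_i)` between the stratum
#' distribution `p_i` and the pooled distribution `q_i` over the whole
#' alignment (or the domain-of-life subset, see `reference`). The null is
#' built by redrawing the stratum membership uniformly at fixed stratum
#' size — equivalently, permuting the class-label vector — and recomputing
#' the statistic `null_reps` times; per-column null quantiles are reported
#' at 0.95, 0.99 and 0.999 and `exceeds_null` compares against the 0.99
#' quantile. `exceeds_cutoff` applies the fixed relative-entropy cutoff
#' (default 0.2 bits, strict inequality).
#'
#' @param aln a [labeled_alignment()].
#' @param sel a [stratum_selector()] naming the subclass.
#' @param cutoff fixed significance cutoff on the divergence scale
#'   (default 0.2; the conventional literature value — note the log base
#'   the cutoff is quoted in is rarely stated, this package uses bits).
#' @param null_reps permutation replicates m (default 1e5, the published
#'   convergence point; at least 100).
#' @param seed integer seed; the profile is fully reproducible given
#'   `(aln, sel, cutoff, null_reps, seed)`.
#' @param include_gap count gaps as a fifth state (default TRUE).
#' @param pseudocount optional Laplace pseudocount added to every state
#'   count (default 0; the mixture in the JSD already removes
#'   zero-denominator terms, so smoothing is only useful for tiny strata).
#' @param reference `"full"` compares the stratum against the whole
#'   alignment; `"domain"` restricts the reference population to rows
#'   matching the selector's `life_domain`.
#' @return an `importance_profile`: list with `table` (data.frame with
#'   columns `column_label`, `l_value`, `q95`, `q99`, `q999`,
#'   `exceeds_null`, `exceeds_cutoff`), plus `stratum`, `cutoff`,
#'   `null_reps`, `seed`, `stratum_size`.
#' @export
importance_profile <- function(aln, sel, cutoff = 0.2, null_reps = 1e5,
                               seed = 1L, include_gap = TRUE,
                               pseudocount = 0,
                               reference = c("full", "domain")) {
  stopifnot(inherits(aln, "labeled_alignment"), inherits(sel, "stratum_selector"))
  reference <- match.arg(reference)
  null_reps <- as.integer(null_reps)
  if (null_reps < 100L) stop("null_reps must be at least 100")
  ref <- aln
  if (reference == "domain" && !is.null(sel$life_domain))
    ref <- stratify(aln, stratum_selector(life_domain = sel$life_domain))
  rows <- .selector_rows(ref, sel)
  if (!length(rows))
    stop("empty stratum: no rows match selector ", format(sel))
  E <- .encode_alignment(ref)
  n <- nrow(E); L <- ncol(E); k <- length(rows)
  Q <- .counts_to_probs(.col_counts(E), include_gap, pseudocount)
  P <- .counts_to_probs(.col_counts(E, rows), include_gap, pseudocount)
  if (anyNA(Q) || anyNA(P))
    stop("empty support at some column under the chosen gap policy")
  l <- .jsd_cols(P, Q)
  set.seed(seed)
  null <- matrix(0, nrow = null_reps, ncol = L)
  for (r in seq_len(null_reps)) {
    Pr <- .counts_to_probs(.col_counts(E, sample.int(n, k)),
                           include_gap, pseudocount)
    null[r, ] <- .jsd_cols(Pr, Q)
  }
  qs <- apply(null, 2L, stats::quantile,
              probs = c(0.95, 0.99, 0.999), names = FALSE)
  tab <- data.frame(column_label = ref$column_labels,
                    l_value = l,
                    q95 = qs[1L, ], q99 = qs[2L, ], q999 = qs[3L, ],
                    exceeds_null = l > qs[2L, ],
                    exceeds_cutoff = l > cutoff,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, stratum = sel, cutoff = cutoff,
                 null_reps = null_reps, seed = as.integer(seed),
                 stratum_size = k, include_gap = include_gap,
                 reference = reference),
            class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, ...) {
  cat("importance_profile for stratum", format(x$stratum),
      "(n =", x$stratum_size, ")\n")
  cat("cutoff:", x$cutoff, " null_reps:", x$null_reps, " seed:", x$seed, "\n")
  cat(sum(x$table$exceeds_cutoff), "of", nrow(x$table),
      "columns exceed the cutoff\n")
  top <- x$table[order(-x$table$l_value), ][seq_len(min(5L, nrow(x$table))), ]
  cat("top columns:",
      paste(top$column_label, round(top$l_value, 3), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Second-order conditioning on an anchor column
#'
#' Distribution of states at every other column among the rows that carry
#' `anchor_state` at `anchor_column` — the building block for separating
#' class-specific signal from structural (e.g. base-pairing) signal.
#'
#' @param aln a [labeled_alignment()].
#' @param anchor_column column to condition on.
#' @param anchor_state one of `"a","c","g","u","gap"`.
#' @return named list of `position_distribution` objects, one per
#'   non-anchor column; each `support_count` equals the number of rows
#'   carrying the anchor state.
#' @export
conditional_profile <- function(aln, anchor_column, anchor_state) {
  stopifnot(inherits(aln, "labeled_alignment"))
  ci <- match(anchor_column, aln$column_labels)
  if (is.na(ci)) stop("no column labeled '", anchor_column, "'")
  state <- match.arg(anchor_state, c("a", "c", "g", "u", "gap"))
  chr <- if (state == "gap") "-" else state
  rows <- which(aln$mat[, ci] == chr)
  if (!length(rows))
    stop("empty support: no rows carry '", state, "' at column '",
         anchor_column, "'")
  E <- .encode_alignment(aln)
  cnt <- .col_counts(E, rows)
  out <- lapply(setdiff(seq_len(ncol(E)), ci), function(q) {
    probs <- cnt[, q] / length(rows)
    names(probs) <- c("a", "c", "g", "u", "gap")
    structure(list(probs = probs, support_count = length(rows),
                   column_label = aln$column_labels[q]),
              class = "position_distribution")
  })
  names(out) <- aln$column_labels[-ci]
  out
}

#' Classify columns against a reference determinant list
#'
#' Reproduces the standard literature-comparison table: a column that is in
#' the reference list and above the cutoff is `confirmed`; in the list but
#' at or below the cutoff, `low_significance`; above the cutoff but absent
#' from the list, `suggested`; everything else `unremarkable`.
#'
#' @param profile an [importance_profile()].
#' @param reference character vector of reference column labels (see
#'   [read_reference_list()] for the `"3-70"` pair notation).
#' @return data.frame with columns `column_label`, `status`, `l_value`,
#'   `in_reference_list`.
#' @export
classify_determinants <- function(profile, reference) {
  stopifnot(inherits(profile, "importance_profile"))
  reference <- unique(as.character(reference))
  unknown <- setdiff(reference, profile$table$column_label)
  if (length(unknown)) {
    warning("reference label(s) not in alignment, ignored: ",
            paste(unknown, collapse = ", "))
    reference <- setdiff(reference, unknown)
  }
  tab <- profile$table
  in_ref <- tab$column_label %in% reference
  high <- tab$exceeds_cutoff
  status <- ifelse(in_ref & high, "confirmed",
            ifelse(in_ref & !high, "low_significance",
            ifelse(high, "suggested", "unremarkable")))
  data.frame(column_label = tab$column_label, status = status,
             l_value = tab$l_value, in_reference_list = in_ref,
             stringsAsFactors = FALSE)
}

#' Read a reference determinant list
#'
#' Plain text, one entry per line; pair notation `"3-70"` expands to both
#' members. A leading `-` is part of the label (the `-1` position), not a
#' pair separator; comment lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return character vector of column labels.
#' @export
read_reference_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- unlist(lapply(lines, function(x) {
    parts <- strsplit(x, "-", fixed = TRUE)[[1L]]
    if (length(parts) == 2L && all(nzchar(parts))) parts else x
  }), use.names = FALSE)
  unique(out)
}

#' Write an importance profile as TSV
#'
#' @param profile an [importance_profile()].
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "importance_profile"))
  utils::write.table(profile$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Combine profiles from several strata into a matrix
#'
#' Rows are strata, columns are alignment positions, entries are l values —
#' the layout behind the usual heat-map summary of position importance.
#'
#' @param profiles list of [importance_profile()] objects over the same
#'   column set.
#' @return numeric matrix with stratum names as rownames and column labels
#'   as colnames.
#' @export
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  labs <- profiles[[1L]]$table$column_label
  for (p in profiles)
    if (!identical(p$table$column_label, labs))
      stop("profiles do not share a column set")
  m <- do.call(rbind, lapply(profiles, function(p) p$table$l_value))
  rownames(m) <- vapply(profiles, function(p) format(p$stratum), "")
  colnames(m) <- labs
  m
}
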