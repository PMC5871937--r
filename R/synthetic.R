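# Synthetic labeled alignments with known ground truth: complementary stem
# pairs, invariant columns, class-specific determinant columns, gap-bearing
# variable-region columns, i.i.d. background. Rows are exchangeable — no
# phylogenetic correlation is modeled, so calibration tests exercise the
# statistics, not the biology.

.WC <- c(a = "u", c = "g", g = "c", u = "a")

#' Specification of a synthetic alignment
#'
#' The default spec sketches a small tRNA-like world: five amino-acid
#' classes of 400 sequences each (2000 rows, the scale at which the
#' statistics are routinely run at desk scale), 76 columns, a 7-pair stem
#' block at 95% Watson-Crick complementarity emulating an acceptor stem,
#' a handful of invariant columns, one strong determinant column per
#' class, and a 4-column variable region with 60% gaps.
#'
#' @param n_per_class sequences per class.
#' @param classes list of `c(aa_class, life_domain)` pairs.
#' @param n_columns alignment length.
#' @param stems list of `list(col_a, col_b, complementarity)`: col_b is the
#'   Watson-Crick complement of col_a with the stated probability, else an
#'   independent background draw. Complement map is a-u, c-g; wobble pairs
#'   are introduced with probability `wobble` (default 0).
#' @param invariant_columns named list/vector mapping column index to a
#'   fixed state.
#' @param determinants list of `list(column, aa_class, life_domain, shift)`
#'   where `shift` is a length-4 probability vector over `a,c,g,u` used for
#'   rows of the matching class instead of the background.
#' @param gap_columns named numeric vector mapping column index to a gap
#'   probability (gaps overwrite whatever state was drawn).
#' @param background length-4 probability vector over `a,c,g,u` (default
#'   uniform).
#' @param wobble probability that a complementary stem draw uses a g-u
#'   wobble pair instead of the Watson-Crick partner.
#' @param seed integer seed; generation is byte-identical for a fixed spec.
#' @return a `synthetic_spec` (validated).
#' @export
synthetic_spec <- function(n_per_class = 400L,
                           classes = list(c("Gly", "Bac"), c("Ala", "Bac"),
                                          c("Asp", "Bac"), c("His", "Bac"),
                                          c("Ser", "Bac")),
                           n_columns = 76L,
                           stems = lapply(1:7, function(i)
                             list(col_a = i, col_b = 15L - i,
                                  complementarity = 0.95)),
                           invariant_columns = c("20" = "u", "24" = "a",
                                                 "40" = "g", "60" = "c"),
                           determinants = lapply(seq_len(5), function(i)
                             list(column = 29L + i,
                                  aa_class = c("Gly", "Ala", "Asp", "His",
                                               "Ser")[i],
                                  life_domain = "Bac",
                                  shift = c(0.97, 0.01, 0.01, 0.01)[
                                    ((seq_len(4) + i - 2L) %% 4L) + 1L])),
                           gap_columns = c("50" = 0.6, "51" = 0.6,
                                           "52" = 0.6, "53" = 0.6),
                           background = rep(0.25, 4),
                           wobble = 0,
                           seed = 1L) {
  spec <- structure(list(n_per_class = as.integer(n_per_class),
                         classes = classes, n_columns = as.integer(n_columns),
                         stems = stems,
                         invariant_columns = invariant_columns,
                         determinants = determinants,
                         gap_columns = gap_columns, background = background,
                         wobble = wobble, seed = as.integer(seed)),
                    class = "synthetic_spec")
  .validate_spec(spec)
  spec
}

.check_prob <- function(p, what, len = 4L) {
  if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop(what, " must be a length-", len, " probability vector summing to 1")
}

.validate_spec <- function(spec) {
  stopifnot(spec$n_per_class >= 1L, spec$n_columns >= 1L,
            length(spec$classes) >= 1L)
  .check_prob(spec$background, "background")
  stem_cols <- integer()
  for (s in spec$stems) {
    a <- as.integer(s$col_a); b <- as.integer(s$col_b)
    if (a == b || a < 1L || b < 1L || a > spec$n_columns || b > spec$n_columns)
      stop("stem pair (", s$col_a, ",", s$col_b, ") out of range")
    if (s$complementarity < 0 || s$complementarity > 1)
      stop("complementarity must lie in [0,1]")
    stem_cols <- c(stem_cols, a, b)
  }
  if (anyDuplicated(stem_cols))
    stop("stem pairs must use distinct columns")
  inv_cols <- as.integer(names(spec$invariant_columns))
  det_cols <- vapply(spec$determinants, function(d) as.integer(d$column), 0L)
  if (length(inv_cols) && (any(inv_cols < 1L) || any(inv_cols > spec$n_columns)))
    stop("invariant column out of range")
  if (length(det_cols) && (any(det_cols < 1L) || any(det_cols > spec$n_columns)))
    stop("determinant column out of range")
  if (length(inv_cols) &&
      !all(unlist(spec$invariant_columns) %in% c("a", "c", "g", "u")))
    stop("invariant states must be one of a, c, g, u")
  for (d in spec$determinants) .check_prob(d$shift, "determinant shift")
  if (length(intersect(inv_cols, det_cols)))
    stop("column(s) ", paste(intersect(inv_cols, det_cols), collapse = ", "),
         " declared both invariant and determinant")
  for (what in list(inv_cols, det_cols))
    if (length(intersect(what, stem_cols)))
      stop("column(s) ", paste(intersect(what, stem_cols), collapse = ", "),
           " layered onto stem columns")
  if (anyDuplicated(inv_cols) || anyDuplicated(det_cols))
    stop("duplicate invariant or determinant column")
  gcols <- as.integer(names(spec$gap_columns))
  if (length(gcols) && (any(gcols < 1L) || any(gcols > spec$n_columns)))
    stop("gap column out of range")
  if (any(spec$gap_columns < 0 | spec$gap_columns > 1))
    stop("gap probabilities must lie in [0,1]")
  invisible(spec)
}

# Planted per-class length-5 distribution of a column (before any stem
# coupling; stems are described by their complementarity, not a marginal).
.planted_dist <- function(spec, col, aa, dom) {
  g <- unname(spec$gap_columns[as.character(col)])
  if (is.na(g) || !length(g)) g <- 0
  inv <- if (as.character(col) %in% names(spec$invariant_columns))
    spec$invariant_columns[[as.character(col)]] else NULL
  base <- spec$background
  if (!is.null(inv)) {
    base <- as.numeric(c(a = 1, c = 2, g = 3, u = 4)[inv] == 1:4)
  }
  for (d in spec$determinants) {
    if (as.integer(d$column) == col && d$aa_class == aa &&
        d$life_domain == dom) base <- d$shift
  }
  c(base * (1 - g), g)
}

#' Generate a synthetic labeled alignment
#'
#' Draws an alignment from a [synthetic_spec()] and returns it together
#' with a machine-readable ground-truth record: the planted stems,
#' invariant columns, gap columns, and for every planted determinant its
#' analytically expected Jensen-Shannon divergence against the pooled
#' distribution (computed from the planted parameters, not from the
#' sample).
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `alignment` (a [labeled_alignment()]) and
#'   `truth` (list: `stems`, `determinants` with `expected_jsd`,
#'   `invariant_columns`, `gap_columns`, `seed`).
#' @export
generate_alignment <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .validate_spec(spec)
  set.seed(spec$seed)
  k <- length(spec$classes)
  n <- spec$n_per_class * k
  L <- spec$n_columns
  aa <- vapply(spec$classes, `[`, "", 1L)
  dom <- vapply(spec$classes, `[`, "", 2L)
  row_class <- rep(seq_len(k), each = spec$n_per_class)
  nt <- c("a", "c", "g", "u")
  mat <- matrix(sample(nt, n * L, replace = TRUE, prob = spec$background),
                nrow = n, ncol = L)
  for (col in names(spec$invariant_columns))
    mat[, as.integer(col)] <- spec$invariant_columns[[col]]
  for (d in spec$determinants) {
    ci <- match(TRUE, aa == d$aa_class & dom == d$life_domain)
    if (is.na(ci))
      stop("determinant class (", d$aa_class, ",", d$life_domain,
           ") not among spec classes")
    rows <- which(row_class == ci)
    mat[rows, as.integer(d$column)] <-
      sample(nt, length(rows), replace = TRUE, prob = d$shift)
  }
  for (s in spec$stems) {
    a <- as.integer(s$col_a); b <- as.integer(s$col_b)
    paired <- stats::runif(n) < s$complementarity
    partner <- .WC[mat[, a]]
    if (spec$wobble > 0) {
      wob <- paired & stats::runif(n) < spec$wobble
      partner[wob & mat[, a] == "g"] <- "u"
      partner[wob & mat[, a] == "u"] <- "g"
    }
    mat[paired, b] <- partner[paired]
  }
  for (col in names(spec$gap_columns)) {
    ci <- as.integer(col)
    hit <- stats::runif(n) < spec$gap_columns[[col]]
    mat[hit, ci] <- "-"
  }
  ids <- sprintf("seq%05d", seq_len(n))
  rownames(mat) <- ids
  classes <- data.frame(id = ids, aa_class = aa[row_class],
                        life_domain = dom[row_class],
                        stringsAsFactors = FALSE)
  aln <- labeled_alignment(mat, classes = classes)
  truth <- .ground_truth(spec, aa, dom)
  list(alignment = aln, truth = truth)
}

.ground_truth <- function(spec, aa, dom) {
  k <- length(spec$classes)
  dets <- lapply(spec$determinants, function(d) {
    col <- as.integer(d$column)
    per_class <- lapply(seq_len(k), function(ci)
      .planted_dist(spec, col, aa[ci], dom[ci]))
    pooled <- Reduce(`+`, per_class) / k
    ci <- match(TRUE, aa == d$aa_class & dom == d$life_domain)
    data.frame(column = col, aa_class = d$aa_class,
               life_domain = d$life_domain,
               expected_jsd = jsd(per_class[[ci]], pooled),
               stringsAsFactors = FALSE)
  })
  stems <- lapply(spec$stems, function(s)
    data.frame(col_a = as.integer(s$col_a), col_b = as.integer(s$col_b),
               complementarity = s$complementarity))
  list(stems = if (length(stems)) do.call(rbind, stems) else NULL,
       determinants = if (length(dets)) do.call(rbind, dets) else NULL,
       invariant_columns = spec$invariant_columns,
       gap_columns = spec$gap_columns,
       seed = spec$seed)
}

#' Write a synthetic alignment and its sidecars
#'
#' Emits gapped FASTA, a class-label TSV, a column-label file, and a JSON
#' ground-truth sidecar, all re-readable by [read_alignment()] /
#' [attach_class_labels()].
#'
#' @param sim result of [generate_alignment()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the four paths.
#' @export
write_synthetic <- function(sim, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, paste0(prefix, ".fasta")),
             classes = file.path(dir, paste0(prefix, "_classes.tsv")),
             labels = file.path(dir, paste0(prefix, "_column_labels.txt")),
             truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_alignment(sim$alignment, paths[["fasta"]],
                  class_file = paths[["classes"]],
                  label_file = paths[["labels"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
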