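# Labeled gapped alignments: loading, validation, class labels, stratification.
# Every downstream statistic reports against the column labels owned here.

.ALPHABET <- c("a", "c", "g", "u", "-")
.GAP <- 5L
.DOMAINS <- c("Arc", "Bac", "Euk", "unknown")

#' Construct a labeled alignment
#'
#' A `labeled_alignment` couples a gapped sequence matrix (one row per
#' sequence, single characters from the normalized alphabet `a,c,g,u,-`)
#' with per-column position labels and per-row class labels (amino-acid
#' class and domain of life). Alignments are treated as immutable: all
#' operations return new objects.
#'
#' @param mat character matrix of single characters, rownames are sequence
#'   ids.
#' @param column_labels character vector, one unique label per column.
#'   tRNA-style alignments typically use the standard numbering scheme
#'   (see [trna_standard_labels()]); defaults to `"1" ... "L"`.
#' @param classes data.frame with columns `id`, `aa_class`, `life_domain`
#'   covering every row of `mat`, or `NULL` for all-`unknown` labels.
#' @return an object of class `labeled_alignment` with fields `mat`,
#'   `ids`, `column_labels`, `classes`.
#' @export
labeled_alignment <- function(mat, column_labels = NULL, classes = NULL) {
  stopifnot(is.matrix(mat), is.character(mat))
  ids <- rownames(mat)
  if (is.null(ids)) stop("alignment matrix must have sequence ids as rownames")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(column_labels)) column_labels <- as.character(seq_len(ncol(mat)))
  column_labels <- as.character(column_labels)
  if (length(column_labels) != ncol(mat))
    stop("got ", length(column_labels), " column labels for ", ncol(mat), " columns")
  if (anyDuplicated(column_labels))
    stop("column labels must be unique")
  bad <- !(mat %in% .ALPHABET)
  if (any(bad)) {
    w <- which(bad)[1L]
    ri <- (w - 1L) %% nrow(mat) + 1L
    ci <- (w - 1L) %/% nrow(mat) + 1L
    stop("illegal residue '", mat[ri, ci], "' in record '", ids[ri],
         "' at column ", ci, " (alphabet is a,c,g,u,-)")
  }
  if (is.null(classes)) {
    classes <- data.frame(id = ids, aa_class = "unknown",
                          life_domain = "unknown", stringsAsFactors = FALSE)
  }
  classes <- .validate_classes(classes, ids)
  structure(list(mat = mat, ids = ids, column_labels = column_labels,
                 classes = classes),
            class = "labeled_alignment")
}

.validate_classes <- function(classes, ids) {
  stopifnot(is.data.frame(classes),
            all(c("id", "aa_class", "life_domain") %in% names(classes)))
  classes$id <- as.character(classes$id)
  classes$aa_class <- as.character(classes$aa_class)
  classes$life_domain <- as.character(classes$life_domain)
  if (anyDuplicated(classes$id))
    stop("duplicate id in class-label table: ",
         paste(unique(classes$id[duplicated(classes$id)]), collapse = ", "))
  missing <- setdiff(ids, classes$id)
  if (length(missing)) {
    classes <- rbind(classes[, c("id", "aa_class", "life_domain")],
                     data.frame(id = missing, aa_class = "unknown",
                                life_domain = "unknown", stringsAsFactors = FALSE))
  }
  bad <- !(classes$life_domain %in% .DOMAINS)
  if (any(bad))
    stop("life_domain must be one of ", paste(.DOMAINS, collapse = ", "),
         "; got: ", paste(unique(classes$life_domain[bad]), collapse = ", "))
  rownames(classes) <- classes$id
  classes[ids, c("id", "aa_class", "life_domain")]
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("labeled_alignment:", nrow(x$mat), "sequences x", ncol(x$mat), "columns\n")
  tab <- table(paste(x$classes$aa_class, x$classes$life_domain, sep = "/"))
  cat("classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.labeled_alignment <- function(x) dim(x$mat)

# Normalize raw sequence strings to the a,c,g,u,- alphabet.
# T/t -> u, '.' -> '-', case folded; anything else is reported with coordinates.
.normalize_residues <- function(seqs, ids) {
  s <- chartr("T.", "u-", tolower(seqs))
  s <- chartr("t", "u", s)
  bad <- regexpr("[^acgu-]", s)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("illegal residue '", substr(s[i], bad[i], bad[i]), "' in record '",
         ids[i], "' at column ", bad[i], " (alphabet is a,c,g,u,-)")
  }
  s
}

#' Read a gapped alignment from FASTA or Stockholm
#'
#' Residues are normalized on load: case-folded, `T`/`t` mapped to `u`,
#' `.` mapped to `-`. Any other character is rejected with its row/column
#' coordinates; ambiguity codes and modified nucleotides are not accepted.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` (gapped) or `"stockholm"`.
#' @param label_file optional sidecar column-label file: one label per line,
#'   line k labels column k. When absent, columns are labeled `"1" ... "L"`.
#' @return a [labeled_alignment()] with all class labels `unknown`
#'   (see [attach_class_labels()]).
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm"),
                           label_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    seqs <- as.character(set)
    ids <- sub("\\s.*$", "", names(set))
  } else {
    rec <- .read_stockholm(path)
    seqs <- rec$seqs
    ids <- rec$ids
  }
  if (!length(seqs)) stop("no sequence records in ", path)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  len <- nchar(seqs)
  if (length(unique(len)) != 1L) {
    off <- which(len != len[1L])[1L]
    stop("alignment is ragged: record '", ids[off], "' has length ", len[off],
         " but '", ids[1L], "' has length ", len[1L])
  }
  seqs <- .normalize_residues(seqs, ids)
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE, dimnames = list(ids, NULL))
  labels <- NULL
  if (!is.null(label_file)) {
    labels <- readLines(label_file)
    labels <- trimws(labels[nzchar(trimws(labels))])
  }
  labeled_alignment(mat, column_labels = labels)
}

# Minimal Stockholm reader: sequence lines only ("name seq"), wrapped blocks
# concatenated per name; '#' annotation and '//' terminator skipped. No
# installed package parses Stockholm, hence the hand-written reader.
.read_stockholm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "//")]
  if (!length(lines)) return(list(ids = character(), seqs = character()))
  parts <- regmatches(lines, regexpr("\\S+", lines))
  rest <- trimws(substring(lines, nchar(parts) + 1L))
  agg <- tapply(rest, factor(parts, levels = unique(parts)),
                paste0, collapse = "")
  list(ids = names(agg), seqs = unname(agg))
}

#' Write a labeled alignment
#'
#' Writes gapped FASTA plus optional sidecar files so that a
#' write/read/attach round trip reproduces the object exactly.
#'
#' @param aln a [labeled_alignment()].
#' @param path output FASTA path.
#' @param class_file optional path for the class-label TSV
#'   (columns `id`, `aa_class`, `life_domain`).
#' @param label_file optional path for the column-label sidecar
#'   (one label per line).
#' @export
write_alignment <- function(aln, path, class_file = NULL, label_file = NULL) {
  stopifnot(inherits(aln, "labeled_alignment"))
  seqs <- apply(aln$mat, 1L, paste0, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path)
  if (!is.null(class_file))
    utils::write.table(aln$classes, class_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(label_file))
    writeLines(aln$column_labels, label_file)
  invisible(path)
}

#' Attach amino-acid class / domain-of-life labels
#'
#' @param aln a [labeled_alignment()].
#' @param table a data.frame with columns `id`, `aa_class`, `life_domain`,
#'   or a path to a TSV with that header. Ids in the table that are absent
#'   from the alignment are skipped with a warning (metadata tables are
#'   routinely supersets of the alignment); alignment rows absent from the
#'   table get `aa_class = "unknown"`.
#' @return a new `labeled_alignment`; the input is not modified.
#' @export
attach_class_labels <- function(aln, table) {
  stopifnot(inherits(aln, "labeled_alignment"))
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.table(table, sep = "\t", header = TRUE,
                               colClasses = "character", quote = "")
  stopifnot(is.data.frame(table))
  if (!nrow(table)) {
    return(labeled_alignment(aln$mat, aln$column_labels, classes = NULL))
  }
  table$id <- as.character(table$id)
  if (anyDuplicated(table$id))
    stop("duplicate id in class-label table: ",
         paste(unique(table$id[duplicated(table$id)]), collapse = ", "))
  unknown <- setdiff(table$id, aln$ids)
  if (length(unknown)) {
    warning(length(unknown), " table id(s) not present in alignment, skipped: ",
            paste(utils::head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ..." else "")
    table <- table[!(table$id %in% unknown), , drop = FALSE]
  }
  labeled_alignment(aln$mat, aln$column_labels, classes = table)
}

#' Stratum selector
#'
#' Picks alignment rows by amino-acid class and/or domain of life. A `NULL`
#' field matches everything, so `stratum_selector()` selects all rows.
#'
#' @param aa_class optional amino-acid class (e.g. `"Gly"`).
#' @param life_domain optional domain of life (`"Arc"`, `"Bac"`, `"Euk"`).
#' @export
stratum_selector <- function(aa_class = NULL, life_domain = NULL) {
  structure(list(aa_class = aa_class, life_domain = life_domain),
            class = "stratum_selector")
}

#' @export
format.stratum_selector <- function(x, ...) {
  paste(if (is.null(x$aa_class)) "*" else x$aa_class,
        if (is.null(x$life_domain)) "*" else x$life_domain, sep = "/")
}

#' @export
print.stratum_selector <- function(x, ...) {
  cat("stratum_selector:", format(x), "\n")
  invisible(x)
}

.selector_rows <- function(aln, sel) {
  keep <- rep(TRUE, length(aln$ids))
  if (!is.null(sel$aa_class)) keep <- keep & aln$classes$aa_class == sel$aa_class
  if (!is.null(sel$life_domain)) keep <- keep & aln$classes$life_domain == sel$life_domain
  which(keep)
}

#' Restrict an alignment to one stratum
#'
#' @param aln a [labeled_alignment()].
#' @param sel a [stratum_selector()].
#' @return a new `labeled_alignment` containing exactly the matching rows,
#'   row order preserved, same columns and labels. Selecting zero rows is an
#'   error: downstream per-column distributions would be undefined.
#' @export
stratify <- function(aln, sel) {
  stopifnot(inherits(aln, "labeled_alignment"), inherits(sel, "stratum_selector"))
  rows <- .selector_rows(aln, sel)
  if (!length(rows))
    stop("empty stratum: no rows match selector ", format(sel))
  labeled_alignment(aln$mat[rows, , drop = FALSE], aln$column_labels,
                    classes = aln$classes[rows, , drop = FALSE])
}

#' Standard tRNA position labels
#'
#' The canonical tRNA numbering scheme: positions 1-76 with the inserted
#' D-loop labels 17a, 20a, 20b, the variable-arm e-positions, and the -1
#' position found in some histidine tRNAs. Ships as a convenience default
#' map for tRNA-style alignments; nothing downstream assumes it — column
#' labels are opaque strings and the method is alignment-generic.
#'
#' @param include_minus1 include the "-1" label in front of position 1.
#' @param include_e include the variable-arm e-position block between
#'   positions 45 and 46.
#' @return character vector of labels in 5'-to-3' order.
#' @export
trna_standard_labels <- function(include_minus1 = TRUE, include_e = TRUE) {
  lab <- c(if (include_minus1) "-1",
           as.character(1:17), "17a", "18", "19", "20", "20a", "20b",
           as.character(21:45),
           if (include_e) c(paste0("e", 11:17), paste0("e", 1:5), paste0("e", 21:27)),
           as.character(46:76))
  lab
}

# Map a canonical tRNA label to its cloverleaf arm; used for DOT coloring.
.trna_arm <- function(label) {
  n <- suppressWarnings(as.integer(sub("[ab]$", "", label)))
  if (startsWith(label, "e")) return("variable")
  if (is.na(n)) return("other")
  if (n >= 1 && n <= 7) return("acceptor")
  if (n >= 66 && n <= 72) return("acceptor")
  if (n >= 10 && n <= 25) return("D")
  if (n >= 27 && n <= 43) return("anticodon")
  if (n >= 49 && n <= 65) return("T")
  "other"
}
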