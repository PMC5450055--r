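#' Secondary structure objects
#'
#' A `secondary_structure` holds an RNA sequence together with a set of
#' non-crossing base pairs, the representation every other function in the
#' package consumes. Pairs are stored 1-based with `i < j`; each nucleotide
#' participates in at most one pair; crossing (pseudoknotted) pair sets are
#' rejected at construction.
#'
#' @param pairs integer matrix with two columns (5' index, 3' index) or an
#'   empty/NULL value for a pairless strand. Rows may be in any order and
#'   orientation; they are normalised to `i < j` and sorted.
#' @param length number of nucleotides. Defaults to `nchar(sequence)` when a
#'   sequence is given.
#' @param sequence nucleotide string over `A,C,G,U,N` (other letters are kept
#'   verbatim with a warning; `T` is *not* silently mapped to `U`). Defaults
#'   to all-`N` of the requested length.
#' @return an object of class `secondary_structure` with fields `sequence`,
#'   `pairs` (m x 2 integer matrix), `length` and `pair_table` (vector mapping
#'   each position to its partner, 0 when unpaired).
#' @examples
#' s <- secondary_structure(pairs = rbind(c(1, 6), c(2, 5)), length = 6)
#' write_dotbracket(s)
#' @export
secondary_structure <- function(pairs = NULL, length = NULL, sequence = NULL) {
  if (is.null(length)) {
    if (is.null(sequence)) stop("either 'length' or 'sequence' must be given")
    length <- nchar(sequence)
  }
  length <- as.integer(length)
  if (length < 1L) stop("structure length must be >= 1")
  if (is.null(sequence)) {
    sequence <- strrep("N", length)
  } else if (nchar(sequence) != length) {
    stop(sprintf("sequence length %d does not match structure length %d",
                 nchar(sequence), length))
  }
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c("A", "C", "G", "U", "N"))
  if (base::length(bad) > 0L)
    warning(sprintf("non-standard bases kept verbatim: %s",
                    paste(bad, collapse = ",")))

  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    flip <- pairs[, 1L] > pairs[, 2L]
    pairs[flip, ] <- pairs[flip, 2:1]
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    if (any(pairs[, 1L] == pairs[, 2L])) stop("a base cannot pair with itself")
    if (any(pairs < 1L) || any(pairs > length))
      stop("pair index out of range 1..length")
    idx <- as.vector(pairs)
    if (anyDuplicated(idx))
      stop("a base appears in more than one pair")
  }
  pt <- integer(length)
  pt[pairs[, 1L]] <- pairs[, 2L]
  pt[pairs[, 2L]] <- pairs[, 1L]
  s <- structure(
    list(sequence = sequence, pairs = pairs, length = length, pair_table = pt),
    class = "secondary_structure")
  if (!validate_pseudoknot_free(s))
    stop("pseudoknot: crossing base pairs are not supported")
  s
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("secondary_structure: %d nt, %d base pairs\n",
              x$length, nrow(x$pairs)))
  if (x$length <= 120L) {
    cat(" ", x$sequence, "\n ", write_dotbracket(x), "\n", sep = "")
  }
  invisible(x)
}

#' Test that a pair set is free of pseudoknots
#'
#' Two pairs (i,j) and (k,l) cross when `i < k < j < l`; a structure
#' containing a crossing cannot be written in one bracket family and is
#' outside the scope of the layout engine.
#'
#' @param structure a `secondary_structure`, or a bare 2-column pair matrix.
#' @return `TRUE` iff no two pairs cross.
#' @export
validate_pseudoknot_free <- function(structure) {
  pairs <- if (inherits(structure, "secondary_structure")) structure$pairs
           else matrix(as.integer(structure), ncol = 2L)
  m <- nrow(pairs)
  if (m < 2L) return(TRUE)
  # stack sweep: O(n log n) by openings sorted; small m, quadratic is fine
  for (a in seq_len(m - 1L)) {
    i <- pairs[a, 1L]; j <- pairs[a, 2L]
    k <- pairs[(a + 1L):m, 1L]; l <- pairs[(a + 1L):m, 2L]
    if (any((i < k & k < j & j < l) | (k < i & i < l & l < j))) return(FALSE)
  }
  TRUE
}

#' Parse a dot-bracket string
#'
#' Accepts the plain single-family dot-bracket alphabet `.` `(` `)` plus
#' whitespace. Extended families (`[`, `{`, `<`) encode pseudoknots and are
#' rejected. The text may also be a two-line FASTA-like record (sequence line
#' followed by the structure line).
#'
#' @param text dot-bracket string, or sequence+structure separated by a
#'   newline.
#' @param sequence optional nucleotide string of matching length.
#' @return a [secondary_structure()].
#' @examples
#' parse_dotbracket("((..))")$pairs
#' @export
parse_dotbracket <- function(text, sequence = NULL) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("^>.*$", "", lines)
  lines <- gsub("[[:space:]]", "", lines)
  lines <- lines[nzchar(lines)]
  if (base::length(lines) == 0L) stop("empty dot-bracket input")
  if (base::length(lines) > 1L && grepl("^[ACGUNTacgunt]+$", lines[1]) &&
      grepl("[.()]", lines[2])) {
    if (is.null(sequence)) sequence <- toupper(lines[1])
    db <- paste(lines[-1], collapse = "")
  } else {
    db <- paste(lines, collapse = "")
  }
  chars <- strsplit(db, "")[[1]]
  if (any(chars %in% c("[", "]", "{", "}", "<", ">")))
    stop("pseudoknot unsupported: extended bracket families are not accepted")
  bad <- which(!chars %in% c(".", "(", ")"))
  if (base::length(bad) > 0L)
    stop(sprintf("invalid dot-bracket character '%s' at position %d",
                 chars[bad[1]], bad[1]))
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  for (pos in seq_along(chars)) {
    c <- chars[pos]
    if (c == "(") {
      open <- c(open, pos)
    } else if (c == ")") {
      if (base::length(open) == 0L)
        stop(sprintf("unbalanced at position %d", pos))
      pairs <- rbind(pairs, c(open[base::length(open)], pos))
      open <- open[-base::length(open)]
    }
  }
  if (base::length(open) > 0L)
    stop(sprintf("unbalanced at position %d", open[1]))
  secondary_structure(pairs = pairs, length = base::length(chars),
                      sequence = sequence)
}

#' Write a structure as a dot-bracket string
#'
#' Inverse of [parse_dotbracket()] on the (length, pairs) content.
#'
#' @param structure a `secondary_structure`.
#' @return a dot-bracket string.
#' @export
write_dotbracket <- function(structure) {
  if (!validate_pseudoknot_free(structure))
    stop("pseudoknot: crossing pairs cannot be written in one bracket family")
  out <- rep(".", structure$length)
  if (nrow(structure$pairs) > 0L) {
    out[structure$pairs[, 1L]] <- "("
    out[structure$pairs[, 2L]] <- ")"
  }
  paste(out, collapse = "")
}

# shared by CT/BPSEQ: partner column -> deduplicated symmetric pair matrix
.pairs_from_partner <- function(partner, what) {
  n <- base::length(partner)
  for (i in seq_len(n)) {
    p <- partner[i]
    if (p != 0L) {
      if (p < 1L || p > n)
        stop(sprintf("%s: partner %d of position %d out of range", what, p, i))
      if (partner[p] != i)
        stop(sprintf(
          "%s: asymmetric pairing (row %d says %d but row %d says %d)",
          what, i, p, p, partner[p]))
    }
  }
  i <- which(partner > seq_len(n))
  cbind(i, partner[i])
}

.body_lines <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines[nzchar(lines) & !grepl("^#", lines)]
}

#' Parse a CT (connectivity table) record
#'
#' Standard CT layout: a header line whose first field is the nucleotide
#' count, then one 6-column line per nucleotide: index, base, 5' neighbour,
#' 3' neighbour, pairing partner (0 = unpaired), natural index. Trailing
#' columns are ignored.
#'
#' @param text CT file contents.
#' @return a [secondary_structure()].
#' @export
parse_ct <- function(text) {
  lines <- .body_lines(text)
  if (base::length(lines) < 2L) stop("CT: need a header line and >= 1 record")
  n <- suppressWarnings(as.integer(strsplit(lines[1], "[[:space:]]+")[[1]][1]))
  if (is.na(n) || n < 1L) stop("CT: header must start with the record count")
  body <- lines[-1]
  if (base::length(body) != n)
    stop(sprintf("CT: header count %d but %d records", n, base::length(body)))
  fields <- strsplit(body, "[[:space:]]+")
  ncol_ok <- vapply(fields, function(f) base::length(f) >= 6L, logical(1))
  if (!all(ncol_ok))
    stop(sprintf("CT: record %d has fewer than 6 columns", which(!ncol_ok)[1]))
  idx <- vapply(fields, function(f) as.integer(f[1]), integer(1))
  if (!identical(idx, seq_len(n)))
    stop("CT: record indices must run 1..n contiguously")
  base_ <- vapply(fields, `[`, character(1), 2L)
  partner <- vapply(fields, function(f) as.integer(f[5]), integer(1))
  secondary_structure(pairs = .pairs_from_partner(partner, "CT"),
                      length = n,
                      sequence = paste(toupper(base_), collapse = ""))
}

#' Parse a BPSEQ record
#'
#' One line per nucleotide: index, base, partner (0 = unpaired). Indices must
#' be contiguous from 1 and the partner column symmetric.
#'
#' @param text BPSEQ file contents.
#' @return a [secondary_structure()].
#' @export
parse_bpseq <- function(text) {
  lines <- .body_lines(text)
  if (base::length(lines) == 0L) stop("BPSEQ: empty input")
  fields <- strsplit(lines, "[[:space:]]+")
  ok <- vapply(fields, function(f) base::length(f) >= 3L, logical(1))
  if (!all(ok))
    stop(sprintf("BPSEQ: line %d has fewer than 3 columns", which(!ok)[1]))
  idx <- vapply(fields, function(f) as.integer(f[1]), integer(1))
  n <- base::length(idx)
  if (!identical(idx, seq_len(n)))
    stop("BPSEQ: indices must be contiguous from 1")
  base_ <- vapply(fields, `[`, character(1), 2L)
  partner <- vapply(fields, function(f) as.integer(f[3]), integer(1))
  secondary_structure(pairs = .pairs_from_partner(partner, "BPSEQ"),
                      length = n,
                      sequence = paste(toupper(base_), collapse = ""))
}

#' Read a structure file, dispatching on format
#'
#' @param path file path.
#' @param format one of `"dotbracket"`, `"ct"`, `"bpseq"`; guessed from the
#'   file extension by default (`.ct`, `.bpseq`, else dot-bracket).
#' @return a [secondary_structure()].
#' @export
read_structure <- function(path, format = c("auto", "dotbracket", "ct", "bpseq")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ct = "ct", bpseq = "bpseq", "dotbracket")
  }
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  switch(format,
         dotbracket = parse_dotbracket(text),
         ct = parse_ct(text),
         bpseq = parse_bpseq(text))
}
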