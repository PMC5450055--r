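# run fn with a private RNG stream; the caller's .Random.seed is untouched
.with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# complementary sequence for a structure: paired positions drawn from the
# canonical and wobble pairs, unpaired positions uniform
.random_sequence <- function(pairs, n) {
  seq <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  if (nrow(pairs) > 0L) {
    duplexes <- list(c("G", "C"), c("C", "G"), c("A", "U"),
                     c("U", "A"), c("G", "U"), c("U", "G"))
    pick <- sample.int(6L, nrow(pairs), replace = TRUE,
                       prob = c(0.3, 0.3, 0.15, 0.15, 0.05, 0.05))
    for (r in seq_len(nrow(pairs))) {
      d <- duplexes[[pick[r]]]
      seq[pairs[r, 1L]] <- d[1L]
      seq[pairs[r, 2L]] <- d[2L]
    }
  }
  paste(seq, collapse = "")
}

#' Generate a random valid secondary structure
#'
#' Builds a pseudoknot-free structure of exactly `n` nucleotides by
#' recursive interval subdivision: an interval either stays unpaired or
#' opens a stem of at least `min_stem` stacked pairs whose interior is, with
#' probability `branch_prob`, split into a multiloop of two branches, and
#' otherwise continues into an internal/bulge loop or terminates in a
#' hairpin of at least `min_hairpin` unpaired bases. Non-crossing by
#' construction; deterministic per seed; O(n).
#'
#' @param n target length (>= `min_hairpin`).
#' @param seed integer RNG seed (the caller's RNG state is preserved).
#' @param min_stem minimum consecutive pairs per stem; 0 yields a pairless
#'   strand for short `n`.
#' @param min_hairpin minimum unpaired bases in a hairpin (>= 3, the
#'   physical minimum).
#' @param branch_prob probability that a stem interior opens a multiloop.
#' @return a [secondary_structure()] with a complementarity-consistent
#'   random sequence.
#' @examples
#' random_structure(40, seed = 1)
#' @export
random_structure <- function(n, seed = 1L, min_stem = 2L, min_hairpin = 3L,
                             branch_prob = 0.25) {
  stopifnot(min_hairpin >= 3L, branch_prob >= 0, branch_prob <= 1)
  if (n < min_hairpin)
    stop(sprintf("n = %d is below the minimum hairpin size %d", n, min_hairpin))
  helix_min <- 2L * max(min_stem, 1L) + min_hairpin

  .with_seed(seed, function() {
    # each gen_* returns a character vector of dots/brackets of exact length
    gen_interior <- function(len) {
      if (len < helix_min) return(rep(".", len))
      if (len >= 2L * helix_min + 3L && stats::runif(1) < branch_prob) {
        # multiloop: two branches with small unpaired gaps
        g0 <- sample(0:2, 1L); g1 <- sample(1:3, 1L); g2 <- sample(0:2, 1L)
        avail <- len - g0 - g1 - g2
        if (avail >= 2L * helix_min) {
          split <- sample(helix_min:(avail - helix_min), 1L)
          return(c(rep(".", g0), gen_helix(split), rep(".", g1),
                   gen_helix(avail - split), rep(".", g2)))
        }
      }
      # internal/bulge continuation or hairpin
      if (stats::runif(1) < 0.75 && len >= helix_min + 1L) {
        left <- sample(0:3, 1L); right <- sample(0:3, 1L)
        if (len - left - right >= helix_min && left + right > 0L)
          return(c(rep(".", left), gen_helix(len - left - right),
                   rep(".", right)))
      }
      rep(".", len)  # hairpin (len >= min_hairpin here)
    }
    gen_helix <- function(len) {
      # a stem of s pairs wrapped around its interior
      smax <- (len - min_hairpin) %/% 2L
      if (smax < max(min_stem, 1L)) return(rep(".", len))
      s <- min(smax, max(min_stem, 1L) + stats::rgeom(1L, 0.35))
      c(rep("(", s), gen_interior(len - 2L * s), rep(")", s))
    }
    gen_top <- function(len) {
      if (len < helix_min) return(rep(".", len))
      d5 <- sample(0:3, 1L); d3 <- sample(0:3, 1L)
      if (len - d5 - d3 < helix_min) { d5 <- 0L; d3 <- 0L }
      c(rep(".", d5), gen_helix(len - d5 - d3), rep(".", d3))
    }
    db <- paste(gen_top(n), collapse = "")
    s <- parse_dotbracket(db)
    secondary_structure(pairs = s$pairs, length = n,
                        sequence = .random_sequence(s$pairs, n))
  })
}

#' A 76-nt cloverleaf test structure
#'
#' A synthetic, generic tRNA-like cloverleaf (not any particular database
#' entry): a 7-pair acceptor stem and three hairpin arms radiating from one
#' multiloop, with a 3' single-stranded tail. Its compressed graph has
#' exactly one multiloop, three hairpin loops and one exterior loop.
#'
#' @return a [secondary_structure()] of length 76.
#' @examples
#' table(build_compressed_graph(cloverleaf_fixture())$kind)
#' @export
cloverleaf_fixture <- function() {
  db <- paste0(
    "(((((((",          # acceptor stem
    "..",
    "((((", "........", "))))",   # first hairpin arm
    ".",
    "(((((", ".......", ")))))",  # anticodon-like arm
    ".....",                      # variable region
    "(((((", ".......", ")))))",  # third arm
    ")))))))",
    "....")                       # 3' tail
  s <- parse_dotbracket(db)
  secondary_structure(pairs = s$pairs, length = s$length,
                      sequence = .with_seed(7602L, function()
                        .random_sequence(s$pairs, s$length)))
}

#' Generate a graded suite of structures
#'
#' One random structure per requested length, emulating a size gradient at
#' desk scale; deterministic per seed.
#'
#' @param sizes vector of target lengths.
#' @param seed base RNG seed; structure `i` uses `seed + 7919 * i`.
#' @param ... further arguments passed to [random_structure()].
#' @return a list of [secondary_structure()] objects.
#' @export
graded_suite <- function(sizes, seed = 1L, ...) {
  lapply(seq_along(sizes), function(i)
    random_structure(sizes[i], seed = seed + 7919L * i, ...))
}
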