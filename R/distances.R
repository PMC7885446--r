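## Pairwise-deletion sequence comparisons.
##
## All distances in the package use pairwise deletion: for each pair of
## sequences, sites carrying N or "-" in either member are excluded, and
## differences are counted over the remaining (usable) sites.

## Integer-code a character matrix: A,C,G,T -> 1..4; N,- -> NA.
.encode <- function(mat) {
  code <- match(mat, .BASES)
  dim(code) <- dim(mat)
  code
}

#' Pairwise nucleotide differences under pairwise deletion
#'
#' @param x A [hap_alignment], `hap_table`, or character matrix of aligned
#'   sequences (rows = sequences).
#' @return List with `diffs` and `usable`, both `dist` objects over the
#'   input rows: the number of differing sites and the number of sites at
#'   which both sequences are unambiguous.
#' @export
pairwise_differences <- function(x) {
  mat <- if (inherits(x, "hap_alignment")) {
    x$seq
  } else if (inherits(x, "hap_table")) {
    x$sequences
  } else {
    x
  }
  n <- nrow(mat)
  if (is.null(n) || n < 1L) abort_input("need at least one sequence")
  code <- .encode(mat)
  okm <- !is.na(code)
  usable <- tcrossprod(okm * 1L)
  diffs <- matrix(0L, n, n)
  if (n > 1L) {
    ## only variable columns can contribute differences
    varcols <- which(apply(code, 2L, function(z) {
      z <- z[!is.na(z)]
      length(z) > 0L && any(z != z[1L])
    }))
    for (j in varcols) {
      z <- code[, j]
      ne <- outer(z, z, "!=")
      ne[is.na(ne)] <- FALSE
      diffs <- diffs + ne
    }
  }
  dimnames(diffs) <- dimnames(usable) <- list(rownames(mat), rownames(mat))
  list(diffs = stats::as.dist(diffs), usable = stats::as.dist(usable), n = n)
}

#' Hamming distance matrix between haplotypes
#'
#' Symmetric matrix of pairwise-deletion difference counts; zero diagonal.
#'
#' @param table A `hap_table` (or [hap_alignment]).
#' @return Integer matrix of pairwise substitution counts.
#' @export
hamming_matrix <- function(table) {
  pd <- pairwise_differences(table)
  as.matrix(pd$diffs)
}
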