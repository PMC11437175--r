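#' Tetranucleotide projection kernel
#'
#' Constructs the fixed orthonormal basis used to project 256-dimensional
#' tetramer frequency vectors into the constrained 103-dimensional space.
#' Tetramer frequencies of a double-stranded genome are not free: counting is
#' strand-symmetric, frequencies sum to one, and overlapping windows tie the
#' trimer prefix and suffix margins together. The kernel is the orthonormal
#' null space of the stacked linear constraint system on the frequency
#' deviation vector:
#'
#' * reverse-complement symmetry: `f(w) = f(revcomp(w))` for every tetramer `w`;
#' * unit sum: `f` is orthogonal to the all-ones vector (frequencies sum to a
#'   constant, so deviations sum to zero);
#' * trimer continuity: for each of the 64 trimers `t`,
#'   `sum_x f(t.x) = sum_x f(x.t)` (every occurrence of `t` extends one base to
#'   the right and one to the left, up to contig-edge effects).
#'
#' The null space has dimension 103; its basis columns are themselves
#' invariant under the reverse-complement permutation of the tetramer axes.
#'
#' @param tol Relative singular-value tolerance used to separate the null
#'   space from the row space of the constraint matrix.
#' @return An object of class `tnf_kernel`: a list with `matrix` (256 x 103,
#'   orthonormal columns, rows in `kmer_order`) and `kmer_order` (the 256
#'   tetramers in lexicographic A < C < G < T order, last base varying
#'   fastest, matching [Biostrings::oligonucleotideFrequency()]).
#' @examples
#' k <- tnf_kernel()
#' dim(k$matrix)                       # 256 x 103
#' max(abs(crossprod(k$matrix) - diag(103)))
#' @export
tnf_kernel <- function(tol = 1e-10) {
  cached <- get0("kernel", envir = .tnf_cache)
  if (!is.null(cached)) return(cached)
  kmers <- tnf_kmer_order()
  A <- tnf_constraint_matrix(kmers)
  s <- svd(A, nu = 0, nv = 256)
  d <- c(s$d, rep(0, 256 - length(s$d)))
  rank <- sum(d > tol * max(d))
  basis <- s$v[, (rank + 1):256, drop = FALSE]
  rownames(basis) <- kmers
  out <- structure(list(matrix = basis, kmer_order = kmers),
                   class = "tnf_kernel")
  assign("kernel", out, envir = .tnf_cache)
  out
}

.tnf_cache <- new.env(parent = emptyenv())

#' All tetramers in canonical lexicographic order
#'
#' Order matches `Biostrings::oligonucleotideFrequency(width = 4)`: the last
#' position varies fastest.
#' @return Character vector of length 256.
#' @keywords internal
tnf_kmer_order <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p4 = b, p3 = b, p2 = b, p1 = b,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3, g$p4)
}

#' Reverse complement of k-mer strings
#' @keywords internal
revcomp_kmers <- function(kmers) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(kmers, ""), function(ch) {
    paste(rev(unname(comp[ch])), collapse = "")
  }, character(1))
}

# Stacked constraint rows (RC pairs, unit sum, 64 trimer continuity rows)
# acting on the 256-dim frequency deviation vector.
tnf_constraint_matrix <- function(kmers = tnf_kmer_order()) {
  n <- length(kmers)
  idx <- stats::setNames(seq_len(n), kmers)
  rc <- idx[revcomp_kmers(kmers)]

  pair_i <- which(seq_len(n) < rc)        # one row per non-palindromic pair
  rc_rows <- matrix(0, length(pair_i), n)
  for (r in seq_along(pair_i)) {
    rc_rows[r, pair_i[r]] <- 1
    rc_rows[r, rc[pair_i[r]]] <- -1
  }

  ones_row <- matrix(1, 1, n)

  trimers <- substr(kmers[seq(1, n, by = 4)], 1, 3)  # 64 unique trimers
  tri_rows <- matrix(0, length(trimers), n)
  prefix <- substr(kmers, 1, 3)
  suffix <- substr(kmers, 2, 4)
  for (r in seq_along(trimers)) {
    tri_rows[r, prefix == trimers[r]] <- tri_rows[r, prefix == trimers[r]] + 1
    tri_rows[r, suffix == trimers[r]] <- tri_rows[r, suffix == trimers[r]] - 1
  }

  rbind(rc_rows, ones_row, tri_rows)
}
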