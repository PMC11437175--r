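#' Count tetramers in contig sequences
#'
#' Slides a width-4 window with step 1 over each sequence; windows containing
#' any base outside A/C/G/T (case-insensitive) are skipped. Sequences shorter
#' than 4 bp yield all-zero counts.
#'
#' @param sequences A [Biostrings::DNAStringSet] or named character vector of
#'   contig sequences.
#' @return Integer matrix, one row per contig, 256 columns in the kernel's
#'   `kmer_order`.
#' @export
count_tetramers <- function(sequences) {
  if (is.character(sequences)) {
    if (any(!nzchar(sequences))) {
      bad <- names(sequences)[!nzchar(sequences)]
      if (is.null(bad)) bad <- which(!nzchar(sequences))
      stop("empty sequence for contig(s): ", paste(bad, collapse = ", "))
    }
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (any(Biostrings::width(sequences) == 0)) {
    bad <- names(sequences)[Biostrings::width(sequences) == 0]
    stop("empty sequence for contig(s): ", paste(bad, collapse = ", "))
  }
  counts <- Biostrings::oligonucleotideFrequency(sequences, width = 4, step = 1)
  rownames(counts) <- names(sequences)
  storage.mode(counts) <- "integer"
  counts
}

#' Project raw tetramer counts into the constrained TNF space
#'
#' Counts are normalized to frequencies (sum 1), centered by subtracting the
#' uniform frequency 1/256, and multiplied by the kernel. Rows with zero total
#' counts map to the zero vector.
#'
#' @param counts Integer/numeric matrix (or vector) of 256 tetramer counts per
#'   contig, columns in `kmer_order`.
#' @param kernel A [tnf_kernel()] object.
#' @return Numeric matrix, one row per contig, 103 columns.
#' @export
project_tnf <- function(counts, kernel = tnf_kernel()) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  stopifnot(ncol(counts) == 256)
  tot <- rowSums(counts)
  freq <- counts / ifelse(tot > 0, tot, 1)
  freq[tot == 0, ] <- 0
  centered <- freq - 1 / 256
  centered[tot == 0, ] <- 0
  out <- centered %*% kernel$matrix
  rownames(out) <- rownames(counts)
  out
}

#' Z-scale matrix columns across contigs
#'
#' Subtracts the column mean and divides by the population (1/N) standard
#' deviation. Zero-variance columns (including any column when there is a
#' single row) are set to 0.
#'
#' @param m Numeric matrix.
#' @return Numeric matrix of the same shape.
#' @export
zscale_columns <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 1)
  mu <- colMeans(m)
  centered <- sweep(m, 2, mu)
  sd_pop <- sqrt(colMeans(centered^2))
  scale_by <- ifelse(sd_pop > 0, sd_pop, 1)
  out <- sweep(centered, 2, scale_by, "/")
  out[, sd_pop == 0] <- 0
  out
}

#' Normalize per-sample contig depths into abundance features
#'
#' Three steps: (1) divide each sample column by that sample's total mapped
#' reads (or, when totals are absent, by the column sum of depths); (2) record
#' each contig's total abundance as its row sum — the sample-relative
#' abundance, taken before across-sample normalization; (3) normalize each
#' row with positive total to sum to 1. All-zero rows stay zero.
#'
#' @param depths Numeric matrix, contigs x samples, nonnegative.
#' @param sample_totals Optional numeric vector of per-sample mapped-read
#'   totals (strictly positive). Defaults to the per-sample column sums.
#' @return List of class `abundance_matrix`: `per_sample` (row-normalized
#'   matrix), `total` (numeric vector), `sample_ids`.
#' @export
normalize_abundances <- function(depths, sample_totals = NULL) {
  if (is.null(dim(depths))) depths <- matrix(depths, nrow = 1)
  if (any(depths < 0)) {
    bad <- which(depths < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative depth for contig '%s' in sample '%s'",
                 rownames(depths)[bad[1]] %||% bad[1],
                 colnames(depths)[bad[2]] %||% bad[2]))
  }
  if (is.null(sample_totals)) {
    sample_totals <- colSums(depths)
    sample_totals[sample_totals == 0] <- 1
  }
  stopifnot(length(sample_totals) == ncol(depths), all(sample_totals > 0))
  within <- sweep(depths, 2, sample_totals, "/")
  total <- rowSums(within)
  per_sample <- within / ifelse(total > 0, total, 1)
  per_sample[total == 0, ] <- 0
  structure(list(per_sample = per_sample,
                 total = stats::setNames(total, rownames(depths)),
                 sample_ids = colnames(depths)),
            class = "abundance_matrix")
}

#' Assemble the contig feature table
#'
#' Concatenates the z-scaled 103-dimensional TNF block, the row-normalized
#' per-sample abundances, and the untransformed total-abundance column into
#' the Nc x (103 + Ns + 1) table the refiner trains on.
#'
#' @param tnf_z Numeric matrix, contigs x 103 (z-scaled projected TNF).
#' @param abund An `abundance_matrix` from [normalize_abundances()].
#' @return Object of class `feature_matrix`: `values`, `contig_ids`,
#'   `n_samples`, and `blocks` giving the column index of each block.
#' @export
assemble_features <- function(tnf_z, abund) {
  stopifnot(inherits(abund, "abundance_matrix"))
  if (nrow(tnf_z) != nrow(abund$per_sample))
    stop("row-count mismatch between TNF and abundance blocks")
  ids_t <- rownames(tnf_z)
  ids_a <- rownames(abund$per_sample)
  if (!is.null(ids_t) && !is.null(ids_a) && !identical(ids_t, ids_a))
    stop("contig id mismatch between TNF and abundance blocks")
  d_tnf <- ncol(tnf_z)
  ns <- ncol(abund$per_sample)
  values <- cbind(tnf_z, abund$per_sample, abund$total)
  colnames(values) <- c(paste0("tnf", seq_len(d_tnf)),
                        abund$sample_ids %||% paste0("sample", seq_len(ns)),
                        "total_abundance")
  structure(list(values = values,
                 contig_ids = ids_t %||% as.character(seq_len(nrow(values))),
                 n_samples = ns,
                 blocks = list(tnf = seq_len(d_tnf),
                               abundance = d_tnf + seq_len(ns),
                               total = d_tnf + ns + 1L)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d contigs x (%d TNF + %d abundance + 1 total)\n",
              nrow(x$values), length(x$blocks$tnf), x$n_samples))
  invisible(x)
}

#' Compute the full feature table from contigs and depths
#'
#' Convenience pipeline: drop contigs below the minimum length, align the
#' depth table to the surviving contigs, count and project tetramers, z-scale
#' the projected block across contigs, and normalize abundances.
#'
#' @param sequences [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @param depths Numeric matrix contigs x samples (or path to a depth TSV with
#'   a `contigname` first column), rows matched to contigs by name.
#' @param sample_totals Optional per-sample mapped-read totals.
#' @param min_contig_length Contigs shorter than this are dropped (default
#'   2000 bp).
#' @param kernel Projection kernel; defaults to [tnf_kernel()].
#' @return A `feature_matrix`.
#' @export
compute_features <- function(sequences, depths, sample_totals = NULL,
                             min_contig_length = 2000, kernel = tnf_kernel()) {
  if (is.character(sequences) && length(sequences) == 1 && file.exists(sequences))
    sequences <- read_contigs(sequences)
  if (is.character(depths) && length(depths) == 1 && file.exists(depths))
    depths <- read_depths(depths)
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(toupper(sequences))
  keep <- Biostrings::width(sequences) >= min_contig_length
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("dropped %d contig(s) shorter than %d bp", n_drop,
                    min_contig_length))
  sequences <- sequences[keep]
  if (length(sequences) == 0) stop("no contigs pass the minimum length filter")
  ids <- names(sequences)
  if (is.null(ids)) stop("contig sequences must be named")
  missing <- setdiff(ids, rownames(depths))
  if (length(missing) > 0)
    stop("contigs missing from the depth table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  depths <- depths[ids, , drop = FALSE]
  tnf_z <- zscale_columns(project_tnf(count_tetramers(sequences), kernel))
  abund <- normalize_abundances(depths, sample_totals)
  assemble_features(tnf_z, abund)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
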