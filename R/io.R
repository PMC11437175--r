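#' Read contig sequences from a FASTA file
#'
#' Contig ids are the first whitespace-delimited token of each header.
#' @param path Path to a (possibly line-wrapped) multi-record FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Read a per-contig per-sample depth table
#'
#' Expects a TSV with header `contigname<TAB>sample1<TAB>...` and one row per
#' contig.
#' @param path Path to the TSV.
#' @return Numeric matrix with contig rownames and sample colnames.
#' @export
read_depths <- function(path) {
  if (!file.exists(path)) stop("depth TSV not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2) stop("depth TSV needs a contig column and >= 1 sample column")
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Write a depth table TSV
#' @param depths Numeric matrix, contigs x samples.
#' @param path Output path.
#' @export
write_depths <- function(depths, path) {
  dt <- data.table::data.table(contigname = rownames(depths))
  for (j in seq_len(ncol(depths)))
    dt[[colnames(depths)[j] %||% paste0("sample", j)]] <- depths[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
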