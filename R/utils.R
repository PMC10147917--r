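#' Generate a random DNA sequence
#'
#' Uniform i.i.d. bases. Used throughout the simulator for gene bodies,
#' intergenic spacers and read flanks.
#'
#' @param n Sequence length in nucleotides.
#' @param bases Alphabet to draw from.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  if (n <= 0) return("")
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA sequences
#'
#' @param x Character vector of DNA sequences (IUPAC codes accepted).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# All k-mers of a sequence as a character vector; position i holds the k-mer
# starting at base i (1-based). Returns character(0) if the sequence is
# shorter than k.
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Keeps simulator functions reproducible without
# clobbering the session RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed; kept below 2^31.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# Normalise a reads argument to a tibble with read_id / sequence columns.
# Accepts a data frame, a named character vector, or an unnamed character
# vector (ids are generated).
as_reads_tbl <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "sequence") %in% names(reads)))
    return(as_tibble(reads[, c("read_id", "sequence")]))
  }
  if (is.character(reads)) {
    ids <- names(reads) %||% (if (length(reads)) paste0("read", seq_along(reads))
                              else character(0))
    return(tibble(read_id = ids, sequence = unname(reads)))
  }
  abort("`reads` must be a data frame with read_id/sequence or a character vector")
}

# Total length of query positions covered by k-mers starting at `qpos`
# (1-based), each of width k, as a fraction of query_length.
coverage_fraction <- function(qpos, k, query_length) {
  if (length(qpos) == 0) return(0)
  cov <- IRanges::reduce(IRanges::IRanges(start = qpos, width = k))
  sum(IRanges::width(cov)) / query_length
}
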