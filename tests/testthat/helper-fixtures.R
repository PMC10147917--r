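# Shared fixtures, built in code at load time.

# Deterministic random sequence without touching the session RNG.
fixed_dna <- function(n, seed) {
  withr::with_seed(seed, random_dna(n))
}

# A read carrying `n` copies of `query` separated by the given spacers
# (recycled), with random flanks.
read_with_copies <- function(query, n, spacer_lengths = 1200, flank = 1000,
                             seed = 1) {
  withr::with_seed(seed, {
    parts <- random_dna(flank)
    if (n > 0) {
      parts <- c(parts, query)
      if (n > 1) {
        sp <- rep_len(spacer_lengths, n - 1)
        for (i in seq_len(n - 1)) parts <- c(parts, random_dna(sp[i]), query)
      }
    }
    paste(c(parts, random_dna(flank)), collapse = "")
  })
}

# Point-mutate a fraction of positions.
mutate_seq <- function(seq, rate, seed = 1) {
  withr::with_seed(seed, {
    b <- strsplit(seq, "")[[1]]
    i <- sample(length(b), round(rate * length(b)))
    b[i] <- sample(c("A", "C", "G", "T"), length(i), replace = TRUE)
    paste(b, collapse = "")
  })
}

# Brute-force oracle: number of non-overlapping exact occurrences of
# `query` in `read` (forward or reverse complement), by plain string
# search. Independent of the k-mer machinery.
oracle_copy_count <- function(read, query) {
  hits <- function(s, q) {
    out <- gregexpr(q, s, fixed = TRUE)[[1]]
    sum(out > 0)
  }
  max(hits(read, query), hits(revcomp(read), query))
}

# Small shared query for the k-mer tests.
test_query <- fixed_dna(528, seed = 101)
test_index <- kmer_index(test_query, k = 19)
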