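#' Build a two-stranded k-mer index of a query sequence
#'
#' Indexes every unambiguous k-mer of `query` on both strands, so that a
#' match against a read reports the query offset and the orientation of the
#' matching copy. k-mers containing non-ACGT characters are skipped.
#'
#' @param query A single DNA sequence (character scalar).
#' @param k K-mer length in nucleotides. The default follows the standard
#'   choice for long-read gene searches at percent-level error rates.
#' @return An object of class `kmer_index` holding the k-mer table, `k` and
#'   the query length.
#' @examples
#' idx <- kmer_index("ACGTACGTAC", k = 8)
#' idx$query_length
#' @export
kmer_index <- function(query, k = 19) {
  if (!is.character(query) || length(query) != 1 || is.na(query)) {
    abort("`query` must be a single DNA sequence")
  }
  query <- toupper(query)
  k <- as.integer(k)
  if (k < 1) abort("`k` must be >= 1")
  L <- nchar(query)
  if (L < k) abort(sprintf("query too short: length %d < k = %d", L, k))

  fwd <- seq_kmers(query, k)
  rev <- seq_kmers(revcomp(query), k)
  ok_f <- grepl("^[ACGT]+$", fwd)
  ok_r <- grepl("^[ACGT]+$", rev)

  kmer <- c(fwd[ok_f], rev[ok_r])
  # the i-th k-mer of the reverse complement covers query positions
  # [L - k - i + 2, L - i + 1]; its query offset is the left end.
  qpos <- c(which(ok_f), (L - k + 2L) - which(ok_r))
  strand <- rep(c("+", "-"), c(sum(ok_f), sum(ok_r)))

  ord <- order(kmer, strand, qpos)
  kmer <- kmer[ord]
  qpos <- qpos[ord]
  strand <- strand[ord]

  rl <- rle(kmer)
  structure(
    list(
      k = k,
      query_length = L,
      qpos = qpos,
      strand = strand,
      uniq = rl$values,
      grp_start = cumsum(c(1L, rl$lengths[-length(rl$lengths)])),
      grp_len = rl$lengths
    ),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf(
    "<kmer_index> k = %d, query length = %d nt, %d distinct k-mers (%d entries)\n",
    x$k, x$query_length, length(x$uniq), length(x$qpos)
  ))
  invisible(x)
}

# Match a vector of read k-mers (position i = k-mer starting at read base i)
# against an index; returns all (read_pos, query_pos, strand) hits.
scan_kmer_vector <- function(kmers, index) {
  empty <- tibble(read_pos = integer(), query_pos = integer(), strand = character())
  if (length(kmers) == 0) return(empty)
  j <- match(kmers, index$uniq)
  hit <- which(!is.na(j))
  if (length(hit) == 0) return(empty)
  g <- j[hit]
  reps <- index$grp_len[g]
  rows <- rep(index$grp_start[g], reps) + sequence(reps) - 1L
  out <- tibble(
    read_pos = rep.int(hit, reps),
    query_pos = index$qpos[rows],
    strand = index$strand[rows]
  )
  arrange(out, .data$read_pos, .data$query_pos)
}

#' Scan a read for k-mer matches against an index
#'
#' Reports every position at which a k-mer of `read` equals an indexed k-mer
#' of the query, on either strand, sorted by read position. A read shorter
#' than `k` yields no matches; read k-mers containing ambiguous bases cannot
#' match (the index holds none).
#'
#' @param read A single DNA sequence.
#' @param index A [kmer_index()].
#' @return A tibble with columns `read_pos`, `query_pos` (both 1-based
#'   k-mer start offsets) and `strand`, carrying `k` and `query_length`
#'   attributes for downstream clustering.
#' @export
scan_read <- function(read, index) {
  stopifnot(inherits(index, "kmer_index"))
  read <- toupper(read)
  out <- scan_kmer_vector(seq_kmers(read, index$k), index)
  attr(out, "k") <- index$k
  attr(out, "query_length") <- index$query_length
  out
}

#' Cluster k-mer matches into blocks under a maximum-gap rule
#'
#' Successive matches (by read position) further apart than `gap_threshold`
#' start a new block: the rule used to delimit putative gene copies in raw
#' long reads. Block strand is the majority orientation of member matches;
#' ties go to the member with the smallest query offset.
#'
#' @param matches A tibble as returned by [scan_read()].
#' @param gap_threshold Maximum allowed distance (nt) between successive
#'   k-mer start positions within one block. 800 nt is the published rule
#'   of thumb at k = 19.
#' @param k,query_length K-mer size and query length; taken from the
#'   attributes of `matches` when absent.
#' @return A tibble of blocks: `start`, `end` (1-based inclusive read
#'   coordinates), `strand`, `n_kmers`, `query_coverage`.
#' @export
cluster_matches <- function(matches, gap_threshold = 800,
                            k = attr(matches, "k"),
                            query_length = attr(matches, "query_length")) {
  if (gap_threshold < 1) abort("invalid threshold: gap_threshold must be >= 1")
  if (is.null(k) || is.null(query_length)) {
    abort("`k` and `query_length` are required (pass them or use scan_read() output)")
  }
  empty <- tibble(
    start = integer(), end = integer(), strand = character(),
    n_kmers = integer(), query_coverage = double(), query_span = double()
  )
  if (nrow(matches) == 0) return(empty)
  m <- arrange(matches, .data$read_pos, .data$query_pos)
  block <- cumsum(c(1L, as.integer(diff(m$read_pos) > gap_threshold)))
  summarise_blocks(m, block, k, query_length)
}

# Shared block summary used by cluster_matches() and call_copies().
summarise_blocks <- function(m, block, k, query_length) {
  groups <- split(seq_len(nrow(m)), factor(block, levels = unique(block)))
  rows <- map(groups, function(i) {
    st <- m$strand[i]
    np <- sum(st == "+")
    nm <- length(st) - np
    strand <- if (np > nm) "+" else if (nm > np) "-" else st[which.min(m$query_pos[i])]
    tibble(
      start = min(m$read_pos[i]),
      end = max(m$read_pos[i]) + k - 1L,
      strand = strand,
      n_kmers = length(i),
      query_coverage = coverage_fraction(m$query_pos[i], k, query_length),
      query_span = (max(m$query_pos[i]) - min(m$query_pos[i]) + k) / query_length
    )
  })
  bind_rows(rows)
}

# Resolve k-mers matching several query offsets (e.g. a query containing its
# own internal tandem repeat): per read position keep the hit closest to the
# trajectory extrapolated from the previous position, preferring the current
# strand. Returns a filtered match tibble, one row per read position.
select_match_path <- function(m) {
  if (nrow(m) <= 1) return(m)
  pos <- m$read_pos
  firsts <- which(c(TRUE, pos[-1] != pos[-length(pos)]))
  if (length(firsts) == nrow(m)) return(m)  # already unique per position
  keep <- integer(length(firsts))
  prev_q <- NA_integer_
  prev_p <- NA_integer_
  prev_s <- NA_character_
  bounds <- c(firsts, nrow(m) + 1L)
  for (i in seq_along(firsts)) {
    rows <- bounds[i]:(bounds[i + 1L] - 1L)
    if (length(rows) == 1L || is.na(prev_q)) {
      j <- rows[1L]
    } else {
      same <- rows[m$strand[rows] == prev_s]
      cand <- if (length(same)) same else rows
      gap <- pos[cand[1L]] - prev_p
      expected <- if (identical(prev_s, "-")) prev_q - gap else prev_q + gap
      j <- cand[which.min(abs(m$query_pos[cand] - expected))]
    }
    keep[i] <- j
    prev_q <- m$query_pos[j]
    prev_p <- pos[j]
    prev_s <- m$strand[j]
  }
  m[keep, ]
}

#' Count copies of a query gene in a single read
#'
#' The copy-counting core: scans the read for query k-mers, clusters matches
#' with the maximum-gap rule, splits clusters where the query coordinate
#' resets (the signature of tandem copies closer than the gap threshold),
#' and keeps segments passing both support filters. The copy count is the
#' number of surviving blocks.
#'
#' @inheritParams scan_read
#' @inheritParams cluster_matches
#' @param min_kmers Minimum member matches per block; guards against random
#'   k-mer collisions.
#' @param min_query_coverage Minimum fraction of query positions covered by
#'   member k-mers. The default 0.25 keeps roughly half-length truncated
#'   gene copies countable.
#' @return An object of class `copy_call`: a list with `copy_count`,
#'   `blocks` (tibble of surviving block intervals with strand) and
#'   `read_length`.
#' @examples
#' q <- random_dna(528)
#' call_copies(q, kmer_index(q))$copy_count
#' @export
call_copies <- function(read, index, gap_threshold = 800,
                        min_kmers = 5, min_query_coverage = 0.1) {
  stopifnot(inherits(index, "kmer_index"))
  if (min_kmers < 0 || min_query_coverage < 0) abort("thresholds must be >= 0")
  matches <- scan_read(read, index)
  call_copies_from_matches(matches, index$k, index$query_length,
                           gap_threshold, min_kmers, min_query_coverage,
                           read_length = nchar(read))
}

call_copies_from_matches <- function(matches, k, query_length, gap_threshold,
                                     min_kmers, min_query_coverage,
                                     read_length) {
  if (gap_threshold < 1) abort("invalid threshold: gap_threshold must be >= 1")
  empty <- new_copy_call(0L, tibble(
    start = integer(), end = integer(), strand = character(),
    n_kmers = integer(), query_coverage = double(), query_span = double()
  ), read_length)
  if (nrow(matches) == 0) return(empty)

  m <- select_match_path(arrange(matches, .data$read_pos, .data$query_pos))
  n <- nrow(m)
  if (n == 0) return(empty)

  gap_break <- c(FALSE, diff(m$read_pos) > gap_threshold)
  dq <- c(0L, diff(m$query_pos))
  strand_break <- c(FALSE, m$strand[-1] != m$strand[-n])
  # query coordinate reset: a new copy starts when the query offset jumps
  # backwards (forward strand) or forwards (reverse strand) by more than k.
  reset <- c(FALSE, (m$strand[-1] == "+" & dq[-1] < -k) |
                    (m$strand[-1] == "-" & dq[-1] > k))
  block <- cumsum(gap_break | strand_break | reset) + 1L

  blocks <- summarise_blocks(m, block, k, query_length)
  keep <- blocks$n_kmers >= min_kmers & blocks$query_coverage >= min_query_coverage
  new_copy_call(sum(keep), blocks[keep, ], read_length)
}

new_copy_call <- function(copy_count, blocks, read_length) {
  structure(
    list(copy_count = as.integer(copy_count), blocks = blocks,
         read_length = as.integer(read_length)),
    class = "copy_call"
  )
}

#' @export
print.copy_call <- function(x, ...) {
  cat(sprintf("<copy_call> %d cop%s in a %d nt read\n",
              x$copy_count, if (x$copy_count == 1) "y" else "ies", x$read_length))
  if (nrow(x$blocks)) print(x$blocks)
  invisible(x)
}

#' Count query-gene copies across a set of reads
#'
#' Tibble-first wrapper around [call_copies()]: one row per read, with the
#' surviving blocks kept as a list column for downstream extraction.
#'
#' @param reads A data frame with `read_id` and `sequence` columns, or a
#'   (named) character vector of sequences.
#' @param query Query gene sequence, or a prebuilt [kmer_index()].
#' @inheritParams call_copies
#' @param k K-mer size used when `query` is a sequence.
#' @return A tibble: `read_id`, `read_length`, `n_blocks`, `copy_count`,
#'   `blocks` (list of block tibbles).
#' @export
count_copies <- function(reads, query, k = 19, gap_threshold = 800,
                         min_kmers = 5, min_query_coverage = 0.1) {
  reads <- as_reads_tbl(reads)
  index <- if (inherits(query, "kmer_index")) query else kmer_index(query, k)
  calls <- map(reads$sequence, call_copies, index = index,
               gap_threshold = gap_threshold, min_kmers = min_kmers,
               min_query_coverage = min_query_coverage)
  tibble(
    read_id = reads$read_id,
    read_length = nchar(reads$sequence),
    n_blocks = map_int(calls, ~ nrow(.x$blocks)),
    copy_count = map_int(calls, "copy_count"),
    blocks = map(calls, "blocks")
  )
}

# Compact "start-end(strand)" rendering of a blocks tibble, used in TSV
# reports.
format_blocks <- function(blocks) {
  if (nrow(blocks) == 0) return("")
  paste(sprintf("%d-%d(%s)", blocks$start, blocks$end, blocks$strand),
        collapse = ";")
}
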