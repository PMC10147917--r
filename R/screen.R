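#' Build an anchor pair from two flanking genes
#'
#' The duplicated region of icefish mitogenomes is enclosed by the 12S rRNA
#' and CYTB genes; a read informs the copy-number spectrum only when it
#' reaches both flanks. An `anchor_pair` simply bundles the two gene
#' sequences with their labels.
#'
#' @param left_name,right_name Gene labels (must differ).
#' @param left_seq,right_seq Gene sequences from the annotated reference.
#' @param k K-mer size the anchors will be used with (validation only).
#' @return An object of class `anchor_pair`.
#' @export
anchor_pair <- function(left_name, right_name, left_seq, right_seq, k = 19) {
  if (identical(left_name, right_name)) abort("anchor names must be distinct")
  if (nchar(left_seq) < k || nchar(right_seq) < k) {
    abort("anchor sequences must be at least k nt")
  }
  structure(
    list(left_name = left_name, right_name = right_name,
         left_seq = toupper(left_seq), right_seq = toupper(right_seq)),
    class = "anchor_pair"
  )
}

#' Screen reads for mitochondrial origin by matching-block length
#'
#' A read is called mitochondrial when its longest k-mer matching block
#' against the reference spans at least `min_block` nt. Requiring a long
#' block rejects NuMTs (nuclear insertions of mtDNA), which contribute only
#' short blocks. The reference is doubled head-to-tail before indexing so
#' reads crossing the circular origin form a single block; reported spans
#' never exceed the read.
#'
#' @param reads Data frame with `read_id`/`sequence`, or character vector.
#' @param reference Mitogenome sequence (single string).
#' @param k K-mer size.
#' @param gap_threshold Maximum within-block gap (nt) between successive
#'   matching k-mer starts.
#' @param min_block Minimum matching-block span (nt) to accept a read as
#'   mitochondrial. Published screens used 5000 nt (3000 nt for two
#'   samples with shorter reads).
#' @param circular Double the reference before indexing (default TRUE).
#' @return A tibble: `read_id`, `read_length`, `mt_block_span`, `is_mt`.
#' @export
screen_mt_reads <- function(reads, reference, k = 19, gap_threshold = 800,
                            min_block = 5000, circular = TRUE) {
  if (!is.character(reference) || length(reference) != 1 || nchar(reference) == 0) {
    abort("`reference` must be a non-empty DNA sequence")
  }
  if (min_block <= 0) abort("`min_block` must be > 0")
  reads <- as_reads_tbl(reads)
  ref <- if (circular) paste0(reference, reference) else reference
  index <- kmer_index(ref, k)
  span <- map_int(reads$sequence, function(s) {
    m <- scan_read(s, index)
    if (nrow(m) == 0) return(0L)
    b <- cluster_matches(m, gap_threshold)
    as.integer(max(b$end - b$start + 1L))
  })
  tibble(
    read_id = reads$read_id,
    read_length = nchar(reads$sequence),
    mt_block_span = span,
    is_mt = span >= min_block
  )
}

#' Does a read span both anchor genes?
#'
#' A read spans the anchor pair when each anchor query yields a passing
#' block whose matches extend over at least `min_anchor_span` of the gene:
#' the read must contain (essentially) the whole gene, not merely brush
#' it, so reads ending inside an anchor do not enter the spectrum.
#' Orientation is `+` when every passing block of both anchors lies on
#' the forward strand, `-` when all lie on the reverse strand, `mixed`
#' otherwise, and `na` when the read does not span.
#'
#' @param read A single DNA sequence.
#' @param anchors An [anchor_pair()].
#' @inheritParams call_copies
#' @param k K-mer size.
#' @param min_anchor_span Minimum fraction of the anchor gene that the
#'   matching block must extend over (block query span / gene length).
#' @return A list with elements `spans` (logical), `orientation`
#'   (`"+"`, `"-"`, `"mixed"` or `"na"`), and `between_lo`/`between_hi`:
#'   the read interval enclosed by the two anchor matches, within which
#'   gene copies are counted.
#' @export
spans_anchor_pair <- function(read, anchors, k = 19, gap_threshold = 800,
                              min_kmers = 5, min_query_coverage = 0.1,
                              min_anchor_span = 0.8) {
  stopifnot(inherits(anchors, "anchor_pair"))
  idx <- list(kmer_index(anchors$left_seq, k), kmer_index(anchors$right_seq, k))
  calls <- map(idx, ~ call_copies(read, .x, gap_threshold, min_kmers,
                                  min_query_coverage))
  spans_from_calls(calls[[1]], calls[[2]], min_anchor_span)
}

spans_from_calls <- function(left_call, right_call, min_anchor_span = 0.8) {
  lb <- left_call$blocks[left_call$blocks$query_span >= min_anchor_span, ]
  rb <- right_call$blocks[right_call$blocks$query_span >= min_anchor_span, ]
  if (nrow(lb) == 0 || nrow(rb) == 0) {
    return(list(spans = FALSE, orientation = "na",
                between_lo = NA_integer_, between_hi = NA_integer_))
  }
  st <- c(lb$strand, rb$strand)
  orientation <- if (all(st == "+")) "+" else if (all(st == "-")) "-" else "mixed"
  # read interval enclosed by the two anchors: from the end of the
  # best-supported block of the first-encountered anchor to the start of
  # the second's
  best <- function(b) b[which.max(b$n_kmers), ]
  b1 <- best(lb); b2 <- best(rb)
  if (b2$start < b1$start) { tmp <- b1; b1 <- b2; b2 <- tmp }
  list(spans = TRUE, orientation = orientation,
       between_lo = as.integer(b1$end), between_hi = as.integer(b2$start))
}

#' Screen reads for anchor spanning
#'
#' Vectorised [spans_anchor_pair()] over a read set.
#'
#' @inheritParams screen_mt_reads
#' @inheritParams spans_anchor_pair
#' @return A tibble: `read_id`, `spans_anchors`, `anchor_orientation`.
#' @export
screen_anchor_reads <- function(reads, anchors, k = 19, gap_threshold = 800,
                                min_kmers = 5, min_query_coverage = 0.1,
                                min_anchor_span = 0.8) {
  stopifnot(inherits(anchors, "anchor_pair"))
  reads <- as_reads_tbl(reads)
  idx_l <- kmer_index(anchors$left_seq, k)
  idx_r <- kmer_index(anchors$right_seq, k)
  res <- map(reads$sequence, function(s) {
    spans_from_calls(
      call_copies(s, idx_l, gap_threshold, min_kmers, min_query_coverage),
      call_copies(s, idx_r, gap_threshold, min_kmers, min_query_coverage),
      min_anchor_span
    )
  })
  tibble(
    read_id = reads$read_id,
    spans_anchors = map_lgl(res, "spans"),
    anchor_orientation = map_chr(res, "orientation"),
    between_lo = map_int(res, "between_lo"),
    between_hi = map_int(res, "between_hi")
  )
}
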