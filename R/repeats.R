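#' Find tandem repeats in a DNA sequence
#'
#' Detects tandem repeats by self-comparison at every candidate period
#' (lag): positions `i` and `i + d` are compared across the sequence, a
#' window of length `d` slides over the agreement profile, and maximal
#' regions whose windowed identity reaches `min_identity` are reported with
#' TRF-style fractional copy numbers (region length / period, one
#' decimal). Harmonic echoes of a repeat at multiples of its true period
#' are suppressed, but a genuinely nested secondary repeat — a shorter
#' period whose copies have diverged inside a near-perfect larger unit —
#' is kept alongside its container.
#'
#' Mitochondrial control regions commonly carry such repeats (periods tens
#' to hundreds of nt, fractional copy numbers), and their expansion is the
#' usual cause of control-region length variation.
#'
#' @param seq A single DNA sequence (e.g. a control region or a whole
#'   mitogenome).
#' @param min_period,max_period Candidate period range (nt).
#' @param min_copies Minimum fractional copy number to report. Windowed
#'   detection needs two full periods, so values below ~2.0 mark partial
#'   trailing copies rather than shorter arrays.
#' @param min_identity Minimum mean per-base agreement between adjacent
#'   period windows.
#' @param min_matches Minimum number of agreeing positions in the
#'   self-comparison; guards against chance agreements at short periods
#'   (a quarter of random positions agree by chance), in the spirit of
#'   TRF's minimum alignment score.
#' @return A tibble of class `tandem_repeats`: `start`, `end` (1-based
#'   inclusive), `period`, `copies`, `identity`, `consensus`.
#' @examples
#' motif <- random_dna(53)
#' find_tandem_repeats(strrep(motif, 5))
#' @export
find_tandem_repeats <- function(seq, min_period = 10, max_period = 400,
                                min_copies = 1.9, min_identity = 0.8,
                                min_matches = 25) {
  empty <- structure(
    tibble(start = integer(), end = integer(), period = integer(),
           copies = double(), identity = double(), consensus = character()),
    class = c("tandem_repeats", class(tibble())))
  if (!is.character(seq) || length(seq) != 1) abort("`seq` must be one sequence")
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0) return(empty)
  if (min_period < 1 || min_period > max_period) abort("invalid period range")
  s <- utf8ToInt(seq)

  cands <- list()
  for (d in min_period:min(max_period, floor(n / 2))) {
    eq <- s[1:(n - d)] == s[(d + 1):n]
    m <- n - 2 * d + 1          # number of full comparison windows
    if (m < 1) next
    cs <- c(0, cumsum(eq))
    ws <- (cs[(d + 1):(n - d + 1)] - cs[1:m]) / d
    pass <- ws >= min_identity
    if (!any(pass)) next
    regions <- pass_runs(pass, max_gap = d)
    for (r in regions) {
      # windows smear boundaries by up to ~d/4 into random flanks; refine to
      # the maximal-scoring stretch of position agreements (match +1,
      # mismatch -4: positive drift exactly when local identity > 0.8)
      lo <- max(1L, r[1] - d)
      hi <- min(length(eq), r[2] + 2L * d - 1L)
      seg <- eq[lo:hi]
      pref <- cumsum(ifelse(seg, 1, -4))
      floor_before <- cummin(c(0, pref[-length(pref)]))
      j <- which.max(pref - floor_before)
      if (pref[j] - floor_before[j] <= 0) next
      i0 <- which.min(c(0, pref)[1:j])  # prefix index before segment start
      start <- lo + i0 - 1L
      last_eq <- lo + j - 1L
      end <- last_eq + d
      trials <- last_eq - start + 1L
      matches <- sum(eq[start:last_eq])
      identity <- matches / trials
      copies <- round((end - start + 1) / d, 1)
      if (copies < min_copies || identity < min_identity || matches < min_matches) next
      cands[[length(cands) + 1]] <- tibble(
        start = as.integer(start), end = as.integer(end), period = d,
        copies = copies, identity = identity
      )
    }
  }
  if (length(cands) == 0) return(empty)
  cands <- distinct(bind_rows(cands))
  out <- suppress_harmonics(cands)
  out$consensus <- map_chr(seq_len(nrow(out)), function(i) {
    repeat_consensus(seq, out$start[i], out$end[i], out$period[i])
  })
  out <- arrange(out, .data$start, .data$period)
  structure(out, class = c("tandem_repeats", class(out)))
}

# Runs of TRUE in `pass`, merging runs separated by gaps <= max_gap.
# Returns a list of c(first, last) index pairs.
pass_runs <- function(pass, max_gap) {
  idx <- which(pass)
  if (length(idx) == 0) return(list())
  brk <- which(diff(idx) > max_gap)
  starts <- idx[c(1, brk + 1)]
  ends <- idx[c(brk, length(idx))]
  map2(starts, ends, c)
}

# Drop harmonic echoes: for two repeats occupying essentially the same
# interval with periods p < q = m * p, the q-repeat is redundant unless its
# identity clearly exceeds the p-repeat's (then the q-unit is a genuine
# higher-order repeat containing diverged sub-repeats, and both levels are
# reported).
suppress_harmonics <- function(cands, epsilon = 0.05) {
  cands <- arrange(cands, .data$period)
  drop <- rep(FALSE, nrow(cands))
  for (i in seq_len(nrow(cands))) {
    for (j in seq_len(nrow(cands))) {
      if (i == j || drop[i] || drop[j]) next
      p <- cands$period[i]; q <- cands$period[j]
      if (q <= p || q %% p != 0) next
      ov <- min(cands$end[i], cands$end[j]) - max(cands$start[i], cands$start[j]) + 1
      shorter <- min(cands$end[i] - cands$start[i], cands$end[j] - cands$start[j]) + 1
      if (ov < 0.9 * shorter) next
      if (cands$identity[i] >= cands$identity[j] - epsilon) drop[j] <- TRUE
    }
  }
  cands[!drop, ]
}

# Column-majority consensus over the period-phased windows of the repeat
# region; returns a string of length `period`.
repeat_consensus <- function(seq, start, end, period) {
  region <- substr(seq, start, end)
  full <- floor(nchar(region) / period)
  if (full < 1) return(substr(region, 1, period))
  chars <- strsplit(substr(region, 1, full * period), "")[[1]]
  mat <- matrix(chars, nrow = period)
  paste(apply(mat, 1, function(col) names(which.max(table(col)))), collapse = "")
}
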