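#' Decompose a target sequence into reference gene blocks
#'
#' Locates every copy of every reference gene in a target mitogenome
#' (assembly or long read) by k-mer block matching, yielding an ordered,
#' stranded block list — the input to rearrangement classification.
#' Circular targets are rotated so the block of `anchor_gene` (trnF by
#' default, the gene conventionally written first) starts near position 1,
#' and the rotated sequence is scanned doubled so nothing is lost at the
#' join.
#'
#' @param target Target DNA sequence (single string).
#' @param genes Named character vector of reference gene sequences, or a
#'   data frame with `gene` and `sequence` columns.
#' @inheritParams call_copies
#' @param k K-mer size; must not exceed the shortest gene (~66 nt tRNAs
#'   allow k up to 31).
#' @param circular Treat the target as circular.
#' @param anchor_gene Gene whose block is rotated to the start of circular
#'   targets.
#' @return An object of class `block_decomposition`: list with `blocks`
#'   (tibble `gene`, `start`, `end`, `strand`, `n_kmers`,
#'   `query_coverage`, sorted by `start`), `target_length`, `circular`,
#'   `rotation` (offset applied, nt).
#' @export
decompose <- function(target, genes, k = 19, gap_threshold = 800,
                      min_kmers = 5, min_query_coverage = 0.1,
                      circular = TRUE, anchor_gene = "trnF") {
  genes <- as_gene_set(genes)
  short <- nchar(genes) < k
  if (any(short)) {
    abort(sprintf("reference genes shorter than k = %d: %s", k,
                  paste(names(genes)[short], collapse = ", ")))
  }
  target <- toupper(target)
  L <- nchar(target)
  rotation <- 0L

  if (circular && anchor_gene %in% names(genes)) {
    idx <- kmer_index(genes[[anchor_gene]], k)
    cc <- call_copies(paste0(target, target), idx, gap_threshold,
                      min_kmers, min_query_coverage)
    hits <- cc$blocks$start[cc$blocks$start <= L]
    if (length(hits)) {
      rotation <- min(hits) - 1L
      if (rotation > 0) {
        target <- paste0(substr(target, rotation + 1L, L),
                         substr(target, 1L, rotation))
      }
    }
  }

  scan_target <- if (circular) paste0(target, target) else target
  blocks <- map(names(genes), function(g) {
    idx <- kmer_index(genes[[g]], k)
    cc <- call_copies(scan_target, idx, gap_threshold, min_kmers,
                      min_query_coverage)
    b <- cc$blocks
    if (circular) b <- b[b$start <= L, , drop = FALSE]
    if (nrow(b)) b$gene <- g
    b
  }) |>
    bind_rows()

  if (nrow(blocks) == 0) {
    warn("decomposition empty: no reference gene located in target")
    blocks <- tibble(gene = character(), start = integer(), end = integer(),
                     strand = character(), n_kmers = integer(),
                     query_coverage = double())
  } else {
    blocks <- blocks |>
      select("gene", "start", "end", "strand", "n_kmers", "query_coverage") |>
      arrange(.data$start, .data$end) |>
      collapse_overlaps()
  }

  structure(
    list(blocks = blocks, target_length = L, circular = circular,
         rotation = rotation),
    class = "block_decomposition"
  )
}

as_gene_set <- function(genes) {
  if (is.data.frame(genes)) {
    stopifnot(all(c("gene", "sequence") %in% names(genes)))
    return(setNames(toupper(genes$sequence), genes$gene))
  }
  if (is.character(genes) && !is.null(names(genes))) return(toupper(genes))
  abort("`genes` must be a named character vector or a gene/sequence data frame")
}

# Competing calls over the same span collapse to the higher-coverage one;
# a tRNA nested in an rRNA/long-gene margin is allowed to overlap.
collapse_overlaps <- function(blocks) {
  n <- nrow(blocks)
  if (n < 2) return(blocks)
  is_trna <- grepl("^trn", blocks$gene)
  drop <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (drop[i] || drop[j]) next
      ov <- min(blocks$end[i], blocks$end[j]) - max(blocks$start[i], blocks$start[j]) + 1
      if (ov <= 0) next
      shorter <- min(blocks$end[i] - blocks$start[i], blocks$end[j] - blocks$start[j]) + 1
      if (ov <= 0.5 * shorter) next
      if (is_trna[i] != is_trna[j]) next  # nested annotation, keep both
      loser <- if (blocks$query_coverage[i] >= blocks$query_coverage[j]) j else i
      drop[loser] <- TRUE
    }
  }
  blocks[!drop, , drop = FALSE]
}

#' @export
print.block_decomposition <- function(x, ...) {
  cat(sprintf("<block_decomposition> %d blocks on a %d nt %s target\n",
              nrow(x$blocks), x$target_length,
              if (x$circular) "circular" else "linear"))
  print(architecture_string(x))
  invisible(x)
}

#' Render a decomposition as a compact architecture string
#'
#' Tandem-duplicated runs are compressed as `(unit)xN`, minus-strand
#' blocks are prefixed `-`. Useful for diffing architectures in tests and
#' reports.
#'
#' @param decomposition A [decompose()] result.
#' @param canonical_order Gene order used for event detection.
#' @return A single character string.
#' @export
architecture_string <- function(decomposition, canonical_order = mito_gene_order()) {
  b <- decomposition$blocks
  if (nrow(b) == 0) return("")
  lab <- ifelse(b$strand == "-", paste0("-", b$gene), b$gene)
  ev <- classify_events(decomposition, canonical_order)
  dups <- ev[ev$type == "tandem_duplication", , drop = FALSE]
  if (nrow(dups)) {
    dups <- dups[order(-dups$first_block), , drop = FALSE]
    for (i in seq_len(nrow(dups))) {
      u <- dups$unit[[i]]
      a <- dups$first_block[i]
      span <- length(u) * dups$n_copies[i]
      lab <- append(
        lab[-(a:(a + span - 1))],
        sprintf("(%s)x%d", paste(u, collapse = " "), dups$n_copies[i]),
        after = a - 1
      )
    }
  }
  paste(lab, collapse = " ")
}

#' Classify rearrangement events from a block decomposition
#'
#' Works on the ordered gene-label string (robust to sequence divergence):
#' \itemize{
#'   \item \strong{tandem_duplication}: a maximal gene subsequence repeated
#'     two or more times consecutively; the unit is the shortest repeating
#'     string of labels.
#'   \item \strong{remnant_block}: immediately adjacent to a duplication of
#'     unit U, a consecutive proper suffix of U (the 5' genes of the unit
#'     were lost); the missing prefix is named in `evidence`.
#'   \item \strong{inversion}: a maximal run of two or more consecutive
#'     minus-strand blocks whose label order is reversed relative to the
#'     canonical order; `span` is the block extent in target coordinates.
#' }
#' Circular decompositions are classified on the doubled label sequence,
#' so the result is invariant under rotation.
#'
#' @param decomposition A [decompose()] result.
#' @param canonical_order Character vector giving the canonical gene order.
#' @return A tibble of events: `type`, `unit` (list column of gene
#'   labels), `n_copies`, `span`, `first_block`, `evidence`.
#' @export
classify_events <- function(decomposition, canonical_order = mito_gene_order()) {
  b <- decomposition$blocks
  empty <- tibble(type = character(), unit = list(), n_copies = integer(),
                  span = integer(), first_block = integer(),
                  evidence = character())
  n <- nrow(b)
  if (n == 0) return(empty)
  labels <- b$gene
  strands <- b$strand

  dups <- find_tandem_dups(labels, decomposition$circular, canonical_order)
  events <- list()
  for (d in dups) {
    first <- ((d$start - 1L) %% n) + 1L
    idx <- ((seq(d$start, d$start + d$u * d$r - 1L) - 1L) %% n) + 1L
    events[[length(events) + 1]] <- tibble(
      type = "tandem_duplication",
      unit = list(labels[((seq(d$start, d$start + d$u - 1L) - 1L) %% n) + 1L]),
      n_copies = d$r,
      span = span_of(b, idx, decomposition),
      first_block = first,
      evidence = sprintf("%d consecutive copies of a %d-gene unit", d$r, d$u)
    )
    rem <- find_remnant(labels, d, n)
    if (!is.null(rem)) {
      events[[length(events) + 1]] <- tibble(
        type = "remnant_block",
        unit = list(rem$suffix),
        n_copies = 1L,
        span = span_of(b, rem$idx, decomposition),
        first_block = rem$idx[1],
        evidence = sprintf("suffix of duplicated unit; missing prefix: %s",
                           paste(rem$missing, collapse = ","))
      )
    }
  }

  for (run in minus_runs(strands, decomposition$circular)) {
    idx <- ((run - 1L) %% n) + 1L
    if (length(idx) < 2) next
    if (!is_reversed_order(labels[idx], canonical_order)) next
    events[[length(events) + 1]] <- tibble(
      type = "inversion",
      unit = list(labels[idx]),
      n_copies = NA_integer_,
      span = span_of(b, idx, decomposition),
      first_block = idx[1],
      evidence = sprintf("%d consecutive minus-strand blocks in reversed order",
                         length(idx))
    )
  }

  if (length(events) == 0) return(empty)
  out <- bind_rows(events) |> distinct(.data$type, .data$first_block, .keep_all = TRUE)
  arrange(out, .data$first_block)
}

# Target-coordinate extent of a set of block indices (circular-safe: if the
# set wraps, measure on the unwrapped doubled coordinates).
span_of <- function(b, idx, decomposition) {
  starts <- b$start[idx]
  ends <- b$end[idx]
  if (decomposition$circular && (max(starts) - min(starts)) > decomposition$target_length / 2 &&
      any(diff(sort(starts)) > decomposition$target_length / 2)) {
    L <- decomposition$target_length
    wrap <- starts < L / 2
    starts[wrap] <- starts[wrap] + L
    ends[wrap] <- ends[wrap] + L
  }
  as.integer(max(ends) - min(starts) + 1L)
}

# All maximal tandem repeats of the label sequence: list of
# (start, u = unit length, r = copies). Operates on the doubled sequence
# for circular inputs; keeps left-maximal, non-contained, canonical-phase
# events with primitive units.
find_tandem_dups <- function(labels, circular, canonical_order) {
  n <- length(labels)
  lab <- if (circular) c(labels, labels) else labels
  found <- list()
  for (u in seq_len(floor(n / 2))) {
    for (i in seq_len(n)) {
      unit <- lab[i:(i + u - 1)]
      if (any(is.na(unit))) next
      if (!is_primitive(unit)) next
      # left-maximality
      if (i - u >= 1 && identical(lab[(i - u):(i - 1)], unit)) next
      if (circular && identical(lab[((i - u - 1) %% (2 * n)) + seq_len(u)], unit) && i - u < 1) next
      r <- 1L
      while (i + (r + 1) * u - 1 <= length(lab) &&
             (r + 1) * u <= n &&
             identical(lab[(i + r * u):(i + (r + 1) * u - 1)], unit)) {
        r <- r + 1L
      }
      if (r >= 2) found[[length(found) + 1]] <- list(start = i, u = u, r = r)
    }
  }
  if (length(found) == 0) return(list())
  # drop events contained in a longer event's span
  spans <- map(found, function(d) c(d$start, d$start + d$u * d$r - 1L))
  len <- map_dbl(spans, ~ .x[2] - .x[1] + 1)
  ord <- order(-len)
  kept <- list()
  kept_spans <- list()
  for (o in ord) {
    s <- spans[[o]]
    contained <- any(map_lgl(kept_spans, ~ s[1] >= .x[1] && s[2] <= .x[2] &&
                               (s[2] - s[1]) < (.x[2] - .x[1])))
    if (!contained) {
      kept[[length(kept) + 1]] <- found[[o]]
      kept_spans[[length(kept_spans) + 1]] <- s
    }
  }
  # among rotation-phase duplicates over overlapping spans, prefer the unit
  # that is a contiguous run of the canonical order, then the leftmost
  drop <- rep(FALSE, length(kept))
  for (a in seq_along(kept)) {
    for (b2 in seq_along(kept)) {
      if (a == b2 || drop[a] || drop[b2]) next
      da <- kept[[a]]; db <- kept[[b2]]
      if (da$u != db$u) next
      ua <- lab[da$start:(da$start + da$u - 1)]
      ub <- lab[db$start:(db$start + db$u - 1)]
      if (!is_rotation(ua, ub)) next
      sa <- kept_spans[[a]]; sb <- kept_spans[[b2]]
      if (min(sa[2], sb[2]) - max(sa[1], sb[1]) + 1 < da$u) next
      ca <- is_canonical_run(ua, canonical_order)
      cb <- is_canonical_run(ub, canonical_order)
      loser <- if (ca && !cb) b2 else if (cb && !ca) a else if (sa[1] <= sb[1]) b2 else a
      drop[loser] <- TRUE
    }
  }
  kept <- kept[!drop]
  # dedupe circular images (same start modulo n)
  seen <- character(0)
  out <- list()
  for (d in kept) {
    key <- sprintf("%d:%d:%d", ((d$start - 1L) %% n) + 1L, d$u, d$r)
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- d
  }
  out
}

is_primitive <- function(unit) {
  u <- length(unit)
  if (u == 1) return(TRUE)
  for (p in seq_len(u - 1)) {
    if (u %% p == 0 && identical(unit, rep(unit[1:p], u / p))) return(FALSE)
  }
  TRUE
}

is_rotation <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  paste(b, collapse = "\r") %in%
    map_chr(seq_along(a), ~ paste(c(a[.x:length(a)], a[seq_len(.x - 1)]), collapse = "\r"))
}

is_canonical_run <- function(unit, canonical_order) {
  m <- length(canonical_order)
  cyc <- c(canonical_order, canonical_order)
  hit <- which(cyc == unit[1])
  any(map_lgl(hit, function(h) {
    h + length(unit) - 1 <= length(cyc) &&
      identical(cyc[h:(h + length(unit) - 1)], unit)
  }))
}

# Adjacent remnant: a proper suffix of the duplication unit immediately
# before (or after) the run. Returns suffix labels, missing prefix and the
# label indices, or NULL.
find_remnant <- function(labels, d, n) {
  lab <- c(labels, labels, labels)  # generous circular padding
  offset <- n                       # work in the middle copy
  start <- d$start + offset
  end <- d$start + d$u * d$r - 1L + offset
  unit <- lab[start:(start + d$u - 1)]
  for (s in (d$u - 1):1) {
    suffix <- unit[(d$u - s + 1):d$u]
    before <- (start - s):(start - 1)
    if (all(before >= 1) && identical(lab[before], suffix)) {
      return(list(suffix = suffix,
                  missing = unit[1:(d$u - s)],
                  idx = ((before - 1L) %% n) + 1L))
    }
    after <- (end + 1):(end + s)
    if (all(after <= length(lab)) && identical(lab[after], suffix)) {
      return(list(suffix = suffix,
                  missing = unit[1:(d$u - s)],
                  idx = ((after - 1L) %% n) + 1L))
    }
  }
  NULL
}

# Maximal runs (index vectors) of minus-strand blocks; on circular inputs
# runs may wrap (indices beyond n refer modulo n).
minus_runs <- function(strands, circular) {
  n <- length(strands)
  s <- if (circular) c(strands, strands) else strands
  runs <- list()
  i <- 1
  limit <- length(s)
  while (i <= limit) {
    if (s[i] == "-") {
      j <- i
      while (j < limit && s[j + 1] == "-") j <- j + 1
      if (i <= n && (j - i + 1) <= n) runs[[length(runs) + 1]] <- i:j
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (circular && length(runs) > 1) {
    # drop duplicated images of the same run
    keys <- map_chr(runs, ~ paste(sort(((.x - 1) %% n) + 1), collapse = ","))
    runs <- runs[!duplicated(keys)]
  }
  runs
}

# TRUE when the reversed run of labels appears in canonical relative order.
is_reversed_order <- function(run_labels, canonical_order) {
  pos <- match(rev(run_labels), canonical_order)
  if (anyNA(pos)) return(FALSE)
  all(diff(pos) > 0) || all(diff(pos %% length(canonical_order)) > 0)
}
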