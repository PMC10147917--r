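#' Build a copy-number spectrum from per-read copy calls
#'
#' Tabulates copy counts over the reads that span the anchor pair. The
#' spectrum is the heteroplasmy evidence: a multimodal spectrum means reads
#' drawn from structurally different mitogenome variants coexist in one
#' individual. Reads with a copy count of 0 are kept as class 0 — complete
#' loss of the focal gene from a variant is biologically real.
#'
#' @param calls A data frame of per-read calls with `read_id` and
#'   `copy_count` (e.g. from [count_copies()]).
#' @param spanning_ids Optional character vector of anchor-spanning read
#'   ids; calls are restricted to these, and `n_spanning` records their
#'   number.
#' @param sample Sample label carried into reports.
#' @return A `copy_spectrum`: a tibble with `copy_number` and `n_reads`
#'   (zero-read classes omitted), with attributes `n_spanning` and
#'   `sample`.
#' @examples
#' build_spectrum(tibble::tibble(read_id = letters[1:4], copy_count = c(1, 3, 3, 4)))
#' @export
build_spectrum <- function(calls, spanning_ids = NULL, sample = NA_character_) {
  stopifnot(all(c("read_id", "copy_count") %in% names(calls)))
  calls <- as_tibble(calls)
  if (!is.null(spanning_ids)) {
    calls <- filter(calls, .data$read_id %in% spanning_ids)
    n_spanning <- length(unique(spanning_ids))
  } else {
    n_spanning <- nrow(calls)
  }
  spec <- calls |>
    count(copy_number = as.integer(.data$copy_count), name = "n_reads") |>
    arrange(.data$copy_number)
  structure(spec, class = c("copy_spectrum", class(spec)),
            n_spanning = n_spanning, sample = sample)
}

#' @export
print.copy_spectrum <- function(x, ...) {
  cat(sprintf("<copy_spectrum> %s: %d spanning reads\n",
              attr(x, "sample") %||% "sample", attr(x, "n_spanning")))
  NextMethod()
}

#' Call heteroplasmy from a copy-number spectrum
#'
#' The individual is called heteroplasmic when at least two copy-number
#' classes with at least one gene copy are each supported by `min_support`
#' reads. Classes below the support threshold are still reported, flagged
#' `singleton`, since a single well-anchored read can represent a rare
#' variant. Class 0 is reported but flagged `excluded` and never drives
#' the verdict: spanning reads that traversed the far side of the circle
#' between the anchors legitimately contain no focal-gene copy, so a
#' 0-class is not by itself variant evidence (complete loss of the gene
#' from a variant is instead visible in the architecture module).
#'
#' @param spectrum A [build_spectrum()] result (or a tibble with
#'   `copy_number` and `n_reads`).
#' @param min_support Reads required for a class to count towards the
#'   verdict.
#' @return A `heteroplasmy_call`: list with `is_heteroplasmic`, `classes`
#'   (tibble with a `flag` column), `min_support`, `n_spanning`, `sample`.
#' @export
call_heteroplasmy <- function(spectrum, min_support = 2) {
  if (min_support < 1) abort("`min_support` must be >= 1")
  classes <- as_tibble(spectrum[, c("copy_number", "n_reads")]) |>
    mutate(flag = dplyr::case_when(
      .data$copy_number == 0 ~ "excluded",
      .data$n_reads >= min_support ~ "confident",
      TRUE ~ "singleton"
    ))
  structure(
    list(
      is_heteroplasmic = sum(classes$flag == "confident") >= 2,
      classes = classes,
      min_support = min_support,
      n_spanning = attr(spectrum, "n_spanning") %||% sum(classes$n_reads),
      sample = attr(spectrum, "sample") %||% NA_character_
    ),
    class = "heteroplasmy_call"
  )
}

#' @export
print.heteroplasmy_call <- function(x, ...) {
  verdict <- if (x$is_heteroplasmic) "HETEROPLASMIC" else "not heteroplasmic"
  cat(sprintf("<heteroplasmy_call> %s (min_support = %d)\n", verdict, x$min_support))
  print(x$classes)
  invisible(x)
}

#' Partition reads by copy-number class
#'
#' Groups read identifiers by their copy count so each class can be
#' exported (see [export_partition()]) and assembled independently — the
#' route to per-variant mitogenome assemblies.
#'
#' @inheritParams build_spectrum
#' @return A tibble: `copy_number`, `n_reads`, `read_ids` (list column).
#'   Every called read appears in exactly one class.
#' @export
partition_reads <- function(calls) {
  stopifnot(all(c("read_id", "copy_count") %in% names(calls)))
  as_tibble(calls) |>
    group_by(copy_number = as.integer(.data$copy_count)) |>
    summarise(n_reads = n(), read_ids = list(.data$read_id)) |>
    arrange(.data$copy_number)
}

#' Write per-class FASTA files for a read partition
#'
#' @param partition A [partition_reads()] result.
#' @param reads The read set the partition was computed from.
#' @param dir Output directory (created if missing).
#' @param sample Sample label used in file names
#'   (`<sample>.copies<k>.fasta`).
#' @return Invisibly, the written file paths.
#' @export
export_partition <- function(partition, reads, dir, sample = "sample") {
  reads <- as_reads_tbl(reads)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- pmap(partition, function(copy_number, n_reads, read_ids) {
    path <- file.path(dir, sprintf("%s.copies%d.fasta", sample, copy_number))
    sel <- filter(reads, .data$read_id %in% read_ids)
    write_fasta(sel, path)
    path
  })
  invisible(unlist(paths))
}
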