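#' Tidy a copy-number spectrum
#'
#' @param x A `copy_spectrum`.
#' @param ... Unused.
#' @return A tibble with `copy_number`, `n_reads`, `proportion`.
#' @exportS3Method generics::tidy
#' @export
tidy.copy_spectrum <- function(x, ...) {
  as_tibble(x) |>
    mutate(proportion = .data$n_reads / sum(.data$n_reads))
}

#' @rdname tidy.copy_spectrum
#' @return For `glance()`: a one-row tibble with `n_spanning`,
#'   `n_classes`, `modal_class`, `sample`.
#' @exportS3Method generics::glance
#' @export
glance.copy_spectrum <- function(x, ...) {
  tibble(
    n_spanning = attr(x, "n_spanning"),
    n_classes = nrow(x),
    modal_class = if (nrow(x)) x$copy_number[which.max(x$n_reads)] else NA_integer_,
    sample = attr(x, "sample") %||% NA_character_
  )
}

#' Tidy a heteroplasmy call
#'
#' @param x A `heteroplasmy_call`.
#' @param ... Unused.
#' @return Per-class tibble with support flags.
#' @exportS3Method generics::tidy
#' @export
tidy.heteroplasmy_call <- function(x, ...) x$classes

#' @rdname tidy.heteroplasmy_call
#' @return For `glance()`: a one-row verdict tibble.
#' @exportS3Method generics::glance
#' @export
glance.heteroplasmy_call <- function(x, ...) {
  tibble(
    is_heteroplasmic = x$is_heteroplasmic,
    n_classes = nrow(x$classes),
    n_confident = sum(x$classes$flag == "confident"),
    min_support = x$min_support,
    n_spanning = x$n_spanning,
    sample = x$sample
  )
}

#' Tidy a block decomposition
#'
#' @param x A `block_decomposition`.
#' @param ... Unused.
#' @return The block tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.block_decomposition <- function(x, ...) x$blocks

#' @rdname tidy.block_decomposition
#' @exportS3Method generics::glance
#' @export
glance.block_decomposition <- function(x, ...) {
  tibble(
    n_blocks = nrow(x$blocks),
    n_genes = length(unique(x$blocks$gene)),
    target_length = x$target_length,
    circular = x$circular
  )
}
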