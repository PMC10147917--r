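#' Canonical mitochondrial gene table
#'
#' Gene labels and vertebrate-typical lengths used by the genome
#' generator. The duplication-prone unit (ND6, trnE, trnP and the control
#' region) sits after trnT, matching the single-copy layout of the
#' notothenioid mitogenomes the generator emulates. ND6 is 528 nt
#' (175 codons plus stop).
#'
#' @return A tibble with `gene` and `length` in canonical order.
#' @export
mito_genes <- function() {
  tibble(
    gene = c("trnF", "12S", "trnV", "16S", "trnL1", "ND1", "trnI", "trnQ",
             "trnM", "ND2", "trnW", "trnA", "trnN", "trnC", "trnY", "COX1",
             "trnS1", "trnD", "COX2", "trnK", "ATP8", "ATP6", "COX3", "trnG",
             "ND3", "trnR", "ND4L", "ND4", "trnH", "trnS2", "trnL2", "ND5",
             "CYTB", "trnT", "ND6", "trnE", "trnP", "CR"),
    length = c(69L, 950L, 72L, 1700L, 74L, 975L, 71L, 71L,
               69L, 1046L, 71L, 69L, 73L, 66L, 70L, 1551L,
               71L, 68L, 691L, 74L, 168L, 683L, 785L, 68L,
               349L, 69L, 297L, 1381L, 69L, 67L, 73L, 1839L,
               1141L, 72L, 528L, 69L, 70L, 1000L)
  )
}

#' Canonical gene order
#'
#' @return Character vector of gene labels in canonical order.
#' @export
mito_gene_order <- function() mito_genes()$gene

#' Declare a synthetic mitogenome architecture
#'
#' A genome plan captures the structural-variant grammar seen in icefish
#' mitogenomes: a tandemly repeated ND6/trnE/trnP/CR unit in 1 or more
#' copies, frameshift insertions in chosen copies, an optional remnant
#' suffix of the unit (partial duplicate whose 5' genes were lost), an
#' optional control-region tandem repeat, and an optional inversion of a
#' contiguous gene span. Gene bodies and spacers are seeded random DNA:
#' plans sharing a `seed` share gene sequences, so they model structural
#' variants of one individual's mitogenome.
#'
#' @param n_copies Number of tandem copies of `dup_unit` (>= 1).
#' @param dup_unit Gene labels of the duplicated unit, placed after trnT.
#' @param truncations Optional tibble/data frame with `copy`, `offset`,
#'   `bases`: insert `bases` into the first gene of `dup_unit` in the given
#'   copy at `offset` (models the published 1/3/4-base frameshift
#'   insertions).
#' @param remnant Optional proper suffix of `dup_unit` (e.g.
#'   `c("trnP", "CR")`) placed between trnT and the full copies.
#' @param cr_repeat Optional `c(period, copies)`: embed a tandem repeat of
#'   that geometry in every control-region copy.
#' @param inversion Optional `c(from, to)` gene labels: reverse-complement
#'   the span from the start of `from` to the end of `to` in place. Must
#'   not partially overlap a duplicated unit copy.
#' @param gene_lengths Named integer vector overriding default gene
#'   lengths (e.g. `c(CR = 2651)`).
#' @param spacer_range Intergenic spacer length range (nt), drawn
#'   uniformly per junction.
#' @param cassette_spacer Spacer (nt) between trnT and the duplicated
#'   region (observed 177-304 nt in icefishes).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @param label Variant label used in pools and reports.
#' @return An object of class `genome_plan`.
#' @export
genome_plan <- function(n_copies = 1,
                        dup_unit = c("ND6", "trnE", "trnP", "CR"),
                        truncations = NULL,
                        remnant = NULL,
                        cr_repeat = NULL,
                        inversion = NULL,
                        gene_lengths = NULL,
                        spacer_range = c(5, 40),
                        cassette_spacer = 250,
                        seed = 1,
                        label = NULL) {
  if (n_copies < 1) abort("`n_copies` must be >= 1")
  if (!is.null(truncations)) {
    truncations <- as_tibble(truncations)
    stopifnot(all(c("copy", "offset", "bases") %in% names(truncations)))
    if (any(truncations$copy > n_copies)) abort("truncation copy index exceeds n_copies")
  }
  if (!is.null(remnant)) {
    nu <- length(dup_unit)
    if (length(remnant) >= nu ||
        !identical(unname(remnant), dup_unit[(nu - length(remnant) + 1):nu])) {
      abort("`remnant` must be a proper suffix of `dup_unit`")
    }
  }
  if (!is.null(cr_repeat)) {
    if (length(cr_repeat) != 2 || cr_repeat[2] < 1) abort("invalid `cr_repeat`")
  }
  structure(
    list(n_copies = as.integer(n_copies), dup_unit = dup_unit,
         truncations = truncations, remnant = remnant,
         cr_repeat = cr_repeat, inversion = inversion,
         gene_lengths = gene_lengths, spacer_range = spacer_range,
         cassette_spacer = cassette_spacer, seed = as.integer(seed),
         label = label %||% sprintf("copies%d", n_copies)),
    class = "genome_plan"
  )
}

#' @export
print.genome_plan <- function(x, ...) {
  cat(sprintf("<genome_plan> %s: (%s) x %d", x$label,
              paste(x$dup_unit, collapse = " "), x$n_copies))
  if (!is.null(x$remnant)) cat(sprintf(" + remnant [%s]", paste(x$remnant, collapse = " ")))
  if (!is.null(x$cr_repeat)) cat(sprintf(" + CR repeat %g x %g", x$cr_repeat[1], x$cr_repeat[2]))
  if (!is.null(x$inversion)) cat(sprintf(" + inversion %s..%s", x$inversion[1], x$inversion[2]))
  cat(sprintf(", seed %d\n", x$seed))
  invisible(x)
}

#' Reference gene sequences of a genome plan
#'
#' The seeded gene set a plan's genome is built from; the natural query
#' set for [decompose()] and [count_copies()] against genomes or reads
#' generated from the same seed.
#'
#' @param plan A [genome_plan()].
#' @return Named character vector of gene sequences in canonical order.
#' @export
plan_genes <- function(plan) plan_gene_seqs(plan)

# Seeded gene sequences shared by all plans with the same seed. The control
# region is generated at the (possibly repeat-extended) length.
plan_gene_seqs <- function(plan) {
  lens <- setNames(mito_genes()$length, mito_genes()$gene)
  if (!is.null(plan$gene_lengths)) {
    lens[names(plan$gene_lengths)] <- plan$gene_lengths
  }
  seqs <- with_seed(child_seed(plan$seed, 1L), {
    setNames(map_chr(lens, random_dna), names(lens))
  })
  if (!is.null(plan$cr_repeat)) {
    period <- as.integer(plan$cr_repeat[1])
    copies <- plan$cr_repeat[2]
    arr_len <- round(period * copies)
    motif <- with_seed(child_seed(plan$seed, 2L), random_dna(period))
    array <- substr(strrep(motif, ceiling(copies)), 1, arr_len)
    cr_len <- max(unname(lens["CR"]), arr_len + 200L)
    base <- if (nchar(seqs[["CR"]]) >= cr_len) {
      substr(seqs[["CR"]], 1, cr_len)
    } else {
      paste0(seqs[["CR"]],
             with_seed(child_seed(plan$seed, 3L), random_dna(cr_len - nchar(seqs[["CR"]]))))
    }
    flank <- cr_len - arr_len
    left <- floor(flank / 2)
    seqs[["CR"]] <- paste0(substr(base, 1, left), array,
                           substr(base, left + arr_len + 1, cr_len))
  }
  seqs
}

#' Realise a genome plan as a circular sequence with annotation
#'
#' Deterministic given the plan's seed. The annotation records every gene
#' copy with 1-based inclusive coordinates and strand; an inversion
#' reverse-complements its span in place (minus-strand annotation rows).
#'
#' @param plan A [genome_plan()].
#' @return An object of class `mito_genome`: list with `sequence`,
#'   `annotation` (tibble `gene`, `start`, `end`, `strand`, `copy`),
#'   `length`, `label`, `plan`.
#' @export
make_genome <- function(plan) {
  stopifnot(inherits(plan, "genome_plan"))
  seqs <- plan_gene_seqs(plan)
  order_base <- setdiff(mito_gene_order(), plan$dup_unit)
  unit_first <- plan$dup_unit[1]

  # ordered genome elements: genes and spacers, unit copies grouped
  elements <- list()
  push <- function(type, label, seq, group = NA_integer_) {
    elements[[length(elements) + 1]] <<- list(type = type,
                                              label = as.character(label),
                                              seq = seq,
                                              group = as.integer(group))
  }
  spacers <- with_seed(child_seed(plan$seed, 4L), {
    # more draws than junctions we will ever need
    n_junc <- length(order_base) + (plan$n_copies + 1) * (length(plan$dup_unit) + 1) + 10
    map_chr(sample(plan$spacer_range[1]:plan$spacer_range[2], n_junc, replace = TRUE),
            random_dna)
  })
  sp_i <- 0L
  next_spacer <- function() {
    sp_i <<- sp_i + 1L
    spacers[[sp_i]]
  }

  unit_seq <- function(copy) {
    out <- setNames(seqs[plan$dup_unit], plan$dup_unit)
    tr <- plan$truncations
    if (!is.null(tr) && copy %in% tr$copy) {
      r <- tr[tr$copy == copy, ][1, ]
      g <- unit_first
      s <- out[[g]]
      out[[g]] <- paste0(substr(s, 1, r$offset), r$bases,
                         substr(s, r$offset + 1, nchar(s)))
    }
    out
  }

  group_id <- 0L
  for (g in order_base) {
    push("gene", g, seqs[[g]])
    if (g == "trnT") {
      push("spacer", NA, random_dna_seeded(plan, 5L, plan$cassette_spacer))
      if (!is.null(plan$remnant)) {
        group_id <- group_id + 1L
        for (rg in plan$remnant) {
          push("gene", rg, seqs[[rg]], group = group_id)
          push("spacer", NA, next_spacer(), group = group_id)
        }
      }
      for (cp in seq_len(plan$n_copies)) {
        group_id <- group_id + 1L
        us <- unit_seq(cp)
        for (ug in plan$dup_unit) {
          push("gene", ug, us[[ug]], group = group_id)
          push("spacer", NA, next_spacer(), group = group_id)
        }
      }
    } else {
      push("spacer", NA, next_spacer())
    }
  }

  el <- tibble(
    type = map_chr(elements, "type"),
    label = map_chr(elements, "label"),
    seq = map_chr(elements, "seq"),
    group = map_int(elements, "group"),
    strand = "+"
  )

  if (!is.null(plan$inversion)) {
    from <- which(el$type == "gene" & el$label == plan$inversion[1])
    to <- which(el$type == "gene" & el$label == plan$inversion[2])
    if (length(from) == 0 || length(to) == 0) abort("inversion gene not found")
    i1 <- min(from); i2 <- max(to)
    if (i2 < i1) abort("inversion span is empty")
    inside <- seq(i1, i2)
    grp <- el$group[!is.na(el$group) & el$type == "gene"]
    for (g in unique(grp)) {
      idx <- which(!is.na(el$group) & el$group == g & el$type == "gene")
      if (any(idx %in% inside) && !all(idx %in% inside)) {
        abort("inversion partially overlaps a duplicated unit copy")
      }
    }
    seg <- el[rev(inside), ]
    seg$seq <- revcomp(seg$seq)
    seg$strand <- ifelse(seg$strand == "+", "-", "+")
    el <- bind_rows(el[seq_len(i1 - 1), ], seg,
                    if (i2 < nrow(el)) el[(i2 + 1):nrow(el), ])
  }

  widths <- nchar(el$seq)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  genes <- el$type == "gene"
  annotation <- tibble(
    gene = el$label[genes],
    start = starts[genes],
    end = ends[genes],
    strand = el$strand[genes]
  ) |>
    group_by(.data$gene) |>
    mutate(copy = row_number()) |>
    ungroup()

  structure(
    list(sequence = paste(el$seq, collapse = ""),
         annotation = annotation,
         length = sum(widths),
         label = plan$label,
         plan = plan),
    class = "mito_genome"
  )
}

random_dna_seeded <- function(plan, offset, n) {
  with_seed(child_seed(plan$seed, offset), random_dna(n))
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %d nt, %d annotated gene copies\n",
              x$label, x$length, nrow(x$annotation)))
  invisible(x)
}

#' Assemble a heteroplasmic pool of genome variants
#'
#' @param plans List of [genome_plan()]s (typically sharing a seed so the
#'   variants differ only structurally).
#' @param frequencies Variant frequencies; must sum to 1 (tolerance 1e-9).
#' @return An object of class `mito_pool`.
#' @export
make_pool <- function(plans, frequencies) {
  if (inherits(plans, "genome_plan")) plans <- list(plans)
  if (length(plans) != length(frequencies)) {
    abort("`plans` and `frequencies` must have the same length")
  }
  if (abs(sum(frequencies) - 1) > 1e-9) abort("frequencies must sum to 1")
  if (any(frequencies < 0)) abort("frequencies must be non-negative")
  genomes <- map(plans, make_genome)
  structure(
    list(genomes = genomes,
         frequencies = frequencies,
         labels = map_chr(genomes, "label")),
    class = "mito_pool"
  )
}

#' @export
print.mito_pool <- function(x, ...) {
  cat("<mito_pool>\n")
  for (i in seq_along(x$genomes)) {
    cat(sprintf("  %s: %.3f (%d nt)\n", x$labels[i], x$frequencies[i],
                x$genomes[[i]]$length))
  }
  invisible(x)
}

#' Long-read error model
#'
#' Independent per-base substitution, insertion and deletion rates. The
#' defaults approximate the indel-dominated profile of PacBio continuous
#' long reads (CLR): ~11% total error, mostly indels.
#'
#' @param sub_rate,ins_rate,del_rate Per-base probabilities; must sum to
#'   less than 0.5.
#' @return An object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.01, ins_rate = 0.06, del_rate = 0.04) {
  if (any(c(sub_rate, ins_rate, del_rate) < 0)) abort("rates must be >= 0")
  if (sub_rate + ins_rate + del_rate >= 0.5) abort("total error rate must be < 0.5")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate),
            class = "error_model")
}

# Apply the error model to one sequence (RNG state managed by the caller).
apply_errors <- function(seq, model) {
  n <- nchar(seq)
  if (n == 0) return(seq)
  total <- model$sub_rate + model$ins_rate + model$del_rate
  if (total == 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  u <- runif(n)
  del <- u < model$del_rate
  sub <- !del & u < model$del_rate + model$sub_rate
  ins <- !del & !sub & u < total
  if (any(sub)) {
    # substitute with one of the three other bases
    alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                  nrow = 4, byrow = TRUE)
    i <- which(sub)
    row <- match(b[i], c("A", "C", "G", "T"))
    b[i] <- alt[cbind(row, sample.int(3, length(i), replace = TRUE))]
  }
  if (any(ins)) {
    i <- which(ins)
    b[i] <- paste0(b[i], sample(c("A", "C", "G", "T"), length(i), replace = TRUE))
  }
  if (any(del)) b[del] <- ""
  paste(b, collapse = "")
}

#' Sample noisy long reads from a heteroplasmic pool
#'
#' Each read draws a variant by pool frequency, a uniform origin on the
#' circle, a truncated-normal length (capped at the variant's genome
#' length), and a random strand; errors are then applied base-wise. The
#' ground-truth table records, per read, the source variant, origin,
#' error-free length, strand, the number of focal-gene copies wholly inside
#' the sampled arc, and whether the arc contains both anchor genes.
#'
#' @param pool A [make_pool()] result.
#' @param n_reads Number of reads.
#' @param length_mean,length_sd,length_min Read-length distribution (nt);
#'   normal truncated below at `length_min`. Defaults emulate a CLR run
#'   with N50 in the 10-30 kbp range.
#' @param model An [error_model()].
#' @param seed Integer seed; reads and truth are bit-identical across runs
#'   with the same seed.
#' @param anchor_genes Labels of the two anchors flanking the duplicated
#'   region.
#' @param copy_gene Focal gene whose copies are counted.
#' @return A list with `reads` (tibble `read_id`, `sequence`) and `truth`
#'   (tibble `read_id`, `variant`, `true_copy_count` — copies wholly inside
#'   the sampled arc —, `spanning_copy_count` — copies enclosed between the
#'   two anchors, NA for non-spanning reads —, `spans_anchors`, `origin`,
#'   `length`, `strand`).
#' @export
sample_reads <- function(pool, n_reads, length_mean = 12000, length_sd = 4000,
                         length_min = 1000, model = error_model(), seed = 1,
                         anchor_genes = c("12S", "CYTB"), copy_gene = "ND6") {
  stopifnot(inherits(pool, "mito_pool"), n_reads >= 1)
  with_seed(seed, {
    v <- sample.int(length(pool$genomes), n_reads, replace = TRUE,
                    prob = pool$frequencies)
    lens <- rnorm(n_reads, length_mean, length_sd)
    while (any(bad <- lens < length_min)) {
      lens[bad] <- rnorm(sum(bad), length_mean, length_sd)
    }
    lens <- as.integer(round(lens))
    glen <- map_int(pool$genomes, "length")[v]
    lens <- pmin(lens, glen)
    origin <- map_int(glen, sample.int, size = 1)
    strand <- ifelse(runif(n_reads) < 0.5, "+", "-")

    doubled <- map_chr(pool$genomes, ~ paste0(.x$sequence, .x$sequence))
    raw <- substr(doubled[v], origin, origin + lens - 1L)
    flip <- strand == "-"
    if (any(flip)) raw[flip] <- revcomp(raw[flip])
    seqs <- map_chr(raw, apply_errors, model = model)

    truth <- tibble(
      read_id = sprintf("read%05d", seq_len(n_reads)),
      variant = pool$labels[v],
      true_copy_count = NA_integer_,
      spanning_copy_count = NA_integer_,
      spans_anchors = NA,
      origin = origin,
      length = lens,
      strand = strand
    )
    for (i in seq_along(pool$genomes)) {
      sel <- v == i
      if (!any(sel)) next
      at <- arc_truth(pool$genomes[[i]], origin[sel], lens[sel],
                      anchor_genes, copy_gene)
      truth$true_copy_count[sel] <- at$copies
      truth$spanning_copy_count[sel] <- at$between
      truth$spans_anchors[sel] <- at$spans
    }
    list(reads = tibble(read_id = truth$read_id, sequence = seqs), truth = truth)
  })
}

# For a set of arcs [origin, origin + len) on one genome's circle, count
# focal-gene copies wholly contained, test containment of both anchors
# (at least `anchor_frac` of each anchor inside the arc), and count the
# copies lying in the stretch enclosed by the two anchors (the copies a
# spanning read's spectrum entry reports).
arc_truth <- function(genome, origin, len, anchor_genes, copy_gene,
                      anchor_frac = 1) {
  L <- genome$length
  ann <- genome$annotation
  rel <- function(s) (s - origin) %% L
  contained <- function(s, e) rel(s) + (e - s + 1L) <= len
  overlap <- function(s, e) {
    # circular intersection length of the gene arc with [origin, origin+len)
    glen <- e - s + 1L
    rs <- rel(s)
    seg1 <- pmax(0L, pmin(len, pmin(L, rs + glen)) - rs)
    seg2 <- pmax(0L, pmin(len, pmax(0L, rs + glen - L)))
    seg1 + seg2
  }
  a1 <- ann[ann$gene == anchor_genes[1], ][1, ]
  a2 <- ann[ann$gene == anchor_genes[2], ][1, ]
  if (anchor_frac >= 1) {
    spans <- contained(a1$start, a1$end) & contained(a2$start, a2$end)
  } else {
    spans <- overlap(a1$start, a1$end) >= anchor_frac * (a1$end - a1$start + 1) &
      overlap(a2$start, a2$end) >= anchor_frac * (a2$end - a2$start + 1)
  }
  nd <- ann[ann$gene == copy_gene, , drop = FALSE]
  copies <- rep(0L, length(origin))
  for (j in seq_len(nrow(nd))) {
    copies <- copies + as.integer(contained(nd$start[j], nd$end[j]))
  }
  # anchor interval in read order
  r1s <- rel(a1$start); r1e <- r1s + (a1$end - a1$start)
  r2s <- rel(a2$start); r2e <- r2s + (a2$end - a2$start)
  swap <- r2s < r1s
  lo <- ifelse(swap, r2e, r1e)
  hi <- ifelse(swap, r1s, r2s)
  between <- rep(0L, length(origin))
  for (j in seq_len(nrow(nd))) {
    bs <- rel(nd$start[j])
    be <- bs + (nd$end[j] - nd$start[j])
    between <- between + as.integer(bs > lo & be < hi)
  }
  between[!spans] <- NA_integer_
  list(spans = spans, copies = copies, between = between)
}

#' Expected copy-number class proportions under the read geometry
#'
#' The probability that a read spans the anchor pair depends on each
#' variant's genome length and on the length of the arc the read must
#' cover, so observed class proportions among spanning reads are not the
#' pool frequencies. This helper computes the expected proportions by
#' Monte Carlo over the same (variant, origin, length) geometry the
#' simulator uses — independent of any k-mer matching — for use as the
#' reference distribution in goodness-of-fit checks.
#'
#' @inheritParams sample_reads
#' @param n_sim Monte Carlo draws.
#' @param anchor_span The pipeline's `min_anchor_span` acceptance
#'   threshold being emulated.
#' @param k K-mer size of the emulated measurement.
#' @param model Error model of the reads. Matching blocks lose ground at
#'   gene boundaries — the matched span starts at the first error-free
#'   k-mer, which at long-read error rates sits tens of nt inside the
#'   gene, with a heavy tail — so the expectation simulates the measured
#'   anchor span (geometric overlap minus two boundary losses) rather
#'   than assuming the geometric overlap is observed.
#' @return A tibble with `copy_number` and `expected_prop` (proportions
#'   among anchor-spanning draws).
#' @export
expected_spectrum <- function(pool, n_sim = 50000, length_mean = 12000,
                              length_sd = 4000, length_min = 1000, seed = 1,
                              anchor_genes = c("12S", "CYTB"),
                              copy_gene = "ND6", anchor_span = 0.8,
                              k = 19, model = error_model()) {
  with_seed(seed, {
    v <- sample.int(length(pool$genomes), n_sim, replace = TRUE,
                    prob = pool$frequencies)
    lens <- rnorm(n_sim, length_mean, length_sd)
    while (any(bad <- lens < length_min)) {
      lens[bad] <- rnorm(sum(bad), length_mean, length_sd)
    }
    lens <- as.integer(round(lens))
    glen <- map_int(pool$genomes, "length")[v]
    lens <- pmin(lens, glen)
    origin <- map_int(glen, sample.int, size = 1)

    loss_pool <- boundary_loss_sample(model, k, 4L * n_sim)
    copies <- integer(n_sim)
    spans <- logical(n_sim)
    li <- 0L
    for (i in seq_along(pool$genomes)) {
      sel <- which(v == i)
      if (!length(sel)) next
      g <- pool$genomes[[i]]
      at <- arc_truth(g, origin[sel], lens[sel], anchor_genes, copy_gene,
                      anchor_frac = 0.01)
      ok <- rep(TRUE, length(sel))
      for (a in anchor_genes) {
        r <- g$annotation[g$annotation$gene == a, ][1, ]
        alen <- r$end - r$start + 1L
        cov <- arc_overlap(g$length, origin[sel], lens[sel], r$start, r$end)
        x1 <- loss_pool[li + seq_along(sel)]; li <- li + length(sel)
        x2 <- loss_pool[li + seq_along(sel)]; li <- li + length(sel)
        measured <- cov - x1 - x2
        ok <- ok & measured >= anchor_span * alen
      }
      copies[sel] <- at$between
      spans[sel] <- ok
    }
    tibble(copy_number = copies[spans]) |>
      count(.data$copy_number, name = "n") |>
      mutate(expected_prop = .data$n / sum(.data$n)) |>
      select("copy_number", "expected_prop")
  })
}

# Longest contiguous intersection of a gene [s, e] with arcs [origin,
# origin + len) on a circle of length L (vectorised over origins). A gene
# split across the two ends of a near-full-circle read yields two partial
# pieces; a matching block can only extend over one of them.
arc_overlap <- function(L, origin, len, s, e) {
  glen <- e - s + 1L
  rs <- (s - origin) %% L
  seg1 <- pmax(0L, pmin(len, pmin(L, rs + glen)) - rs)
  seg2 <- pmax(0L, pmin(len, pmax(0L, rs + glen - L)))
  as.integer(pmax(seg1, seg2))
}

# Empirical draws of the boundary loss of a matching block: the distance
# from the end of the covered gene portion to the nearest error-free
# k-mer, under i.i.d. per-base error events. Uses the caller's RNG
# stream.
boundary_loss_sample <- function(model, k, n_draws) {
  p <- model$sub_rate + model$ins_rate + model$del_rate
  if (p <= 0 || n_draws == 0) return(rep(0L, n_draws))
  m <- 400000L
  err <- runif(m) < p
  cs <- c(0L, cumsum(err))
  # k-mer starting at i is intact when no event falls in [i, i + k - 1]
  intact <- which(cs[(1:(m - k + 1)) + k - 1L + 1L] - cs[1:(m - k + 1)] == 0L)
  entry <- sample.int(m - 20L * k, n_draws, replace = TRUE)
  nxt <- findInterval(entry - 1L, intact) + 1L
  nxt[nxt > length(intact)] <- length(intact)
  pmax(0L, intact[nxt] - entry)
}

#' Preset study-condition pools and plans
#'
#' Convenience constructors for the architectures the package's test
#' battery exercises: a four-variant heteroplasmic pool with copy numbers
#' 4/3/1/5 at frequencies 0.70/0.23/0.04/0.03 (`pool_esox`); a pool with
#' copy numbers 2/3/1/4 at frequencies 304/504, 193/504, 6/504, 1/504
#' (`pool_aceratus`); a four-copy genome with frameshift-truncated copies
#' 2 and 4 (`plan_gunnari`); a two-copy genome with a trnP/CR remnant
#' (`plan_georgianus`); and a single-copy genome with an expanded,
#' repeat-bearing control region inside a ~6.5 kbp inversion
#' (`plan_borchgrevinki`).
#'
#' @param seed Integer seed shared by the variants.
#' @return A `mito_pool` or `genome_plan`.
#' @name presets
NULL

#' @rdname presets
#' @export
pool_esox <- function(seed = 1) {
  make_pool(
    list(
      genome_plan(n_copies = 4, seed = seed, label = "copies4"),
      genome_plan(n_copies = 3, seed = seed, label = "copies3"),
      genome_plan(n_copies = 1, seed = seed, label = "copies1"),
      genome_plan(n_copies = 5, seed = seed, label = "copies5")
    ),
    frequencies = c(0.70, 0.23, 0.04, 0.03)
  )
}

#' @rdname presets
#' @export
pool_aceratus <- function(seed = 1) {
  make_pool(
    list(
      genome_plan(n_copies = 2, seed = seed, label = "copies2"),
      genome_plan(n_copies = 3, seed = seed, label = "copies3"),
      genome_plan(n_copies = 1, seed = seed, label = "copies1"),
      genome_plan(n_copies = 4, seed = seed, label = "copies4")
    ),
    frequencies = c(304, 193, 6, 1) / 504
  )
}

#' @rdname presets
#' @export
plan_gunnari <- function(seed = 1) {
  genome_plan(
    n_copies = 4,
    truncations = tibble(copy = c(2L, 4L), offset = c(300L, 300L),
                         bases = c("GGG", "GGGG")),
    seed = seed, label = "gunnari_like"
  )
}

#' @rdname presets
#' @export
plan_georgianus <- function(seed = 1) {
  genome_plan(n_copies = 2, remnant = c("trnP", "CR"),
              seed = seed, label = "georgianus_like")
}

#' @rdname presets
#' @export
plan_borchgrevinki <- function(seed = 1) {
  genome_plan(
    n_copies = 1,
    cr_repeat = c(291, 3.0),
    inversion = c("ND5", "CR"),
    gene_lengths = c(CR = 2651L),
    seed = seed, label = "borchgrevinki_like"
  )
}
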