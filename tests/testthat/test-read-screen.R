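ref_genome <- make_genome(genome_plan(n_copies = 2, seed = 303))
ref_seq <- ref_genome$sequence

test_that("long reads sampled from the reference pass the screen", {
  read <- substr(ref_seq, 2001, 14000)
  res <- screen_mt_reads(read, ref_seq)
  expect_true(res$is_mt)
  expect_gte(res$mt_block_span, 11900)
})

test_that("random reads and NuMT-like inserts are rejected", {
  random_read <- fixed_dna(10000, seed = 41)
  numt <- withr::with_seed(42, paste0(
    random_dna(4000), substr(ref_seq, 5001, 7000), random_dna(4000)
  ))
  res <- screen_mt_reads(
    tibble::tibble(read_id = c("rand", "numt"), sequence = c(random_read, numt)),
    ref_seq, min_block = 5000
  )
  expect_false(any(res$is_mt))
  # the NuMT read still shows its ~2 kbp block
  expect_gt(res$mt_block_span[res$read_id == "numt"], 1500)
  expect_lt(res$mt_block_span[res$read_id == "numt"], 2500)
})

test_that("reads crossing the circular origin form one block", {
  L <- nchar(ref_seq)
  read <- paste0(substr(ref_seq, L - 3999, L), substr(ref_seq, 1, 4000))
  res <- screen_mt_reads(read, ref_seq, min_block = 5000)
  expect_true(res$is_mt)
  expect_gte(res$mt_block_span, 7900)
})

test_that("screen pass rate is monotone in min_block", {
  reads <- withr::with_seed(43, {
    tibble::tibble(
      read_id = paste0("r", 1:6),
      sequence = vapply(1:6, function(i) {
        o <- sample(nchar(ref_seq) - 9000, 1)
        substr(ref_seq, o, o + sample(2000:9000, 1))
      }, character(1))
    )
  })
  passes <- vapply(c(1000, 3000, 5000, 8000),
                   function(mb) sum(screen_mt_reads(reads, ref_seq, min_block = mb)$is_mt),
                   integer(1))
  expect_true(all(diff(passes) <= 0))
})

test_that("degenerate screen inputs error or return empty", {
  expect_error(screen_mt_reads("ACGT", ""), "reference")
  expect_equal(nrow(screen_mt_reads(character(0), ref_seq)), 0)
  expect_error(screen_mt_reads("ACGT", ref_seq, min_block = 0), "min_block")
})

ann <- ref_genome$annotation
anchors <- anchor_pair(
  "12S", "CYTB",
  mitoblocks:::gene_sequence(ref_seq, ann, "12S"),
  mitoblocks:::gene_sequence(ref_seq, ann, "CYTB")
)

test_that("anchor spanning requires both anchors, orientation tracks strand", {
  L <- nchar(ref_seq)
  cytb_start <- min(ann$start[ann$gene == "CYTB"])
  s12_end <- max(ann$end[ann$gene == "12S"])
  spanning <- paste0(substr(ref_seq, cytb_start - 100, L),
                     substr(ref_seq, 1, s12_end + 100))
  res <- spans_anchor_pair(spanning, anchors)
  expect_true(res$spans)
  expect_equal(res$orientation, "+")
  expect_lt(res$between_lo, res$between_hi)

  rc <- spans_anchor_pair(revcomp(spanning), anchors)
  expect_true(rc$spans)
  expect_equal(rc$orientation, "-")

  one_side <- substr(ref_seq, 1, s12_end + 500)  # 12S only
  res1 <- spans_anchor_pair(one_side, anchors)
  expect_false(res1$spans)
  expect_equal(res1$orientation, "na")
})

test_that("mt recall and NuMT rejection are both perfect at zero error", {
  pool <- make_pool(list(genome_plan(n_copies = 2, seed = 303)), 1)
  sim <- sample_reads(pool, 40, model = error_model(0, 0, 0), seed = 77,
                      length_mean = 9000, length_sd = 2000, length_min = 6000)
  numts <- withr::with_seed(78, {
    tibble::tibble(
      read_id = paste0("numt", 1:10),
      sequence = vapply(1:10, function(i) {
        o <- sample(nchar(ref_seq) - 2000, 1)
        paste0(random_dna(4000), substr(ref_seq, o, o + 1999), random_dna(4000))
      }, character(1))
    )
  })
  all_reads <- dplyr::bind_rows(sim$reads, numts)
  res <- screen_mt_reads(all_reads, ref_seq, min_block = 5000)
  expect_true(all(res$is_mt[1:40]))
  expect_false(any(res$is_mt[41:50]))
})
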