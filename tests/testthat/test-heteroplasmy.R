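test_that("build_spectrum tabulates copy counts over spanning reads", {
  expect_equal(nrow(build_spectrum(tibble::tibble(read_id = character(),
                                                  copy_count = integer()))), 0)

  calls <- tibble::tibble(read_id = c("a", "b", "c", "d"),
                          copy_count = c(1, 3, 3, 4))
  spec <- build_spectrum(calls)
  expect_equal(spec$copy_number, c(1L, 3L, 4L))
  expect_equal(spec$n_reads, c(1L, 2L, 1L))
  expect_equal(attr(spec, "n_spanning"), 4)

  # restriction to spanning ids; n_spanning records the id set size
  spec2 <- build_spectrum(calls, spanning_ids = c("a", "b", "z"))
  expect_equal(sum(spec2$n_reads), 2)
  expect_equal(attr(spec2, "n_spanning"), 3)
})

test_that("published-scale spectra are reproduced by pure counting", {
  # 6 + 304 + 193 + 1 reads over classes 1..4
  calls <- tibble::tibble(
    read_id = sprintf("r%03d", 1:504),
    copy_count = rep(c(1, 2, 3, 4), c(6, 304, 193, 1))
  )
  spec <- build_spectrum(calls, sample = "aceratus_like")
  expect_equal(spec$copy_number, 1:4)
  expect_equal(spec$n_reads, c(6L, 304L, 193L, 1L))

  het <- call_heteroplasmy(spec, min_support = 2)
  expect_true(het$is_heteroplasmic)
  expect_equal(het$classes$flag, c("confident", "confident", "confident", "singleton"))
})

test_that("heteroplasmy verdict needs two supported classes", {
  expect_false(call_heteroplasmy(
    build_spectrum(tibble::tibble(read_id = paste0("r", 1:33), copy_count = 4))
  )$is_heteroplasmic)

  # classes 1/3/4/5 with 2/11/33/1 reads: heteroplasmic, class 5 a singleton
  calls <- tibble::tibble(
    read_id = paste0("r", 1:47),
    copy_count = rep(c(1, 3, 4, 5), c(2, 11, 33, 1))
  )
  het <- call_heteroplasmy(build_spectrum(calls), min_support = 2)
  expect_true(het$is_heteroplasmic)
  expect_equal(het$classes$flag[het$classes$copy_number == 5], "singleton")
  expect_equal(sum(het$classes$flag == "confident"), 3)

  expect_error(call_heteroplasmy(build_spectrum(calls), min_support = 0),
               "min_support")
})

test_that("tidy and glance summarise spectra and verdicts", {
  calls <- tibble::tibble(read_id = paste0("r", 1:47),
                          copy_count = rep(c(1, 3, 4, 5), c(2, 11, 33, 1)))
  spec <- build_spectrum(calls, sample = "s1")
  td <- tidy(spec)
  expect_equal(sum(td$proportion), 1)
  gl <- glance(spec)
  expect_equal(gl$modal_class, 4L)
  expect_equal(gl$n_classes, 4L)
  gh <- glance(call_heteroplasmy(spec))
  expect_true(gh$is_heteroplasmic)
  expect_equal(gh$n_confident, 3L)
})

test_that("partition_reads is a disjoint cover of the calls", {
  calls <- tibble::tibble(read_id = c("r1", "r2", "r3"),
                          copy_count = c(2, 3, 2))
  p <- partition_reads(calls)
  expect_equal(p$copy_number, c(2L, 3L))
  expect_equal(p$read_ids[[1]], c("r1", "r3"))
  expect_equal(p$read_ids[[2]], "r2")
  expect_setequal(unlist(p$read_ids), calls$read_id)
  expect_equal(sum(p$n_reads), nrow(calls))

  expect_equal(nrow(partition_reads(calls[0, ])), 0)
})

test_that("export_partition writes one FASTA per class", {
  dir <- withr::local_tempdir()
  reads <- tibble::tibble(read_id = c("r1", "r2", "r3"),
                          sequence = c("ACGTACGT", "AAAACCCC", "GGGGTTTT"))
  calls <- tibble::tibble(read_id = reads$read_id, copy_count = c(2, 3, 2))
  paths <- export_partition(partition_reads(calls), reads, dir, sample = "sp")
  expect_setequal(basename(paths), c("sp.copies2.fasta", "sp.copies3.fasta"))
  back <- read_seqs(file.path(dir, "sp.copies2.fasta"))
  expect_equal(back$read_id, c("r1", "r3"))
})

test_that("simulated pools partition according to truth at zero error", {
  pool <- make_pool(
    list(genome_plan(n_copies = 2, seed = 55, label = "v2"),
         genome_plan(n_copies = 3, seed = 55, label = "v3")),
    c(0.5, 0.5)
  )
  sim <- sample_reads(pool, 60, model = error_model(0, 0, 0), seed = 56)
  ref <- pool$genomes[[2]]
  rep <- run_full(sim$reads, ref$sequence, ref$annotation,
                  run_config(min_block = 3000), sample = "zero_err")
  j <- dplyr::inner_join(rep$calls, sim$truth, by = "read_id")
  ok <- !is.na(j$spanning_copy_count)
  expect_true(all(j$copy_count[ok] == j$spanning_copy_count[ok]))
  p <- partition_reads(rep$calls[rep$calls$read_id %in% j$read_id[ok], ])
  for (i in seq_len(nrow(p))) {
    truth_ids <- j$read_id[ok][j$spanning_copy_count[ok] == p$copy_number[i]]
    expect_setequal(p$read_ids[[i]], truth_ids)
  }
})
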