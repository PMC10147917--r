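test_that("plans validate their structural grammar", {
  expect_error(genome_plan(n_copies = 0), "n_copies")
  expect_error(genome_plan(remnant = c("trnE", "trnP")), "suffix")
  expect_error(genome_plan(n_copies = 2,
                           truncations = data.frame(copy = 3, offset = 10,
                                                    bases = "G")),
               "copy index")
  expect_error(genome_plan(cr_repeat = c(53, 0.5)), "cr_repeat")
  # inversion must cover unit copies fully or not at all
  expect_error(
    make_genome(genome_plan(n_copies = 2, inversion = c("CYTB", "ND6"),
                            seed = 1)),
    "partially overlaps"
  )
})

test_that("genomes are deterministic and share genes across same-seed plans", {
  g1 <- make_genome(genome_plan(n_copies = 2, seed = 9))
  g2 <- make_genome(genome_plan(n_copies = 2, seed = 9))
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$annotation, g2$annotation)

  g3 <- make_genome(genome_plan(n_copies = 4, seed = 9))
  genes <- plan_genes(genome_plan(seed = 9))
  # every ND6 copy in both variants is the same sequence
  for (g in list(g1, g3)) {
    nd <- g$annotation[g$annotation$gene == "ND6", ]
    for (i in seq_len(nrow(nd))) {
      expect_equal(substr(g$sequence, nd$start[i], nd$end[i]), genes[["ND6"]])
    }
  }
})

test_that("frameshift truncations lengthen the right copy only", {
  plan <- genome_plan(
    n_copies = 4,
    truncations = tibble::tibble(copy = 2L, offset = 300L, bases = "GGG"),
    seed = 10
  )
  g <- make_genome(plan)
  nd <- g$annotation[g$annotation$gene == "ND6", ]
  widths <- nd$end - nd$start + 1
  expect_equal(widths, c(528, 531, 528, 528))
  # architecture is still a clean x4 duplication
  dec <- decompose(g$sequence, plan_genes(plan))
  ev <- classify_events(dec)
  expect_equal(ev$type, "tandem_duplication")
  expect_equal(ev$n_copies, 4L)
})

test_that("a planned CR repeat is recovered by the repeat finder", {
  plan <- genome_plan(cr_repeat = c(53, 8.8), seed = 11)
  cr <- plan_genes(plan)[["CR"]]
  r <- find_tandem_repeats(cr)
  expect_equal(r$period, 53L)
  expect_equal(r$copies, 8.8)
  expect_lte(abs(r$end - r$start + 1 - 466L), 2)  # 53 * 8.8 rounded
})

test_that("pool frequencies must sum to one", {
  plans <- list(genome_plan(n_copies = 2, seed = 3),
                genome_plan(n_copies = 3, seed = 3))
  expect_error(make_pool(plans, c(0.6, 0.3)), "sum to 1")
  expect_error(make_pool(plans, c(0.6)), "same length")
  pool <- make_pool(plans, c(0.6, 0.4))
  expect_equal(pool$labels, c("copies2", "copies3"))
})

test_that("error model rates are validated and applied at the right density", {
  expect_error(error_model(sub_rate = -0.1), "rates")
  expect_error(error_model(0.2, 0.2, 0.2), "< 0.5")
  seq <- fixed_dna(20000, seed = 12)
  noisy <- withr::with_seed(13, apply_errors(seq, error_model(0.1, 0, 0)))
  expect_equal(nchar(noisy), nchar(seq))  # substitutions keep length
  mism <- mean(strsplit(noisy, "")[[1]] != strsplit(seq, "")[[1]])
  expect_lt(abs(mism - 0.1), 0.01)  # substitutions always change the base
  ins <- withr::with_seed(14, apply_errors(seq, error_model(0, 0.06, 0)))
  expect_lt(abs(nchar(ins) / nchar(seq) - 1.06), 0.01)
  del <- withr::with_seed(15, apply_errors(seq, error_model(0, 0, 0.04)))
  expect_lt(abs(nchar(del) / nchar(seq) - 0.96), 0.01)
})

test_that("reads and truth are bit-identical across runs with one seed", {
  pool <- pool_esox(seed = 16)
  s1 <- sample_reads(pool, 30, seed = 17)
  s2 <- sample_reads(pool, 30, seed = 17)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- sample_reads(pool, 30, seed = 18)
  expect_false(identical(s1$reads$sequence, s3$reads$sequence))
})

test_that("error-free reads are exact substrings honouring origin and strand", {
  pool <- pool_esox(seed = 19)
  sim <- sample_reads(pool, 40, model = error_model(0, 0, 0), seed = 20)
  for (i in seq_len(40)) {
    v <- match(sim$truth$variant[i], pool$labels)
    doubled <- paste0(pool$genomes[[v]]$sequence, pool$genomes[[v]]$sequence)
    expected <- substr(doubled, sim$truth$origin[i],
                       sim$truth$origin[i] + sim$truth$length[i] - 1)
    if (sim$truth$strand[i] == "-") expected <- revcomp(expected)
    expect_identical(sim$reads$sequence[i], expected)
  }
})

test_that("anchor-spanning truth agrees with the k-mer screen at zero error", {
  pool <- pool_esox(seed = 21)
  sim <- sample_reads(pool, 60, model = error_model(0, 0, 0), seed = 22)
  ref <- pool$genomes[[1]]
  anchors <- anchor_pair(
    "12S", "CYTB",
    mitoblocks:::gene_sequence(ref$sequence, ref$annotation, "12S"),
    mitoblocks:::gene_sequence(ref$sequence, ref$annotation, "CYTB")
  )
  res <- screen_anchor_reads(sim$reads, anchors)
  # truth requires full anchor containment; the screen can additionally
  # accept reads with a partial anchor match, never the reverse
  expect_true(all(res$spans_anchors[sim$truth$spans_anchors]))
})

test_that("class proportions among spanning reads track the geometric expectation", {
  pool <- pool_aceratus(seed = 23)
  sim <- sample_reads(pool, 2000, model = error_model(0, 0, 0), seed = 24)
  truth_spec <- table(sim$truth$spanning_copy_count[sim$truth$spans_anchors])
  es <- expected_spectrum(pool, n_sim = 40000, seed = 25, anchor_span = 1,
                          model = error_model(0, 0, 0))
  obs <- merge(
    data.frame(copy_number = as.integer(names(truth_spec)),
               n = as.vector(truth_spec)),
    as.data.frame(es), all = TRUE
  )
  obs$n[is.na(obs$n)] <- 0
  obs$expected_prop[is.na(obs$expected_prop)] <- 1e-9
  p <- withr::with_seed(26, stats::chisq.test(obs$n, p = obs$expected_prop,
                                              rescale.p = TRUE,
                                              simulate.p.value = TRUE,
                                              B = 2000)$p.value)
  expect_gt(p, 0.01)
})
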