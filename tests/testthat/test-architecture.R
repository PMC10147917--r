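canon_plan <- genome_plan(n_copies = 1, seed = 501)
canon_genes <- plan_genes(canon_plan)

test_that("the reference decomposes into itself: one block per gene, all forward", {
  g <- make_genome(canon_plan)
  dec <- decompose(g$sequence, canon_genes)
  expect_equal(nrow(dec$blocks), nrow(g$annotation))
  expect_equal(dec$blocks$gene, g$annotation$gene)
  expect_true(all(dec$blocks$strand == "+"))
  expect_equal(nrow(classify_events(dec)), 0)
  expect_equal(glance(dec)$n_genes, 38L)
})

test_that("a triplicated unit yields interleaved blocks and one duplication event", {
  g <- make_genome(genome_plan(n_copies = 3, seed = 501))
  dec <- decompose(g$sequence, canon_genes)
  for (gene in c("ND6", "trnE", "trnP", "CR")) {
    expect_equal(sum(dec$blocks$gene == gene), 3, info = gene)
  }
  ev <- classify_events(dec)
  expect_equal(ev$type, "tandem_duplication")
  expect_equal(ev$unit[[1]], c("ND6", "trnE", "trnP", "CR"))
  expect_equal(ev$n_copies, 3L)
  expect_match(architecture_string(dec), "(ND6 trnE trnP CR)x3", fixed = TRUE)
})

test_that("a remnant trnP/CR block is classified with its missing prefix", {
  g <- make_genome(genome_plan(n_copies = 2, remnant = c("trnP", "CR"), seed = 501))
  dec <- decompose(g$sequence, canon_genes)
  ev <- classify_events(dec)
  expect_setequal(ev$type, c("tandem_duplication", "remnant_block"))
  dup <- ev[ev$type == "tandem_duplication", ]
  rem <- ev[ev$type == "remnant_block", ]
  expect_equal(dup$n_copies, 2L)
  expect_equal(rem$unit[[1]], c("trnP", "CR"))
  expect_match(rem$evidence, "ND6,trnE")
})

test_that("an in-place inversion flips strands and reverses local order", {
  plan <- genome_plan(n_copies = 1, inversion = c("trnF", "16S"), seed = 502)
  g <- make_genome(plan)
  dec <- decompose(g$sequence, plan_genes(plan), anchor_gene = "trnL1")
  inv_genes <- c("trnF", "12S", "trnV", "16S")
  b <- dec$blocks
  expect_true(all(b$strand[b$gene %in% inv_genes] == "-"))
  expect_true(all(b$strand[!b$gene %in% inv_genes] == "+"))
  ev <- classify_events(dec)
  inv <- ev[ev$type == "inversion", ]
  expect_equal(nrow(inv), 1)
  expect_setequal(inv$unit[[1]], inv_genes)
})

test_that("inversion span matches the planned extent within k-1", {
  plan <- plan_borchgrevinki(seed = 503)
  g <- make_genome(plan)
  dec <- decompose(g$sequence, plan_genes(plan))
  inv <- classify_events(dec)
  inv <- inv[inv$type == "inversion", ]
  ann <- g$annotation
  planned <- max(ann$end[ann$strand == "-"]) - min(ann$start[ann$strand == "-"]) + 1
  expect_equal(nrow(inv), 1)
  expect_lte(abs(inv$span - planned), 18)
  expect_setequal(inv$unit[[1]],
                  c("ND5", "CYTB", "trnT", "ND6", "trnE", "trnP", "CR"))
})

test_that("classification is invariant under rotation of the circle", {
  g <- make_genome(genome_plan(n_copies = 3, seed = 501))
  ev_ref <- classify_events(decompose(g$sequence, canon_genes))
  expect_equal(nrow(ev_ref), 1)  # guards against a vacuous comparison
  for (off in c(5000, 12000, 19000)) {
    rot <- paste0(substr(g$sequence, off + 1, g$length),
                  substr(g$sequence, 1, off))
    ev <- classify_events(decompose(rot, canon_genes))
    expect_equal(ev$type, ev_ref$type, info = paste("offset", off))
    expect_equal(ev$n_copies, ev_ref$n_copies, info = paste("offset", off))
    expect_equal(ev$unit, ev_ref$unit, info = paste("offset", off))
  }
})

test_that("an empty target warns rather than errors", {
  expect_warning(dec <- decompose(fixed_dna(3000, seed = 505), canon_genes),
                 "decomposition empty")
  expect_equal(nrow(dec$blocks), 0)
  expect_equal(nrow(classify_events(dec)), 0)
})

test_that("reference genes shorter than k are rejected", {
  genes <- c(canon_genes[1:3], short = "ACGTACGT")
  expect_error(decompose("ACGT", genes), "shorter than k")
})
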