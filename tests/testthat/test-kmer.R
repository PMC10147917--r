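test_that("kmer_index enumerates both strands with mirrored offsets", {
  idx <- kmer_index("ACGTACGTA", k = 8)
  # 2 forward 8-mers plus their reverse complements
  expect_equal(length(idx$qpos), 4)
  expect_setequal(idx$strand, c("+", "-"))
  expect_equal(sort(idx$qpos[idx$strand == "+"]), c(1, 2))
  expect_equal(sort(idx$qpos[idx$strand == "-"]), c(1, 2))

  # a query with no repeated k-mers has L - k + 1 forward entries
  q <- fixed_dna(400, seed = 7)
  idx2 <- kmer_index(q, k = 19)
  expect_equal(sum(idx2$strand == "+"), nchar(q) - 18)

  # k-mers overlapping an ambiguous base are absent
  idx3 <- kmer_index("AAANAAACCC", k = 3)
  expect_false(any(grepl("N", idx3$uniq)))
  expect_equal(sum(idx3$strand == "+"), 5)  # AAA, AAA, AAC, ACC, CCC
})

test_that("kmer_index rejects degenerate queries", {
  expect_error(kmer_index("ACGT", k = 19), "query too short")
  expect_error(kmer_index("", k = 3), "query too short")
  expect_error(kmer_index("ACGT", k = 0), "k")
})

test_that("scan_read finds identity and reverse-complement matches", {
  m <- scan_read(test_query, test_index)
  fwd <- m[m$strand == "+", ]
  expect_equal(fwd$read_pos, 1:(528 - 18))
  expect_equal(fwd$query_pos, fwd$read_pos)

  mrc <- scan_read(revcomp(test_query), test_index)
  expect_equal(sum(mrc$strand == "-"), sum(m$strand == "+"))

  # reads shorter than k yield no matches
  expect_equal(nrow(scan_read("ACGT", test_index)), 0)
})

test_that("random read and random query share no 19-mers", {
  read <- fixed_dna(5000, seed = 11)
  m <- scan_read(read, test_index)
  expect_equal(nrow(m), 0)
  # brute-force confirmation on the same pair
  rk <- unique(substring(read, 1:(nchar(read) - 18), 19:nchar(read)))
  qk <- substring(test_query, 1:510, 19:528)
  expect_equal(length(intersect(rk, union(qk, revcomp(qk)))), 0)
})

test_that("cluster_matches applies the maximum-gap rule", {
  m <- tibble::tibble(
    read_pos = c(100L, 119L, 138L, 1200L, 1219L),
    query_pos = c(1L, 20L, 39L, 1L, 20L),
    strand = "+"
  )
  b <- cluster_matches(m, gap_threshold = 800, k = 19, query_length = 57)
  expect_equal(nrow(b), 2)          # 1200 - 138 = 1062 > 800
  expect_equal(b$start, c(100L, 1200L))
  expect_equal(b$end, c(156L, 1237L))

  b1 <- cluster_matches(m, gap_threshold = 2000, k = 19, query_length = 57)
  expect_equal(nrow(b1), 1)         # 1062 <= 2000

  # empty input, unsorted input, invalid threshold
  expect_equal(nrow(cluster_matches(m[0, ], 800, k = 19, query_length = 57)), 0)
  expect_equal(cluster_matches(m[c(4, 1, 5, 2, 3), ], 800, k = 19, query_length = 57), b)
  expect_error(cluster_matches(m, gap_threshold = 0, k = 19, query_length = 57),
               "invalid threshold")
})

test_that("block strand is the majority, ties broken by smallest query offset", {
  m <- tibble::tibble(
    read_pos = c(1L, 10L, 20L, 30L),
    query_pos = c(5L, 2L, 7L, 9L),
    strand = c("-", "+", "-", "-")
  )
  b <- cluster_matches(m, 800, k = 19, query_length = 50)
  expect_equal(b$strand, "-")
  tie <- tibble::tibble(
    read_pos = c(1L, 10L),
    query_pos = c(8L, 3L),
    strand = c("-", "+")
  )
  bt <- cluster_matches(tie, 800, k = 19, query_length = 50)
  expect_equal(bt$strand, "+")  # member with smallest query offset is '+'
})

test_that("query coverage measures distinct covered query positions", {
  m <- tibble::tibble(
    read_pos = c(1L, 2L, 3L),
    query_pos = c(1L, 2L, 3L),
    strand = "+"
  )
  b <- cluster_matches(m, 800, k = 19, query_length = 42)
  expect_equal(b$query_coverage, 21 / 42)
  expect_equal(b$n_kmers, 3L)
})
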