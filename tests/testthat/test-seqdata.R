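test_that("CSV reading preserves order, labels and auto-detects headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sequence,label", "CCCCACCCGT,1", "CCCCTCACCC,0"), path)
  recs <- read_sequence_csv(path)
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$sequence, c("CCCCACCCGT", "CCCCTCACCC"))
  expect_equal(recs$label, c(1L, 0L))

  # same rows without a header parse identically
  writeLines(c("CCCCACCCGT,1", "CCCCTCACCC,0"), path)
  expect_equal(read_sequence_csv(path)$label, c(1L, 0L))

  # single-column unlabelled file
  writeLines(c("sequence", "ACGT"), path)
  un <- read_sequence_csv(path, has_labels = FALSE)
  expect_equal(un$sequence, "ACGT")
  expect_true(is.na(un$label))
})

test_that("an empty data section yields an empty collection, not an error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("sequence,label", path)
  expect_equal(nrow(read_sequence_csv(path)), 0L)
  writeLines(character(0), path)
  expect_equal(nrow(read_sequence_csv(path)), 0L)
})

test_that("CSV write-then-read round-trips random records exactly", {
  recs <- sequence_records(random_dna(50, 60, seed = 42),
                           label = withr::with_seed(43, sample(0:1, 50, TRUE)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sequence_csv(recs, path)
  back <- read_sequence_csv(path)
  expect_identical(back$sequence, recs$sequence)
  expect_identical(back$label, recs$label)
})

test_that("malformed labels and off-alphabet bases are rejected with context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ACGT,1", "ACGT,2"), path)
  expect_error(read_sequence_csv(path), "malformed label '2' at data row 2")
  writeLines(c("ACGT,1", "ACXT,0"), path)
  expect_error(read_sequence_csv(path), "'X' outside alphabet")
  # permissive policy admits IUPAC codes for downstream masking
  expect_equal(nrow(read_sequence_csv(path, alphabet = "permissive")), 2L)
})

test_that("FASTA round-trip carries labels in headers", {
  skip_if_not_installed("Biostrings")
  recs <- sequence_records(random_dna(10, 40, seed = 5),
                           label = c(rep(0L, 5), rep(1L, 5)))
  path <- withr::local_tempfile(fileext = ".fa")
  write_sequence_fasta(recs, path)
  back <- read_sequence_fasta(path)
  expect_identical(back$sequence, recs$sequence)
  expect_identical(back$label, recs$label)
  expect_identical(back$id, recs$id)
})

test_that("split parts are disjoint, exhaustive and follow the 4:1 ratios", {
  d <- generate_synthetic(synthetic_config(n_per_class = 50, seq_length = 20,
                                           seed = 2))
  for (seed in c(1L, 7L, 99L)) {
    sp <- split_dataset(d, seed = seed)
    ids <- c(sp$train$id, sp$validation$id, sp$test_unlabelled$id)
    expect_equal(sort(ids), sort(d$id))
    expect_equal(anyDuplicated(ids), 0L)
    expect_equal(nrow(sp$test_unlabelled), 20L)  # floor(100 / 5)
    expect_equal(nrow(sp$validation), 16L)       # floor(80 / 5)
    expect_equal(nrow(sp$train), 64L)
    # stratification: class balance preserved in every part
    expect_equal(sum(sp$train$label == 0), 32L)
    expect_equal(sum(sp$validation$label == 0), 8L)
    expect_equal(sum(sp$test_labels == 0), 10L)
    # test labels stripped but retained out-of-band
    expect_true(all(is.na(sp$test_unlabelled$label)))
  }
})

test_that("splitting is deterministic under a seed and sized on tiny input", {
  d <- sequence_records(random_dna(5, 10, seed = 1),
                        label = c(0L, 1L, 0L, 1L, 0L))
  a <- gmean:::partition_records(d, c(4, 1), seed = 3L)
  b <- gmean:::partition_records(d, c(4, 1), seed = 3L)
  expect_identical(a, b)
  expect_equal(nrow(a$large), 4L)
  expect_equal(nrow(a$small), 1L)
  expect_setequal(c(a$large$id, a$small$id), d$id)
  expect_error(split_dataset(d[1:2, ], seed = 1),
               "cannot be split")
  expect_error(split_dataset(transform(d, label = NA_integer_)),
               "labelled")
})

test_that("the generator yields exactly n_per_class records per class", {
  d <- generate_synthetic(synthetic_config(n_per_class = 100, seq_length = 30,
                                           seed = 11))
  expect_equal(nrow(d), 200L)
  expect_equal(as.vector(table(d$label)), c(100L, 100L))
  expect_true(all(nchar(d$sequence) == 30L))
  expect_true(all(grepl("^[ACGT]+$", d$sequence)))
})

test_that("planted-motif frequencies match the binomial scan oracle", {
  motif1 <- "GGGACTTT"
  # with insertion disabled, hits come from background alone
  d0 <- generate_synthetic(synthetic_config(n_per_class = 1000,
                                            seq_length = 100,
                                            insertion_prob = 0,
                                            seed = 21))
  q <- motif_hit_prob(motif1, 100)
  hits0 <- sum(grepl(motif1, d0$sequence[d0$label == 1], fixed = TRUE))
  ci0 <- qbinom(c(0.005, 0.995), 1000, q)
  expect_gte(hits0, ci0[1])
  expect_lte(hits0, ci0[2])

  # with insertion_prob 0.9 the hit rate is 0.9 plus background hits
  d9 <- generate_synthetic(synthetic_config(n_per_class = 1000,
                                            seq_length = 100,
                                            insertion_prob = 0.9,
                                            seed = 22))
  p_eff <- 0.9 + 0.1 * q
  hits9 <- sum(grepl(motif1, d9$sequence[d9$label == 1], fixed = TRUE))
  ci9 <- qbinom(c(0.005, 0.995), 1000, p_eff)
  expect_gte(hits9, ci9[1])
  expect_lte(hits9, ci9[2])
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_per_class = 25, seq_length = 40, seed = 33)
  expect_identical(generate_synthetic(cfg), generate_synthetic(cfg))
  # and the global RNG stream is left untouched
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(generate_synthetic(cfg))
    expect_equal(runif(1), before)
  })
})

test_that("background composition obeys the law of large numbers", {
  bg <- c(A = 0.1, C = 0.4, G = 0.3, T = 0.2)
  d <- generate_synthetic(synthetic_config(n_per_class = 500,
                                           seq_length = 100,
                                           insertion_prob = 0,
                                           background = bg, seed = 8))
  bases <- strsplit(paste(d$sequence, collapse = ""), "")[[1]]
  freq <- table(factor(bases, c("A", "C", "G", "T"))) / length(bases)
  expect_true(all(abs(as.numeric(freq) - bg) < 0.01))
})

test_that("PWM motifs are sampled column-wise and bad configs error", {
  pwm <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm[1, ] <- 1  # degenerate PWM: always AAAA
  d <- generate_synthetic(synthetic_config(n_per_class = 50, seq_length = 20,
                                           motif_class1 = pwm,
                                           insertion_prob = c(0, 1),
                                           seed = 4))
  expect_true(all(grepl("AAAA", d$sequence[d$label == 1], fixed = TRUE)))
  expect_error(synthetic_config(seq_length = 5, motif_class0 = "TGACGTCA"),
               "exceeds seq_length")
  expect_error(synthetic_config(background = c(0.5, 0.5, 0.1, 0)),
               "sum to 1")
  expect_error(synthetic_config(insertion_prob = 1.2), "\\[0, 1\\]")
})
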