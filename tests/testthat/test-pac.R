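test_that("make_counts tallies, filters and orders deterministically", {
  m <- make_counts(list(A = rep("ACGT", 3)), evidence_filter(1, 1))
  expect_identical(m, matrix(3L, 1, 1, dimnames = list("ACGT", "A")))
  # a sequence reaching 2 counts in one sample only is dropped by (2,2)
  m <- make_counts(list(A = rep("ACGT", 2), B = "TTTT"), evidence_filter(2, 2))
  expect_equal(nrow(m), 0)
  expect_error(make_counts(list(A = "ACGT", A = "ACGT")), "duplicate")

  # dictionary-merge oracle on random multisets
  set.seed(61)
  ins <- lapply(setNames(1:3, c("s1", "s2", "s3")), function(i)
    sample(rand_seqs(8, 16:18, seed = 60), 50, replace = TRUE))
  got <- make_counts(ins, evidence_filter(1, 1))
  want <- oracle_counts(ins)
  expect_setequal(rownames(got), rownames(want))
  expect_identical(got, want[rownames(got), , drop = FALSE])
  # deterministic order: total desc, ties lexicographic
  tot <- rowSums(got)
  expect_true(all(diff(tot) <= 0))
  ties <- split(rownames(got), tot)
  expect_true(all(vapply(ties, function(x) identical(x, sort(x)), logical(1))))
})

test_that("make_pac aligns tables and rejects missing samples", {
  counts <- make_counts(list(B = c("ACGT", "ACGT"), A = "GGGG"),
                        evidence_filter(1, 1))
  pheno <- data.frame(sample_id = c("A", "B", "C"), group = c("x", "y", "z"))
  pac <- make_pac(pheno, counts)
  expect_true(pac_check(pac)$ok)
  expect_identical(pac$pheno$sample_id, colnames(pac$counts))
  expect_identical(pac$anno$seq, rownames(pac$counts))
  expect_equal(pac$anno$length, nchar(pac$anno$seq))
  expect_error(make_pac(data.frame(sample_id = "A"), counts), "missing")
})

test_that("pac_check reports violations as data", {
  pac <- toy_pac()
  expect_true(pac_check(pac)$ok)
  broken <- pac
  broken$anno <- broken$anno[-1, , drop = FALSE]
  chk <- pac_check(broken)
  expect_false(chk$ok)
  expect_match(paste(chk$violations, collapse = "; "), "row key mismatch")
  neg <- pac
  neg$counts[1, 1] <- -1L
  expect_match(paste(pac_check(neg)$violations, collapse = "; "), "negative")
})

test_that("pac_filter restricts rows and columns and is idempotent", {
  pac <- toy_pac(seed = 2, n_seq = 40, n_samples = 6)
  expect_equal(pac_filter(pac), pac)
  f <- pac_filter(pac, size_range = c(20, 24))
  expect_true(all(f$anno$length >= 20 & f$anno$length <= 24))
  expect_true(pac_check(f)$ok)
  # min_cpm rule equals a brute-force row scan on the full matrix
  cpm <- pac_norm(pac)
  keep <- rowSums(cpm >= 20000) >= 2
  f2 <- pac_filter(pac, min_cpm = 20000, min_samples_over_cpm = 2)
  expect_identical(rownames(f2$counts), rownames(pac$counts)[keep])
  expect_equal(pac_filter(f2, min_cpm = 20000, min_samples_over_cpm = 2), f2)
  # column predicate
  f3 <- pac_filter(pac, pheno_subset = function(p) p$group == "a")
  expect_true(all(f3$pheno$group == "a"))
  expect_error(pac_filter(pac, size_range = c(100, 200)), "all sequences")
  expect_error(pac_filter(pac, pheno_subset = function(p) rep(FALSE, nrow(p))),
               "all samples")
  # original untouched
  expect_true(pac_check(pac)$ok)
})

test_that("CPM normalization matches the elementwise formula", {
  pac <- toy_pac(seed = 3)
  cpm <- pac_norm(pac)
  expect_equal(unname(colSums(cpm)), rep(1e6, ncol(cpm)))
  j <- 2; s <- 5
  expect_equal(cpm[s, j],
               pac$counts[s, j] * 1e6 / sum(pac$counts[, j]))
  one <- make_pac(data.frame(sample_id = "A"),
                  matrix(10L, 1, 1, dimnames = list("ACGTACGTACGTACGT", "A")))
  expect_equal(unname(pac_norm(one)[1, 1]), 1e6)
})

test_that("group summaries match a hand-rolled oracle", {
  pac <- toy_pac(seed = 4, n_samples = 6)
  cpm <- pac_norm(pac)
  ms <- pac_summary(pac, "group", "mean_cpm")
  for (g in c("a", "b"))
    expect_equal(ms[[g]],
                 unname(rowMeans(cpm[, pac$pheno$group == g, drop = FALSE])))
  fc <- pac_summary(pac, "group", "log2fc")
  expect_equal(fc$log2fc_b_vs_a,
               log2((ms$b + 1) / (ms$a + 1)))
  # identical groups give zero fold change
  dup <- make_pac(data.frame(sample_id = c("A", "B"), g = c("x", "y")),
                  matrix(c(5L, 5L, 7L, 7L), 2, 2, byrow = TRUE,
                         dimnames = list(c("ACGTACGTACGTACGTA",
                                           "TTTTACGTACGTACGT"), c("A", "B"))))
  expect_equal(pac_summary(dup, "g", "log2fc")[[1]], c(0, 0))
  expect_error(pac_summary(pac, "nope"), "unknown")
})

test_that("write_pac / read_pac round-trips deeply equal objects", {
  pac <- toy_pac(seed = 5)
  pac$pheno$contamination <- seq(0, 0.3, length.out = nrow(pac$pheno))
  d <- withr::local_tempdir()
  write_pac(pac, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  back <- read_pac(d)
  expect_equal(back, pac)
  expect_true(pac_check(back)$ok)
})

test_that("count columns conserve retained reads from trimming", {
  pool <- source_pool("p", setNames(gen_references(7, 2, 150), c("r1", "r2")),
                      lengths = 16:40)
  mix <- matrix(1, 2, 1, dimnames = list(c("S1", "S2"), "p"))
  spec <- sim_spec(pool, mix, n_reads_per_sample = 400, error_rate = 0.01,
                   seed = 71, adapterless_fraction = 0.1)
  sim <- simulate_fastq(spec, withr::local_tempdir())
  tr <- trim_samples(sim$fastq, trim_params(spec$adapter))
  counts <- make_counts(tr$inserts, evidence_filter(1, 1))
  expect_identical(as.integer(colSums(counts)), tr$report$reads_retained)
})
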