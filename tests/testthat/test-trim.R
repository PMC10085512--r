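AD <- "AGATCGGAAGAGC"

test_that("find_adapter places exact and adapter-only reads", {
  p <- trim_params(AD, max_mismatch_fraction = 0, min_overlap = 10)
  read <- paste0("ACGTACGTACGTACGTAC", "AGATCGGAAG")
  expect_equal(find_adapter(read, p), 18L)
  expect_equal(find_adapter(paste0(AD, "TTTTT"), trim_params(AD)), 0L)
  expect_true(is.na(find_adapter(strrep("ACGT", 10), trim_params(AD))))
})

test_that("find_adapter equals the exhaustive position-overlap oracle", {
  reads <- rand_seqs(250, 30:60, seed = 21)
  # make some reads carry a (mutated) adapter at a random position
  set.seed(22)
  for (i in seq(1, 250, by = 2)) {
    p0 <- sample(5:35, 1)
    ad <- AD
    if (i %% 3 == 0) substr(ad, 3, 3) <- "T"   # one mismatch
    reads[i] <- paste0(substr(reads[i], 1, p0), ad)
  }
  for (mm in c(0, 0.1, 0.2)) {
    par <- trim_params(AD, max_mismatch_fraction = mm, min_overlap = 8)
    got <- find_adapter(reads, par)
    want <- vapply(reads, oracle_find_adapter, integer(1), AD, mm, 8,
                   USE.NAMES = FALSE)
    expect_identical(got, want)
  }
})

test_that("trim_read applies policies in order and reports one reason", {
  par <- trim_params(AD)
  r <- trim_read(paste0(strrep("AC", 9), AD), params = par)
  expect_equal(r$insert, strrep("AC", 9))
  expect_equal(r$reason, "retained")
  # adapter at 0: empty insert fails the size filter
  r <- trim_read(paste0(AD, strrep("T", 10)), params = par)
  expect_equal(r$reason, "size")
  # no adapter, keep policy: full read retained if within size range
  keep <- trim_params(AD, policy_no_adapter = "keep")
  r <- trim_read(strrep("ACGT", 10), params = keep)
  expect_equal(r$insert, strrep("ACGT", 10))
  # N filter fires only on the retained insert
  r <- trim_read(paste0(strrep("A", 15), "NNN", AD), params = par)
  expect_equal(r$reason, "N")
  r <- trim_read(paste0(strrep("A", 18), AD, "NNN"),
                 params = trim_params(AD, min_overlap = 10))
  expect_equal(r$reason, "retained")
  # quality filter uses mean Phred over the insert only
  qpar <- trim_params(AD, min_mean_quality = 30)
  read <- paste0(strrep("A", 18), AD)
  lowq <- paste0(strrep("#", 18), strrep("I", nchar(AD)))  # '#' = Q2
  r <- trim_read(read, lowq, qpar)
  expect_equal(r$reason, "quality")
  expect_error(trim_read("ACGT", "II", par), "length")
})

test_that("trim_fastq conserves reads across report categories", {
  pool <- source_pool("p", setNames(gen_references(1, 2, 200), c("r1", "r2")),
                      lengths = 16:40)
  mix <- matrix(1, 1, 1, dimnames = list("S1", "p"))
  spec <- sim_spec(pool, mix, n_reads_per_sample = 800, error_rate = 0.02,
                   seed = 31, adapterless_fraction = 0.15)
  sim <- simulate_fastq(spec, withr::local_tempdir())
  rep <- trim_fastq(sim$fastq[[1]], trim_params(AD))$report
  expect_equal(rep$reads_in,
               rep$reads_retained + rep$reads_discarded_no_adapter +
                 rep$reads_discarded_size + rep$reads_discarded_N +
                 rep$reads_discarded_quality)
  # adapterless discards near binomial(n, 0.15)
  sd <- sqrt(800 * 0.15 * 0.85)
  expect_lt(abs(rep$reads_discarded_no_adapter - 800 * 0.15), 3 * sd)
})

test_that("error-free simulated inserts are recovered exactly", {
  pool <- source_pool("p", setNames(gen_references(2, 3, 150),
                                    c("r1", "r2", "r3")), lengths = 16:40)
  mix <- matrix(c(1, 1), 2, 1, dimnames = list(c("S1", "S2"), "p"))
  spec <- sim_spec(pool, mix, n_reads_per_sample = 600, error_rate = 0,
                   seed = 41)
  sim <- simulate_fastq(spec, withr::local_tempdir())
  tr <- trim_samples(sim$fastq, trim_params(AD))
  for (s in c("S1", "S2")) {
    truth <- table(sim$ground_truth$insert_seq[sim$ground_truth$sample == s])
    got <- tr$inserts[[s]]
    expect_identical(got[order(names(got))],
                     setNames(as.integer(truth), names(truth)))
  }
})

test_that("raising the mismatch tolerance never loses adapter calls", {
  reads <- rand_seqs(150, 40:50, seed = 51)
  set.seed(52)
  for (i in 1:150) {
    ad <- AD
    k <- sample(0:2, 1)
    if (k > 0) for (j in sample(nchar(ad), k)) substr(ad, j, j) <- "A"
    reads[i] <- paste0(substr(reads[i], 1, sample(16:30, 1)), ad)
  }
  prev <- -1L
  for (mm in c(0, 0.1, 0.2, 0.3)) {
    nhit <- sum(!is.na(find_adapter(reads, trim_params(AD,
                                                       max_mismatch_fraction = mm))))
    expect_gte(nhit, prev)
    prev <- nhit
  }
})

test_that("trim_fastq handles empty and duplicated-read files", {
  empty <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), empty)
  res <- trim_fastq(empty, trim_params(AD))
  expect_length(res$inserts, 0)
  expect_equal(res$report$reads_in, 0)

  dup <- withr::local_tempfile(fileext = ".fastq")
  read <- paste0(strrep("GA", 10), AD)
  writeLines(unlist(lapply(1:5, function(i)
    c(paste0("@r", i), read, "+", strrep("I", nchar(read))))), dup)
  res <- trim_fastq(dup, trim_params(AD))
  expect_identical(res$inserts, setNames(5L, strrep("GA", 10)))
})

test_that("malformed FASTQ is reported with its record index", {
  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "@r2", "ACGTA", "+", "III"), bad)   # qual too short
  expect_error(trim_fastq(bad, trim_params(AD)), "record 2")
})
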