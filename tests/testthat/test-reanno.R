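test_that("align_k_mismatch finds expected placements", {
  ref <- reference_set("toy", c(rec = "ACGTACGT"))
  hits <- align_k_mismatch("ACG", ref, align_spec(0, strands = "forward"))
  expect_equal(hits$pos, c(0L, 4L))
  expect_true(all(hits$mismatches == 0))
  hits <- align_k_mismatch("ACGA", ref, align_spec(1, strands = "forward"))
  expect_true(any(hits$pos == 0 & hits$mismatches == 1))
  expect_error(align_k_mismatch("ACGN", ref), "non-ACGT")
})

test_that("alignment equals the sliding-window Hamming oracle", {
  records <- setNames(rand_seqs(3, c(120, 200, 80), seed = 81),
                      c("c", "a", "b"))
  ref <- reference_set("rand", records)
  queries <- c(rand_seqs(25, 12:20, seed = 82),
               # planted queries guaranteed to hit
               substr(records[["a"]], 11, 28),
               substr(records[["b"]], 3, 17))
  for (k in 0:3) {
    spec <- align_spec(k)
    for (q in queries) {
      got <- align_k_mismatch(q, ref, spec)
      want <- oracle_align(q, records, k)
      expect_equal(got[, c("record_id", "pos", "strand", "mismatches")],
                   want, info = sprintf("k=%d q=%s", k, q))
    }
  }
})

test_that("reverse-complementing the reference flips only strand labels", {
  records <- setNames(rand_seqs(1, 150, seed = 83), "r")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(records)))
  names(rc) <- "r"
  q <- substr(records[[1]], 40, 59)
  h1 <- align_k_mismatch(q, reference_set("f", records), align_spec(1))
  h2 <- align_k_mismatch(q, reference_set("r", rc), align_spec(1))
  expect_equal(nrow(h1), nrow(h2))
  # a + hit at pos p becomes a - hit at W - p - L
  W <- nchar(records[[1]]); L <- nchar(q)
  mapped <- data.frame(pos = W - h1$pos - L,
                       strand = ifelse(h1$strand == "+", "-", "+"),
                       mismatches = h1$mismatches)
  mapped <- mapped[order(mapped$pos, mapped$strand), ]
  h2s <- h2[order(h2$pos, h2$strand), c("pos", "strand", "mismatches")]
  expect_equal(unname(as.matrix(h2s)), unname(as.matrix(mapped)))
})

test_that("hit sets are monotone in the mismatch allowance", {
  records <- setNames(rand_seqs(2, 300, seed = 84), c("r1", "r2"))
  ref <- reference_set("rand", records)
  queries <- rand_seqs(15, 10:14, seed = 85)
  for (q in queries) {
    prev <- NULL
    for (k in 0:3) {
      h <- align_k_mismatch(q, ref, align_spec(k))
      key <- paste(h$record_id, h$pos, h$strand)
      if (!is.null(prev)) expect_true(all(prev %in% key))
      prev <- key
    }
  }
})

test_that("reanno records minimal strata and hit counts per set", {
  refA <- reference_set("miRNA", c(m1 = "ACGTACGTACGTACGTACGT"))
  refB <- reference_set("rRNA", c(r1 = strrep("GT", 30)))
  seqs <- c("ACGTACGTACGT",        # verbatim in miRNA (and rRNA? no)
            "TTTTTTTTTTTT")        # nowhere
  tab <- reanno(seqs, list(refA, refB), align_spec(0))
  expect_equal(tab$miRNA_stratum, c("mis0", "no_hit"))
  expect_equal(tab$rRNA_stratum, c("no_hit", "no_hit"))
  expect_true(tab$miRNA_nhits[1] >= 1)
  # with k=1 a single-substitution probe lands in mis1
  probe <- "ACGTACGTACGA"
  tab <- reanno(probe, refA, align_spec(1))
  expect_equal(tab$miRNA_stratum, "mis1")
  # batch PDict path and per-query path agree
  seqs2 <- c(rand_seqs(10, 10:12, seed = 86), "ACGTACGTACGT")
  t0 <- reanno(seqs2, refA, align_spec(0))
  for (i in seq_along(seqs2)) {
    h <- align_k_mismatch(seqs2[i], refA, align_spec(0))
    expect_equal(t0$miRNA_stratum[i] == "mis0", nrow(h) > 0)
    if (nrow(h)) expect_equal(t0$miRNA_nhits[i], nrow(h))
  }
})

test_that("hierarchy resolution follows priority and mismatch policy", {
  tab <- data.frame(seq = c("s1", "s2", "s3"),
                    rRNA_stratum = c("mis0", "no_hit", "no_hit"),
                    rRNA_nhits = c(1L, 0L, 0L),
                    miRNA_stratum = c("mis0", "mis2", "no_hit"),
                    miRNA_nhits = c(2L, 1L, 0L),
                    tRNA_stratum = c("no_hit", "mis1", "no_hit"),
                    tRNA_nhits = c(0L, 3L, 0L),
                    stringsAsFactors = FALSE)
  hier <- hierarchy_spec(c("rRNA", "miRNA", "tRNA"))
  strict <- simplify_reanno(tab, hier)
  expect_equal(strict$resolved_class, c("rRNA", "miRNA", "no_anno"))
  expect_equal(strict$resolved_stratum, c("mis0", "mis2", "no_hit"))
  pref <- simplify_reanno(tab, hier, "prefer_less_mismatch_within_class")
  expect_equal(pref$resolved_class, c("rRNA", "tRNA", "no_anno"))
  expect_equal(pref$resolved_stratum, c("mis0", "mis1", "no_hit"))
  expect_error(simplify_reanno(tab, hierarchy_spec(c("rRNA", "piRNA"))),
               "piRNA")

  # random tables: both policies equal a brute-force rule evaluation
  set.seed(87)
  sets <- c("a", "b", "c")
  rt <- data.frame(seq = paste0("q", 1:50), stringsAsFactors = FALSE)
  for (s in sets) {
    rt[[paste0(s, "_stratum")]] <- sample(c("mis0", "mis1", "mis2", "mis3",
                                            "no_hit"), 50, replace = TRUE)
    rt[[paste0(s, "_nhits")]] <- sample(0:5, 50, replace = TRUE)
  }
  hier <- hierarchy_spec(sets)
  rank <- function(x) match(x, c("mis0", "mis1", "mis2", "mis3", "no_hit"))
  for (policy in c("strict_hierarchy", "prefer_less_mismatch_within_class")) {
    got <- simplify_reanno(rt, hier, policy)
    for (i in 1:50) {
      strata <- vapply(sets, function(s) rt[[paste0(s, "_stratum")]][i], "")
      hit <- which(strata != "no_hit")
      want <- if (!length(hit)) "no_anno"
      else if (policy == "strict_hierarchy") sets[hit[1]]
      else sets[hit[which.min(rank(strata[hit]))]]
      expect_identical(got$resolved_class[i], want)
    }
  }
})

test_that("error-free reads annotate mis0 in their source pool", {
  pools <- list(
    source_pool("host", setNames(gen_references(91, 2, 200), c("h1", "h2")),
                lengths = 16:30),
    source_pool("microbe", setNames(gen_references(92, 2, 200), c("m1", "m2")),
                lengths = 16:30))
  mix <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("S1", c("host", "microbe")))
  spec <- sim_spec(pools, mix, n_reads_per_sample = 300, error_rate = 0,
                   seed = 93)
  sim <- simulate_fastq(spec, withr::local_tempdir())
  tr <- trim_fastq(sim$fastq[[1]], trim_params(spec$adapter))
  refs <- lapply(pools, function(p) reference_set(p$name, p$sequences))
  tab <- reanno(names(tr$inserts), refs, align_spec(0))
  truth <- tapply(sim$ground_truth$pool, sim$ground_truth$insert_seq,
                  function(x) x[1])
  for (i in seq_len(nrow(tab))) {
    src <- truth[[tab$seq[i]]]
    expect_equal(tab[[paste0(src, "_stratum")]][i], "mis0")
  }
})

test_that("false-positive fraction is non-decreasing in k", {
  ref <- reference_set("rand", setNames(rand_seqs(1, 3000, seed = 94), "g"))
  fp <- false_positive_curve(lengths = 9:11, ref = ref, k_values = 0:3,
                             n = 150, seed = 95)
  expect_true(all(diff(fp$fraction_hit) >= 0))
  # fractions match a brute-force recomputation on the same draws
  qs <- pacseq:::.with_seed(95, {
    L <- sample(9:11, 150, replace = TRUE)
    vapply(L, function(l) paste(sample(c("A", "C", "G", "T"), l,
                                       replace = TRUE), collapse = ""), "")
  })
  for (ki in 1:4) {
    k <- fp$k[ki]
    frac <- mean(vapply(qs, function(q)
      nrow(oracle_align(q, ref$records, k)) > 0, logical(1)))
    expect_equal(fp$fraction_hit[ki], frac)
  }
  expect_error(false_positive_curve(integer(0), ref), "empty")
})
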