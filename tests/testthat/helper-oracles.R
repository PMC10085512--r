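# Independent oracles, deliberately written as naive direct translations
# of the definitions, sharing no code with the implementation.

# Exhaustive position x overlap scan for the 3' adapter.
oracle_find_adapter <- function(read, adapter, mm_frac, min_overlap) {
  L <- nchar(read)
  rb <- strsplit(read, "")[[1]]
  ab <- strsplit(adapter, "")[[1]]
  for (p in 0:(L - 1)) {
    overlap <- min(L - p, length(ab))
    if (overlap < min_overlap) next
    mm <- sum(rb[(p + 1):(p + overlap)] != ab[1:overlap])
    if (mm <= floor(mm_frac * overlap)) return(p)
  }
  NA_integer_
}

# Sliding-window Hamming scan over every record and both strands.
oracle_align <- function(query, records, k, strands = "both") {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  out <- list()
  for (id in sort(names(records))) {
    ref <- records[[id]]
    W <- nchar(ref); L <- nchar(query)
    if (L > W) next
    refb <- strsplit(ref, "")[[1]]
    for (strand in if (strands == "both") c("+", "-") else "+") {
      q <- if (strand == "+") query else rc(query)
      qb <- strsplit(q, "")[[1]]
      for (s in 0:(W - L)) {
        mm <- sum(refb[(s + 1):(s + L)] != qb)
        if (mm <= k)
          out[[length(out) + 1]] <- data.frame(
            record_id = id, pos = s, strand = strand, mismatches = mm,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(record_id = character(0), pos = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$record_id, res$pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Dictionary-merge tally of per-sample sequence multisets.
oracle_counts <- function(insert_lists) {
  dict <- list()
  for (s in names(insert_lists)) {
    for (sq in insert_lists[[s]]) {
      if (is.null(dict[[sq]])) dict[[sq]] <- setNames(
        rep(0, length(insert_lists)), names(insert_lists))
      dict[[sq]][s] <- dict[[sq]][s] + 1
    }
  }
  if (!length(dict))
    return(matrix(0L, 0, length(insert_lists),
                  dimnames = list(NULL, names(insert_lists))))
  m <- do.call(rbind, dict)
  storage.mode(m) <- "integer"
  m
}

# tRF rule table, re-derived independently: decide each flag separately
# and look the label up in an explicit table.
oracle_trf_label <- function(start, end, ref_len, loop, tol = 0) {
  at5 <- start <= tol
  at3 <- end >= ref_len - tol
  cut5_in_loop <- end > loop[1] && end < loop[2]     # cleavage point of a
  cut3_in_loop <- start > loop[1] && start < loop[2] # 5'/3' fragment
  key <- paste(at5, at3)
  switch(key,
         "TRUE TRUE" = "whole-tRNA",
         "TRUE FALSE" = if (cut5_in_loop) "5p-half" else "5p-tRF",
         "FALSE TRUE" = if (cut3_in_loop) "3p-half" else "3p-tRF",
         "FALSE FALSE" = "i-tRF")
}

# A small deterministic PAC for structural tests.
toy_pac <- function(seed = 1, n_seq = 30, n_samples = 4) {
  set.seed(seed)
  seqs <- unique(replicate(n_seq, paste(
    sample(c("A", "C", "G", "T"), sample(16:30, 1), replace = TRUE),
    collapse = "")))
  counts <- matrix(rpois(length(seqs) * n_samples, 5) + 1L,
                   nrow = length(seqs),
                   dimnames = list(seqs, paste0("S", seq_len(n_samples))))
  storage.mode(counts) <- "integer"
  pheno <- data.frame(sample_id = colnames(counts),
                      group = rep(c("a", "b"), length.out = n_samples),
                      stringsAsFactors = FALSE)
  make_pac(pheno, counts)
}

rand_seqs <- function(n, lens, seed) {
  set.seed(seed)
  vapply(rep_len(lens, n), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}
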