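# Synthetic small-RNA read simulator with per-read ground truth.
#
# Emulates an sRNA library: short inserts drawn from one or more reference
# pools (e.g. host miRNA vs microbial RNA), sequenced with read-through
# into the 3' adapter, with optional substitution errors and a fraction of
# adapterless reads.  Every read carries a ground-truth record so trimming,
# counting and annotation can be verified exactly.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.random_dna <- function(n, lengths) {
  lengths <- rep_len(lengths, n)
  vapply(lengths, function(L)
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""), character(1))
}

#' Generate random reference sequences
#'
#' Draws i.i.d. uniform-random DNA strings, deterministically for a given
#' seed.  Used both to build synthetic reference pools and to generate the
#' completely randomized sequences of the false-positive alignment
#' experiment (see [false_positive_curve()]).
#'
#' @param seed Integer seed controlling all randomness.
#' @param n Number of sequences (>= 1).
#' @param length Length of each sequence in nt (>= 1), recycled to `n`.
#' @return Character vector of `n` DNA strings over \{A,C,G,T\}.
#' @examples
#' gen_references(seed = 1, n = 2, length = 8)
#' @export
gen_references <- function(seed, n, length) {
  seed <- .assert_scalar_int(seed, "seed")
  n <- .assert_scalar_int(n, "n", min = 1)
  if (any(length < 1)) stop("'length' must be >= 1", call. = FALSE)
  .with_seed(seed, .random_dna(n, as.integer(length)))
}

#' Define a source pool of reference sequences
#'
#' A pool is one "species" or feature database that simulated reads can
#' derive from: a set of reference sequences plus a distribution over
#' insert lengths.
#'
#' @param name Pool label (appears in the ground truth).
#' @param sequences Character vector of ACGT reference sequences; names are
#'   used as source ids (defaults to `name_1`, `name_2`, ...).
#' @param lengths Integer vector of possible insert lengths in nt
#'   (default 16:45, the typical sRNA range).
#' @param probs Optional probability per length (default uniform).
#' @return A `source_pool` object.
#' @export
source_pool <- function(name, sequences, lengths = 16:45, probs = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  .assert_dna(sequences, "sequences")
  if (is.null(names(sequences)))
    names(sequences) <- paste0(name, "_", seq_along(sequences))
  lengths <- as.integer(lengths)
  if (any(lengths < 1)) stop("insert lengths must be >= 1", call. = FALSE)
  if (max(lengths) > min(nchar(sequences)))
    stop("insert lengths exceed the shortest source sequence", call. = FALSE)
  if (!is.null(probs)) {
    stopifnot(length(probs) == length(lengths), all(probs >= 0), sum(probs) > 0)
    probs <- probs / sum(probs)
  }
  structure(list(name = name, sequences = sequences,
                 lengths = lengths, probs = probs),
            class = "source_pool")
}

#' Specify a simulated sequencing experiment
#'
#' @param pools List of [source_pool()] objects.
#' @param mixture Numeric matrix or data.frame, samples x pools (rownames =
#'   sample ids, colnames = pool names); each row must sum to 1.  A sample's
#'   reads are drawn from the pools with these probabilities, so a column of
#'   this table is the per-sample contamination fraction when one pool plays
#'   the contaminant.
#' @param n_reads_per_sample Reads per sample.
#' @param adapter 3' adapter sequence (default the Illumina TruSeq small-RNA
#'   adapter prefix `AGATCGGAAGAGC`).
#' @param error_rate Per-base substitution probability on the insert, in
#'   \[0,1).
#' @param seed Integer seed; identical specs give byte-identical FASTQ.
#' @param read_length Fixed read length in nt (default 50), with adapter
#'   read-through as in typical sRNA libraries.
#' @param adapterless_fraction Fraction of reads carrying no adapter at all
#'   (insert padded with random bases instead); exercises the trim policy
#'   that discards reads without adapter evidence.
#' @param phred Constant base quality (default 40).
#' @param random_quality If `TRUE`, qualities are drawn uniformly from
#'   2..`phred` per base instead of constant (for quality-filter tests).
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(pools, mixture, n_reads_per_sample,
                     adapter = "AGATCGGAAGAGC", error_rate = 0, seed = 1,
                     read_length = 50, adapterless_fraction = 0,
                     phred = 40, random_quality = FALSE) {
  if (inherits(pools, "source_pool")) pools <- list(pools)
  stopifnot(length(pools) >= 1, all(vapply(pools, inherits, TRUE, "source_pool")))
  pool_names <- vapply(pools, `[[`, character(1), "name")
  if (anyDuplicated(pool_names)) stop("pool names must be unique", call. = FALSE)
  mixture <- as.matrix(mixture)
  if (is.null(rownames(mixture)) || is.null(colnames(mixture)))
    stop("'mixture' needs sample rownames and pool colnames", call. = FALSE)
  if (!setequal(colnames(mixture), pool_names))
    stop("mixture columns must match pool names", call. = FALSE)
  mixture <- mixture[, pool_names, drop = FALSE]
  if (any(mixture < 0) || any(mixture > 1) ||
      any(abs(rowSums(mixture) - 1) > 1e-8))
    stop("mixture fractions must lie in [0,1] and sum to 1 per sample",
         call. = FALSE)
  .assert_dna(adapter, "adapter")
  stopifnot(error_rate >= 0, error_rate < 1,
            adapterless_fraction >= 0, adapterless_fraction <= 1)
  n_reads_per_sample <- .assert_scalar_int(n_reads_per_sample,
                                           "n_reads_per_sample", min = 1)
  read_length <- .assert_scalar_int(read_length, "read_length", min = 1)
  structure(list(pools = setNames(pools, pool_names), mixture = mixture,
                 n_reads_per_sample = n_reads_per_sample, adapter = adapter,
                 error_rate = error_rate, seed = .assert_scalar_int(seed, "seed"),
                 read_length = read_length,
                 adapterless_fraction = adapterless_fraction,
                 phred = .assert_scalar_int(phred, "phred", min = 2),
                 random_quality = isTRUE(random_quality)),
            class = "sim_spec")
}

.mutate_seq <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- runif(length(b)) < error_rate
    if (any(hit))
      b[hit] <- vapply(b[hit], function(orig)
        sample(setdiff(DNA_BASES, orig), 1L), character(1))
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate FASTQ files with ground truth
#'
#' Writes one 4-line FASTQ per sample.  Each read is an insert (a random
#' slice of a source sequence from a pool chosen by the sample's mixture,
#' with substitution errors applied at `error_rate`) followed by as much of
#' the 3' adapter as fits the read length; adapterless reads are padded
#' with random bases instead.  Output is byte-identical for identical
#' specs.
#'
#' @param spec A [sim_spec()] object.
#' @param out_dir Directory for the FASTQ files (created if needed).
#' @param gzip Write gzip-compressed FASTQ (default `FALSE`).
#' @return List with `fastq` (named vector of file paths per sample),
#'   `ground_truth` (data.frame: read_id, sample, pool, source_id,
#'   insert_start, insert_end 0-based half-open on the source, insert_seq =
#'   the true error-free insert, has_adapter), and the `spec`.
#' @export
simulate_fastq <- function(spec, out_dir, gzip = FALSE) {
  stopifnot(inherits(spec, "sim_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- rownames(spec$mixture)
  .with_seed(spec$seed, {
    gt <- vector("list", length(samples))
    paths <- setNames(character(length(samples)), samples)
    for (si in seq_along(samples)) {
      smp <- samples[si]
      n <- spec$n_reads_per_sample
      pool_idx <- sample.int(length(spec$pools), n, replace = TRUE,
                             prob = spec$mixture[smp, ])
      ins_len <- integer(n); src_id <- character(n)
      ins_start <- integer(n); true_ins <- character(n)
      for (i in seq_len(n)) {
        pool <- spec$pools[[pool_idx[i]]]
        L <- if (length(pool$lengths) == 1L) pool$lengths else
          sample(pool$lengths, 1L, prob = pool$probs)
        j <- sample.int(length(pool$sequences), 1L)
        src <- pool$sequences[[j]]
        s0 <- sample.int(nchar(src) - L + 1L, 1L) - 1L   # 0-based
        ins_len[i] <- L; src_id[i] <- names(pool$sequences)[j]
        ins_start[i] <- s0
        true_ins[i] <- substr(src, s0 + 1L, s0 + L)
      }
      seq_ins <- .mutate_seq(true_ins, spec$error_rate)
      has_ad <- runif(n) >= spec$adapterless_fraction
      reads <- character(n)
      for (i in seq_len(n)) {
        ins <- substr(seq_ins[i], 1L, min(ins_len[i], spec$read_length))
        fill_n <- spec$read_length - nchar(ins)
        tail_seq <- if (fill_n <= 0L) "" else if (has_ad[i])
          substr(spec$adapter, 1L, fill_n) else ""
        reads[i] <- paste0(ins, tail_seq)
        pad <- spec$read_length - nchar(reads[i])
        if (pad > 0L)  # adapter shorter than read-through, or adapterless
          reads[i] <- paste0(reads[i], paste(sample(DNA_BASES, pad,
                                                    replace = TRUE),
                                             collapse = ""))
      }
      quals <- if (spec$random_quality)
        vapply(seq_len(n), function(i)
          intToUtf8(33L + sample(2:spec$phred, spec$read_length,
                                 replace = TRUE)), character(1))
      else rep(strrep(intToUtf8(33L + spec$phred), spec$read_length), n)
      ids <- sprintf("%s_r%06d", smp, seq_len(n))
      dna <- Biostrings::DNAStringSet(reads)
      names(dna) <- ids
      path <- file.path(out_dir, paste0(smp, ".fastq", if (gzip) ".gz"))
      Biostrings::writeXStringSet(dna, path, format = "fastq",
                                  qualities = Biostrings::BStringSet(quals),
                                  compress = gzip)
      paths[smp] <- path
      gt[[si]] <- data.frame(
        read_id = ids, sample = smp,
        pool = names(spec$pools)[pool_idx], source_id = src_id,
        insert_start = ins_start, insert_end = ins_start + ins_len,
        insert_seq = true_ins, has_adapter = has_ad,
        stringsAsFactors = FALSE)
    }
    list(fastq = paths, ground_truth = do.call(rbind, gt), spec = spec)
  })
}

#' Write a ground-truth table to TSV
#' @param ground_truth Data frame from [simulate_fastq()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  write.table(ground_truth, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Generate a toy tRNA model
#'
#' Produces a random tRNA-like reference sequence with recorded
#' anticodon-loop coordinates, as a fixture for fragment classification.
#' The loop interval is on the body (the mature tRNA without CCA); when
#' `cca = TRUE` the classification reference is the body plus the
#' post-transcriptional 3' CCA.
#'
#' @param seed Integer seed.
#' @param body_len Body length in nt (default 76, a canonical tRNA).
#' @param loop 0-based half-open anticodon-loop interval on the body
#'   (default `c(31, 38)`, the canonical 7-nt loop).
#' @param cca Append CCA to the reference (default `TRUE`).
#' @param id Model identifier.
#' @return A [trna_model()] object.
#' @export
gen_trna_model <- function(seed, body_len = 76, loop = c(31, 38),
                           cca = TRUE, id = "tRNA_toy") {
  body_len <- .assert_scalar_int(body_len, "body_len", min = 1)
  body <- .with_seed(seed, .random_dna(1L, body_len))
  trna_model(id = id, body = body, loop = loop, cca = cca)
}
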