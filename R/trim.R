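# Mismatch-tolerant 3' adapter trimming.
#
# The adapter is searched as a prefix-overlap at every read position:
# the leftmost position whose overlap with the adapter start is at least
# `min_overlap` nt and mismatches at most floor(max_mismatch_fraction *
# overlap) wins.  No indels: substitution-only matching mirrors the error
# model of short-read sRNA data.  In sRNA libraries detection of the
# adapter is evidence that the full insert was sequenced, so reads without
# adapter are discarded by default.

#' Trimming parameters
#'
#' @param adapter 3' adapter sequence (ACGT).
#' @param max_mismatch_fraction Fraction of compared adapter bases allowed
#'   to mismatch (default 0.1; must be < 0.5).
#' @param min_overlap Minimum nt of adapter that must be visible at the
#'   read 3' end for a partial match (default 10).
#' @param size_range Inclusive insert length range kept, in nt (default
#'   `c(16, 75)`; mature sRNA targets seldom exceed 75 nt).
#' @param policy_no_adapter `"discard"` (default) or `"keep"`: what to do
#'   with reads in which no adapter is found.  Discarding is the safe
#'   default for sRNA libraries, where absence of adapter means the insert
#'   end was not reached.
#' @param max_N Maximum number of ambiguous `N` bases allowed in the
#'   retained insert (default 0).
#' @param min_mean_quality Minimum arithmetic mean Phred score over the
#'   retained insert, or `NULL` (default) to skip the quality filter.
#' @return A `trim_params` object.
#' @export
trim_params <- function(adapter, max_mismatch_fraction = 0.1,
                        min_overlap = 10, size_range = c(16, 75),
                        policy_no_adapter = c("discard", "keep"),
                        max_N = 0, min_mean_quality = NULL) {
  .assert_dna(adapter, "adapter")
  stopifnot(length(adapter) == 1L)
  if (max_mismatch_fraction < 0 || max_mismatch_fraction >= 0.5)
    stop("max_mismatch_fraction must be in [0, 0.5)", call. = FALSE)
  min_overlap <- .assert_scalar_int(min_overlap, "min_overlap", min = 1)
  if (min_overlap > nchar(adapter))
    stop("min_overlap exceeds adapter length", call. = FALSE)
  stopifnot(length(size_range) == 2L, size_range[1] <= size_range[2])
  policy_no_adapter <- match.arg(policy_no_adapter)
  structure(list(adapter = adapter,
                 max_mismatch_fraction = max_mismatch_fraction,
                 min_overlap = min_overlap,
                 size_range = as.integer(size_range),
                 policy_no_adapter = policy_no_adapter,
                 max_N = .assert_scalar_int(max_N, "max_N", min = 0),
                 min_mean_quality = min_mean_quality),
            class = "trim_params")
}

# Vectorised adapter search over reads of arbitrary length.  Returns the
# 0-based adapter start per read, or NA when no position qualifies.
.find_adapter_batch <- function(reads, params) {
  n <- length(reads)
  out <- rep(NA_integer_, n)
  if (n == 0L) return(out)
  ad <- strsplit(params$adapter, "", fixed = TRUE)[[1L]]
  alen <- length(ad)
  lens <- nchar(reads)
  for (L in sort(unique(lens))) {
    idx <- which(lens == L)
    if (L < params$min_overlap) next
    mat <- matrix(unlist(strsplit(reads[idx], "", fixed = TRUE),
                         use.names = FALSE), nrow = length(idx), byrow = TRUE)
    pos <- rep(NA_integer_, length(idx))
    undecided <- seq_along(idx)
    for (p in 0:(L - params$min_overlap)) {
      ov <- min(L - p, alen)
      allowed <- floor(params$max_mismatch_fraction * ov)
      cols <- (p + 1L):(p + ov)
      mm <- rowSums(mat[undecided, cols, drop = FALSE] !=
                      matrix(ad[seq_len(ov)], nrow = length(undecided),
                             ncol = ov, byrow = TRUE))
      hit <- mm <= allowed
      pos[undecided[hit]] <- p
      undecided <- undecided[!hit]
      if (!length(undecided)) break
    }
    out[idx] <- pos
  }
  out
}

#' Locate the 3' adapter in a read
#'
#' Returns the leftmost 0-based position `p` such that `read[p..]` matches
#' a prefix of the adapter with overlap of at least `min_overlap` nt and at
#' most `floor(max_mismatch_fraction * overlap)` mismatches, or `NA` if no
#' position qualifies.  `p = 0` means the insert is empty (adapter dimer).
#'
#' @param read A single read sequence (or character vector of reads).
#' @param params A [trim_params()] object.
#' @return Integer 0-based adapter start per read; `NA` when absent.
#' @examples
#' p <- trim_params("AGATCGGAAGAGC")
#' find_adapter(paste0(strrep("ACGT", 5), "AGATCGGAAGAGC"), p)  # 20
#' @export
find_adapter <- function(read, params) {
  stopifnot(inherits(params, "trim_params"))
  if (!is.character(read) || !length(read) || any(!nzchar(read)))
    stop("'read' must be one or more non-empty strings", call. = FALSE)
  .find_adapter_batch(toupper(read), params)
}

.TRIM_REASONS <- c("no_adapter", "size", "N", "quality")

# Vectorised core shared by trim_read and trim_fastq.  Returns a list with
# insert (NA when discarded) and reason ("retained" or a discard category).
.trim_batch <- function(reads, quals, params) {
  reads <- toupper(reads)
  n <- length(reads)
  pos <- .find_adapter_batch(reads, params)
  insert <- ifelse(is.na(pos), reads, substr(reads, 1L, pos))
  reason <- rep("retained", n)
  no_ad <- is.na(pos)
  if (params$policy_no_adapter == "discard") reason[no_ad] <- "no_adapter"
  live <- reason == "retained"
  ilen <- nchar(insert)
  bad_size <- live & (ilen < params$size_range[1] | ilen > params$size_range[2])
  reason[bad_size] <- "size"
  live <- reason == "retained"
  n_count <- nchar(insert) - nchar(gsub("N", "", insert, fixed = TRUE))
  bad_n <- live & n_count > params$max_N
  reason[bad_n] <- "N"
  live <- reason == "retained"
  if (!is.null(params$min_mean_quality) && any(live)) {
    mean_q <- vapply(which(live), function(i) {
      q <- utf8ToInt(substr(quals[i], 1L, nchar(insert[i]))) - 33L
      mean(q)
    }, numeric(1))
    bad_q <- which(live)[mean_q < params$min_mean_quality]
    reason[bad_q] <- "quality"
  }
  insert[reason != "retained"] <- NA_character_
  list(insert = insert, reason = reason)
}

#' Trim a single read
#'
#' Cuts the read at the adapter and applies, in order: the no-adapter
#' policy, the insert size range, the ambiguous-base limit and the mean
#' quality threshold.  Exactly one outcome is reported.
#'
#' @param read Read sequence.
#' @param quality Phred+33 quality string of the same length, or `NULL`
#'   when no quality filter is used.
#' @param params A [trim_params()] object.
#' @return List with `insert` (the retained sequence or `NA`) and `reason`
#'   (`"retained"`, `"no_adapter"`, `"size"`, `"N"` or `"quality"`).
#' @export
trim_read <- function(read, quality = NULL, params) {
  stopifnot(is.character(read), length(read) == 1L, nzchar(read))
  if (is.null(quality)) quality <- strrep("I", nchar(read))
  if (nchar(quality) != nchar(read))
    stop("read and quality have different lengths", call. = FALSE)
  res <- .trim_batch(read, quality, params)
  list(insert = res$insert[[1L]], reason = res$reason[[1L]])
}

# Locate the offending record so parse errors are actionable.
.diagnose_fastq <- function(path, orig_msg) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- tryCatch(readLines(con, warn = FALSE), finally = close(con))
  nrec <- length(lines) %/% 4L
  for (i in seq_len(nrec + 1L)) {
    lo <- 4L * (i - 1L) + 1L
    if (lo > length(lines)) break
    block <- lines[lo:min(4L * i, length(lines))]
    if (length(block) < 4L || is.na(block[1L]) ||
        !startsWith(block[1L], "@") || !startsWith(block[3L], "+") ||
        nchar(block[2L]) != nchar(block[4L]))
      stop(sprintf("malformed FASTQ record %d in %s", i, path),
           call. = FALSE)
  }
  stop(sprintf("cannot parse FASTQ file %s: %s", path, orig_msg),
       call. = FALSE)
}

.read_fastq <- function(path) {
  res <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(reads = as.character(x),
         quals = as.character(S4Vectors::mcols(x)$qualities))
  }, error = function(e) .diagnose_fastq(path, conditionMessage(e)))
  # Biostrings does not always reject truncated quality strings.
  if (any(nchar(res$reads) != nchar(res$quals)))
    .diagnose_fastq(path, "sequence/quality length mismatch")
  res
}

#' Trim a FASTQ file
#'
#' Applies [trim_read()] to every record of a (possibly gzipped) FASTQ
#' file and tallies the outcome per category.
#'
#' @param path FASTQ file path.
#' @param params A [trim_params()] object.
#' @param sample Sample label used in the report (default: file base name).
#' @return List with `inserts` (named integer vector: retained insert
#'   sequence -> multiplicity) and `report` (one-row data.frame: reads_in,
#'   reads_with_adapter, reads_discarded_no_adapter, reads_discarded_size,
#'   reads_discarded_N, reads_discarded_quality, reads_retained).  The
#'   categories always partition `reads_in`.
#' @export
trim_fastq <- function(path, params, sample = NULL) {
  stopifnot(inherits(params, "trim_params"))
  if (is.null(sample))
    sample <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  fq <- .read_fastq(path)
  res <- .trim_batch(fq$reads, fq$quals, params)
  kept <- res$insert[res$reason == "retained"]
  inserts <- if (length(kept)) {
    tab <- table(kept)
    setNames(as.integer(tab), names(tab))
  } else setNames(integer(0), character(0))
  with_ad <- sum(!is.na(.find_adapter_batch(toupper(fq$reads), params)))
  tally <- function(r) sum(res$reason == r)
  report <- data.frame(
    sample = sample,
    reads_in = length(fq$reads),
    reads_with_adapter = with_ad,
    reads_discarded_no_adapter = tally("no_adapter"),
    reads_discarded_size = tally("size"),
    reads_discarded_N = tally("N"),
    reads_discarded_quality = tally("quality"),
    reads_retained = tally("retained"),
    stringsAsFactors = FALSE)
  list(inserts = inserts, report = report)
}

#' Trim several FASTQ files
#'
#' @param paths Named character vector of FASTQ paths; names are sample
#'   ids (default: file base names).
#' @param params A [trim_params()] object.
#' @return List with `inserts` (named list of per-sample insert multisets)
#'   and `report` (data.frame with one row per sample).
#' @export
trim_samples <- function(paths, params) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(paths))
  res <- lapply(names(paths), function(s)
    trim_fastq(paths[[s]], params, sample = s))
  list(inserts = setNames(lapply(res, `[[`, "inserts"), names(paths)),
       report = do.call(rbind, lapply(res, `[[`, "report")))
}
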