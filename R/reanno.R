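# Hierarchical multi-reference annotation with mismatch strata.
#
# Each unique sequence of a count table is aligned end-to-end (ungapped,
# Hamming distance <= k, both strands) against an ordered set of reference
# FASTA sets.  Per reference set the minimal mismatch stratum (mis0..mis3
# or no_hit) is recorded; a user-declared hierarchy then resolves one
# class per sequence.  All hits are retained at the alignment level —
# multimapping is resolved only at class level, never by arbitrarily
# picking one locus.

#' A named reference sequence set
#'
#' @param name Set label (e.g. `"miRNA"`, `"tRNA"`, `"bacteria"`).
#' @param records Named character vector of ACGT sequences, or a path to a
#'   (multi-record) FASTA file.
#' @return A `reference_set` object.
#' @export
reference_set <- function(name, records) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(records) == 1L && file.exists(records) &&
      grepl("\\.(fa|fasta|fna)(\\.gz)?$", records, ignore.case = TRUE)) {
    x <- Biostrings::readDNAStringSet(records)
    records <- setNames(as.character(x),
                        sub("\\s.*$", "", names(x)))
  }
  if (is.null(names(records)) || anyDuplicated(names(records)))
    stop("reference records must have unique ids", call. = FALSE)
  records <- toupper(records)
  if (any(!nzchar(records)))
    stop("empty reference sequence in set ", name, call. = FALSE)
  .assert_dna(records, sprintf("records of set '%s'", name))
  dna <- Biostrings::DNAStringSet(records)   # parsed once, reused per query
  structure(list(name = name, records = records, dna = dna),
            class = "reference_set")
}

#' Alignment parameters
#'
#' @param max_mismatch Maximum Hamming distance k, 0..3 (default 0).
#'   Capped at 3: the false-positive alignment rate grows rapidly with k
#'   (see [false_positive_curve()]), so larger values are not offered.
#' @param strands `"both"` (default) or `"forward"`.
#' @return An `align_spec` object.
#' @export
align_spec <- function(max_mismatch = 0, strands = c("both", "forward")) {
  max_mismatch <- .assert_scalar_int(max_mismatch, "max_mismatch", min = 0)
  if (max_mismatch > 3)
    stop("max_mismatch must be <= 3", call. = FALSE)
  structure(list(max_mismatch = max_mismatch,
                 strands = match.arg(strands)),
            class = "align_spec")
}

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# All end-to-end placements of `query` on one reference string with
# Hamming distance <= k.  Returns 0-based start positions and mismatch
# counts on the forward strand of the reference.
.match_one <- function(query_dna, subject_dna, k) {
  hits <- Biostrings::matchPattern(query_dna, subject_dna,
                                   max.mismatch = k, with.indels = FALSE)
  st <- IRanges::start(hits)
  # matchPattern can report out-of-bounds starts when min.mismatch tricks
  # are used; with defaults all hits are in-bounds, but guard anyway.
  ok <- st >= 1L & IRanges::end(hits) <= length(subject_dna)
  st <- st[ok]
  if (!length(st)) return(list(pos = integer(0), mm = integer(0)))
  mm <- Biostrings::neditStartingAt(query_dna, subject_dna, starting.at = st)
  list(pos = st - 1L, mm = as.integer(mm))
}

#' Ungapped k-mismatch alignment of one query against a reference set
#'
#' Reports every end-to-end placement of the query (and, for `"both"`
#' strands, of its reverse complement) on each reference record with at
#' most `max_mismatch` substitutions.  No indels.  Minus-strand hits are
#' reported at forward-strand coordinates.  Output order is deterministic:
#' by record id, then position, then strand (`+` before `-`).
#'
#' @param query A single ACGT sequence.
#' @param ref A [reference_set()].
#' @param spec An [align_spec()].
#' @return Data frame with columns `query`, `ref_set`, `record_id`, `pos`
#'   (0-based start on the forward strand), `strand`, `mismatches`; zero
#'   rows when the query does not place.
#' @export
align_k_mismatch <- function(query, ref, spec = align_spec()) {
  stopifnot(inherits(ref, "reference_set"), inherits(spec, "align_spec"))
  if (!is.character(query) || length(query) != 1L || !nzchar(query))
    stop("'query' must be a single non-empty string", call. = FALSE)
  query <- toupper(query)
  .assert_dna(query, "query")
  qd <- Biostrings::DNAString(query)
  rc <- Biostrings::reverseComplement(qd)
  out <- list()
  for (id in names(ref$records)) {
    subj <- ref$dna[[id]]
    if (nchar(query) > length(subj)) next
    fwd <- .match_one(qd, subj, spec$max_mismatch)
    hit_rows <- function(h, strand)
      data.frame(query = rep(query, length(h$pos)),
                 ref_set = rep(ref$name, length(h$pos)),
                 record_id = rep(id, length(h$pos)),
                 pos = h$pos, strand = rep(strand, length(h$pos)),
                 mismatches = h$mm, stringsAsFactors = FALSE)
    rows <- hit_rows(fwd, "+")
    if (spec$strands == "both") {
      rev <- .match_one(rc, subj, spec$max_mismatch)
      rows <- rbind(rows, hit_rows(rev, "-"))
    }
    if (nrow(rows))
      out[[id]] <- rows[order(rows$pos, rows$strand), , drop = FALSE]
  }
  if (!length(out))
    return(data.frame(query = character(0), ref_set = character(0),
                      record_id = character(0), pos = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out[order(names(out))])
  rownames(res) <- NULL
  res
}

.STRATA <- c("mis0", "mis1", "mis2", "mis3", "no_hit")

#' Annotate sequences against multiple reference sets
#'
#' For every sequence and reference set, records the minimal mismatch
#' stratum (`mis0`..`mis3`, or `no_hit` when the sequence does not place
#' within `max_mismatch`) and the number of placements at that stratum.
#'
#' @param sequences Character vector of unique ACGT sequences (e.g. the
#'   Anno keys of a PAC object).
#' @param refs List of [reference_set()] objects (>= 1).
#' @param spec An [align_spec()].
#' @return Data frame with a `seq` column plus, per set,
#'   `<set>_stratum` and `<set>_nhits`.
#' @export
reanno <- function(sequences, refs, spec = align_spec()) {
  if (inherits(refs, "reference_set")) refs <- list(refs)
  stopifnot(length(refs) >= 1,
            all(vapply(refs, inherits, TRUE, "reference_set")),
            inherits(spec, "align_spec"))
  set_names <- vapply(refs, `[[`, character(1), "name")
  if (anyDuplicated(set_names))
    stop("reference set names must be unique", call. = FALSE)
  sequences <- as.character(sequences)
  if (length(sequences)) .assert_dna(sequences, "sequences")
  out <- data.frame(seq = sequences, stringsAsFactors = FALSE)
  for (r in refs) {
    strat <- rep("no_hit", length(sequences))
    nh <- integer(length(sequences))
    # Perfect matches first, batched through PDict (one scan per record
    # and length group); only sequences without a perfect match fall back
    # to the per-query scan at k >= 1.
    exact <- .count_exact_hits(sequences, r, spec$strands)
    hit0 <- exact > 0L
    strat[hit0] <- "mis0"
    nh[hit0] <- exact[hit0]
    if (spec$max_mismatch > 0L) {
      for (i in which(!hit0)) {
        hits <- align_k_mismatch(sequences[i], r, spec)
        if (nrow(hits)) {
          best <- min(hits$mismatches)
          strat[i] <- paste0("mis", best)
          nh[i] <- sum(hits$mismatches == best)
        }
      }
    }
    out[[paste0(r$name, "_stratum")]] <- strat
    out[[paste0(r$name, "_nhits")]] <- nh
  }
  out
}

# Total number of perfect (0-mismatch) placements of each sequence on a
# reference set via PDict batch matching.
.count_exact_hits <- function(sequences, ref, strands = "both") {
  counts <- integer(length(sequences))
  lens <- nchar(sequences)
  max_rec <- max(Biostrings::width(ref$dna))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (L > max_rec) next
    fwd <- Biostrings::DNAStringSet(sequences[idx])
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- if (strands == "both")
      Biostrings::PDict(Biostrings::reverseComplement(fwd)) else NULL
    for (j in seq_along(ref$dna)) {
      subj <- ref$dna[[j]]
      if (L > length(subj)) next
      counts[idx] <- counts[idx] +
        as.integer(Biostrings::countPDict(pd_f, subj))
      if (!is.null(pd_r))
        counts[idx] <- counts[idx] +
          as.integer(Biostrings::countPDict(pd_r, subj))
    }
  }
  counts
}

#' Hierarchy of sequence classes
#'
#' An ordered priority list mapping class labels to reference set names.
#' When a sequence hits several reference sets, the first class in the
#' list wins; sequences hitting nothing become the fallback class.
#'
#' @param classes Named list: class label -> character vector of reference
#'   set name(s), in priority order; or a character vector of set names
#'   (each set its own class).
#' @param fallback Label for unresolved sequences (default `"no_anno"`).
#' @return A `hierarchy_spec` object.
#' @export
hierarchy_spec <- function(classes, fallback = "no_anno") {
  if (is.character(classes))
    classes <- setNames(as.list(classes), classes)
  stopifnot(is.list(classes), length(classes) >= 1,
            !is.null(names(classes)), all(nzchar(names(classes))))
  structure(list(classes = classes, fallback = fallback),
            class = "hierarchy_spec")
}

.stratum_rank <- function(x) match(x, .STRATA)  # no_hit ranks last

#' Resolve one class per sequence from a reannotation table
#'
#' `strict_hierarchy` (default): the first class in the hierarchy whose
#' reference sets show any hit wins, annotated with the best stratum among
#' them.  `prefer_less_mismatch_within_class`: the class achieving the
#' minimal mismatch stratum wins, with hierarchy order breaking ties.
#'
#' @param table A reannotation data.frame from [reanno()].
#' @param hierarchy A [hierarchy_spec()].
#' @param mismatch_policy `"strict_hierarchy"` or
#'   `"prefer_less_mismatch_within_class"`.
#' @return The input table with `resolved_class` and `resolved_stratum`
#'   columns appended.
#' @export
simplify_reanno <- function(table, hierarchy,
                            mismatch_policy = c("strict_hierarchy",
                                                "prefer_less_mismatch_within_class")) {
  stopifnot(is.data.frame(table), inherits(hierarchy, "hierarchy_spec"))
  mismatch_policy <- match.arg(mismatch_policy)
  all_sets <- unique(unlist(hierarchy$classes, use.names = FALSE))
  cols <- paste0(all_sets, "_stratum")
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("hierarchy names reference sets absent from the table: ",
         paste(sub("_stratum$", "", missing), collapse = ", "),
         call. = FALSE)
  n <- nrow(table)
  # Best stratum rank per class (min over the class's reference sets).
  class_rank <- vapply(hierarchy$classes, function(sets) {
    ranks <- vapply(sets, function(s)
      .stratum_rank(table[[paste0(s, "_stratum")]]), integer(n))
    if (n == 1L) min(ranks) else apply(matrix(ranks, nrow = n), 1L, min)
  }, integer(n))
  class_rank <- matrix(class_rank, nrow = n,
                       dimnames = list(NULL, names(hierarchy$classes)))
  no_hit_rank <- .stratum_rank("no_hit")
  resolved <- rep(hierarchy$fallback, n)
  stratum <- rep("no_hit", n)
  for (i in seq_len(n)) {
    ranks <- class_rank[i, ]
    hit <- which(ranks < no_hit_rank)
    if (!length(hit)) next
    pick <- if (mismatch_policy == "strict_hierarchy") hit[1L]
            else hit[which.min(ranks[hit])]   # ties: earliest in hierarchy
    resolved[i] <- names(hierarchy$classes)[pick]
    stratum[i] <- .STRATA[ranks[pick]]
  }
  table$resolved_class <- resolved
  table$resolved_stratum <- stratum
  table
}

#' False-positive alignment rate as a function of allowed mismatches
#'
#' Draws completely randomized sequences with a given empirical length
#' distribution, aligns them against a reference, and reports the fraction
#' that place at all for each allowed mismatch number k, plus the ratio to
#' the perfect-mapping (k = 0) rate.  Because the hit set at k is a subset
#' of the hit set at k + 1, the fraction is non-decreasing in k: allowing
#' more mismatches can only inflate the false-positive alignment rate.
#'
#' @param lengths Integer vector: the empirical insert-length distribution
#'   to sample from (with replacement).
#' @param ref A [reference_set()].
#' @param k_values Mismatch numbers to evaluate (subset of 0:3).
#' @param n Number of random sequences (>= 1).
#' @param seed Integer seed.
#' @param strands Passed to [align_spec()].
#' @return Data frame with columns `k`, `fraction_hit`, `ratio_vs_k0`
#'   (NA when the k = 0 fraction is zero).
#' @export
false_positive_curve <- function(lengths, ref, k_values = 0:3, n = 1000,
                                 seed = 1, strands = "both") {
  if (!length(lengths)) stop("empty length distribution", call. = FALSE)
  n <- .assert_scalar_int(n, "n", min = 1)
  k_values <- sort(unique(as.integer(k_values)))
  stopifnot(all(k_values >= 0), all(k_values <= 3))
  qs <- .with_seed(seed, {
    L <- if (length(lengths) == 1L) rep(lengths, n)
         else sample(as.integer(lengths), n, replace = TRUE)
    .random_dna(n, L)
  })
  kmax <- max(k_values)
  spec <- align_spec(kmax, strands)
  # One scan at kmax per query; the best stratum determines all k at once.
  best <- vapply(qs, function(q) {
    hits <- align_k_mismatch(q, ref, spec)
    if (nrow(hits)) min(hits$mismatches) else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
  frac <- vapply(k_values, function(k)
    mean(!is.na(best) & best <= k), numeric(1))
  f0 <- if (0 %in% k_values) frac[k_values == 0] else NA_real_
  data.frame(k = k_values, fraction_hit = frac,
             ratio_vs_k0 = if (!is.na(f0) && f0 > 0) frac / f0
                           else rep(NA_real_, length(k_values)))
}
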