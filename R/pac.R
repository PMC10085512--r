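# The PAC object: Pheno / Anno / Counts.
#
# Three aligned tables keyed by exact read sequence: Pheno (one row per
# sample), Anno (one row per unique sequence), Counts (sequence x sample
# integers).  Row keys of Counts equal the Anno keys in the same order;
# column keys equal the Pheno sample ids in the same order.  Every
# operation that returns a PAC re-establishes these invariants, so the
# count table can be re-annotated, filtered and summarised at any time
# without losing the link back to the raw reads.

#' Evidence filter for count-table construction
#'
#' A sequence enters the count table only if it reaches `min_count` reads
#' in at least `min_samples` distinct samples.  The defaults (2 reads in 2
#' samples) are a conservative noise filter; `evidence_filter(1, 1)` keeps
#' every observed sequence.
#'
#' @param min_count Minimum count per qualifying sample (>= 1).
#' @param min_samples Minimum number of qualifying samples (>= 1).
#' @return An `evidence_filter` object.
#' @export
evidence_filter <- function(min_count = 2, min_samples = 2) {
  structure(list(min_count = .assert_scalar_int(min_count, "min_count", 1),
                 min_samples = .assert_scalar_int(min_samples, "min_samples", 1)),
            class = "evidence_filter")
}

.as_multiset <- function(x) {
  # Accept either a character vector with repeats or a named count vector.
  if (is.character(x)) {
    tab <- table(x)
    setNames(as.integer(tab), names(tab))
  } else {
    stopifnot(!is.null(names(x)), all(x >= 0), all(x == as.integer(x)))
    setNames(as.integer(x), names(x))
  }
}

#' Build the count table of unique sequences
#'
#' Tallies identical sequences across samples into an integer matrix,
#' applies the evidence filter, and orders rows deterministically
#' (descending total count, ties broken lexicographically by sequence).
#'
#' @param inserts Named list, one element per sample: either a character
#'   vector of retained insert sequences (repeats = multiplicity) or a
#'   named integer vector of sequence -> count (as from [trim_fastq()]).
#' @param filter An [evidence_filter()]; default `evidence_filter(2, 2)`.
#' @return Integer matrix, rows = sequences, columns = samples.
#' @export
make_counts <- function(inserts, filter = evidence_filter()) {
  stopifnot(is.list(inserts), length(inserts) >= 1,
            inherits(filter, "evidence_filter"))
  if (is.null(names(inserts)) || any(!nzchar(names(inserts))))
    stop("'inserts' must be named by sample id", call. = FALSE)
  if (anyDuplicated(names(inserts)))
    stop("duplicate sample ids in 'inserts'", call. = FALSE)
  tabs <- lapply(inserts, .as_multiset)
  seqs <- sort(unique(unlist(lapply(tabs, names), use.names = FALSE)))
  m <- matrix(0L, nrow = length(seqs), ncol = length(tabs),
              dimnames = list(seqs, names(inserts)))
  for (j in seq_along(tabs))
    m[names(tabs[[j]]), j] <- tabs[[j]]
  keep <- rowSums(m >= filter$min_count) >= filter$min_samples
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(m)
  ord <- order(-rowSums(m), rownames(m), method = "radix")
  m[ord, , drop = FALSE]
}

#' Assemble a PAC object
#'
#' Aligns the Pheno table with the count matrix (Pheno may list extra
#' samples; its rows are permuted and subset to the count columns) and
#' creates the Anno table with the sequence-length column.
#'
#' @param pheno Data frame with a unique, non-empty `sample_id` column plus
#'   arbitrary metadata columns.
#' @param counts Integer matrix from [make_counts()] (rows = sequences,
#'   columns = samples).
#' @param anno Optional pre-built annotation data.frame with a `seq` column
#'   covering all count rows; by default a fresh Anno with `seq` and
#'   `length` is created.
#' @return A `PAC` object: `list(pheno, anno, counts)`.
#' @export
make_pac <- function(pheno, counts, anno = NULL) {
  pheno <- as.data.frame(pheno, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(pheno))
    stop("'pheno' must have a sample_id column", call. = FALSE)
  if (anyDuplicated(pheno$sample_id) || any(!nzchar(pheno$sample_id)))
    stop("sample_id must be unique and non-empty", call. = FALSE)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  missing <- setdiff(colnames(counts), pheno$sample_id)
  if (length(missing))
    stop("count columns missing from pheno: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pheno <- pheno[match(colnames(counts), pheno$sample_id), , drop = FALSE]
  rownames(pheno) <- pheno$sample_id
  if (is.null(anno)) {
    anno <- data.frame(seq = rownames(counts),
                       length = nchar(rownames(counts)),
                       stringsAsFactors = FALSE)
  } else {
    anno <- as.data.frame(anno, stringsAsFactors = FALSE)
    if (!"seq" %in% names(anno) || !all(rownames(counts) %in% anno$seq))
      stop("'anno' must have a seq column covering all count rows",
           call. = FALSE)
    anno <- anno[match(rownames(counts), anno$seq), , drop = FALSE]
  }
  rownames(anno) <- anno$seq
  structure(list(pheno = pheno, anno = anno, counts = counts),
            class = "PAC")
}

#' @export
print.PAC <- function(x, ...) {
  cat(sprintf("PAC object: %d sequences x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  pheno columns:", paste(names(x$pheno), collapse = ", "), "\n")
  cat("  anno columns: ", paste(names(x$anno), collapse = ", "), "\n")
  cat("  total counts: ", sum(x$counts), "\n")
  invisible(x)
}

#' Validate a PAC object
#'
#' Checks every structural invariant: table classes, unique non-empty
#' keys, exact key/order agreement between Counts rows and Anno, and
#' between Counts columns and Pheno, non-negative integer counts, and the
#' `length` column matching the sequence keys.  Never mutates; violations
#' are returned as data, not thrown.
#'
#' @param pac A `PAC` object.
#' @return List with `ok` (logical) and `violations` (character vector).
#' @export
pac_check <- function(pac) {
  v <- character(0)
  if (!inherits(pac, "PAC") || !all(c("pheno", "anno", "counts") %in% names(pac)))
    return(list(ok = FALSE, violations = "not a PAC object"))
  p <- pac$pheno; a <- pac$anno; m <- pac$counts
  if (!is.data.frame(p) || !"sample_id" %in% names(p))
    v <- c(v, "pheno is not a data.frame with sample_id")
  else {
    if (anyDuplicated(p$sample_id)) v <- c(v, "duplicate sample ids")
    if (any(!nzchar(p$sample_id))) v <- c(v, "empty sample id")
  }
  if (!is.matrix(m) || !is.numeric(m))
    v <- c(v, "counts is not a numeric matrix")
  else {
    if (any(m < 0)) v <- c(v, "negative counts")
    if (any(m != round(m))) v <- c(v, "non-integer counts")
    if (is.data.frame(a) && "seq" %in% names(a)) {
      if (!identical(rownames(m), a$seq))
        v <- c(v, "row key mismatch between counts and anno")
      if (anyDuplicated(a$seq)) v <- c(v, "duplicate sequence keys")
      if ("length" %in% names(a) && !all(a$length == nchar(a$seq)))
        v <- c(v, "anno length column disagrees with sequence keys")
    } else v <- c(v, "anno is not a data.frame with a seq column")
    if (is.data.frame(p) && "sample_id" %in% names(p) &&
        !identical(colnames(m), p$sample_id))
      v <- c(v, "column key mismatch between counts and pheno")
  }
  list(ok = length(v) == 0L, violations = v)
}

.stop_if_invalid <- function(pac) {
  chk <- pac_check(pac)
  if (!chk$ok)
    stop("invalid PAC object: ", paste(chk$violations, collapse = "; "),
         call. = FALSE)
  invisible(pac)
}

#' Focus a PAC object on sequences and samples of interest
#'
#' Returns a new PAC restricted to the rows and columns passing all given
#' predicates; the input is never modified.  CPM used by the `min_cpm`
#' rule is computed on the selected samples' full library sizes, before
#' any row is removed within this call.
#'
#' @param pac A valid `PAC` object.
#' @param size_range Optional inclusive `c(min, max)` on sequence length.
#' @param min_cpm,min_samples_over_cpm Optional: keep sequences with CPM
#'   >= `min_cpm` in at least `min_samples_over_cpm` samples (default 1).
#' @param pheno_subset Optional predicate `function(pheno) -> logical` over
#'   Pheno rows (sample selection).
#' @param anno_subset Optional predicate `function(anno) -> logical` over
#'   Anno rows (sequence selection).
#' @return A new `PAC` object; errors if nothing survives.
#' @export
pac_filter <- function(pac, size_range = NULL, min_cpm = NULL,
                       min_samples_over_cpm = 1, pheno_subset = NULL,
                       anno_subset = NULL) {
  .stop_if_invalid(pac)
  keep_col <- rep(TRUE, ncol(pac$counts))
  if (!is.null(pheno_subset)) {
    keep_col <- as.logical(pheno_subset(pac$pheno))
    stopifnot(length(keep_col) == nrow(pac$pheno), !anyNA(keep_col))
  }
  if (!any(keep_col))
    stop("pac_filter removed all samples", call. = FALSE)
  counts <- pac$counts[, keep_col, drop = FALSE]
  pheno <- pac$pheno[keep_col, , drop = FALSE]
  keep_row <- rep(TRUE, nrow(counts))
  if (!is.null(size_range)) {
    stopifnot(length(size_range) == 2L)
    keep_row <- keep_row & pac$anno$length >= size_range[1] &
      pac$anno$length <= size_range[2]
  }
  if (!is.null(anno_subset)) {
    sel <- as.logical(anno_subset(pac$anno))
    stopifnot(length(sel) == nrow(pac$anno), !anyNA(sel))
    keep_row <- keep_row & sel
  }
  if (!is.null(min_cpm)) {
    libsize <- colSums(counts)
    if (any(libsize == 0))
      stop("zero library size in sample(s): ",
           paste(colnames(counts)[libsize == 0], collapse = ", "),
           call. = FALSE)
    cpm <- sweep(counts, 2, libsize, "/") * 1e6
    keep_row <- keep_row &
      rowSums(cpm >= min_cpm) >= min_samples_over_cpm
  }
  if (!any(keep_row))
    stop("pac_filter removed all sequences", call. = FALSE)
  make_pac(pheno, counts[keep_row, , drop = FALSE],
           anno = pac$anno[keep_row, , drop = FALSE])
}

#' Library-size normalization
#'
#' Counts per million: `cpm(s, j) = counts(s, j) * 1e6 / libsize(j)`, with
#' each library size taken over all sequences currently in the PAC.
#'
#' @param pac A valid `PAC` object.
#' @param method Only `"cpm"`.
#' @return Numeric matrix with the same dimnames as the counts.
#' @export
pac_norm <- function(pac, method = "cpm") {
  .stop_if_invalid(pac)
  method <- match.arg(method, "cpm")
  libsize <- colSums(pac$counts)
  if (any(libsize == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(pac$counts)[libsize == 0], collapse = ", "),
         call. = FALSE)
  sweep(pac$counts, 2, libsize, "/") * 1e6
}

#' Per-group summaries of the count table
#'
#' `mean_cpm`: arithmetic mean CPM within each level of a Pheno grouping
#' column.  `log2fc`: `log2((mean_cpm_group + 1) / (mean_cpm_ref + 1))`
#' with a 1-CPM pseudocount to avoid infinities on dropouts; requires
#' exactly two groups (the reference defaults to the first level in sorted
#' order) or an explicit `reference`.
#'
#' @param pac A valid `PAC` object.
#' @param group_column Name of a Pheno column defining groups.
#' @param stat `"mean_cpm"` or `"log2fc"`.
#' @param reference Reference level for `log2fc` (optional with 2 groups).
#' @return Data frame, one row per sequence, one column per group (or per
#'   group-vs-reference contrast, named `log2fc_<group>_vs_<ref>`).
#' @export
pac_summary <- function(pac, group_column, stat = c("mean_cpm", "log2fc"),
                        reference = NULL) {
  .stop_if_invalid(pac)
  stat <- match.arg(stat)
  if (!group_column %in% names(pac$pheno))
    stop("unknown pheno column: ", group_column, call. = FALSE)
  grp <- as.character(pac$pheno[[group_column]])
  levels <- sort(unique(grp))
  if (any(!nzchar(levels)) || length(levels) < 1)
    stop("grouping column has empty levels", call. = FALSE)
  cpm <- pac_norm(pac)
  means <- vapply(levels, function(g)
    rowMeans(cpm[, grp == g, drop = FALSE]), numeric(nrow(cpm)))
  means <- matrix(means, nrow = nrow(cpm),
                  dimnames = list(rownames(cpm), levels))
  if (stat == "mean_cpm")
    return(as.data.frame(means))
  if (is.null(reference)) {
    if (length(levels) != 2L)
      stop("log2fc needs exactly 2 groups or an explicit reference",
           call. = FALSE)
    reference <- levels[1L]
  }
  if (!reference %in% levels)
    stop("reference level not found: ", reference, call. = FALSE)
  others <- setdiff(levels, reference)
  out <- vapply(others, function(g)
    log2((means[, g] + 1) / (means[, reference] + 1)), numeric(nrow(means)))
  out <- matrix(out, nrow = nrow(means),
                dimnames = list(rownames(means),
                                paste0("log2fc_", others, "_vs_", reference)))
  as.data.frame(out)
}

#' Write a PAC object to a directory
#'
#' Writes `pheno.tsv`, `anno.tsv` and `counts.tsv` (tab-separated, header
#' row, sequence key column `seq`) plus `manifest.json` recording the
#' package version and any provenance the caller supplies.
#'
#' @param pac A valid `PAC` object.
#' @param dir Output directory (created if needed).
#' @param provenance Optional named list merged into the manifest (input
#'   files, parameters, ...).
#' @return `dir`, invisibly.
#' @export
write_pac <- function(pac, dir, provenance = list()) {
  .stop_if_invalid(pac)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, f)
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(pac$pheno, "pheno.tsv")
  tsv(pac$anno, "anno.tsv")
  cdf <- data.frame(seq = rownames(pac$counts), pac$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  tsv(cdf, "counts.tsv")
  manifest <- c(list(format = "pacseq PAC directory",
                     package_version = as.character(packageVersion("pacseq")),
                     n_sequences = nrow(pac$counts),
                     n_samples = ncol(pac$counts)),
                provenance)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a PAC object written by [write_pac()]
#'
#' @param dir Directory containing `pheno.tsv`, `anno.tsv`, `counts.tsv`.
#' @return A `PAC` object.
#' @export
read_pac <- function(dir) {
  need <- file.path(dir, c("pheno.tsv", "anno.tsv", "counts.tsv"))
  if (!all(file.exists(need)))
    stop("not a PAC directory (missing pheno/anno/counts tsv): ", dir,
         call. = FALSE)
  pheno <- read.delim(need[1], stringsAsFactors = FALSE)
  anno <- read.delim(need[2], stringsAsFactors = FALSE)
  cdf <- read.delim(need[3], stringsAsFactors = FALSE, check.names = FALSE)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$seq
  storage.mode(counts) <- "integer"
  make_pac(pheno, counts, anno = anno)
}
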