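# Positional classification of tRNA-derived fragments (tRFs).
#
# Mature tRNAs are cleaved into reproducible fragment classes: halves
# (cleaved in the anticodon loop), 5'/3' tRFs (terminus-anchored, cleaved
# elsewhere) and internal i'-tRFs.  Classification here is purely
# positional — a fragment's placement on a tRNA reference with known
# anticodon-loop coordinates determines its label — so it works in any
# species for which tRNA sequences and loop coordinates are available,
# with no species-specific lookup table.

#' tRNA-fragment class labels
#'
#' The six positional subtype labels, in the fixed order used for
#' deterministic tie-breaking.
#' @export
TRF_LABELS <- c("5p-half", "3p-half", "5p-tRF", "3p-tRF", "i-tRF",
                "whole-tRNA")

#' A tRNA reference model
#'
#' @param id tRNA identifier.
#' @param body Mature tRNA sequence WITHOUT the 3' CCA.
#' @param loop 0-based half-open anticodon-loop interval on the body,
#'   e.g. `c(31, 38)` for the canonical 7-nt loop of a 76-nt tRNA.
#' @param cca If `TRUE` (default), the classification reference is
#'   `body + "CCA"`, reflecting the post-transcriptional 3' addition; a
#'   fragment then counts as 3'-anchored only if it reaches the end of the
#'   CCA.
#' @return A `trna_model` object with the classification reference in
#'   `$ref` and its length in `$ref_len`.
#' @export
trna_model <- function(id, body, loop, cca = TRUE) {
  .assert_dna(body, "body")
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            length(body) == 1L, length(loop) == 2L)
  loop <- as.integer(loop)
  if (!(loop[1] >= 0 && loop[1] < loop[2] && loop[2] <= nchar(body)))
    stop("anticodon loop outside the tRNA body", call. = FALSE)
  ref <- if (isTRUE(cca)) paste0(body, "CCA") else body
  structure(list(id = id, body = body, loop = loop, cca = isTRUE(cca),
                 ref = ref, ref_len = nchar(ref)),
            class = "trna_model")
}

#' tRF classification parameters
#'
#' @param end_tolerance Slack in nt when deciding whether a fragment
#'   terminus is anchored at a tRNA terminus (default 0 = exact; 1-2 nt
#'   absorbs non-templated additions).
#' @param max_mismatch Substitutions allowed when placing sequences on the
#'   tRNA references (0..3, default 0).
#' @param multi_trna_policy When a sequence places on several tRNAs:
#'   `"report_all"` (default) keeps every placement and reports the union
#'   of labels — unique placement of short repeated sequences is often
#'   impossible and forcing one is arbitrary — or `"majority_label"`,
#'   which reports the most frequent label across placements (ties broken
#'   by the fixed label order 5p-half, 3p-half, 5p-tRF, 3p-tRF, i-tRF,
#'   whole-tRNA).
#' @return A `trf_params` object.
#' @export
trf_params <- function(end_tolerance = 0, max_mismatch = 0,
                       multi_trna_policy = c("report_all", "majority_label")) {
  structure(list(
    end_tolerance = .assert_scalar_int(end_tolerance, "end_tolerance", 0),
    max_mismatch = .assert_scalar_int(max_mismatch, "max_mismatch", 0),
    multi_trna_policy = match.arg(multi_trna_policy)), class = "trf_params")
}

#' Classify one fragment placement on a tRNA
#'
#' A terminus is "anchored" when it lies within `end_tolerance` nt of the
#' corresponding reference terminus.  Both termini anchored: whole-tRNA.
#' 5'-anchored with the cleavage point strictly inside the anticodon loop:
#' 5p-half, otherwise 5p-tRF; symmetrically for 3'-anchored fragments;
#' neither terminus anchored: i-tRF.
#'
#' @param start,end 0-based half-open fragment interval on the model's
#'   classification reference (CCA-inclusive when `cca = TRUE`).
#' @param model A [trna_model()].
#' @param params A [trf_params()].
#' @return One of `"5p-half"`, `"3p-half"`, `"5p-tRF"`, `"3p-tRF"`,
#'   `"i-tRF"`, `"whole-tRNA"`.
#' @export
classify_fragment <- function(start, end, model, params = trf_params()) {
  stopifnot(inherits(model, "trna_model"), inherits(params, "trf_params"))
  start <- .assert_scalar_int(start, "start")
  end <- .assert_scalar_int(end, "end")
  if (!(start >= 0 && start < end && end <= model$ref_len))
    stop(sprintf("fragment (%d,%d) out of bounds for reference of length %d",
                 start, end, model$ref_len), call. = FALSE)
  tol <- params$end_tolerance
  five <- start <= tol
  three <- end >= model$ref_len - tol
  in_loop <- function(pos) pos > model$loop[1] && pos < model$loop[2]
  if (five && three) return("whole-tRNA")
  if (five) return(if (in_loop(end)) "5p-half" else "5p-tRF")
  if (three) return(if (in_loop(start)) "3p-half" else "3p-tRF")
  "i-tRF"
}

#' Classify all sequences of a PAC object as tRNA fragments
#'
#' Each sequence is placed on each tRNA model with the ungapped
#' k-mismatch aligner (sense strand: tRFs are processed from the mature
#' tRNA, so antisense placements are not fragments), every placement is
#' labelled with [classify_fragment()], and the multi-tRNA policy
#' condenses placements into one annotation per sequence.  Sequences that
#' place on no model are labelled `"not_tRNA"`.
#'
#' @param pac A valid `PAC` object (or a character vector of sequences).
#' @param models List of [trna_model()] objects (>= 1).
#' @param params A [trf_params()].
#' @return List with `calls` (data.frame of every placement: seq, trna_id,
#'   start, end, mismatches, label), `anno` (the PAC Anno with a
#'   `trf_label` column appended; multiple labels joined with `;` under
#'   `report_all`), and `summary` (data.frame label x tRNA x fragment
#'   length with placement counts — the subtype stratification).
#' @export
classify_all <- function(pac, models, params = trf_params()) {
  if (inherits(models, "trna_model")) models <- list(models)
  stopifnot(length(models) >= 1,
            all(vapply(models, inherits, TRUE, "trna_model")),
            inherits(params, "trf_params"))
  if (inherits(pac, "PAC")) {
    .stop_if_invalid(pac)
    seqs <- pac$anno$seq
    anno <- pac$anno
  } else {
    seqs <- as.character(pac)
    anno <- data.frame(seq = seqs, length = nchar(seqs),
                       stringsAsFactors = FALSE)
  }
  spec <- align_spec(params$max_mismatch, strands = "forward")
  refs <- lapply(models, function(m)
    reference_set(m$id, setNames(m$ref, m$id)))
  calls <- list()
  for (i in seq_along(seqs)) {
    for (j in seq_along(models)) {
      hits <- align_k_mismatch(seqs[i], refs[[j]], spec)
      if (!nrow(hits)) next
      lab <- vapply(hits$pos, function(p)
        classify_fragment(p, p + nchar(seqs[i]), models[[j]], params),
        character(1))
      calls[[length(calls) + 1L]] <- data.frame(
        seq = seqs[i], trna_id = models[[j]]$id, start = hits$pos,
        end = hits$pos + nchar(seqs[i]), mismatches = hits$mismatches,
        label = lab, stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(seq = character(0), trna_id = character(0),
               start = integer(0), end = integer(0),
               mismatches = integer(0), label = character(0),
               stringsAsFactors = FALSE)
  lab_per_seq <- vapply(seqs, function(s) {
    labs <- calls$label[calls$seq == s]
    if (!length(labs)) return("not_tRNA")
    if (params$multi_trna_policy == "majority_label") {
      tab <- table(factor(labs, levels = TRF_LABELS))
      names(tab)[which.max(tab)]   # which.max takes first on ties
    } else paste(sort(unique(labs)), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  anno$trf_label <- lab_per_seq
  summary <- if (nrow(calls)) {
    agg <- stats::aggregate(list(n = calls$seq),
                            by = list(label = calls$label,
                                      trna_id = calls$trna_id,
                                      length = calls$end - calls$start),
                            FUN = length)
    agg[order(agg$label, agg$trna_id, agg$length), , drop = FALSE]
  } else data.frame(label = character(0), trna_id = character(0),
                    length = integer(0), n = integer(0))
  rownames(summary) <- NULL
  list(calls = calls, anno = anno, summary = summary)
}

#' Read tRNA models from FASTA plus a loop-coordinate sidecar
#'
#' @param fasta FASTA of mature tRNA bodies (no CCA).
#' @param loops TSV with columns `id`, `loop_start`, `loop_end` (0-based
#'   half-open on the body) and `cca` (logical).
#' @return List of [trna_model()] objects.
#' @export
read_trna_models <- function(fasta, loops) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tab <- read.delim(loops, stringsAsFactors = FALSE)
  need <- c("id", "loop_start", "loop_end", "cca")
  if (!all(need %in% names(tab)))
    stop("loop table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(tab$id, names(seqs))
  if (length(missing))
    stop("loop table ids absent from FASTA: ",
         paste(missing, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    trna_model(id = tab$id[i], body = as.character(seqs[[tab$id[i]]]),
               loop = c(tab$loop_start[i], tab$loop_end[i]),
               cca = as.logical(tab$cca[i])))
}
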