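# Composition summaries, PCA on normalized counts, and the yield-loss
# contamination model.
#
# When a contaminant (e.g. microbiota in clinical self-samples) makes up a
# fraction x of a library, it displaces target reads and drives the main
# axis of variation of the count table.  The displacement follows the
# rectangular hyperbola used in weed science to model crop yield loss as
# a function of weed density:
#
#     y = I * x / (1 + I * x / A)
#
# where I is the initial slope (response per unit contamination as x -> 0)
# and A the asymptotic response as x -> infinity.

#' Per-sample class composition
#'
#' Fraction of each sample attributable to each sequence class, weighted
#' either by reads (count sums) or by unique sequences.
#'
#' @param pac A valid `PAC` object.
#' @param class_column Name of an Anno column holding the class labels
#'   (e.g. `resolved_class` from [simplify_reanno()]).
#' @param weight `"reads"` (default) or `"sequences"`.
#' @return List with `fractions` (data.frame samples x classes, rows sum
#'   to 1) and `totals` (per-sample denominators).
#' @export
composition <- function(pac, class_column, weight = c("reads", "sequences")) {
  .stop_if_invalid(pac)
  weight <- match.arg(weight)
  if (!class_column %in% names(pac$anno))
    stop("unknown anno column: ", class_column, call. = FALSE)
  cls <- as.character(pac$anno[[class_column]])
  classes <- sort(unique(cls))
  if (weight == "reads") {
    sums <- t(rowsum(pac$counts, group = cls))   # samples x classes
    totals <- colSums(pac$counts)
  } else {
    present <- pac$counts > 0
    sums <- t(rowsum(present + 0, group = cls))
    totals <- colSums(present)
  }
  if (any(totals == 0))
    stop("sample(s) with zero total: ",
         paste(names(totals)[totals == 0], collapse = ", "), call. = FALSE)
  frac <- sweep(sums, 1, totals, "/")
  list(fractions = as.data.frame(frac[, classes, drop = FALSE]),
       totals = totals)
}

#' PCA of a PAC count table
#'
#' Transforms counts to `log2(CPM + 1)`, centers each sequence across
#' samples (samples are the observations), and decomposes by SVD.
#' Component signs are fixed so that each loading vector's
#' largest-magnitude element is positive, making results reproducible
#' across runs and platforms.
#'
#' @param pac A valid `PAC` object with >= 2 samples and >= 2 sequences.
#' @param n_components Number of components to keep (default: full rank).
#' @param transform `"log2cpm"` (default) or `"none"` (raw counts,
#'   centered only).
#' @return List with `scores` (samples x components), `loadings`
#'   (sequences x components), `var_explained` (fraction per component,
#'   non-increasing, summing to 1 over the full rank).
#' @export
pca_counts <- function(pac, n_components = NULL, transform = c("log2cpm", "none")) {
  .stop_if_invalid(pac)
  transform <- match.arg(transform)
  if (ncol(pac$counts) < 2L) stop("PCA needs >= 2 samples", call. = FALSE)
  if (nrow(pac$counts) < 2L) stop("PCA needs >= 2 sequences", call. = FALSE)
  x <- if (transform == "log2cpm") log2(pac_norm(pac) + 1) else pac$counts
  x <- t(x)                                   # samples x sequences
  x <- scale(x, center = TRUE, scale = FALSE)
  full_rank <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- full_rank
  n_components <- min(.assert_scalar_int(n_components, "n_components", 1),
                      full_rank)
  sv <- svd(x)
  d2 <- sv$d^2
  var_explained <- d2 / sum(d2)
  keep <- seq_len(n_components)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], n_components)
  loadings <- sv$v[, keep, drop = FALSE]
  for (j in keep) {                            # deterministic sign
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(x), paste0("PC", keep))
  dimnames(loadings) <- list(colnames(x), paste0("PC", keep))
  structure(list(scores = scores, loadings = loadings,
                 var_explained = var_explained[keep],
                 var_explained_full = var_explained),
            class = "pca_result")
}

.yl_curve <- function(x, I, A) I * x / (1 + I * x / A)

#' Fit the rectangular-hyperbola yield-loss model
#'
#' Nonlinear least squares for `y = I*x / (1 + I*x/A)` with `A > 0`,
#' linking a per-sample contamination fraction `x` to a sample-level
#' response `y` (for instance a PC1 score).  The optimizer restarts from
#' three deterministic initializations (the slope of the lowest-x quartile
#' for I, the maximum |y| for A, and scaled variants) and keeps the best
#' residual sum of squares; the fit is invariant to sample order.
#'
#' @param x Contamination fraction per sample, in \[0,1\].
#' @param y Response per sample (same length).
#' @return A `yield_loss_fit`: list with `I`, `A`, `rss`, `converged`,
#'   `fitted`, and `n`.
#' @export
fit_yield_loss <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(unique(x)) < 3L)
    stop("degenerate design: need >= 3 distinct contamination values",
         call. = FALSE)
  if (any(x < 0 | x > 1))
    stop("contamination fractions must lie in [0,1]", call. = FALSE)
  ord <- order(x, y)                 # order invariance
  xs <- x[ord]; ys <- y[ord]
  q1 <- xs <= quantile(xs, 0.25)
  base_I <- if (sum(q1 & xs > 0) >= 1)
    median(ys[q1 & xs > 0] / xs[q1 & xs > 0]) else
    max(abs(ys)) / max(mean(xs), .Machine$double.eps)
  if (!is.finite(base_I) || base_I == 0) base_I <- 1
  A0 <- max(abs(ys)); if (A0 == 0) A0 <- 1
  starts <- list(c(I = base_I, A = A0),
                 c(I = base_I * 10, A = A0),
                 c(I = base_I / 10, A = A0 * 2))
  best <- NULL
  dat <- data.frame(x = xs, y = ys)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ I * x / (1 + I * x / A), data = dat,
                        start = as.list(st),
                        lower = c(I = -Inf, A = .Machine$double.eps),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(structure(list(I = NA_real_, A = NA_real_, rss = NA_real_,
                          converged = FALSE, fitted = rep(NA_real_, length(x)),
                          n = length(x)), class = "yield_loss_fit"))
  cf <- stats::coef(best$fit)
  structure(list(I = unname(cf["I"]), A = unname(cf["A"]), rss = best$rss,
                 converged = isTRUE(best$fit$convInfo$isConv),
                 fitted = .yl_curve(x, cf["I"], cf["A"]), n = length(x)),
            class = "yield_loss_fit")
}

#' Evaluate a fitted yield-loss curve
#' @param fit A `yield_loss_fit`.
#' @param x Contamination fractions.
#' @return Predicted response.
#' @export
predict_yield_loss <- function(fit, x) {
  stopifnot(inherits(fit, "yield_loss_fit"))
  .yl_curve(x, fit$I, fit$A)
}

#' @export
print.yield_loss_fit <- function(x, ...) {
  cat(sprintf(
    "Yield-loss fit: y = I*x / (1 + I*x/A)\n  I (initial slope) = %.4g\n  A (asymptote)     = %.4g\n  RSS = %.4g over %d samples (converged: %s)\n",
    x$I, x$A, x$rss, x$n, x$converged))
  invisible(x)
}

#' Relate the main expression axis to contamination
#'
#' Orients PC1 so that its correlation with the contamination fraction is
#' non-negative, reports the Pearson correlation, and fits the yield-loss
#' model to the oriented PC1 scores (shifted so their minimum is zero,
#' since the model passes through the origin while PC scores are
#' centered).
#'
#' @param pca A `pca_result` from [pca_counts()].
#' @param contamination Named numeric vector of per-sample contamination
#'   fractions; names must match the PCA samples.
#' @return List with `correlation` (NA with `degenerate = TRUE` when
#'   contamination is constant), `fit` (a `yield_loss_fit`), `pc1`
#'   (oriented scores) and `response` (the shifted PC1 the model was fit
#'   to).
#' @export
variance_vs_contamination <- function(pca, contamination) {
  stopifnot(inherits(pca, "pca_result"))
  samples <- rownames(pca$scores)
  if (is.null(names(contamination)))
    stop("'contamination' must be named by sample", call. = FALSE)
  if (!setequal(names(contamination), samples))
    stop("sample sets of PCA and contamination differ", call. = FALSE)
  contamination <- contamination[samples]
  pc1 <- pca$scores[, 1L]
  if (sd(contamination) == 0)
    return(list(correlation = NA_real_, degenerate = TRUE, fit = NULL,
                pc1 = pc1, response = NULL))
  r <- cor(pc1, contamination)
  if (!is.na(r) && r < 0) { pc1 <- -pc1; r <- -r }
  response <- pc1 - min(pc1)
  fit <- fit_yield_loss(unname(contamination), unname(response))
  list(correlation = r, degenerate = FALSE, fit = fit,
       pc1 = pc1, response = response)
}
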