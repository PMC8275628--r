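# Ploidy contrasts: detected-gene fold, Welch differential expression with the
# study's call rules, and Kolmogorov-Smirnov distribution-shift calls. Group
# arguments throughout are nucleus selectors (logical vector, integer indices
# or nucleus_id characters) resolved against the matrix's nucleus table.

.resolve_nuclei <- function(tab, sel) {
  if (is.logical(sel)) {
    stopifnot(length(sel) == nrow(tab))
    which(sel)
  } else if (is.character(sel)) {
    idx <- match(sel, tab$nucleus_id)
    if (anyNA(idx)) stop("unknown nucleus ids in group selector")
    idx
  } else {
    as.integer(sel)
  }
}

#' Select nuclei by ploidy
#' @param x a `CountMatrix` or `NormalizedMatrix`.
#' @param ploidy ploidy label(s), e.g. `"2n"`.
#' @return logical selector over nuclei.
#' @export
ploidy_group <- function(x, ploidy) x$nuclei$ploidy %in% ploidy

#' Fold change in detected genes between two groups
#'
#' Ratio of the median number of endogenous genes detected (raw count > 0)
#' in group B over group A, computed on the pre-normalization count matrix.
#' In the study this fold is 1.36 across all cell types and 1.25 within the
#' hepatocyte cluster (4n over 2n).
#'
#' @param cm a `CountMatrix` (typically QC-filtered).
#' @param group_a,group_b nucleus selectors (reference = A).
#' @return the fold `median_B / median_A`.
#' @export
detected_genes_fold <- function(cm, group_a, group_b) {
  ia <- .resolve_nuclei(cm$nuclei, group_a)
  ib <- .resolve_nuclei(cm$nuclei, group_b)
  if (length(ia) == 0L || length(ib) == 0L) stop("both groups must be non-empty")
  endo <- endo_counts(cm)
  det <- as.numeric(Matrix::rowSums(endo > 0))
  med_a <- stats::median(det[ia])
  if (med_a == 0) stop("median detected genes in the reference group is zero")
  stats::median(det[ib]) / med_a
}

# vectorized per-gene Welch statistics on a values matrix split in two groups
.welch_stats <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- .colvars(xa, ma); vb <- .colvars(xb, mb)
  se2 <- va / na + vb / nb
  ok <- se2 > 0
  t_stat <- numeric(length(se2))
  df <- rep(NA_real_, length(se2))
  p <- rep(1, length(se2))
  t_stat[ok] <- (mb - ma)[ok] / sqrt(se2[ok])
  df[ok] <- se2[ok]^2 /
    ((va[ok] / na)^2 / (na - 1) + (vb[ok] / nb)^2 / (nb - 1))
  p[ok] <- 2 * stats::pt(abs(t_stat[ok]), df[ok], lower.tail = FALSE)
  list(mean_a = ma, mean_b = mb, t = t_stat, df = df, p = p)
}

.colvars <- function(x, means) {
  colSums(sweep(x, 2L, means)^2) / (nrow(x) - 1L)
}

#' Welch differential expression with fold-change/Bonferroni call rules
#'
#' Per-gene Welch's t-test on log-normalized values between two groups, with
#' the log2 fold change computed in the convention of the scanpy
#' `rank_genes_groups` implementation the study delegates to:
#' `log2((expm1(mean_log_B) + eps) / (expm1(mean_log_A) + eps))`. A gene is
#' called `up` (in B) if `log2fc > lfc_threshold` and the Bonferroni-adjusted
#' p-value is below `alpha`; `down` if `log2fc < -lfc_threshold` with the same
#' p rule; otherwise `ns`. Genes with zero variance in both groups and equal
#' means get `t = 0`, `p = 1`.
#'
#' @param nm a log-transformed `NormalizedMatrix`.
#' @param group_a,group_b nucleus selectors; fold changes are B relative to A.
#' @param lfc_threshold log2 fold-change call threshold (study value 0.5).
#' @param alpha Bonferroni-adjusted significance level (study value 0.05).
#' @param pseudocount stabilizer added to the de-logged means (default 1e-9).
#' @return data.frame of class `DEResult`: `feature_id`, `gene_name`,
#'   `mean_expr_group` (B), `mean_expr_rest` (A), `base_mean` (mean de-logged
#'   expression over both groups), `log2fc`, `t_stat`, `df`, `p`,
#'   `p_bonferroni`, `call`.
#' @export
welch_de <- function(nm, group_a, group_b, lfc_threshold = 0.5, alpha = 0.05,
                     pseudocount = 1e-9) {
  if (!nm$is_log) stop("welch_de expects log-transformed values")
  ia <- .resolve_nuclei(nm$nuclei, group_a)
  ib <- .resolve_nuclei(nm$nuclei, group_b)
  if (length(ia) < 2L || length(ib) < 2L) stop("each group needs >= 2 nuclei")
  xa <- nm$values[ia, , drop = FALSE]
  xb <- nm$values[ib, , drop = FALSE]
  st <- .welch_stats(xa, xb)
  n_tested <- ncol(nm$values)
  p_bonf <- pmin(1, st$p * n_tested)
  # NaN for inputs outside the log1p domain (negative "log" values)
  log2fc <- suppressWarnings(log2((expm1(st$mean_b) + pseudocount) /
                                    (expm1(st$mean_a) + pseudocount)))
  call <- rep("ns", n_tested)
  call[!is.na(log2fc) & log2fc > lfc_threshold & p_bonf < alpha] <- "up"
  call[!is.na(log2fc) & log2fc < -lfc_threshold & p_bonf < alpha] <- "down"
  base_mean <- (length(ia) * expm1(st$mean_a) + length(ib) * expm1(st$mean_b)) /
    (length(ia) + length(ib))
  out <- data.frame(feature_id = nm$features$feature_id,
                    gene_name = nm$features$gene_name,
                    mean_expr_group = st$mean_b, mean_expr_rest = st$mean_a,
                    base_mean = base_mean, log2fc = log2fc,
                    t_stat = st$t, df = st$df, p = st$p,
                    p_bonferroni = p_bonf, call = call,
                    stringsAsFactors = FALSE)
  class(out) <- c("DEResult", "data.frame")
  out
}

# two-sample KS statistic: sup-norm distance of the empirical CDFs,
# tie-aware (evaluated at pooled unique points)
.ks_stat <- function(a, b) {
  pooled <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pooled)
  Fb <- stats::ecdf(b)(pooled)
  max(abs(Fa - Fb))
}

# asymptotic two-sided two-sample KS p-value (Kolmogorov distribution)
.ks_p_asymptotic <- function(d, na, nb) {
  n_eff <- na * nb / (na + nb)
  lambda <- sqrt(n_eff) * d
  if (lambda < 1e-3) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Kolmogorov-Smirnov distribution-shift calls per gene
#'
#' Two-sample KS test of each gene's log-normalized expression distribution
#' between two groups. A gene is flagged as shifted if `p < alpha` and the KS
#' statistic `D > d_threshold` (study rule: p < 0.05 and D > 0.15). The exact
#' tie-aware p-value is used when the smaller group has fewer than
#' `exact_below` nuclei, the asymptotic Kolmogorov distribution otherwise.
#'
#' @param nm a log-transformed `NormalizedMatrix`.
#' @param group_a,group_b nucleus selectors.
#' @param d_threshold KS-statistic call threshold (study value 0.15).
#' @param alpha p-value call threshold (study value 0.05).
#' @param exact_below exact-p group-size cutoff (default 20).
#' @return data.frame of class `DistShiftResult`: `feature_id`, `gene_name`,
#'   `D`, `p`, `shifted`.
#' @export
ks_shift <- function(nm, group_a, group_b, d_threshold = 0.15, alpha = 0.05,
                     exact_below = 20) {
  if (!nm$is_log) stop("ks_shift expects log-transformed values")
  ia <- .resolve_nuclei(nm$nuclei, group_a)
  ib <- .resolve_nuclei(nm$nuclei, group_b)
  if (length(ia) < 2L || length(ib) < 2L) stop("each group needs >= 2 nuclei")
  na <- length(ia); nb <- length(ib)
  exact <- min(na, nb) < exact_below
  D <- numeric(ncol(nm$values))
  p <- numeric(ncol(nm$values))
  for (j in seq_len(ncol(nm$values))) {
    a <- nm$values[ia, j]
    b <- nm$values[ib, j]
    d <- .ks_stat(a, b)
    D[j] <- d
    p[j] <- if (d == 0) {
      1
    } else if (exact) {
      # shave a relative epsilon off D so the atom at D itself is always
      # included, whichever way floating-point rounding went
      stats::psmirnov(d * (1 - 1e-9), sizes = c(na, nb), z = c(a, b),
                      two.sided = TRUE, lower.tail = FALSE)
    } else {
      .ks_p_asymptotic(d, na, nb)
    }
  }
  out <- data.frame(feature_id = nm$features$feature_id,
                    gene_name = nm$features$gene_name,
                    D = D, p = p, shifted = p < alpha & D > d_threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("DistShiftResult", "data.frame")
  out
}

#' MA-plot table restricted to a mean-expression window
#'
#' Returns `(base_mean, log2fc, call)` for genes whose mean normalized
#' expression lies inside `mean_range` (study window: 0.1 to 100), ready for
#' plotting mean versus fold change.
#'
#' @param de a `DEResult` from [welch_de()].
#' @param mean_range inclusive `(low, high)` window on `base_mean`.
#' @return data.frame with `feature_id`, `gene_name`, `base_mean`, `log2fc`,
#'   `call`.
#' @export
ma_table <- function(de, mean_range = c(0.1, 100)) {
  keep <- de$base_mean >= mean_range[1] & de$base_mean <= mean_range[2]
  de[keep, c("feature_id", "gene_name", "base_mean", "log2fc", "call")]
}

#' Summarize DE and distribution-shift calls
#' @param de a `DEResult`.
#' @param shift optional `DistShiftResult`.
#' @return named list of call counts.
#' @export
de_summary <- function(de, shift = NULL) {
  out <- list(n_tested = nrow(de),
              n_up = sum(de$call == "up"),
              n_down = sum(de$call == "down"))
  if (!is.null(shift)) out$n_shifted <- sum(shift$shifted)
  out
}
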