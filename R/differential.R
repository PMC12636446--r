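# Per-time-bin differential expression between genotypes: fold changes,
# Mann-Whitney tests with per-bin Benjamini-Hochberg correction, and
# persistence counting across developmental windows.

de_bins <- function(cond_ages, ref_ages, bin_min) {
  top <- max(cond_ages, ref_ages)
  seq(0, ceiling((top + 1e-9) / bin_min) * bin_min, by = bin_min)
}

shared_genes_values <- function(cond, ref) {
  cv <- if (inherits(cond, "expression_matrix")) cond$values else cond
  rv <- if (inherits(ref, "expression_matrix")) ref$values else ref
  genes <- intersect(rownames(cv), rownames(rv))
  if (!length(genes)) stop("cohorts share no genes", call. = FALSE)
  list(cond = cv[genes, , drop = FALSE], ref = rv[genes, , drop = FALSE], genes = genes)
}

#' Per-bin log2 fold change between genotypes
#'
#' `log2((mean_cond + pc) / (mean_ref + pc))` per gene within each half-open
#' `[k*bin, (k+1)*bin)` minute window of stage-relative age. Bins empty in
#' either cohort yield `NA`.
#'
#' @param cond,ref expression matrices (RPM scale) for the condition and
#'   reference cohorts; genes are intersected by id.
#' @param cond_ages,ref_ages stage-relative sample ages (min).
#' @param bin_min bin width, minutes.
#' @param pseudocount symmetric pseudocount (RPM).
#' @return gene x bin matrix of log2 ratios; bin start minutes as colnames.
#' @export
binwise_fold_change <- function(cond, ref, cond_ages, ref_ages,
                                bin_min = 60, pseudocount = 1) {
  sv <- shared_genes_values(cond, ref)
  edges <- de_bins(cond_ages, ref_ages, bin_min)
  nb <- length(edges) - 1L
  out <- matrix(NA_real_, length(sv$genes), nb,
                dimnames = list(sv$genes, edges[-length(edges)]))
  cb <- findInterval(cond_ages, edges)
  rb <- findInterval(ref_ages, edges)
  for (b in seq_len(nb)) {
    ci <- which(cb == b); ri <- which(rb == b)
    if (!length(ci) || !length(ri)) next
    mc <- rowMeans(sv$cond[, ci, drop = FALSE])
    mr <- rowMeans(sv$ref[, ri, drop = FALSE])
    out[, b] <- log2((mc + pseudocount) / (mr + pseudocount))
  }
  out
}

#' Per-bin Mann-Whitney differential test with per-bin FDR
#'
#' Two-sided Mann-Whitney U test per gene within each 1-hour window,
#' Benjamini-Hochberg corrected across genes within each bin. Bins with
#' fewer than `min_n` samples in either cohort are skipped with a warning.
#'
#' @inheritParams binwise_fold_change
#' @param min_n minimum samples per cohort per tested bin.
#' @param alpha significance threshold recorded on the result (applied to
#'   adjusted values downstream).
#' @return data.frame of class `binwise_de_result`, long format: `gene_id`,
#'   `bin` (index), `bin_start_min`, `log2fc`, `U`, `p`, `q`, `n_cond`,
#'   `n_ref`; attributes `alpha` and `n_bins_tested`.
#' @export
binwise_test <- function(cond, ref, cond_ages, ref_ages, bin_min = 60,
                         pseudocount = 1, min_n = 3, alpha = 0.01) {
  sv <- shared_genes_values(cond, ref)
  edges <- de_bins(cond_ages, ref_ages, bin_min)
  nb <- length(edges) - 1L
  cb <- findInterval(cond_ages, edges)
  rb <- findInterval(ref_ages, edges)
  fc <- binwise_fold_change(cond, ref, cond_ages, ref_ages, bin_min, pseudocount)
  res <- list()
  skipped <- 0L
  for (b in seq_len(nb)) {
    ci <- which(cb == b); ri <- which(rb == b)
    if (length(ci) < min_n || length(ri) < min_n) {
      if (length(ci) + length(ri) > 0) skipped <- skipped + 1L
      next
    }
    stat <- mwu_test_rows(sv$cond[, ci, drop = FALSE], sv$ref[, ri, drop = FALSE])
    q <- stats::p.adjust(stat$p, method = "BH")
    res[[length(res) + 1L]] <- data.frame(
      gene_id = sv$genes, bin = b, bin_start_min = edges[b],
      log2fc = fc[, b], U = stat$U, p = stat$p, q = q,
      n_cond = length(ci), n_ref = length(ri),
      stringsAsFactors = FALSE
    )
  }
  if (skipped) warning(skipped, " bin(s) skipped for insufficient samples")
  if (!length(res)) stop("no bin had enough samples in both cohorts", call. = FALSE)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "n_bins_tested") <- length(res)
  class(out) <- c("binwise_de_result", "data.frame")
  out
}

# Row-wise two-sided Mann-Whitney U test. Matches wilcox.test: exact null
# distribution when there are no ties and both groups have <= 50 samples,
# otherwise the tie-corrected normal approximation with continuity
# correction.
mwu_test_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  n <- n1 + n2
  xy <- cbind(x, y)
  exact_allowed <- n1 <= 50 && n2 <= 50
  U <- numeric(nrow(x)); p <- numeric(nrow(x))
  for (g in seq_len(nrow(x))) {
    rk <- rank(xy[g, ])
    u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    U[g] <- u
    has_ties <- anyDuplicated(xy[g, ]) > 0
    if (exact_allowed && !has_ties) {
      p_lo <- stats::pwilcox(u, n1, n2)
      p_hi <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
      p[g] <- min(1, 2 * min(p_lo, p_hi))
    } else {
      ties <- table(xy[g, ])
      tie_term <- sum(ties^3 - ties)
      sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
      if (sigma2 <= 0) {
        p[g] <- 1
      } else {
        z <- (abs(u - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
        p[g] <- min(1, 2 * stats::pnorm(-max(z, 0)))
      }
    }
  }
  list(U = U, p = p)
}

#' Persistence of differential calls across developmental windows
#'
#' For each k, the number of genes significant (`q < alpha`, or `p < alpha`
#' with `use_adjusted = FALSE`) in at least k tested bins; also returns the
#' genes significant in at least half of the tested bins.
#'
#' @param result a `binwise_de_result`.
#' @param alpha significance threshold.
#' @param use_adjusted threshold the BH-adjusted values (default) or raw p.
#' @return list with `counts` (data.frame `k`, `n_genes`, non-increasing in
#'   k) and `half_or_more` (character gene ids).
#' @export
window_persistence <- function(result, alpha = 0.01, use_adjusted = TRUE) {
  val <- if (use_adjusted) result$q else result$p
  sig <- val < alpha
  nbins <- attr(result, "n_bins_tested")
  per_gene <- tapply(sig, result$gene_id, sum)
  counts <- vapply(seq_len(nbins), function(k) sum(per_gene >= k), integer(1))
  half <- names(per_gene)[per_gene >= ceiling(nbins / 2)]
  list(
    counts = data.frame(k = seq_len(nbins), n_genes = counts),
    half_or_more = sort(half)
  )
}
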