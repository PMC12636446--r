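# Trajectory reconstruction diagnostics: correlation-vs-time-gap curves,
# alignment comparison, sliding-window smoothing, t-SNE embedding, and
# artificial hourly pooling against a reference time course.

# Extract the numeric matrix and optionally move to log2(x+1) scale.
expr_values <- function(matrix, use_log = TRUE) {
  v <- if (inherits(matrix, "expression_matrix")) matrix$values else matrix
  if (use_log) log2(v + 1) else v
}

#' Per-pair expression correlations and age gaps
#'
#' Pearson correlation across genes for every unordered sample pair, with
#' the absolute age gap of the pair. Constant (zero-variance) samples are
#' excluded with a warning.
#'
#' @param matrix an [expression_matrix()] (RPM) or numeric matrix.
#' @param ages numeric ages (min), one per sample, in column order.
#' @param use_log correlate on log2(x+1) values (default) or raw.
#' @return data.frame with `i`, `j`, `gap`, `r` (one row per unordered pair
#'   of retained samples).
#' @export
pair_correlations <- function(matrix, ages, use_log = TRUE) {
  v <- expr_values(matrix, use_log)
  if (length(ages) != ncol(v)) stop("`ages` must match the sample count", call. = FALSE)
  sds <- apply(v, 2, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning(sum(drop), " constant-profile sample(s) excluded from pair correlations")
    v <- v[, !drop, drop = FALSE]
    ages <- ages[!drop]
  }
  n <- ncol(v)
  if (n < 2) stop("need at least 2 non-constant samples", call. = FALSE)
  cm <- stats::cor(v)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  data.frame(
    i = idx[, 1], j = idx[, 2],
    gap = abs(ages[idx[, 1]] - ages[idx[, 2]]),
    r = cm[idx]
  )
}

#' Correlation-vs-time-gap curve
#'
#' Bins every unordered sample pair by age gap and reports the mean and SEM
#' of the pairwise expression correlations per bin. The default edges run
#' every 5 minutes from 0 to 600, so the bins partition the full gap range
#' and pair counts sum to n(n-1)/2.
#'
#' @inheritParams pair_correlations
#' @param gap_edges increasing bin edges in minutes; bins are
#'   `[e_k, e_{k+1})` with the last bin closed on the right.
#' @return data.frame with `gap_lo`, `gap_hi`, `mean_r`, `sem_r`, `n_pairs`;
#'   the per-pair table is attached as attribute `"pairs"`.
#' @export
pairwise_gap_correlations <- function(matrix, ages, gap_edges = c(0, seq(5, 600, by = 5)),
                                      use_log = TRUE) {
  if (length(ages) < 3) stop("need at least 3 samples", call. = FALSE)
  pairs <- pair_correlations(matrix, ages, use_log)
  if (any(pairs$gap > max(gap_edges))) {
    stop("gap_edges do not cover the observed gap range", call. = FALSE)
  }
  bin <- findInterval(pairs$gap, gap_edges, rightmost.closed = TRUE)
  k <- length(gap_edges) - 1L
  mean_r <- sem_r <- rep(NA_real_, k)
  n_pairs <- integer(k)
  for (b in seq_len(k)) {
    rr <- pairs$r[bin == b]
    n_pairs[b] <- length(rr)
    if (length(rr)) {
      mean_r[b] <- mean(rr)
      sem_r[b] <- stats::sd(rr) / sqrt(length(rr))
    }
  }
  out <- data.frame(
    gap_lo = gap_edges[-length(gap_edges)], gap_hi = gap_edges[-1],
    mean_r = mean_r, sem_r = sem_r, n_pairs = n_pairs
  )
  attr(out, "pairs") <- pairs
  out
}

#' Compare close-pair and far-pair correlation distributions
#'
#' Splits pairwise correlations at an age-gap cutoff and runs a two-sample
#' Kolmogorov-Smirnov test between the two r distributions.
#'
#' @param pairs data.frame from [pair_correlations()] (or the `"pairs"`
#'   attribute of a gap curve).
#' @param cutoff_min age-gap cutoff in minutes (close: `<= cutoff`).
#' @return list with `statistic`, `p_value`, `n_close`, `n_far`,
#'   `mean_r_close`, `mean_r_far`.
#' @export
compare_gap_groups <- function(pairs, cutoff_min = 5) {
  close_r <- pairs$r[pairs$gap <= cutoff_min]
  far_r <- pairs$r[pairs$gap > cutoff_min]
  if (!length(close_r) || !length(far_r)) stop("both gap groups must be non-empty", call. = FALSE)
  if (length(close_r) < 3 || length(far_r) < 3) {
    warning("very small group(s); KS test has little power")
  }
  ks <- suppressWarnings(stats::ks.test(close_r, far_r))
  list(
    statistic = unname(ks$statistic), p_value = ks$p.value,
    n_close = length(close_r), n_far = length(far_r),
    mean_r_close = mean(close_r), mean_r_far = mean(far_r)
  )
}

#' Compare stage-aligned and hatch-aligned reconstructions
#'
#' Computes the mean correlation among close pairs (age gap `<= cutoff_min`)
#' under the stage-relative and hatch-relative age coordinates, and tests
#' whether the two close-pair r distributions differ (KS).
#'
#' @param matrix expression values (RPM).
#' @param ages_L4 stage-relative ages (min since the L3/L4 transition).
#' @param ages_hatch hatch-relative ages (min since hatch).
#' @param cutoff_min close-pair cutoff, minutes.
#' @param use_log correlate on log2(x+1) values.
#' @return list with `mean_r_L4`, `mean_r_hatch`, `advantage`
#'   (L4 minus hatch), `ks_statistic`, `ks_p`, `n_close_L4`, `n_close_hatch`.
#' @export
compare_alignments <- function(matrix, ages_L4, ages_hatch, cutoff_min = 5,
                               use_log = TRUE) {
  p_l4 <- pair_correlations(matrix, ages_L4, use_log)
  p_ha <- pair_correlations(matrix, ages_hatch, use_log)
  r_l4 <- p_l4$r[p_l4$gap <= cutoff_min]
  r_ha <- p_ha$r[p_ha$gap <= cutoff_min]
  if (!length(r_l4) || !length(r_ha)) stop("no close pairs under one of the alignments", call. = FALSE)
  ks <- suppressWarnings(stats::ks.test(r_l4, r_ha))
  list(
    mean_r_L4 = mean(r_l4), mean_r_hatch = mean(r_ha),
    advantage = mean(r_l4) - mean(r_ha),
    ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
    n_close_L4 = length(r_l4), n_close_hatch = length(r_ha)
  )
}

#' Sliding-window mean trajectory for one gene
#'
#' Boxcar mean on a fixed evaluation grid anchored at age 0: the value at
#' grid time t averages exactly the samples with `|age - t| <= window/2`.
#' Empty windows are reported as `NA`, never interpolated.
#'
#' @param values numeric vector, one value per sample.
#' @param ages sample ages in minutes.
#' @param window_h window width, hours.
#' @param step_h grid step, hours.
#' @return data.frame with `time_min`, `value`, `n` (samples in window).
#' @export
smooth_trajectory <- function(values, ages, window_h = 1.45, step_h = 0.17) {
  if (length(values) != length(ages)) stop("values/ages length mismatch", call. = FALSE)
  half <- window_h * 60 / 2
  grid <- seq(0, max(ages), by = step_h * 60)
  out <- vapply(grid, function(t) {
    in_win <- abs(ages - t) <= half
    n <- sum(in_win)
    c(if (n) mean(values[in_win]) else NA_real_, n)
  }, numeric(2))
  data.frame(time_min = grid, value = out[1, ], n = as.integer(out[2, ]))
}

# ---------------------------------------------------------------------------
# t-SNE (exact, O(n^2)) -- small-n implementation with the standard
# perplexity calibration, early exaggeration and momentum schedule.
# ---------------------------------------------------------------------------

# Conditional affinities for one point via binary search on the kernel
# precision until the target perplexity is met.
tsne_affinities <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (iter in 1:60) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP == 0) sumP <- .Machine$double.eps
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sumP
  }
  P
}

#' Embed samples in 2-D with t-SNE
#'
#' Exact (non-approximated) t-SNE on the sample profiles, with standard
#' perplexity calibration, early exaggeration and momentum schedule. Layout
#' is seed-dependent by contract; quality is therefore summarized as the
#' mean age gap of each sample's 5 nearest embedded neighbors, compared with
#' the cohort-wide mean pairwise age gap.
#'
#' @param matrix an [expression_matrix()] or numeric gene x sample matrix.
#' @param ages sample ages (min), used only for the quality statistic (`NULL`
#'   to skip).
#' @param perplexity target perplexity; clamped (with a warning) when the
#'   sample count is below `3 * perplexity + 1`.
#' @param learning_rate gradient-descent learning rate.
#' @param seed integer seed for the embedding initialization.
#' @param n_iter gradient-descent iterations.
#' @param use_log embed log2(x+1) values.
#' @param pca_dims initial PCA reduction of the gene space (`NULL` to skip).
#' @return list with `coords` (n x 2 matrix), `mean_knn_age_gap`,
#'   `mean_pairwise_age_gap`.
#' @export
embed_samples <- function(matrix, ages = NULL, perplexity = 40, learning_rate = 110,
                          seed = 1L, n_iter = 400, use_log = TRUE, pca_dims = 50) {
  v <- t(expr_values(matrix, use_log))  # samples x genes
  n <- nrow(v)
  if (n <= 3) stop("need more than 3 samples to embed", call. = FALSE)
  if (n < 3 * perplexity + 1) {
    perplexity <- max(2, floor((n - 1) / 3))
    warning("sample count below 3*perplexity; perplexity clamped to ", perplexity)
  }
  if (!is.null(pca_dims) && ncol(v) > pca_dims) {
    v <- stats::prcomp(v, rank. = pca_dims, center = TRUE, scale. = FALSE)$x
  }
  D2 <- as.matrix(stats::dist(v))^2
  P <- tsne_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, .Machine$double.xmin)

  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    exaggeration <- 4
    stop_lying <- 100L
    for (iter in seq_len(n_iter)) {
      Pi <- if (iter <= stop_lying) P * exaggeration else P
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), .Machine$double.xmin)
      L <- (Pi - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      momentum <- if (iter <= 250) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- momentum * dY - learning_rate * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    colnames(Y) <- c("dim1", "dim2")
    rownames(Y) <- if (inherits(matrix, "expression_matrix")) colnames(matrix$values) else colnames(matrix)

    quality <- list(mean_knn_age_gap = NA_real_, mean_pairwise_age_gap = NA_real_)
    if (!is.null(ages)) {
      dE <- as.matrix(stats::dist(Y))
      diag(dE) <- Inf
      k <- min(5L, n - 1L)
      knn_gap <- vapply(seq_len(n), function(i) {
        nb <- order(dE[i, ])[seq_len(k)]
        mean(abs(ages[nb] - ages[i]))
      }, numeric(1))
      gaps <- abs(outer(ages, ages, "-"))
      quality <- list(
        mean_knn_age_gap = mean(knn_gap),
        mean_pairwise_age_gap = mean(gaps[upper.tri(gaps)])
      )
    }
    c(list(coords = Y), quality)
  })
}

#' Artificial hourly pooling of single-animal profiles
#'
#' Emulates a conventional population time course: per gene, the mean
#' expression of samples whose hatch-relative age lies within +/- `window_min`
#' of each integer-hour center. Centers with no samples are dropped (and
#' listed in the `empty_centers_h` attribute).
#'
#' @param matrix an [expression_matrix()] or numeric matrix (RPM scale).
#' @param ages_since_hatch sample ages in minutes since hatch.
#' @param window_min pooling half-window, minutes.
#' @return object of class `pooled_matrix`: list with `values`
#'   (gene x bin), `centers_h`, `n_per_bin`, `window_min`.
#' @export
artificial_pool <- function(matrix, ages_since_hatch, window_min = 30) {
  v <- if (inherits(matrix, "expression_matrix")) matrix$values else matrix
  if (length(ages_since_hatch) != ncol(v)) stop("ages/sample mismatch", call. = FALSE)
  lo <- ceiling(min(ages_since_hatch) / 60)
  hi <- floor(max(ages_since_hatch) / 60)
  if (hi < lo) stop("ages span no hourly center", call. = FALSE)
  centers <- seq(lo, hi)
  cols <- lapply(centers, function(h) which(abs(ages_since_hatch - h * 60) <= window_min))
  n_per_bin <- lengths(cols)
  keep <- n_per_bin > 0
  pooled <- vapply(cols[keep], function(ci) rowMeans(v[, ci, drop = FALSE]), numeric(nrow(v)))
  if (is.null(dim(pooled))) pooled <- matrix(pooled, nrow = nrow(v))
  dimnames(pooled) <- list(rownames(v), sprintf("h%02d", centers[keep]))
  structure(
    list(values = pooled, centers_h = centers[keep], n_per_bin = n_per_bin[keep],
         window_min = window_min, empty_centers_h = centers[!keep]),
    class = "pooled_matrix"
  )
}

#' Compare a pooled time course with a reference time course
#'
#' Matches hourly bins after applying `hour_offset` (pooled hour h is
#' compared with reference hour `h - hour_offset`, e.g. offset 2 compares
#' hours 28-36 against reference 26-34), computes per-gene Pearson r over
#' the shared bins, and a shuffled-reference control in which each reference
#' gene's bins are independently permuted. Real and control r sets are
#' compared by an unpaired t-test.
#'
#' @param pooled,reference `pooled_matrix` objects sharing gene ids.
#' @param hour_offset hours subtracted from pooled centers to find the
#'   matching reference center.
#' @param seed seed for the shuffle control.
#' @return list with `per_gene` (data.frame gene, r, r_shuffled), `mean_r`,
#'   `mean_r_shuffled`, `t_p`, `shared_bins`.
#' @export
compare_to_reference <- function(pooled, reference, hour_offset = 0, seed = 1L) {
  genes <- intersect(rownames(pooled$values), rownames(reference$values))
  if (length(genes) < 2) stop("need at least 2 shared genes", call. = FALSE)
  ref_target <- pooled$centers_h - hour_offset
  keep <- ref_target %in% reference$centers_h
  if (sum(keep) < 3) stop("need at least 3 shared bins after offset alignment", call. = FALSE)
  pv <- pooled$values[genes, keep, drop = FALSE]
  rv <- reference$values[genes, match(ref_target[keep], reference$centers_h), drop = FALSE]
  r <- colwise_pearson(t(pv), t(rv))
  shuffled <- with_seed(seed, t(apply(rv, 1, sample)))
  r_sh <- colwise_pearson(t(pv), t(shuffled))
  bad <- is.na(r) | is.na(r_sh)
  if (any(bad)) {
    warning(sum(bad), " constant gene(s) excluded from reference comparison")
  }
  r_ok <- r[!bad]; rs_ok <- r_sh[!bad]
  tt <- stats::t.test(r_ok, rs_ok, var.equal = FALSE)
  list(
    per_gene = data.frame(gene_id = genes[!bad], r = r_ok, r_shuffled = rs_ok),
    mean_r = mean(r_ok), mean_r_shuffled = mean(rs_ok),
    t_p = tt$p.value, shared_bins = sum(keep)
  )
}
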