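# Temporal clustering of gene-expression profiles: hour-binning and the
# transform chain, correlation distance, Ward agglomeration, cluster means
# and representative genes.

#' Bin expression by developmental time and apply the transform chain
#'
#' Per gene: mean RPM within half-open `[k*bin, (k+1)*bin)` minute bins of
#' stage-relative age, then `log2(x+1)`, then per-gene z-score, then (when
#' `first_bin_norm`) subtraction of the first bin's value so every profile
#' starts at 0.
#'
#' @param matrix an [expression_matrix()] (RPM) or numeric matrix.
#' @param ages_since_L4 sample ages in minutes since the L3/L4 transition.
#' @param bin_min bin width, minutes.
#' @param first_bin_norm subtract the first bin after z-scoring.
#' @return object of class `binned_profile_set`: list with `values`
#'   (gene x bin), `bin_edges` (min), `transform_log`.
#' @export
bin_and_transform <- function(matrix, ages_since_L4, bin_min = 60, first_bin_norm = TRUE) {
  v <- if (inherits(matrix, "expression_matrix")) matrix$values else matrix
  if (length(ages_since_L4) != ncol(v)) stop("ages/sample mismatch", call. = FALSE)
  edges <- seq(0, ceiling(max(ages_since_L4) / bin_min) * bin_min, by = bin_min)
  bin <- findInterval(ages_since_L4, edges, rightmost.closed = FALSE)
  keep_bins <- sort(unique(bin))
  binned <- vapply(keep_bins, function(b) rowMeans(v[, bin == b, drop = FALSE]), numeric(nrow(v)))
  if (is.null(dim(binned))) binned <- matrix(binned, nrow = nrow(v))
  binned <- log2(binned + 1)
  mu <- rowMeans(binned)
  sd_ <- apply(binned, 1, stats::sd)
  flat <- sd_ == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene profile(s) set to all-zero")
    sd_[flat] <- 1
  }
  z <- (binned - mu) / sd_
  z[flat, ] <- 0
  log <- c(sprintf("binned %g min", bin_min), "log2(x+1)", "z-score")
  if (first_bin_norm) {
    z <- z - z[, 1]
    log <- c(log, "first-bin normalized")
  }
  dimnames(z) <- list(rownames(v), sprintf("bin%02d", keep_bins - 1L))
  structure(
    list(values = z, bin_edges = edges[c(keep_bins, max(keep_bins) + 1L)],
         transform_log = log),
    class = "binned_profile_set"
  )
}

#' Correlation distance between temporal profiles
#'
#' `D = 2 * (1 - Pearson r)`, ranging over `[0, 4]`. With a single profile
#' pair returns a scalar; with a profile matrix (genes in rows) returns the
#' full `dist` object. Zero-variance profiles get `r = 0` (distance 2) with
#' a warning, preserving gene accounting.
#'
#' @param a numeric vector or gene x bin matrix.
#' @param b optional second vector.
#' @return scalar or `dist`.
#' @export
correlation_distance <- function(a, b = NULL) {
  if (!is.null(b)) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance profile; correlation taken as 0")
      return(2)
    }
    return(2 * (1 - stats::cor(a, b)))
  }
  m <- if (inherits(a, "binned_profile_set")) a$values else a
  sds <- apply(m, 1, stats::sd)
  cm <- suppressWarnings(stats::cor(t(m)))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance profile(s); correlations taken as 0")
    cm[sds == 0, ] <- 0
    cm[, sds == 0] <- 0
    diag(cm) <- 1
  }
  stats::as.dist(2 * (1 - cm))
}

#' Hierarchical clustering of temporal profiles
#'
#' Agglomerates the correlation-distance matrix under Ward's criterion and
#' cuts the tree at `k` clusters. Variant `"presquared"` treats the
#' `D = 2(1 - r)` values as already-squared distances (Ward applied to the
#' dissimilarities as given); variant `"correlation"` applies Ward to
#' `1 - r` distances with squaring inside the update (the convention of
#' toolboxes that pair Ward linkage with a correlation metric).
#'
#' @param profiles a `binned_profile_set` or gene x feature numeric matrix.
#' @param k number of clusters.
#' @param variant `"presquared"` or `"correlation"`.
#' @return object of class `cluster_result`: list with `k`, `labels` (named
#'   integer vector), `tree` (hclust), `sizes`, `variant`.
#' @export
hcluster <- function(profiles, k, variant = c("presquared", "correlation")) {
  variant <- match.arg(variant)
  m <- if (inherits(profiles, "binned_profile_set")) profiles$values else profiles
  if (k < 1 || k > nrow(m)) stop("`k` must be in [1, n_genes]", call. = FALSE)
  if (variant == "presquared") {
    d <- correlation_distance(m)
    tree <- stats::hclust(d, method = "ward.D")
  } else {
    sds <- apply(m, 1, stats::sd)
    cm <- suppressWarnings(stats::cor(t(m)))
    if (any(sds == 0)) {
      warning(sum(sds == 0), " zero-variance profile(s); correlations taken as 0")
      cm[sds == 0, ] <- 0; cm[, sds == 0] <- 0; diag(cm) <- 1
    }
    tree <- stats::hclust(stats::as.dist(1 - cm), method = "ward.D2")
  }
  labels <- stats::cutree(tree, k = k)
  structure(
    list(k = as.integer(k), labels = labels, tree = tree,
         sizes = as.integer(table(labels)), variant = variant),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d genes in %d clusters (%s Ward); sizes: %s\n",
    length(x$labels), x$k, x$variant, paste(x$sizes, collapse = ", ")
  ))
  invisible(x)
}

#' Run one of the two standard clustering presets
#'
#' Preset `"profiles"`: hour-binned, log2, z-scored, first-bin-normalized
#' profiles under presquared Ward (temporal-pattern clustering, default
#' k = 20). Preset `"markers"`: per-sample log2(x+1) profiles under
#' correlation-metric Ward (marker-selection clustering, default k = 30).
#'
#' @param matrix an [expression_matrix()] (RPM).
#' @param ages_since_L4 stage-relative sample ages (min); used only by the
#'   `"profiles"` preset.
#' @param preset `"profiles"` or `"markers"`.
#' @param k cluster count (`NULL` uses the preset default).
#' @return list with `result` (a `cluster_result`) and `profiles` (the
#'   matrix that was clustered).
#' @export
cluster_preset <- function(matrix, ages_since_L4 = NULL,
                           preset = c("profiles", "markers"), k = NULL) {
  preset <- match.arg(preset)
  if (preset == "profiles") {
    if (is.null(ages_since_L4)) stop("preset 'profiles' needs ages_since_L4", call. = FALSE)
    if (is.null(k)) k <- 20L
    prof <- bin_and_transform(matrix, ages_since_L4, first_bin_norm = TRUE)
    list(result = hcluster(prof, k, "presquared"), profiles = prof$values)
  } else {
    if (is.null(k)) k <- 30L
    v <- log2((if (inherits(matrix, "expression_matrix")) matrix$values else matrix) + 1)
    list(result = hcluster(v, k, "correlation"), profiles = v)
  }
}

#' Cluster mean trajectories
#'
#' Element-wise mean and SD of member profiles per cluster.
#'
#' @param result a `cluster_result`.
#' @param profiles the gene x feature matrix that was clustered (or a
#'   `binned_profile_set`).
#' @return list with `mean` and `sd` (k x feature matrices, rows named by
#'   cluster id).
#' @export
cluster_means <- function(result, profiles) {
  m <- if (inherits(profiles, "binned_profile_set")) profiles$values else profiles
  ids <- sort(unique(result$labels))
  mu <- t(vapply(ids, function(cl) colMeans(m[result$labels == cl, , drop = FALSE]),
                 numeric(ncol(m))))
  sdv <- t(vapply(ids, function(cl) {
    rows <- m[result$labels == cl, , drop = FALSE]
    if (nrow(rows) == 1) rep(0, ncol(m)) else apply(rows, 2, stats::sd)
  }, numeric(ncol(m))))
  rownames(mu) <- rownames(sdv) <- ids
  colnames(mu) <- colnames(sdv) <- colnames(m)
  list(mean = mu, sd = sdv)
}

#' Representative gene of each cluster
#'
#' Within each cluster, the member with the highest Pearson correlation to
#' the cluster's mean profile; numeric ties resolve to the
#' lexicographically smaller gene id.
#'
#' @param result a `cluster_result`.
#' @param profiles the gene x feature matrix used for clustering.
#' @return data.frame with `cluster`, `gene_id`, `r`.
#' @export
representative_genes <- function(result, profiles) {
  m <- if (inherits(profiles, "binned_profile_set")) profiles$values else profiles
  ids <- sort(unique(result$labels))
  rows <- lapply(ids, function(cl) {
    members <- names(result$labels)[result$labels == cl]
    if (length(members) == 1) {
      return(data.frame(cluster = cl, gene_id = members, r = 1))
    }
    mu <- colMeans(m[members, , drop = FALSE])
    r <- suppressWarnings(apply(m[members, , drop = FALSE], 1, stats::cor, y = mu))
    r[is.na(r)] <- 0
    best <- which(r == max(r))
    pick <- members[best][order(members[best])][1]
    data.frame(cluster = cl, gene_id = pick, r = max(r))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
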