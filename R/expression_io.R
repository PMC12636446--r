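# Expression-matrix container, ingest, RPM normalization, gene filters, and
# the join between samples and behaviorally derived ages.

#' Gene-by-sample expression matrix
#'
#' Thin container around a numeric matrix (genes in rows, samples in
#' columns) carrying a unit flag (`"counts"` or `"RPM"`) and a provenance log
#' of the transforms applied.
#'
#' @param values numeric matrix with unique rownames (gene ids) and colnames
#'   (sample ids).
#' @param unit `"counts"` or `"RPM"`.
#' @param log character vector appended to the provenance log.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, unit = c("counts", "RPM"), log = character()) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("gene ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique", call. = FALSE)
  structure(
    list(values = values, unit = unit, log = as.character(log)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes x %d samples [%s]\n",
    nrow(x$values), ncol(x$values), x$unit
  ))
  if (length(x$log)) cat("  transforms:", paste(x$log, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a gene x sample matrix from delimited text
#'
#' Expects genes as rows with a leading gene-id column and a header of sample
#' ids (the round-trip partner of [write_expression_matrix()]).
#'
#' @param path file path (TSV by default).
#' @param unit unit flag to attach.
#' @param sep field separator.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, unit = "counts", sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  expression_matrix(m, unit = unit, log = sprintf("read from %s", basename(path)))
}

#' Write a gene x sample matrix as delimited text
#'
#' @param x an [expression_matrix()] (or bare matrix with dimnames).
#' @param path output path.
#' @param sep field separator.
#' @param header_comment optional `# `-prefixed provenance lines.
#' @export
write_expression_matrix <- function(x, path, sep = "\t", header_comment = NULL) {
  m <- if (inherits(x, "expression_matrix")) x$values else x
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  writeLines(paste(c("gene_id", colnames(m)), collapse = sep), con)
  utils::write.table(
    data.frame(gene_id = rownames(m), m, check.names = FALSE),
    con,
    sep = sep, quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Normalize counts to reads per million (RPM)
#'
#' Divides each sample's counts by its total and scales by 1e6, so every
#' column sums to one million.
#'
#' @param counts an [expression_matrix()] with unit `"counts"`.
#' @return an [expression_matrix()] with unit `"RPM"`.
#' @export
rpm_normalize <- function(counts) {
  if (!inherits(counts, "expression_matrix")) stop("expected an expression_matrix", call. = FALSE)
  if (counts$unit != "counts") stop("RPM normalization requires unit 'counts'", call. = FALSE)
  totals <- colSums(counts$values)
  zero <- which(totals <= 0)
  if (length(zero)) {
    stop("zero-total sample(s): ", paste(colnames(counts$values)[zero], collapse = ", "),
         call. = FALSE)
  }
  values <- sweep(counts$values, 2, totals, "/") * 1e6
  expression_matrix(values, unit = "RPM", log = c(counts$log, "rpm_normalize"))
}

#' Drop genes that carry no usable signal
#'
#' Removes genes that are zero in every sample or that contain any missing
#' value; the removal is recorded in the provenance log.
#'
#' @param matrix an [expression_matrix()].
#' @return filtered [expression_matrix()], with attribute `"dropped"` listing
#'   the removed gene ids.
#' @export
drop_dead_genes <- function(matrix) {
  if (!inherits(matrix, "expression_matrix")) stop("expected an expression_matrix", call. = FALSE)
  v <- matrix$values
  has_na <- rowSums(is.na(v)) > 0
  all_zero <- !has_na & rowSums(v != 0) == 0
  drop <- has_na | all_zero
  out <- expression_matrix(
    v[!drop, , drop = FALSE],
    unit = matrix$unit,
    log = c(matrix$log, sprintf("drop_dead_genes: removed %d of %d", sum(drop), nrow(v)))
  )
  attr(out, "dropped") <- rownames(v)[drop]
  out
}

#' Active-gene filter
#'
#' A gene is active when it has at least `min_reads` counts in at least
#' `min_fraction` of the samples (sample threshold taken as a ceiling).
#'
#' @param counts an [expression_matrix()] with unit `"counts"`.
#' @param min_reads count threshold per sample (inclusive).
#' @param min_fraction fraction of samples that must pass.
#' @return character vector of active gene ids.
#' @export
active_gene_filter <- function(counts, min_reads = 7, min_fraction = 0.30) {
  if (!inherits(counts, "expression_matrix")) stop("expected an expression_matrix", call. = FALSE)
  if (counts$unit != "counts") stop("active-gene filter is defined on counts", call. = FALSE)
  v <- counts$values
  if (nrow(v) == 0 || ncol(v) == 0) stop("empty expression matrix", call. = FALSE)
  need <- ceiling(min_fraction * ncol(v))
  keep <- rowSums(v >= min_reads) >= need
  rownames(v)[keep]
}

#' Join expression samples to behaviorally derived ages
#'
#' Attaches each sample's developmental ages from a timeline table. Every
#' sample must match exactly one timeline row.
#'
#' @param matrix an [expression_matrix()].
#' @param samples data.frame with at least `sample_id` and `individual_id`.
#' @param timelines data.frame of per-individual timelines as produced by
#'   [timelines_table()] (columns `individual_id`, `hatch_min`, `t1`, `t2`,
#'   `t3`, `collection_min`), or `NULL` if `samples` already carries
#'   `age_since_L4` and `age_since_hatch`.
#' @return list with `matrix` (unchanged values) and `samples` (the table
#'   augmented with `age_since_L4` and `age_since_hatch`, ordered as the
#'   matrix columns).
#' @export
attach_ages <- function(matrix, samples, timelines = NULL) {
  if (!inherits(matrix, "expression_matrix")) stop("expected an expression_matrix", call. = FALSE)
  ids <- colnames(matrix$values)
  miss <- setdiff(ids, samples$sample_id)
  if (length(miss)) {
    stop("samples missing from metadata: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in metadata", call. = FALSE)
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  if (!is.null(timelines)) {
    if (anyDuplicated(timelines$individual_id)) {
      stop("duplicate individual_id in timelines", call. = FALSE)
    }
    idx <- match(samples$individual_id, timelines$individual_id)
    if (anyNA(idx)) {
      stop("no timeline for sample(s): ",
           paste(samples$sample_id[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    tl <- timelines[idx, , drop = FALSE]
    samples$age_since_hatch <- tl$collection_min - tl$hatch_min
    samples$age_since_L4 <- tl$collection_min - tl$t3
  }
  if (is.null(samples$age_since_L4) || is.null(samples$age_since_hatch)) {
    stop("ages unavailable: provide timelines or pre-annotated metadata", call. = FALSE)
  }
  if (any(!is.finite(samples$age_since_L4)) || any(!is.finite(samples$age_since_hatch))) {
    stop("non-finite ages after join", call. = FALSE)
  }
  rownames(samples) <- NULL
  list(matrix = matrix, samples = samples)
}
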