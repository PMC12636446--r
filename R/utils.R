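# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and an index, staying within 32-bit
# signed integer range.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 30269) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster labelings of the same items.
#' Used to score recovery of planted archetype structure.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar; 1 for identical partitions (up to relabeling),
#'   around 0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length", call. = FALSE)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  maximum <- (sum_i + sum_j) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

# FNV-1a hash of a character string, reported as 8 hex digits. Used to stamp
# pipeline outputs with a config fingerprint without external dependencies.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Pearson correlation between columns of two matrices, vectorised; returns a
# vector of per-column correlations. Columns with zero variance yield NA.
colwise_pearson <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == ncol(y))
  cx <- sweep(x, 2, colMeans(x))
  cy <- sweep(y, 2, colMeans(y))
  num <- colSums(cx * cy)
  den <- sqrt(colSums(cx^2) * colSums(cy^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
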