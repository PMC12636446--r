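# Shared fixtures and independent oracles for the test suite. Cohorts are
# generated once per session and memoized; all sizes are scaled down from
# the full stated world where a test only needs structure, not power.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small expression cohort: 8 archetypes x 10 genes, 60 individuals.
small_cohort <- function(seed = 1) {
  cached(paste0("cohort", seed), {
    co <- gen_expression_cohort(expression_sim_config(
      n_individuals = 60, n_genes_per_archetype = 10, seed = seed
    ))
    co$rpm <- rpm_normalize(drop_dead_genes(co$counts))
    co
  })
}

# Short behavioral config: compressed stages so a full track is ~200k
# frames lighter than the default world.
short_behavior_config <- function(...) {
  behavior_sim_config(
    stage_durations = c(90, 70, 70, 120), bout_durations = c(20, 20, 20),
    hatch_delay = 30, ...
  )
}

short_track <- function(seed = 5, ...) {
  cached(paste0("track", seed), gen_locomotion_track(short_behavior_config(), individual_seed = seed, ...))
}

# Hand-built speed series (minutes-scale) for bout-detection unit tests.
make_speed_series <- function(speed, frame_rate = 1) {
  structure(
    list(time_s = (seq_along(speed) - 1) / frame_rate, speed = speed,
         frame_rate = frame_rate, smoothing_window = 1L,
         individual_id = "fixture"),
    class = "speed_series"
  )
}

make_track <- function(x, y, frame_rate = 3, id = "fixture") {
  n <- length(x)
  structure(
    list(frames = data.frame(frame = seq_len(n) - 1L,
                             time_s = (seq_len(n) - 1) / frame_rate,
                             x = x, y = y),
         frame_rate = frame_rate, individual_id = id, arena_diameter = 10),
    class = "locomotion_track"
  )
}

# Brute-force Ward agglomeration via the Lance-Williams recurrence applied
# to the dissimilarities as given ("presquared" semantics). Independent of
# stats::hclust; O(n^3) enumeration of all merges.
bf_ward <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  active <- seq_len(n)
  sizes <- rep(1, n)
  members <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  cur <- D
  for (step in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (b <= a) next
        if (cur[a, b] < best[1]) best <- c(cur[a, b], a, b)
      }
    }
    a <- best[2]; b <- best[3]
    heights[step] <- best[1]
    ni <- sizes[a]; nj <- sizes[b]
    new_row <- vapply(seq_along(active), function(k) {
      if (k == a || k == b) return(NA_real_)
      nk <- sizes[k]
      ((ni + nk) * cur[a, k] + (nj + nk) * cur[b, k] - nk * cur[a, b]) /
        (ni + nj + nk)
    }, numeric(1))
    members[[a]] <- sort(c(members[[a]], members[[b]]))
    sizes[a] <- ni + nj
    cur[a, ] <- new_row; cur[, a] <- new_row
    keep <- setdiff(seq_along(active), b)
    cur <- cur[keep, keep, drop = FALSE]
    sizes <- sizes[keep]; members <- members[keep]; active <- active[keep]
    labs <- integer(n)
    for (ci in seq_along(members)) labs[members[[ci]]] <- ci
    partitions[[step]] <- labs
  }
  list(heights = heights, partitions = partitions)
}
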