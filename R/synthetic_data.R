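# Synthetic-data generators: staged locomotion tracks and expression cohorts
# with planted ground truth. Every downstream module is validated against the
# truth objects emitted here.

#' Configuration for the locomotion-track simulator
#'
#' Describes the stereotyped larval activity program of a single *C. elegans*
#' individual grown in a circular arena: a pre-hatch egg period, four active
#' larval stages (L1-L4) separated by three lethargus quiescence bouts, and a
#' collection moment somewhere inside L4. All durations are in minutes.
#'
#' @param frame_rate imaging rate, frames per second.
#' @param stage_durations length-4 numeric, activity-period durations (min)
#'   for L1-L4. The L4 entry is the maximum observable span; each individual
#'   is collected at `collection_age_L4` minutes into L4 (drawn uniformly
#'   over `[0, stage_durations[4]]` when `NA`).
#' @param bout_durations length-3 numeric, lethargus bout durations (min) at
#'   the L1/L2, L2/L3 and L3/L4 transitions.
#' @param hatch_delay minutes of pre-hatch (egg) inactivity at the start of
#'   the recording.
#' @param active_speed_mean,quiescent_speed_mean mean centroid speed
#'   (arena units/s) during activity and quiescence. Quiescent speeds are
#'   drawn from a half-normal with this mean, so bout detection thresholds
#'   are exercised non-trivially; 0 gives exactly stationary bouts.
#' @param jitter_sd per-individual multiplicative (lognormal) SD applied to
#'   stage and bout durations; 0 reproduces the schedule exactly.
#' @param arena_diameter circular arena diameter, arena units.
#' @param active_turn_sd,quiescent_turn_sd per-frame heading SD (radians)
#'   during activity/quiescence; activity defaults to roaming-grade low
#'   turning.
#' @param seed base seed used when a track-level seed is not given.
#' @return object of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(frame_rate = 3,
                                stage_durations = c(720, 480, 480, 600),
                                bout_durations = c(30, 30, 30),
                                hatch_delay = 60,
                                active_speed_mean = 0.15,
                                quiescent_speed_mean = 0.004,
                                jitter_sd = 0.05,
                                arena_diameter = 10,
                                active_turn_sd = 0.08,
                                quiescent_turn_sd = 0.6,
                                seed = 1L) {
  stopifnot_scalar_number(frame_rate, "frame_rate", positive = TRUE)
  if (length(stage_durations) != 4L || any(!is.finite(stage_durations)) || any(stage_durations <= 0)) {
    stop("`stage_durations` must be 4 positive durations (min)", call. = FALSE)
  }
  if (length(bout_durations) != 3L || any(!is.finite(bout_durations)) || any(bout_durations <= 0)) {
    stop("`bout_durations` must be 3 positive durations (min)", call. = FALSE)
  }
  stopifnot_scalar_number(hatch_delay, "hatch_delay", positive = TRUE)
  stopifnot_scalar_number(active_speed_mean, "active_speed_mean", positive = TRUE)
  stopifnot_scalar_number(quiescent_speed_mean, "quiescent_speed_mean")
  if (quiescent_speed_mean < 0 || quiescent_speed_mean >= active_speed_mean) {
    stop("`quiescent_speed_mean` must lie in [0, active_speed_mean)", call. = FALSE)
  }
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0", call. = FALSE)
  structure(
    list(
      frame_rate = frame_rate,
      stage_durations = as.numeric(stage_durations),
      bout_durations = as.numeric(bout_durations),
      hatch_delay = hatch_delay,
      active_speed_mean = active_speed_mean,
      quiescent_speed_mean = quiescent_speed_mean,
      jitter_sd = jitter_sd,
      arena_diameter = arena_diameter,
      active_turn_sd = active_turn_sd,
      quiescent_turn_sd = quiescent_turn_sd,
      seed = as.integer(seed)
    ),
    class = "behavior_sim_config"
  )
}

# Triangle-wave fold of a coordinate into [-h, h]; equivalent to specular
# reflection at the walls, so per-frame step lengths are preserved exactly.
fold_reflect <- function(u, h) {
  if (h <= 0) stop("fold half-width must be positive", call. = FALSE)
  p <- (u + h) %% (4 * h)
  over <- p > 2 * h
  p[over] <- 4 * h - p[over]
  p - h
}

#' Simulate one locomotion track with planted developmental structure
#'
#' Emits a frame-indexed XY centroid series whose speed alternates between an
#' active (roaming-grade) regime and low-speed quiescence bouts centered at
#' the planted stage transitions. Positions stay inside the circular arena
#' via specular reflection.
#'
#' @param config a [behavior_sim_config()].
#' @param individual_seed integer seed for this track.
#' @param individual_id character id stored on the track.
#' @param collection_age_L4 minutes into L4 at which the recording stops;
#'   `NA` draws uniformly over `[0, stage_durations[4]]`.
#' @return list with elements `track` (class `locomotion_track`) and `truth`
#'   (hatch/transition/collection times in minutes, plus the per-frame
#'   active/quiescent regime labels used).
#' @export
gen_locomotion_track <- function(config, individual_seed = config$seed,
                                 individual_id = sprintf("ind%03d", individual_seed %% 1000L),
                                 collection_age_L4 = NA_real_) {
  if (!inherits(config, "behavior_sim_config")) {
    stop("`config` must be a behavior_sim_config", call. = FALSE)
  }
  with_seed(individual_seed, {
    jit <- function(x) if (config$jitter_sd > 0) x * exp(stats::rnorm(length(x), 0, config$jitter_sd)) else x
    stages <- jit(config$stage_durations)
    bouts <- jit(config$bout_durations)
    if (is.na(collection_age_L4)) {
      collection_age_L4 <- stats::runif(1, 0, stages[4])
    }
    # schedule, minutes from recording start
    hatch <- config$hatch_delay
    seg_durs <- c(hatch, stages[1], bouts[1], stages[2], bouts[2], stages[3], bouts[3], collection_age_L4)
    seg_ends <- cumsum(seg_durs)
    quiescent_segs <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
    transitions <- seg_ends[c(2, 4, 6)] + bouts / 2
    total_min <- seg_ends[8]
    fr <- config$frame_rate
    n <- floor(total_min * 60 * fr)
    time_s <- (seq_len(n) - 1) / fr
    seg_idx <- findInterval(time_s / 60, c(0, seg_ends), rightmost.closed = TRUE)
    seg_idx[seg_idx > 8L] <- 8L
    quiet <- quiescent_segs[seg_idx]

    speed <- numeric(n)
    n_act <- sum(!quiet)
    # gamma(shape 9) keeps active speeds well away from zero
    speed[!quiet] <- config$active_speed_mean * stats::rgamma(n_act, shape = 9, rate = 9)
    if (config$quiescent_speed_mean > 0) {
      speed[quiet] <- abs(stats::rnorm(n - n_act, 0, config$quiescent_speed_mean * sqrt(pi / 2)))
    }
    turn_sd <- rep(config$active_turn_sd, n)
    turn_sd[quiet] <- config$quiescent_turn_sd
    heading <- cumsum(stats::rnorm(n, 0, 1) * turn_sd)
    step <- speed / fr
    half <- config$arena_diameter / (2 * sqrt(2))  # inscribed square half-side
    x <- fold_reflect(cumsum(step * cos(heading)), half)
    y <- fold_reflect(cumsum(step * sin(heading)), half)

    track <- structure(
      list(
        frames = data.frame(frame = seq_len(n) - 1L, time_s = time_s, x = x, y = y),
        frame_rate = fr,
        individual_id = individual_id,
        arena_diameter = config$arena_diameter
      ),
      class = "locomotion_track"
    )
    truth <- list(
      individual_id = individual_id,
      hatch_min = hatch,
      transitions_min = transitions,
      collection_min = total_min,
      collection_age_L4 = collection_age_L4,
      bout_intervals = cbind(start = seg_ends[c(2, 4, 6)], end = seg_ends[c(3, 5, 7)]),
      quiescent_frames = quiet
    )
    list(track = track, truth = truth)
  })
}

# ---------------------------------------------------------------------------
# Expression archetypes
# ---------------------------------------------------------------------------

#' The built-in temporal archetype library
#'
#' Eight parametric temporal shapes observed among developmentally dynamic
#' genes: monotone ramps up/down, a two-rate decay, an oscillation, rapid
#' ON/OFF switches, and localized (symmetric and asymmetric) expression
#' bursts. Shapes are positive, O(1)-scale functions of stage-relative age in
#' minutes.
#'
#' @param stage_span stage duration (min) the default parameters target.
#' @return named list of archetype descriptors; each has `fn(t, p)` and a
#'   `sample_params(span)` drawing per-gene parameters (gene-level parameter
#'   spread keeps within-archetype profiles coherent but not identical).
#' @export
archetype_library <- function(stage_span = 600) {
  T <- stage_span
  list(
    ramp_up = list(
      fn = function(t, p) 0.2 + 1.6 * pmin(pmax(t, 0), T) / T * p$scale,
      sample_params = function() list(scale = stats::runif(1, 0.85, 1.15))
    ),
    ramp_down = list(
      fn = function(t, p) 0.2 + 1.6 * (1 - pmin(pmax(t, 0), T) / T) * p$scale,
      sample_params = function() list(scale = stats::runif(1, 0.85, 1.15))
    ),
    two_rate_decay = list(
      fn = function(t, p) {
        0.1 + 1.9 * exp(-p$r1 * pmin(t, p$ts)) * exp(-p$r2 * pmax(t - p$ts, 0))
      },
      sample_params = function() list(
        r1 = stats::runif(1, 0.010, 0.014),
        r2 = stats::runif(1, 0.0015, 0.0030),
        ts = stats::runif(1, 0.28, 0.38) * T
      )
    ),
    oscillation = list(
      fn = function(t, p) 1 + 0.8 * sin(2 * pi * (t - p$phase) / p$period),
      sample_params = function() list(
        period = stats::runif(1, 0.97, 1.03) * 240,
        phase = stats::runif(1, -8, 8)
      )
    ),
    on_switch = list(
      fn = function(t, p) 0.1 + 1.8 / (1 + exp(-(t - p$ts) / p$w)),
      sample_params = function() list(ts = stats::runif(1, 0.45, 0.55) * T, w = stats::runif(1, 10, 20))
    ),
    off_switch = list(
      fn = function(t, p) 0.1 + 1.8 / (1 + exp((t - p$ts) / p$w)),
      sample_params = function() list(ts = stats::runif(1, 0.45, 0.55) * T, w = stats::runif(1, 10, 20))
    ),
    burst = list(
      fn = function(t, p) 0.1 + 1.9 * exp(-(t - p$center)^2 / (2 * p$width^2)),
      sample_params = function() list(
        center = stats::runif(1, 0.52, 0.60) * T,
        width = stats::runif(1, 40, 50)
      )
    ),
    burst_asym = list(
      fn = function(t, p) {
        w <- ifelse(t < p$center, p$rise, p$decay)
        0.1 + 1.9 * exp(-(t - p$center)^2 / (2 * w^2))
      },
      sample_params = function() list(
        center = stats::runif(1, 0.28, 0.36) * T,
        rise = stats::runif(1, 18, 25),
        decay = stats::runif(1, 70, 90)
      )
    )
  )
}

#' Stationary noise-free cohort for gap-correlation validation
#'
#' Builds a deterministic cohort whose pairwise profile correlation is an
#' exact, strictly decreasing function of the age gap. Genes come in
#' quadrature quadruples `1 +/- a*cos(w t)`, `1 +/- a*sin(w t)` over a fixed
#' grid of frequencies (half-normal quantiles with scale `sigma_freq`), so
#' that across genes the mean profile is exactly constant and the Pearson
#' correlation between two samples equals `mean(cos(w * gap))` -- a smooth
#' deterministic decay. Use with raw-scale correlations (`use_log = FALSE`).
#'
#' @param n_individuals samples to draw (ages uniform over the span).
#' @param n_freqs frequency-grid size; emits `4 * n_freqs` genes.
#' @param sigma_freq frequency scale (rad/min); the expected correlation
#'   decays like `exp(-(sigma_freq * gap)^2 / 2)`.
#' @param stage_span stage duration, minutes.
#' @param baseline_mean expected counts at shape 1.
#' @param amplitude cosine amplitude (< 1 keeps shapes positive).
#' @param seed seed for the collection ages.
#' @return list with `counts` ([expression_matrix()]), `samples` (ages
#'   table), and `expected_r(gap)` -- the closed-form correlation function.
#' @export
gen_stationary_cohort <- function(n_individuals = 193, n_freqs = 64,
                                  sigma_freq = 0.004, stage_span = 600,
                                  baseline_mean = 200, amplitude = 0.45,
                                  seed = 1L) {
  if (amplitude <= 0 || amplitude >= 1) stop("`amplitude` must be in (0,1)", call. = FALSE)
  ages <- with_seed(seed, stats::runif(n_individuals, 0, stage_span))
  w <- sigma_freq * stats::qnorm(0.5 + ((seq_len(n_freqs) - 0.5) / n_freqs) / 2)
  shapes <- matrix(0, 4 * n_freqs, n_individuals)
  ids <- character(4 * n_freqs)
  for (k in seq_len(n_freqs)) {
    ck <- cos(w[k] * ages); sk <- sin(w[k] * ages)
    base <- (k - 1) * 4
    shapes[base + 1, ] <- 1 + amplitude * ck
    shapes[base + 2, ] <- 1 - amplitude * ck
    shapes[base + 3, ] <- 1 + amplitude * sk
    shapes[base + 4, ] <- 1 - amplitude * sk
    ids[base + 1:4] <- sprintf("freq%03d_%s", k, c("cp", "cm", "sp", "sm"))
  }
  counts <- baseline_mean * shapes
  dimnames(counts) <- list(ids, sprintf("stat_s%03d", seq_len(n_individuals)))
  list(
    counts = expression_matrix(counts, unit = "counts", log = "stationary cohort"),
    samples = data.frame(
      sample_id = colnames(counts),
      individual_id = sub("_s", "_i", colnames(counts)),
      genotype = "sim", age_since_L4 = ages,
      age_since_hatch = ages + 1830, stringsAsFactors = FALSE
    ),
    expected_r = function(gap) vapply(gap, function(d) mean(cos(w * d)), numeric(1))
  )
}

#' Configuration for the expression-cohort simulator
#'
#' @param n_individuals number of sampled individuals (one sample each).
#' @param stage_span stage duration in minutes over which collection ages are
#'   drawn uniformly.
#' @param n_genes_per_archetype genes planted per archetype.
#' @param archetypes character vector naming entries of
#'   [archetype_library()], or a custom library in the same format.
#' @param baseline_mean expected counts for a shape value of 1 at the mean
#'   library size.
#' @param dispersion negative-binomial overdispersion (`size = 1/dispersion`);
#'   0 emits the deterministic scaled means (noise-free limit).
#' @param library_size_range length-2 range of per-sample total-read scale;
#'   each sample's library factor is uniform over this range divided by its
#'   midpoint.
#' @param prestage_mean mean hatch-to-stage-onset duration (min); hatch-aligned
#'   age = stage age + this duration, jittered per individual.
#' @param jitter_sd lognormal SD of the per-individual pre-stage duration, so
#'   hatch alignment is strictly noisier than stage alignment when positive.
#' @param genotype cohort genotype label.
#' @param genotype_effect `NULL`, or
#'   `list(genes = <ids or indices>, fold = <x>, window_min = c(lo, hi))`:
#'   multiplies the expected expression of those genes by `fold` for samples
#'   whose stage age falls in the window.
#' @param sampling `"uniform"` (ages uniform over the span),
#'   `"stratified"` (equal sample counts in each 60-min window, uniform
#'   within -- the balanced per-bin design used for differential testing),
#'   or `"clustered"` (ages drawn from a few gaussian clumps; stress-test
#'   design).
#' @param seed integer seed for ages, library sizes and count noise.
#' @param param_seed seed for the per-gene archetype parameter draws;
#'   defaults to `seed`. Two cohorts generated with the same `param_seed`
#'   but different `seed` share their gene-level truth and differ only in
#'   individuals and noise -- the paired-genotype (and null-comparison)
#'   design.
#' @return object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_individuals = 193,
                                  stage_span = 600,
                                  n_genes_per_archetype = 50,
                                  archetypes = names(archetype_library()),
                                  baseline_mean = 200,
                                  dispersion = 0.1,
                                  library_size_range = c(8e5, 1.2e6),
                                  prestage_mean = 1830,
                                  jitter_sd = 0.1,
                                  genotype = "N2",
                                  genotype_effect = NULL,
                                  sampling = c("uniform", "stratified", "clustered"),
                                  seed = 1L, param_seed = seed) {
  if (n_individuals < 2) stop("`n_individuals` must be >= 2", call. = FALSE)
  stopifnot_scalar_number(stage_span, "stage_span", positive = TRUE)
  if (dispersion < 0) stop("`dispersion` must be >= 0", call. = FALSE)
  if (is.character(archetypes)) {
    lib <- archetype_library(stage_span)
    missing <- setdiff(archetypes, names(lib))
    if (length(missing)) stop("unknown archetypes: ", paste(missing, collapse = ", "), call. = FALSE)
    archetypes <- lib[archetypes]
  }
  if (length(archetypes) == 0) stop("archetype list must be non-empty", call. = FALSE)
  sampling <- match.arg(sampling)
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      stage_span = stage_span,
      n_genes_per_archetype = as.integer(n_genes_per_archetype),
      archetypes = archetypes,
      baseline_mean = baseline_mean,
      dispersion = dispersion,
      library_size_range = as.numeric(library_size_range),
      prestage_mean = prestage_mean,
      jitter_sd = jitter_sd,
      genotype = genotype,
      genotype_effect = genotype_effect,
      sampling = sampling,
      seed = as.integer(seed),
      param_seed = as.integer(param_seed)
    ),
    class = "expression_sim_config"
  )
}

#' Simulate a single-animal expression cohort with planted temporal structure
#'
#' Draws collection ages across the stage, evaluates each gene's archetype at
#' the individual's stage-relative age, scales to expected counts by library
#' size, and adds negative-binomial noise. Hatch-relative ages carry an
#' individual-specific jittered pre-stage duration, making hatch alignment
#' strictly noisier than stage alignment.
#'
#' @param config an [expression_sim_config()].
#' @return list with `counts` (an [expression_matrix()] of unit `"counts"`),
#'   `samples` (a sample table data.frame: sample_id, individual_id,
#'   genotype, age_since_L4, age_since_hatch), and `truth` (per-gene
#'   archetype labels and parameters, per-individual timing, any genotype
#'   effect planted).
#' @export
gen_expression_cohort <- function(config) {
  if (!inherits(config, "expression_sim_config")) {
    stop("`config` must be an expression_sim_config", call. = FALSE)
  }
  arch_names <- names(config$archetypes)
  gene_params <- with_seed(config$param_seed, {
    lapply(arch_names, function(a) {
      lapply(seq_len(config$n_genes_per_archetype),
             function(j) config$archetypes[[a]]$sample_params())
    })
  })
  with_seed(config$seed, {
    n <- config$n_individuals
    span <- config$stage_span
    ages <- switch(config$sampling,
      uniform = stats::runif(n, 0, span),
      stratified = {
        nb <- max(1L, floor(span / 60))
        per <- rep(n %/% nb, nb)
        if (n %% nb) per[seq_len(n %% nb)] <- per[seq_len(n %% nb)] + 1L
        unlist(lapply(seq_len(nb), function(k) {
          stats::runif(per[k], (k - 1) * 60, k * 60)
        }))
      },
      clustered = {
        centers <- stats::runif(5, 0, span)
        pmin(pmax(stats::rnorm(n, sample(centers, n, replace = TRUE), span / 40), 0), span)
      }
    )
    prestage <- if (config$jitter_sd > 0) {
      config$prestage_mean * exp(stats::rnorm(n, 0, config$jitter_sd))
    } else {
      rep(config$prestage_mean, n)
    }
    sample_ids <- sprintf("%s_s%03d", config$genotype, seq_len(n))
    samples <- data.frame(
      sample_id = sample_ids,
      individual_id = sprintf("%s_i%03d", config$genotype, seq_len(n)),
      genotype = config$genotype,
      age_since_L4 = ages,
      age_since_hatch = ages + prestage,
      stringsAsFactors = FALSE
    )

    n_genes <- length(arch_names) * config$n_genes_per_archetype
    gene_ids <- character(n_genes)
    flat_params <- vector("list", n_genes)
    mu_shape <- matrix(0, n_genes, n)
    g <- 0L
    for (ai in seq_along(arch_names)) {
      arch <- config$archetypes[[arch_names[ai]]]
      for (j in seq_len(config$n_genes_per_archetype)) {
        g <- g + 1L
        gene_ids[g] <- sprintf("%s_g%02d", arch_names[ai], j)
        p <- gene_params[[ai]][[j]]
        flat_params[[g]] <- p
        mu_shape[g, ] <- arch$fn(ages, p)
      }
    }
    mu_shape[mu_shape < 0] <- 0

    lib <- stats::runif(n, config$library_size_range[1], config$library_size_range[2])
    lib_factor <- lib / mean(config$library_size_range)
    mu <- config$baseline_mean * mu_shape * rep(lib_factor, each = n_genes)

    eff <- config$genotype_effect
    if (!is.null(eff)) {
      gi <- if (is.character(eff$genes)) match(eff$genes, gene_ids) else as.integer(eff$genes)
      if (anyNA(gi)) stop("genotype_effect names genes not in the cohort", call. = FALSE)
      si <- which(ages >= eff$window_min[1] & ages < eff$window_min[2])
      mu[gi, si] <- mu[gi, si] * eff$fold
    }

    counts <- if (config$dispersion == 0) {
      mu
    } else {
      matrix(
        stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / config$dispersion),
        n_genes, n
      )
    }
    dimnames(counts) <- list(gene_ids, sample_ids)

    truth <- list(
      timeline = data.frame(
        individual_id = samples$individual_id,
        prestage_min = prestage,
        age_since_L4 = ages,
        age_since_hatch = ages + prestage,
        stringsAsFactors = FALSE
      ),
      genes = data.frame(
        gene_id = gene_ids,
        archetype = rep(arch_names, each = config$n_genes_per_archetype),
        stringsAsFactors = FALSE
      ),
      gene_params = stats::setNames(flat_params, gene_ids),
      genotype_effect = eff
    )
    list(
      counts = expression_matrix(counts, unit = "counts", log = "simulated counts"),
      samples = samples,
      truth = truth
    )
  })
}
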