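# Evaluation statistics: prediction error, segmentation agreement against a
# normative boundary series, partition-agreement scores, length-preserving
# permutation nulls, and boundary-interval (flurry) statistics.

#' Validation prediction error
#'
#' Mean over activities of the mean over timesteps of the squared Euclidean
#' prediction error, computed from event traces.
#'
#' @param traces list of per-activity trace data.frames with a `pe` column
#'   (Euclidean error per timestep).
#' @return Nonnegative scalar.
#' @export
validation_pe <- function(traces) {
  if (length(traces) == 0L) stop("no traces")
  mean(vapply(traces, function(tr) mean(tr$pe^2), numeric(1)))
}

#' Normative boundary series from a set of raters
#'
#' For each timestep, the proportion of raters who placed at least one
#' boundary in that timestep's bin. Boundary times are binned by
#' `floor(time / dt)` and clipped into `[0, T - 1]`.
#'
#' @param raters list of [rater_segmentation()] objects for one activity.
#' @param T number of timesteps.
#' @param dt seconds per timestep.
#' @return Numeric vector of length `T` with entries in `[0, 1]`.
#' @export
normative_series <- function(raters, T, dt) {
  if (length(raters) == 0L) stop("need at least one rater")
  counts <- numeric(T)
  for (r in raters) {
    bins <- pmin(pmax(floor(r$boundary_times / dt), 0), T - 1)
    counts[unique(bins) + 1] <- counts[unique(bins) + 1] + 1
  }
  counts / length(raters)
}

#' Scaled point-biserial segmentation agreement
#'
#' Pearson correlation between a binary boundary series and a continuous
#' normative series, rescaled by the minimum and maximum correlation
#' achievable with the same boundary count: `r_max` places the B boundaries
#' at the B largest normative values, `r_min` at the B smallest. The result
#' is `(r - r_min) / (r_max - r_min)`, in `[0, 1]` whenever defined, and 1
#' exactly when the placement is optimal for its count.
#'
#' @param boundaries binary 0/1 vector.
#' @param normative numeric vector of the same length (proportion of raters
#'   segmenting at each timestep).
#' @return Scalar in `[0, 1]`, or `NA` with a warning when undefined (no
#'   boundaries, all boundaries, or a constant normative series).
#' @export
scaled_point_biserial <- function(boundaries, normative) {
  if (length(boundaries) != length(normative)) stop("length mismatch")
  B <- sum(boundaries)
  n <- length(boundaries)
  if (B == 0 || B == n || stats::sd(normative) == 0) {
    warning("scaled point-biserial undefined (degenerate boundaries or ",
            "constant normative series)")
    return(NA_real_)
  }
  r <- stats::cor(boundaries, normative)
  ord <- order(normative, decreasing = TRUE)
  top <- integer(n); top[ord[seq_len(B)]] <- 1L
  bot <- integer(n); bot[ord[n - seq_len(B) + 1L]] <- 1L
  r_max <- stats::cor(top, normative)
  r_min <- stats::cor(bot, normative)
  if (r_max == r_min) {
    warning("scaled point-biserial undefined (no spread in achievable r)")
    return(NA_real_)
  }
  (r - r_min) / (r_max - r_min)
}

entropy_nat <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Expected mutual information under the hypergeometric permutation model.
expected_mi <- function(a, b, N) {
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - N)
      hi <- min(ai, bj)
      if (lo > hi) next
      for (nij in lo:hi) {
        lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(N - ai + 1) +
          lgamma(N - bj + 1) - lgamma(N + 1) - lgamma(nij + 1) -
          lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
          lgamma(N - ai - bj + nij + 1)
        emi <- emi + (nij / N) * log(N * nij / (ai * bj)) * exp(lp)
      }
    }
  }
  emi
}

#' Adjusted mutual information between two partitions
#'
#' Mutual information between two label sequences over the same timesteps,
#' adjusted for chance by subtracting the expected mutual information under
#' the hypergeometric permutation model and normalizing by the larger of the
#' two entropies (max normalization). Identical partitions score 1; the
#' score is invariant to relabeling either side.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return Scalar `<= 1`.
#' @export
adjusted_mutual_information <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  N <- length(labels_a)
  tab <- table(labels_a, labels_b)
  a <- rowSums(tab)
  b <- colSums(tab)
  h_a <- entropy_nat(a)
  h_b <- entropy_nat(b)
  if (h_a == 0 && h_b == 0) return(1)   # both trivial partitions agree
  mi <- 0
  nz <- which(tab > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(nz))) {
    nij <- tab[nz[i, 1], nz[i, 2]]
    mi <- mi + (nij / N) * log(N * nij / (a[nz[i, 1]] * b[nz[i, 2]]))
  }
  emi <- expected_mi(a, b, N)
  denom <- max(h_a, h_b) - emi
  if (denom == 0) return(0)
  unname((mi - emi) / denom)
}

#' Purity and coverage of a model partition against a reference
#'
#' Purity: each model cluster is credited with its largest overlap with any
#' reference class, summed and divided by N (penalizes mixed model
#' clusters). Coverage: the same with roles swapped (penalizes fragmented
#' reference classes). A partition that strictly refines the reference has
#' purity 1 and coverage < 1.
#'
#' @param model_labels,true_labels label vectors of equal length.
#' @return Named numeric vector `c(purity = ..., coverage = ...)`.
#' @export
purity_coverage <- function(model_labels, true_labels) {
  if (length(model_labels) != length(true_labels)) stop("length mismatch")
  N <- length(model_labels)
  tab <- table(model_labels, true_labels)
  c(purity = sum(apply(tab, 1, max)) / N,
    coverage = sum(apply(tab, 2, max)) / N)
}

label_runs <- function(labels) {
  r <- rle(as.vector(labels))
  data.frame(value = r$values, length = r$lengths,
             onset = cumsum(c(0L, r$lengths[-length(r$lengths)])),
             stringsAsFactors = FALSE)
}

#' Length-preserving permutations of event-label runs
#'
#' Shuffles the order of the runs (events) of a concatenated label sequence,
#' preserving the multiset of run lengths, so each permutation carries the
#' same number of boundaries and the same event-length distribution as the
#' original. Permutations whose boundaries fall inside an activity gap
#' interval — from the onset of the last event of one activity to the onset
#' of the first event of the next, where neither humans nor the model place
#' boundaries — are rejection-sampled away (up to `max_tries` per
#' permutation; failures are kept but flagged).
#'
#' @param labels concatenated per-timestep label vector.
#' @param offsets 0-based start indices of each activity within `labels`
#'   (first element 0).
#' @param n number of permutations.
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap per permutation.
#' @return List of class `"sem_permnull"` with `perms` (list of label
#'   vectors), `gap_intervals`, and `unsatisfied` (logical per permutation).
#' @export
permute_events <- function(labels, offsets, n, seed = 1L,
                           max_tries = 1000L) {
  set.seed(seed)
  runs <- label_runs(labels)
  N <- length(labels)
  # gap intervals in concatenated 0-based time
  gaps <- NULL
  if (length(offsets) > 1L) {
    gaps <- t(vapply(seq_len(length(offsets) - 1L), function(i) {
      act_end <- offsets[i + 1L]          # exclusive end of activity i
      last_onset <- max(runs$onset[runs$onset < act_end])
      c(lo = last_onset, hi = act_end)
    }, numeric(2)))
  }
  ok_boundaries <- function(onsets) {
    b <- onsets[onsets > 0]
    if (is.null(gaps) || length(b) == 0L) return(TRUE)
    for (i in seq_len(nrow(gaps))) {
      if (any(b > gaps[i, 1] & b < gaps[i, 2])) return(FALSE)
    }
    TRUE
  }
  perms <- vector("list", n)
  unsatisfied <- logical(n)
  for (p in seq_len(n)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      ord <- sample(nrow(runs))
      onsets <- cumsum(c(0L, runs$length[ord][-nrow(runs)]))
      if (ok_boundaries(onsets) || tries >= max_tries) break
    }
    unsatisfied[p] <- tries >= max_tries && !ok_boundaries(onsets)
    perms[[p]] <- rep(runs$value[ord], runs$length[ord])
  }
  structure(list(perms = perms, gap_intervals = gaps,
                 unsatisfied = unsatisfied, runs = runs),
            class = "sem_permnull")
}

#' Boundary-interval (flurry) statistics
#'
#' Durations between successive boundaries, in seconds, and the share of
#' durations strictly below a threshold (default 1 s) — a "flurry" is a
#' burst of transitions in rapid succession before the model settles.
#'
#' @param boundaries binary 0/1 vector.
#' @param dt seconds per timestep.
#' @param threshold_s flurry threshold in seconds.
#' @return List with `intervals` (numeric, seconds; empty with < 2
#'   boundaries) and `fraction_below` (`NA` when undefined).
#' @export
boundary_interval_stats <- function(boundaries, dt, threshold_s = 1.0) {
  times <- (which(boundaries == 1) - 1) * dt
  if (length(times) < 2L) {
    return(list(intervals = numeric(0), fraction_below = NA_real_))
  }
  intervals <- diff(times)
  list(intervals = intervals,
       fraction_below = mean(intervals < threshold_s))
}

#' Schema spawn and reuse rates across training
#'
#' Bins the training activities and reports, per bin, the spawn rate (SPAWN
#' decisions per activity) and the reuse rate (the fraction of schema
#' transitions that switch to a previously spawned schema rather than spawn
#' a new one; `NA` in bins with no transitions).
#'
#' @param traces list of per-activity training trace data.frames, in
#'   training order, with a `decision` column.
#' @param bin_activities bin width in activities.
#' @return data.frame with columns `bin`, `activities`, `spawn_rate`,
#'   `reuse_rate`.
#' @export
schema_usage_curves <- function(traces, bin_activities = 10L) {
  if (length(traces) == 0L) stop("no traces")
  bins <- split(seq_along(traces),
                ceiling(seq_along(traces) / bin_activities))
  do.call(rbind, lapply(seq_along(bins), function(b) {
    dec <- unlist(lapply(traces[bins[[b]]], function(tr) tr$decision))
    spawns <- sum(dec == "SPAWN")
    switches <- sum(dec == "SWITCH")
    data.frame(bin = b, activities = length(bins[[b]]),
               spawn_rate = spawns / length(bins[[b]]),
               reuse_rate = if (spawns + switches == 0) NA_real_ else
                 switches / (spawns + switches))
  }))
}

#' Leave-one-out rater agreement
#'
#' Scaled point-biserial of each rater's boundaries against the normative
#' series of the remaining raters — the human-to-human agreement reference.
#'
#' @param raters list of [rater_segmentation()] objects for one activity.
#' @param T,dt timestep count and duration.
#' @return Numeric vector, one agreement value per rater (`NA` where
#'   undefined).
#' @export
rater_agreement <- function(raters, T, dt) {
  vapply(seq_along(raters), function(i) {
    others <- normative_series(raters[-i], T, dt)
    bins <- pmin(pmax(floor(raters[[i]]$boundary_times / dt), 0), T - 1)
    ind <- integer(T)
    ind[unique(bins) + 1] <- 1L
    if (sum(ind) == 0 || sum(ind) == T || stats::sd(others) == 0) {
      return(NA_real_)
    }
    suppressWarnings(scaled_point_biserial(ind, others))
  }, numeric(1))
}
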