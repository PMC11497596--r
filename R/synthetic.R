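# Synthetic activity generator: multi-actor, multi-environment activities
# composed of 6-7 scripted events, each event class with its own stable
# short-run dynamics, plus simulated boundary raters. This is the test bed
# every other module is exercised against: it emulates the statistical
# structure of feature-reduced naturalistic activity recordings (block
# layout, event-class recurrence across actors, noisy human segmentation)
# without any claim to photorealism.

#' Generator configuration
#'
#' @param n_classes number of event classes (>= 2).
#' @param layout scene block layout (see [scene_layout()]).
#' @param separation scale of inter-class attractor distances; pairwise
#'   offset distances grow linearly with it.
#' @param noise_sd emission noise standard deviation per dimension.
#' @param n_actors number of actors; each has an additive style offset.
#' @param actor_offset_sd standard deviation of actor style offsets.
#' @param n_train,n_validation activity counts per split.
#' @param script_length_range inclusive range of events per activity.
#' @param event_duration_range inclusive range (timesteps) of event
#'   durations; minimum 3.
#' @param dt seconds per timestep.
#' @param seed integer seed; the whole corpus is a pure function of the
#'   config.
#' @return List of class `"sem_genconfig"`.
#' @export
generator_config <- function(n_classes = 4L, layout = scene_layout(),
                             separation = 3, noise_sd = 0.05,
                             n_actors = 3L, actor_offset_sd = 0.1,
                             n_train = 30L, n_validation = 6L,
                             script_length_range = c(6L, 7L),
                             event_duration_range = c(5L, 9L),
                             dt = 1 / 3, seed = 1L) {
  stopifnot(n_classes >= 2, separation >= 0, noise_sd >= 0,
            event_duration_range[1] >= 3,
            script_length_range[1] >= 1)
  structure(list(n_classes = as.integer(n_classes), layout = layout,
                 separation = separation, noise_sd = noise_sd,
                 n_actors = as.integer(n_actors),
                 actor_offset_sd = actor_offset_sd,
                 n_train = as.integer(n_train),
                 n_validation = as.integer(n_validation),
                 script_length_range = as.integer(script_length_range),
                 event_duration_range = as.integer(event_duration_range),
                 dt = dt, seed = as.integer(seed)),
            class = "sem_genconfig")
}

random_rotation <- function(d) {
  q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  q
}

#' Draw the event classes of a synthetic corpus
#'
#' Each class has a stable linear recurrence on the motion block (a scaled
#' random rotation with spectral radius < 1), a class attractor offset on
#' the motion and semantic blocks whose scale is `separation`, and the
#' shared emission noise level.
#'
#' @param config a [generator_config()]. Uses the current RNG; seed the
#'   session or call via [generate_corpus()].
#' @return List of event-class objects.
#' @export
make_classes <- function(config) {
  lay <- config$layout
  D <- sum(lay)
  m_idx <- block_indices(lay, "motion")
  s_idx <- block_indices(lay, "semantic")
  lapply(seq_len(config$n_classes), function(cid) {
    rho <- stats::runif(1, 0.6, 0.85)
    A <- rho * random_rotation(length(m_idx))
    offset <- numeric(D)
    offset[m_idx] <- config$separation *
      stats::rnorm(length(m_idx)) / sqrt(length(m_idx))
    offset[s_idx] <- config$separation *
      stats::rnorm(length(s_idx)) / sqrt(length(s_idx))
    list(id = cid, A = A, rho = rho, offset = offset,
         noise_sd = config$noise_sd)
  })
}

#' Generate one synthetic activity from a script
#'
#' Concatenates per-event trajectories: within each event the motion block
#' relaxes toward the event class's attractor under its stable recurrence,
#' the semantic block is piecewise constant (class offset plus a small
#' per-event instance jitter), the two object-change flags spike at event
#' onsets and offsets, and the luminance dimension follows a slow
#' autoregression. Gaussian emission noise is added throughout.
#'
#' @param id activity id.
#' @param script integer vector of event-class ids.
#' @param classes list from [make_classes()].
#' @param actor_offset additive style vector (length D).
#' @param config a [generator_config()].
#' @param actor_id,environment_id annotations.
#' @return A [sem_activity()] with `true_labels` filled.
#' @export
generate_activity <- function(id, script, classes, actor_offset, config,
                              actor_id = NA, environment_id = NA) {
  lay <- config$layout
  D <- sum(lay)
  m_idx <- block_indices(lay, "motion")
  s_idx <- block_indices(lay, "semantic")
  o_idx <- block_indices(lay, "object_change")
  l_idx <- block_indices(lay, "luminance")

  durs <- sample(seq(config$event_duration_range[1],
                     config$event_duration_range[2]),
                 length(script), replace = TRUE)
  T <- sum(durs)
  scenes <- matrix(0, T, D)
  labels <- integer(T)
  x <- classes[[script[1]]]$offset[m_idx]   # motion state starts on-attractor
  lum <- 0
  t <- 0L
  for (e in seq_along(script)) {
    cl <- classes[[script[e]]]
    sem_jitter <- stats::rnorm(length(s_idx), 0, 0.1)
    for (u in seq_len(durs[e])) {
      t <- t + 1L
      off_m <- cl$offset[m_idx] + actor_offset[m_idx]
      x <- off_m + cl$A %*% (x - off_m) +
        stats::rnorm(length(m_idx), 0, cl$noise_sd)
      x <- as.numeric(x)
      scenes[t, m_idx] <- x
      scenes[t, s_idx] <- cl$offset[s_idx] + actor_offset[s_idx] +
        sem_jitter + stats::rnorm(length(s_idx), 0, cl$noise_sd)
      scenes[t, o_idx] <- c(as.numeric(u == 1L), as.numeric(u == durs[e]))
      lum <- 0.95 * lum + stats::rnorm(1, 0, 0.05)
      scenes[t, l_idx] <- lum
      labels[t] <- cl$id
    }
  }
  sem_activity(id, scenes, dt = config$dt, true_labels = labels,
               actor_id = actor_id, environment_id = environment_id,
               layout = lay)
}

#' Generate a full synthetic corpus
#'
#' Training and validation activities share the same event classes and
#' overlapping actors but have independently drawn scripts, so validation
#' tests generalization across instances of the same classes, not
#' memorization. Every class is guaranteed to appear in at least one
#' training activity.
#'
#' @param config a [generator_config()].
#' @return A [sem_corpus()].
#' @export
generate_corpus <- function(config) {
  set.seed(config$seed)
  classes <- make_classes(config)
  D <- sum(config$layout)
  actor_offsets <- lapply(seq_len(config$n_actors), function(a) {
    stats::rnorm(D, 0, config$actor_offset_sd)
  })
  n_total <- config$n_train + config$n_validation
  make_script <- function() {
    len <- sample(seq(config$script_length_range[1],
                      config$script_length_range[2]), 1)
    sample(config$n_classes, len, replace = TRUE)
  }
  scripts <- replicate(n_total, make_script(), simplify = FALSE)
  # guarantee class coverage in training
  missing <- setdiff(seq_len(config$n_classes),
                     unique(unlist(scripts[seq_len(config$n_train)])))
  if (length(missing) > 0L) {
    scripts[[1]][seq_along(missing)] <- missing
  }
  activities <- lapply(seq_len(n_total), function(i) {
    actor <- ((i - 1L) %% config$n_actors) + 1L
    generate_activity(sprintf("act%03d", i), scripts[[i]], classes,
                      actor_offsets[[actor]], config,
                      actor_id = paste0("actor", actor),
                      environment_id = paste0("env",
                                              ((i - 1L) %% 2L) + 1L))
  })
  split <- c(rep("train", config$n_train),
             rep("validation", config$n_validation))
  names(split) <- vapply(activities, function(a) a$id, character(1))
  corp <- sem_corpus(activities, split)
  attr(corp, "classes") <- classes
  attr(corp, "config") <- config
  corp
}

#' Simulate human boundary raters for an activity
#'
#' Each simulated rater starts from the activity's true event boundaries,
#' drops each with probability `miss_prob`, jitters the rest with Gaussian
#' noise (SD `jitter_sd_s` seconds), and adds Poisson false alarms at
#' `false_alarm_rate` per minute, uniformly over the activity span. Times
#' are clipped to the span.
#'
#' @param activity a labeled [sem_activity()].
#' @param n_raters number of raters.
#' @param jitter_sd_s boundary jitter SD in seconds.
#' @param miss_prob per-boundary miss probability.
#' @param false_alarm_rate false alarms per minute.
#' @param grain segmentation grain recorded on the raters.
#' @param seed integer seed.
#' @return List of [rater_segmentation()] objects.
#' @export
simulate_raters <- function(activity, n_raters = 30L, jitter_sd_s = 0.5,
                            miss_prob = 0.2, false_alarm_rate = 1,
                            grain = "fine", seed = 1L) {
  if (is.null(activity$true_labels)) stop("activity has no true labels")
  set.seed(seed)
  T <- nrow(activity$scenes)
  dt <- activity$dt
  span <- T * dt
  true_times <- (which(labels_to_boundaries(activity$true_labels) == 1) - 1) *
    dt
  lapply(seq_len(n_raters), function(r) {
    keep <- stats::runif(length(true_times)) >= miss_prob
    times <- true_times[keep] +
      stats::rnorm(sum(keep), 0, jitter_sd_s)
    n_fa <- stats::rpois(1, false_alarm_rate * span / 60)
    times <- c(times, stats::runif(n_fa, 0, span))
    times <- pmin(pmax(times, 0), span)
    rater_segmentation(paste0("rater", r), activity$id, times,
                       grain = grain, span = span)
  })
}
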