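# Shared fixtures, all built in code.

# Minimal activity: deterministic ramp scenes, optional labels.
toy_activity <- function(id = "a1", T = 10, D = 30, labels = NULL,
                         dt = 1 / 3) {
  scenes <- matrix(seq_len(T * D) / (T * D), T, D)
  sem_activity(id, scenes, dt = dt, true_labels = labels)
}

toy_corpus <- function(n_train = 2, n_val = 1, T = 10, D = 30) {
  n <- n_train + n_val
  acts <- lapply(seq_len(n), function(i) {
    set.seed(i)
    sem_activity(paste0("a", i), matrix(rnorm(T * D), T, D))
  })
  split <- c(rep("train", n_train), rep("validation", n_val))
  names(split) <- paste0("a", seq_len(n))
  sem_corpus(acts, split)
}

# Small synthetic corpus at the generator's study conditions but fewer
# activities, for fast end-to-end runs.
small_gen_corpus <- function(n_train = 3, n_val = 2, seed = 2) {
  generate_corpus(generator_config(n_train = n_train, n_validation = n_val,
                                   seed = seed))
}

# Two-phase curriculum corpus: phase A activities use classes 1..2, phase B
# classes 3..4, validation held out from phase A.
curriculum_corpus <- function(seed = 7, n_a = 8, n_b = 8, n_val = 4) {
  cfg <- generator_config(seed = seed)
  set.seed(seed)
  classes <- make_classes(cfg)
  offs <- lapply(1:2, function(a) rnorm(sum(cfg$layout), 0,
                                        cfg$actor_offset_sd))
  mk <- function(id, cls, actor) {
    script <- sample(cls, sample(6:7, 1), replace = TRUE)
    generate_activity(id, script, classes, offs[[actor]], cfg,
                      actor_id = paste0("actor", actor))
  }
  acts <- c(lapply(seq_len(n_a), function(i)
              mk(sprintf("a%02d", i), 1:2, 1 + i %% 2)),
            lapply(seq_len(n_b), function(i)
              mk(sprintf("b%02d", i), 3:4, 1 + i %% 2)),
            lapply(seq_len(n_val), function(i)
              mk(sprintf("v%02d", i), 1:2, 1 + i %% 2)))
  split <- c(rep("train", n_a + n_b), rep("validation", n_val))
  names(split) <- vapply(acts, function(a) a$id, character(1))
  list(corpus = sem_corpus(acts, split),
       phase_a = sprintf("a%02d", seq_len(n_a)),
       phase_b = sprintf("b%02d", seq_len(n_b)))
}

# Decision sequence of a fit (training), for equivalence checks.
decision_sequence <- function(fit) {
  unlist(lapply(fit$train_traces, function(tr)
    paste(tr$decision, tr$schema)))
}

validation_decision_sequence <- function(fit) {
  unlist(lapply(validation_labels(fit)$traces, function(tr)
    paste(tr$decision, tr$schema)))
}

# Boundaries of a permuted concatenated label sequence, computed per
# activity so joins are not boundaries.
permuted_boundaries <- function(perm, offsets) {
  b <- integer(length(perm))
  for (i in seq_along(offsets)) {
    lo <- offsets[i] + 1
    hi <- if (i < length(offsets)) offsets[i + 1] else length(perm)
    b[lo:hi] <- labels_to_boundaries(perm[lo:hi])
  }
  b
}

# Concatenated normative series over a fit's validation activities, from
# simulated raters.
validation_normative <- function(corpus, activity_ids, seed = 7) {
  unlist(lapply(seq_along(activity_ids), function(i) {
    a <- corpus$activities[[activity_ids[i]]]
    normative_series(simulate_raters(a, seed = seed + i),
                     nrow(a$scenes), a$dt)
  }))
}
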