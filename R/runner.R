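# Training and evaluation protocol: single-pass online learning over a
# corpus, frozen-weight validation checkpoints, seeded multi-simulation runs,
# boundary-rate tuning, input ablations, and the generic-only baseline.

# Run one activity through the model. Mutates nothing; returns updated
# library, gate state, dropout RNG state, and the event trace.
run_activity <- function(lib, activity, variant, control, gate_state,
                         drop_state, learn = TRUE, drop_seed = 1L) {
  scenes <- activity$scenes
  T <- nrow(scenes)
  D <- ncol(scenes)
  k <- control$context_window
  lr <- control$learning_rate

  n <- T
  trace <- list(t = integer(n), schema = integer(n),
                decision = character(n), pe = numeric(n), unc = numeric(n),
                gate_fired = logical(n),
                lp1 = rep(NA_real_, n), lp2 = rep(NA_real_, n),
                lp3 = rep(NA_real_, n))

  active <- attr(lib, "active") %||% 1L
  h0 <- NULL          # carried-in hidden state of the active schema
  active_start <- 0L  # timestep (0-based) at which current tenure began

  for (t0 in seq_len(T) - 1L) {
    observed <- scenes[t0 + 1L, ]
    ctx <- pad_context(scenes[seq_len(t0), , drop = FALSE], t0, k)

    if (n_schemas(lib) == 0L) {
      if (!learn) stop("cannot run validation with an empty schema library")
      sp <- spawn_schema(lib, t0)
      lib <- sp$lib
      active <- sp$id
      h0 <- NULL; active_start <- t0
      pred <- predict_scene(lib$schemas[[active]], ctx, NULL)
      pe <- prediction_error(pred, observed)
      unc <- NA_real_
      if (variant == "unc") {
        ms <- with_rng_stream(drop_state, drop_seed,
          mc_predict(lib$schemas[[active]], ctx, control$dropout_samples,
                     control$dropout_rate, NULL))
        drop_state <- ms$state
        unc <- uncertainty(ms$value)
      }
      decision <- "SPAWN"; fired <- variant == "sem2"
      lp_top <- rep(NA_real_, 3)
      signal <- if (variant == "unc") unc else pe
    } else {
      pred <- predict_scene(lib$schemas[[active]], ctx, h0)
      pe <- prediction_error(pred, observed)
      unc <- NA_real_
      if (variant == "unc") {
        ms <- with_rng_stream(drop_state, drop_seed,
          mc_predict(lib$schemas[[active]], ctx, control$dropout_samples,
                     control$dropout_rate, h0))
        drop_state <- ms$state
        unc <- uncertainty(ms$value)
      }
      signal <- switch(variant, sem2 = pe, pe = pe, unc = unc)
      fired <- if (variant == "sem2") TRUE else
        gate_check(signal, gate_state, active)

      lp_top <- rep(NA_real_, 3)
      if (fired) {
        inf <- infer_step(lib, ctx, observed, control, active, h0)
        lp_sorted <- sort(inf$log_posterior, decreasing = TRUE)
        lp_top <- lp_sorted[seq_len(min(3, length(lp_sorted)))]
        length(lp_top) <- 3
        decision <- inf$kind
        if (inf$kind == "SWITCH") {
          active <- inf$target; h0 <- NULL; active_start <- t0
        } else if (inf$kind == "RESET") {
          h0 <- NULL; active_start <- t0
        } else if (inf$kind == "SPAWN") {
          if (learn) {
            sp <- spawn_schema(lib, t0)
            lib <- sp$lib
            if (is.na(sp$id)) {           # cap reached: fall back to keep
              decision <- "KEEP"
            } else {
              active <- sp$id; h0 <- NULL; active_start <- t0
            }
          } else {
            # frozen validation never grows the library; best existing
            # candidate (excluding spawn) is taken instead
            lp <- inf$log_posterior
            lp <- lp[-length(lp)]
            alt <- infer_best_existing(lp, active, n_schemas(lib))
            decision <- alt$kind
            if (alt$kind == "SWITCH") {
              active <- alt$target; h0 <- NULL; active_start <- t0
            } else if (alt$kind == "RESET") {
              h0 <- NULL; active_start <- t0
            }
          }
        }
        # post-decision signal for the gate baseline
        if (decision != "KEEP") {
          if (variant == "unc") {
            ms <- with_rng_stream(drop_state, drop_seed,
              mc_predict(lib$schemas[[active]], ctx, control$dropout_samples,
                         control$dropout_rate, NULL))
            drop_state <- ms$state
            signal <- uncertainty(ms$value)
          } else {
            signal <- inf$errors[[switch(decision,
                                         RESET = "RESET",
                                         SPAWN = "SPAWN",
                                         as.character(active))]]
          }
        }
      } else {
        decision <- "KEEP"
      }
    }

    if (learn) {
      lib <- train_schema(lib, active, ctx, observed, lr,
                          if (decision == "KEEP") h0 else NULL,
                          p = control$dropout_rate)
      lib <- train_generic(lib, ctx, observed, lr,
                           p = control$dropout_rate)
    }
    gate_state <- gate_update(signal, gate_state, active)

    # advance the active schema's pre-window memory
    drop_idx <- t0 - k + 1L       # 0-based scene leaving the next window
    if (decision == "KEEP" && drop_idx > active_start) {
      # hidden must encode scenes active_start .. t0 - k; add v(t0 - k)
      h0 <- advance_hidden(lib$schemas[[active]],
                           h0 %||% numeric(lib$generic$H),
                           scenes[t0 - k + 1L, ])
    } else if (decision == "KEEP" && !is.null(h0) && drop_idx <= active_start) {
      # nothing ages out yet
    }

    i <- t0 + 1L
    trace$t[i] <- t0
    trace$schema[i] <- active
    trace$decision[i] <- decision
    trace$pe[i] <- pe
    trace$unc[i] <- unc
    trace$gate_fired[i] <- fired
    trace$lp1[i] <- lp_top[1]; trace$lp2[i] <- lp_top[2]
    trace$lp3[i] <- lp_top[3]
  }
  attr(lib, "active") <- active
  trace <- as.data.frame(trace, stringsAsFactors = FALSE)
  trace$activity_id <- activity$id
  list(lib = lib, gate = gate_state, drop_state = drop_state, trace = trace)
}

# Fallback candidate when SPAWN wins during frozen validation: best among
# existing schemas and RESET, same tie-break order.
infer_best_existing <- function(lp, active_id, K) {
  pref <- c(active_id, K + 1L, setdiff(seq_len(K), active_id))
  best <- pref[[1]]
  for (i in pref[-1]) if (lp[[i]] > lp[[best]]) best <- i
  if (best == active_id) list(kind = "KEEP", target = active_id)
  else if (best == K + 1L) list(kind = "RESET", target = active_id)
  else list(kind = "SWITCH", target = best)
}

# Frozen-weight pass over all validation activities. Weights and the training
# gate state are untouched; each activity starts from a copy of the training
# gate state and the current active schema.
validate_pass <- function(lib, corpus, variant, control, gate_state,
                          checkpoint, seed) {
  val <- corpus_split(corpus, "validation")
  traces <- vector("list", length(val))
  names(traces) <- names(val)
  drop_seed <- (seed + 104729L * checkpoint) %% .Machine$integer.max
  drop_state <- NULL
  saved_active <- attr(lib, "active")
  for (i in seq_along(val)) {
    res <- run_activity(lib, val[[i]], variant, control,
                        gate_state, drop_state, learn = FALSE,
                        drop_seed = drop_seed)
    drop_state <- res$drop_state
    traces[[i]] <- res$trace
    # library identical by construction; restore active pointer
  }
  attr(lib, "active") <- saved_active
  pe2 <- vapply(traces, function(tr) mean(tr$pe^2), numeric(1))
  bnd <- vapply(traces, function(tr) {
    sum(labels_to_boundaries(tr$schema, tr$decision,
                             control$count_resets_as_boundaries))
  }, numeric(1))
  list(traces = traces, validation_pe = mean(pe2),
       boundaries_per_activity = mean(bnd), boundary_counts = bnd)
}

#' Fit an event-schema model to a corpus
#'
#' The main fitting function. Trains online in a single pass over the
#' training activities (each scene seen exactly once), spawning, switching,
#' resetting, and updating recurrent schema predictors as it goes. After
#' every `checkpoint_every` training activities (and at the end), all
#' validation activities are run with learning disabled and summarized.
#'
#' @param corpus a [sem_corpus()].
#' @param variant `"sem2"` (schema inference at every timestep), `"pe"`
#'   (inference gated on prediction error), or `"unc"` (inference gated on
#'   Monte Carlo dropout prediction uncertainty).
#' @param control a [sem_control()].
#' @param seed integer seed governing weight initialization, dropout
#'   sampling, and (when `order` is `NULL`) the training order shuffle.
#' @param order optional character vector of training activity ids giving an
#'   explicit training order.
#' @param checkpoint_every validation cadence in training activities.
#' @return An object of class `"event_sem"`; see [summary.event_sem()].
#' @examples
#' corp <- generate_corpus(generator_config(n_train = 4, n_validation = 2,
#'                                          seed = 1))
#' fit <- event_sem(corp, "sem2", seed = 1, checkpoint_every = 2)
#' fit
#' @export
event_sem <- function(corpus, variant = c("sem2", "pe", "unc"),
                      control = sem_control(), seed = 1L, order = NULL,
                      checkpoint_every = 10L) {
  variant <- match.arg(variant)
  stopifnot(inherits(corpus, "sem_corpus"))
  v <- validate_corpus(corpus)
  if (!v$ok) stop("corpus failed validation; see validate_corpus()")

  train_ids <- names(corpus$split)[corpus$split == "train"]
  if (length(train_ids) == 0L) stop("train split is empty")
  set.seed(seed)
  if (is.null(order)) order <- sample(train_ids)
  stopifnot(setequal(order, train_ids))

  D <- ncol(corpus$activities[[1]]$scenes)
  H <- control$hidden_size * control$hidden_multiplier
  lib <- new_library(D, H, control$max_schemas)
  gate <- new_gate_state(control$ema_decay, control$gate_margin)
  drop_state <- NULL
  drop_seed <- (seed + 15485863L) %% .Machine$integer.max

  has_val <- any(corpus$split == "validation")
  train_traces <- vector("list", length(order))
  names(train_traces) <- order
  checkpoints <- list()

  for (i in seq_along(order)) {
    res <- run_activity(lib, corpus$activities[[order[i]]], variant, control,
                        gate, drop_state, learn = TRUE,
                        drop_seed = drop_seed)
    lib <- res$lib; gate <- res$gate; drop_state <- res$drop_state
    train_traces[[i]] <- res$trace
    if (has_val &&
        (i %% checkpoint_every == 0L || i == length(order))) {
      ck <- validate_pass(lib, corpus, variant, control, gate,
                          checkpoint = length(checkpoints) + 1L, seed = seed)
      checkpoints[[length(checkpoints) + 1L]] <- c(
        list(after_activities = i, n_schemas = n_schemas(lib)), ck)
    }
  }

  structure(list(variant = variant, control = control, seed = seed,
                 order = order, library = lib, gate = gate,
                 train_traces = train_traces, checkpoints = checkpoints,
                 layout = corpus$activities[[1]]$layout,
                 dt = corpus$activities[[1]]$dt,
                 call = match.call()),
            class = "event_sem")
}

#' Run several seeded simulations of one model variant
#'
#' Simulation `i` shuffles the training order with seed `seed + i` and uses
#' the same seed for all model randomness, so the full set is reproducible
#' from `seed` alone.
#'
#' @inheritParams event_sem
#' @param n_sims number of simulations (the evaluation protocol uses 8).
#' @return List of `"event_sem"` fits, class `"event_sem_sims"`.
#' @export
run_simulations <- function(corpus, variant = c("sem2", "pe", "unc"),
                            control = sem_control(), n_sims = 8L,
                            seed = 1L, checkpoint_every = 10L) {
  variant <- match.arg(variant)
  fits <- lapply(seq_len(n_sims), function(i) {
    event_sem(corpus, variant, control,
              seed = (seed + i) %% .Machine$integer.max,
              checkpoint_every = checkpoint_every)
  })
  class(fits) <- "event_sem_sims"
  fits
}

#' Checkpoint metric table of one or more fits
#'
#' @param fits an `"event_sem"` fit, an `"event_sem_sims"` list, or a plain
#'   list of fits.
#' @return data.frame with one row per (simulation, checkpoint): validation
#'   prediction error, mean boundaries per validation activity, schema count.
#' @export
checkpoint_table <- function(fits) {
  if (inherits(fits, "event_sem")) fits <- list(fits)
  do.call(rbind, lapply(seq_along(fits), function(s) {
    cks <- fits[[s]]$checkpoints
    do.call(rbind, lapply(seq_along(cks), function(j) {
      data.frame(simulation = s, checkpoint = j,
                 after_activities = cks[[j]]$after_activities,
                 validation_pe = cks[[j]]$validation_pe,
                 boundaries_per_activity = cks[[j]]$boundaries_per_activity,
                 n_schemas = cks[[j]]$n_schemas)
    }))
  }))
}

#' Tune hyperparameters to match a target boundary rate
#'
#' Evaluates each grid point with a reduced-budget training run and returns
#' the point minimizing `|mean validation boundaries per activity - target|`
#' (ties broken by grid order), mirroring the protocol of matching the
#' model's boundary count to the median human fine-grain count.
#'
#' @param corpus a [sem_corpus()].
#' @param grid data.frame whose columns are [sem_control()] argument names;
#'   one row per candidate setting.
#' @param target target mean boundaries per validation activity.
#' @param variant model variant.
#' @param control base control; grid rows override its fields.
#' @param n_train number of training activities used per evaluation
#'   (reduced budget).
#' @param seed integer seed shared by all grid evaluations.
#' @return List with `best` (a `sem_control`), `best_index`, and `table`
#'   (grid with objective values).
#' @export
tune_boundary_rate <- function(corpus, grid, target,
                               variant = c("sem2", "pe", "unc"),
                               control = sem_control(), n_train = 10L,
                               seed = 1L) {
  variant <- match.arg(variant)
  if (nrow(grid) == 0L) stop("empty grid")
  train_ids <- names(corpus$split)[corpus$split == "train"]
  set.seed(seed)
  order <- sample(train_ids)[seq_len(min(n_train, length(train_ids)))]
  sub <- sem_corpus(
    corpus$activities[c(order,
                        names(corpus$split)[corpus$split == "validation"])],
    corpus$split[c(order,
                   names(corpus$split)[corpus$split == "validation"])])
  objective <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    ctl <- control
    for (nm in names(grid)) ctl[[nm]] <- grid[[nm]][g]
    fit <- event_sem(sub, variant, ctl, seed = seed, order = order,
                     checkpoint_every = length(order))
    last <- fit$checkpoints[[length(fit$checkpoints)]]
    objective[g] <- abs(last$boundaries_per_activity - target)
  }
  best_index <- which.min(objective)  # first minimum: grid-order tie-break
  best <- control
  for (nm in names(grid)) best[[nm]] <- grid[[nm]][best_index]
  tab <- grid
  tab$objective <- objective
  list(best = best, best_index = best_index, table = tab)
}

#' Zero one feature block in every scene vector of a corpus
#'
#' Input-deprivation ablation: returns a corpus whose named block (e.g.
#' `"semantic"` or `"motion"`) is zeroed everywhere, all other entries
#' untouched.
#'
#' @param corpus a [sem_corpus()].
#' @param block block name present in the corpus layout.
#' @return A new `"sem_corpus"`.
#' @export
ablate_inputs <- function(corpus, block) {
  idx <- block_indices(corpus$activities[[1]]$layout, block)
  acts <- lapply(corpus$activities, function(a) {
    a$scenes[, idx] <- 0
    a
  })
  sem_corpus(acts, corpus$split)
}

#' Generic-only baseline
#'
#' Trains a single generic predictor (optionally with 2x or 3x hidden units)
#' on the same single-pass schedule, with no schema inference, spawning, or
#' boundaries, and evaluates frozen validation prediction error at the same
#' checkpoints.
#'
#' @inheritParams event_sem
#' @param hidden_multiplier 1, 2, or 3 times the base hidden size.
#' @return List with `checkpoints` (data.frame of validation PE) and
#'   `library` (the trained generic network inside a library).
#' @export
generic_baseline <- function(corpus, control = sem_control(), seed = 1L,
                             hidden_multiplier = 1L, order = NULL,
                             checkpoint_every = 10L) {
  stopifnot(hidden_multiplier %in% 1:3)
  train_ids <- names(corpus$split)[corpus$split == "train"]
  set.seed(seed)
  if (is.null(order)) order <- sample(train_ids)
  D <- ncol(corpus$activities[[1]]$scenes)
  H <- control$hidden_size * hidden_multiplier
  lib <- new_library(D, H)
  k <- control$context_window
  val <- corpus_split(corpus, "validation")
  val_pe <- function(lib) {
    mean(vapply(val, function(a) {
      scenes <- a$scenes
      errs <- vapply(seq_len(nrow(scenes)) - 1L, function(t0) {
        ctx <- pad_context(scenes[seq_len(t0), , drop = FALSE], t0, k)
        prediction_error(predict_scene(lib$generic, ctx), scenes[t0 + 1L, ])
      }, numeric(1))
      mean(errs^2)
    }, numeric(1)))
  }
  checkpoints <- list()
  for (i in seq_along(order)) {
    scenes <- corpus$activities[[order[i]]]$scenes
    for (t0 in seq_len(nrow(scenes)) - 1L) {
      ctx <- pad_context(scenes[seq_len(t0), , drop = FALSE], t0, k)
      lib <- train_generic(lib, ctx, scenes[t0 + 1L, ],
                           control$learning_rate,
                           p = control$dropout_rate)
    }
    if (i %% checkpoint_every == 0L || i == length(order)) {
      checkpoints[[length(checkpoints) + 1L]] <- data.frame(
        after_activities = i, validation_pe = val_pe(lib))
    }
  }
  list(checkpoints = do.call(rbind, checkpoints), library = lib,
       order = order)
}

#' Catastrophic-interference probe on a two-phase curriculum
#'
#' Trains a model on class-set A activities, measures validation prediction
#' error on held-out A activities, continues training on class-set B, and
#' measures A-validation error again. The rise quantifies interference from
#' later learning; a modular schema library should protect earlier schemas
#' better than a single generic network.
#'
#' @param corpus a corpus whose train split contains first-phase then
#'   second-phase activities and whose validation split holds first-phase
#'   held-out activities.
#' @param phase_a_ids,phase_b_ids training activity ids for the two phases.
#' @param model `"sem2"` or `"generic"`.
#' @param control a [sem_control()].
#' @param seed integer seed.
#' @return List with `pe_after_a`, `pe_after_b`, and `rise`
#'   (`pe_after_b - pe_after_a`).
#' @export
interference_probe <- function(corpus, phase_a_ids, phase_b_ids,
                               model = c("sem2", "generic"),
                               control = sem_control(), seed = 1L) {
  model <- match.arg(model)
  order <- c(phase_a_ids, phase_b_ids)
  n_a <- length(phase_a_ids)
  if (model == "generic") {
    gb <- generic_baseline(corpus, control, seed = seed, order = order,
                           checkpoint_every = n_a)
    pes <- gb$checkpoints$validation_pe
    after <- gb$checkpoints$after_activities
  } else {
    fit <- event_sem(corpus, "sem2", control, seed = seed, order = order,
                     checkpoint_every = n_a)
    tab <- checkpoint_table(fit)
    pes <- tab$validation_pe
    after <- tab$after_activities
  }
  pe_a <- pes[match(n_a, after)]
  pe_b <- pes[match(length(order), after)]
  list(pe_after_a = pe_a, pe_after_b = pe_b, rise = pe_b - pe_a)
}
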