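# S3 methods for "event_sem" fits, plus extractors connecting fits to the
# evaluation statistics.

#' @export
print.event_sem <- function(x, ...) {
  last <- x$checkpoints[[length(x$checkpoints)]]
  cat("Event-schema model (variant:", x$variant, ")\n")
  cat("  trained on", length(x$order), "activities (single pass), seed",
      x$seed, "\n")
  cat("  schemas spawned:", n_schemas(x$library), "\n")
  if (!is.null(last)) {
    cat("  final validation PE:", signif(last$validation_pe, 4),
        "| boundaries/activity:",
        signif(last$boundaries_per_activity, 3), "\n")
  }
  invisible(x)
}

#' Summarize an event-schema fit
#'
#' @param object an `"event_sem"` fit.
#' @param ... unused.
#' @return A list of class `"summary.event_sem"` with the checkpoint metric
#'   table, schema usage curves, and decision counts.
#' @export
summary.event_sem <- function(object, ...) {
  dec <- unlist(lapply(object$train_traces, function(tr) tr$decision))
  structure(list(variant = object$variant,
                 n_schemas = n_schemas(object$library),
                 checkpoints = checkpoint_table(object),
                 usage = schema_usage_curves(object$train_traces),
                 decisions = table(factor(dec, levels = c("KEEP", "SWITCH",
                                                          "RESET",
                                                          "SPAWN")))),
            class = "summary.event_sem")
}

#' @export
print.summary.event_sem <- function(x, ...) {
  cat("Event-schema model (variant:", x$variant, "),", x$n_schemas,
      "schemas\n\nTraining decisions:\n")
  print(x$decisions)
  cat("\nValidation checkpoints:\n")
  print(x$checkpoints, row.names = FALSE)
  cat("\nSchema usage (per training bin):\n")
  print(x$usage, row.names = FALSE)
  invisible(x)
}

#' @export
coef.event_sem <- function(object, ...) {
  list(generic = network_weights(object$library$generic),
       schemas = lapply(object$library$schemas, network_weights))
}

#' @export
residuals.event_sem <- function(object, ...) {
  unlist(lapply(object$train_traces, function(tr) {
    stats::setNames(tr$pe, paste0(tr$activity_id, ":", tr$t))
  }), use.names = TRUE)
}

#' Predict on new activities with a fitted model
#'
#' Runs the frozen model (no learning) over new data with the fitted gating
#' and inference machinery, returning event traces.
#'
#' @param object an `"event_sem"` fit.
#' @param newdata a [sem_activity()] or [sem_corpus()].
#' @param seed seed for the dropout stream (uncertainty variant).
#' @param ... unused.
#' @return For a single activity, one trace data.frame; for a corpus, a
#'   named list of trace data.frames over its activities.
#' @export
predict.event_sem <- function(object, newdata, seed = 1L, ...) {
  acts <- if (inherits(newdata, "sem_activity")) {
    stats::setNames(list(newdata), newdata$id)
  } else if (inherits(newdata, "sem_corpus")) {
    newdata$activities
  } else stop("newdata must be a sem_activity or sem_corpus")
  drop_state <- NULL
  out <- vector("list", length(acts))
  names(out) <- names(acts)
  for (i in seq_along(acts)) {
    res <- run_activity(object$library, acts[[i]], object$variant,
                        object$control, object$gate, drop_state,
                        learn = FALSE, drop_seed = seed)
    drop_state <- res$drop_state
    out[[i]] <- res$trace
  }
  if (inherits(newdata, "sem_activity")) out[[1]] else out
}

#' Simulate scene sequences from a fitted schema
#'
#' Rolls a schema network forward generatively: each step predicts the next
#' scene from the recent window and feeds it back with additive Gaussian
#' noise.
#'
#' @param object an `"event_sem"` fit.
#' @param nsim number of sequences.
#' @param seed integer seed.
#' @param schema schema id to roll out (default 1).
#' @param T sequence length in timesteps.
#' @param noise_sd innovation noise SD.
#' @param ... unused.
#' @return A list of `T x D` scene matrices (length `nsim`).
#' @export
simulate.event_sem <- function(object, nsim = 1, seed = 1L, schema = 1L,
                               T = 30L, noise_sd = 0.05, ...) {
  if (schema > n_schemas(object$library)) stop("no such schema")
  set.seed(seed)
  net <- object$library$schemas[[schema]]
  k <- object$control$context_window
  lapply(seq_len(nsim), function(s) {
    scenes <- matrix(0, T, net$D)
    for (t0 in seq_len(T) - 1L) {
      ctx <- pad_context(scenes[seq_len(t0), , drop = FALSE], t0, k)
      scenes[t0 + 1L, ] <- predict_scene(net, ctx) +
        stats::rnorm(net$D, 0, noise_sd)
    }
    scenes
  })
}

#' @export
plot.event_sem <- function(x, ...) {
  tab <- checkpoint_table(x)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(tab$after_activities, tab$validation_pe, type = "b", pch = 16,
       xlab = "training activities seen", ylab = "validation PE",
       main = paste0("Learning (", x$variant, ")"), ...)
  plot(tab$after_activities, tab$boundaries_per_activity, type = "b",
       pch = 16, xlab = "training activities seen",
       ylab = "boundaries / validation activity", main = "Segmentation rate")
  invisible(x)
}

#' Concatenated event labels of a validation checkpoint
#'
#' Extracts, for one checkpoint of a fit, the model's per-timestep event
#' labels across all validation activities, concatenated with recorded
#' activity offsets — the form the partition-agreement statistics and the
#' permutation null operate on.
#'
#' @param fit an `"event_sem"` fit.
#' @param checkpoint checkpoint index (default: last).
#' @return List with `labels` (integer vector), `offsets` (0-based activity
#'   start indices), `activity_ids`, `boundaries` (binary vector, computed
#'   per activity so activity joins are not boundaries), and `traces`.
#' @export
validation_labels <- function(fit, checkpoint = length(fit$checkpoints)) {
  ck <- fit$checkpoints[[checkpoint]]
  traces <- ck$traces
  labels <- unlist(lapply(traces, function(tr) tr$schema), use.names = FALSE)
  lens <- vapply(traces, nrow, integer(1))
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  boundaries <- unlist(lapply(traces, function(tr) {
    labels_to_boundaries(tr$schema, tr$decision,
                         fit$control$count_resets_as_boundaries)
  }), use.names = FALSE)
  list(labels = labels, offsets = unname(offsets),
       activity_ids = names(traces), boundaries = boundaries,
       traces = traces)
}
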