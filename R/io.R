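# File formats and the experiment driver. Everything is plain text: JSON for
# configs and manifests, CSV for scenes/labels/raters/metrics, JSON-lines for
# event traces, so artifacts are inspectable with language-agnostic tooling.

#' Save a corpus to a directory
#'
#' Writes `manifest.json` (ids, dt, layout, actor/environment, split), one
#' `scenes_<id>.csv` per activity (columns `f0..f{D-1}`, one row per
#' timestep), and `labels.csv` (`activity_id,t,value`) when labels exist.
#'
#' @param corpus a [sem_corpus()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  acts <- corpus$activities
  manifest <- list(
    dt = acts[[1]]$dt,
    layout = as.list(acts[[1]]$layout),
    activities = lapply(acts, function(a) {
      list(id = a$id, actor = a$actor_id, environment = a$environment_id,
           split = unname(corpus$split[[a$id]]), n = nrow(a$scenes),
           file = paste0("scenes_", a$id, ".csv"))
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  labels <- list()
  for (a in acts) {
    df <- as.data.frame(a$scenes)
    names(df) <- paste0("f", seq_len(ncol(df)) - 1L)
    utils::write.csv(df, file.path(dir, paste0("scenes_", a$id, ".csv")),
                     row.names = FALSE)
    if (!is.null(a$true_labels)) {
      labels[[a$id]] <- data.frame(activity_id = a$id,
                                   t = seq_along(a$true_labels) - 1L,
                                   value = a$true_labels)
    }
  }
  if (length(labels) > 0L) {
    utils::write.csv(do.call(rbind, labels), file.path(dir, "labels.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Load a corpus from a directory written by [save_corpus()]
#'
#' @param dir corpus directory.
#' @return A [sem_corpus()].
#' @export
load_corpus <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  layout <- unlist(manifest$layout)
  labels <- NULL
  lf <- file.path(dir, "labels.csv")
  if (file.exists(lf)) {
    labels <- utils::read.csv(lf, stringsAsFactors = FALSE)
  }
  acts <- lapply(manifest$activities, function(m) {
    scenes <- as.matrix(utils::read.csv(file.path(dir, m$file)))
    tl <- NULL
    if (!is.null(labels)) {
      sub <- labels[labels$activity_id == m$id, ]
      if (nrow(sub) > 0L) tl <- sub$value[order(sub$t)]
    }
    sem_activity(m$id, scenes, dt = manifest$dt, true_labels = tl,
                 actor_id = m$actor %||% NA, environment_id =
                   m$environment %||% NA, layout = layout)
  })
  split <- vapply(manifest$activities, function(m) m$split, character(1))
  names(split) <- vapply(manifest$activities, function(m) m$id, character(1))
  sem_corpus(acts, split)
}

#' Save rater segmentations to CSV
#'
#' Columns: `rater_id, activity_id, time_s, grain`.
#'
#' @param raters list of [rater_segmentation()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_rater_csv <- function(raters, path) {
  df <- do.call(rbind, lapply(raters, function(r) {
    if (length(r$boundary_times) == 0L) return(NULL)
    data.frame(rater_id = r$rater_id, activity_id = r$activity_id,
               time_s = r$boundary_times, grain = r$grain)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load rater segmentations from CSV
#'
#' Malformed rows (negative times, unknown grain) are rejected with their
#' line numbers.
#'
#' @param path CSV with columns `rater_id, activity_id, time_s, grain`.
#' @return List of [rater_segmentation()] objects, one per
#'   (rater, activity) pair.
#' @export
load_rater_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rater_id", "activity_id", "time_s", "grain")
  if (!all(need %in% names(df))) {
    stop("rater CSV must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(df$time_s) | df$time_s < 0 |
                 !df$grain %in% c("fine", "coarse"))
  if (length(bad) > 0L) {
    stop("malformed rater rows at lines: ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  keys <- split(df, paste(df$rater_id, df$activity_id, sep = "\r"))
  unname(lapply(keys, function(g) {
    rater_segmentation(g$rater_id[1], g$activity_id[1], g$time_s,
                       grain = g$grain[1])
  }))
}

#' Write an event trace as JSON lines
#'
#' One JSON object per timestep: `activity_id, t, schema, decision, pe, unc,
#' gate_fired, log_posterior_top3`.
#'
#' @param trace trace data.frame from a fit or [predict.event_sem()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_trace_jsonl <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(trace))) {
    row <- list(activity_id = trace$activity_id[i], t = trace$t[i],
                schema = trace$schema[i], decision = trace$decision[i],
                pe = trace$pe[i], unc = trace$unc[i],
                gate_fired = trace$gate_fired[i],
                log_posterior_top3 = c(trace$lp1[i], trace$lp2[i],
                                       trace$lp3[i]))
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' Read an event trace from JSON lines
#'
#' @param path file written by [save_trace_jsonl()].
#' @return Trace data.frame.
#' @export
load_trace_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(seq_along(lines), function(i) {
    row <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("malformed trace line ", i, ": ",
                                             conditionMessage(e)))
    lp <- row$log_posterior_top3
    lp <- c(lp, rep(NA_real_, 3 - length(lp)))
    data.frame(t = row$t, schema = row$schema, decision = row$decision,
               pe = row$pe, unc = row$unc %||% NA_real_,
               gate_fired = row$gate_fired,
               lp1 = lp[1] %||% NA_real_, lp2 = lp[2], lp3 = lp[3],
               activity_id = row$activity_id, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Experiment configuration
#'
#' Bundles a generator configuration, model controls, variant, and
#' simulation settings into one serializable object;
#' `load_experiment_config(save_experiment_config(x))` is the identity.
#'
#' @param generator a [generator_config()].
#' @param control a [sem_control()].
#' @param variant model variant.
#' @param n_sims number of seeded simulations.
#' @param seed base seed.
#' @param checkpoint_every validation cadence.
#' @return List of class `"sem_expconfig"`.
#' @export
experiment_config <- function(generator = generator_config(),
                              control = sem_control(),
                              variant = c("sem2", "pe", "unc"),
                              n_sims = 8L, seed = 1L,
                              checkpoint_every = 10L) {
  variant <- match.arg(variant)
  structure(list(generator = generator, control = control,
                 variant = variant, n_sims = as.integer(n_sims),
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "sem_expconfig")
}

#' @rdname experiment_config
#' @param config a `"sem_expconfig"`.
#' @param path JSON file path.
#' @export
save_experiment_config <- function(config, path) {
  x <- unclass(config)
  x$generator <- unclass(x$generator)
  x$generator$layout <- as.list(x$generator$layout)
  x$control <- unclass(x$control)
  x$control$max_schemas <- if (is.finite(x$control$max_schemas))
    x$control$max_schemas else "unbounded"
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname experiment_config
#' @export
load_experiment_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- x$generator
  gen$layout <- unlist(gen$layout)
  generator <- do.call(generator_config, gen)
  ctl <- x$control
  if (identical(ctl$max_schemas, "unbounded")) ctl$max_schemas <- Inf
  control <- do.call(sem_control, ctl)
  experiment_config(generator = generator, control = control,
                    variant = x$variant, n_sims = x$n_sims, seed = x$seed,
                    checkpoint_every = x$checkpoint_every)
}

#' Run a full experiment into a result directory
#'
#' Generates the corpus from the configuration, runs the seeded simulations,
#' and writes: the corpus, per-simulation checkpoint metrics
#' (`metrics.csv`, long format), final-checkpoint validation traces
#' (JSON lines), the configuration, and a manifest with the configuration's
#' MD5 hash and completion state.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  save_experiment_config(config, cfg_path)
  corpus <- generate_corpus(config$generator)
  save_corpus(corpus, file.path(out_dir, "corpus"))
  fits <- run_simulations(corpus, config$variant, config$control,
                          n_sims = config$n_sims, seed = config$seed,
                          checkpoint_every = config$checkpoint_every)
  tab <- checkpoint_table(fits)
  long <- stats::reshape(tab, direction = "long",
                         varying = c("validation_pe",
                                     "boundaries_per_activity", "n_schemas"),
                         v.names = "value", timevar = "metric",
                         times = c("validation_pe",
                                   "boundaries_per_activity", "n_schemas"))
  long <- long[, c("simulation", "checkpoint", "metric", "value")]
  long <- long[order(long$simulation, long$checkpoint, long$metric), ]
  utils::write.csv(long, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  tdir <- file.path(out_dir, "traces")
  dir.create(tdir, showWarnings = FALSE)
  for (s in seq_along(fits)) {
    vl <- validation_labels(fits[[s]])
    for (id in names(vl$traces)) {
      save_trace_jsonl(vl$traces[[id]],
                       file.path(tdir, sprintf("sim%02d_%s.jsonl", s, id)))
    }
  }
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   n_sims = config$n_sims, variant = config$variant,
                   complete = TRUE,
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
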