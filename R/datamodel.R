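# Core containers: scene-vector activities, corpora, rater segmentations.
# Scenes live in a T x D numeric matrix (rows are timesteps); activities and
# corpora are lightweight S3 lists in the base-R style of survival/ape.

#' Default scene-vector block layout
#'
#' Scene vectors summarize one timestep of an activity as a fixed-length real
#' vector. The default 30-dimensional layout mirrors mid-level visual features
#' of everyday activity recordings: 14 body-motion dimensions, 13 object
#' semantic dimensions, 2 object appearance/disappearance flags, and 1
#' luminance-change dimension.
#'
#' @param motion,semantic,object_change,luminance block sizes (dimensions).
#' @return Named integer vector of block sizes; its sum is the scene dimension.
#' @examples
#' scene_layout()
#' sum(scene_layout())  # 30
#' @export
scene_layout <- function(motion = 14L, semantic = 13L, object_change = 2L,
                         luminance = 1L) {
  lay <- c(motion = as.integer(motion), semantic = as.integer(semantic),
           object_change = as.integer(object_change),
           luminance = as.integer(luminance))
  if (any(lay < 0L)) stop("block sizes must be nonnegative")
  lay
}

#' Column indices of a named block in a scene layout
#'
#' @param layout named integer vector of block sizes (see [scene_layout()]).
#' @param block block name, e.g. `"motion"` or `"semantic"`.
#' @return Integer vector of column indices into the scene matrix.
#' @export
block_indices <- function(layout, block) {
  if (!block %in% names(layout)) {
    stop("unknown block '", block, "'; layout has: ",
         paste(names(layout), collapse = ", "))
  }
  ends <- cumsum(layout)
  starts <- ends - layout + 1L
  seq.int(starts[[block]], ends[[block]])
}

#' Construct an activity
#'
#' An activity is an ordered sequence of scene vectors sampled on a regular
#' grid (default one scene every 1/3 s), optionally annotated with a
#' ground-truth event-class label per timestep.
#'
#' @param id activity identifier (character scalar).
#' @param scenes numeric matrix, one row per timestep, one column per scene
#'   dimension.
#' @param dt seconds per timestep.
#' @param true_labels optional per-timestep event-class labels (length
#'   `nrow(scenes)`).
#' @param actor_id,environment_id optional annotations.
#' @param layout named block layout; must sum to `ncol(scenes)`.
#' @return An object of class `"sem_activity"`.
#' @export
sem_activity <- function(id, scenes, dt = 1 / 3, true_labels = NULL,
                         actor_id = NA_character_,
                         environment_id = NA_character_,
                         layout = scene_layout()) {
  scenes <- as.matrix(scenes)
  storage.mode(scenes) <- "double"
  if (nrow(scenes) < 2L) stop("activity '", id, "' needs at least 2 timesteps")
  if (sum(layout) != ncol(scenes)) {
    stop("layout blocks sum to ", sum(layout), " but scenes have ",
         ncol(scenes), " columns")
  }
  if (!is.null(true_labels) && length(true_labels) != nrow(scenes)) {
    stop("true_labels length ", length(true_labels),
         " != timesteps ", nrow(scenes))
  }
  structure(list(id = as.character(id), scenes = scenes, dt = dt,
                 true_labels = true_labels,
                 actor_id = as.character(actor_id),
                 environment_id = as.character(environment_id),
                 layout = layout),
            class = "sem_activity")
}

#' @export
print.sem_activity <- function(x, ...) {
  cat("Activity", x$id, ":", nrow(x$scenes), "timesteps x",
      ncol(x$scenes), "dims, dt =", signif(x$dt, 4), "s",
      if (!is.null(x$true_labels)) "(labeled)" else "(unlabeled)", "\n")
  invisible(x)
}

#' Construct a corpus
#'
#' @param activities list of [sem_activity()] objects.
#' @param split named character vector mapping activity id to `"train"` or
#'   `"validation"`; must cover every activity exactly once.
#' @return An object of class `"sem_corpus"`.
#' @export
sem_corpus <- function(activities, split) {
  if (length(activities) == 0L) stop("empty corpus")
  ids <- vapply(activities, function(a) a$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate activity ids")
  if (!setequal(names(split), ids)) {
    stop("split must name every activity exactly once")
  }
  if (!all(split %in% c("train", "validation"))) {
    stop("split values must be 'train' or 'validation'")
  }
  names(activities) <- ids
  structure(list(activities = activities, split = split[ids]),
            class = "sem_corpus")
}

#' @export
print.sem_corpus <- function(x, ...) {
  cat("Corpus:", length(x$activities), "activities (",
      sum(x$split == "train"), "train /", sum(x$split == "validation"),
      "validation ),", ncol(x$activities[[1]]$scenes), "scene dims\n")
  invisible(x)
}

#' Activities in one split of a corpus
#' @param corpus a [sem_corpus()].
#' @param split `"train"` or `"validation"`.
#' @return List of activities.
#' @export
corpus_split <- function(corpus, split = c("train", "validation")) {
  split <- match.arg(split)
  corpus$activities[names(corpus$split)[corpus$split == split]]
}

#' Validate a corpus
#'
#' Checks the structural invariants every downstream routine relies on:
#' constant scene dimension across activities, finite entries, label lengths
#' matching timestep counts, and a well-formed train/validation split. Each
#' violation is located as precisely as possible (activity, timestep,
#' dimension).
#'
#' @param corpus a [sem_corpus()].
#' @return A list with `ok` (logical) and `issues`, a data.frame with columns
#'   `activity`, `t`, `dim`, `problem` (NA where not applicable).
#' @export
validate_corpus <- function(corpus) {
  if (!inherits(corpus, "sem_corpus")) stop("not a sem_corpus")
  issues <- list()
  note <- function(activity, t, dim, problem) {
    issues[[length(issues) + 1L]] <<- data.frame(
      activity = activity, t = t, dim = dim, problem = problem,
      stringsAsFactors = FALSE)
  }
  dims <- vapply(corpus$activities, function(a) ncol(a$scenes), integer(1))
  d0 <- dims[[1]]
  for (a in corpus$activities) {
    if (ncol(a$scenes) != d0) {
      note(a$id, NA_integer_, NA_integer_,
           sprintf("dimension %d differs from corpus dimension %d",
                   ncol(a$scenes), d0))
    }
    bad <- which(!is.finite(a$scenes), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      for (i in seq_len(nrow(bad))) {
        note(a$id, bad[i, 1] - 1L, bad[i, 2] - 1L, "non-finite entry")
      }
    }
    if (!is.null(a$true_labels) &&
        length(a$true_labels) != nrow(a$scenes)) {
      note(a$id, NA_integer_, NA_integer_, "label length mismatch")
    }
    if (sum(a$layout) != ncol(a$scenes)) {
      note(a$id, NA_integer_, NA_integer_, "layout does not sum to dimension")
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(activity = character(), t = integer(), dim = integer(),
               problem = character(), stringsAsFactors = FALSE)
  list(ok = nrow(issues) == 0L, issues = issues)
}

#' Convert per-timestep labels to a binary boundary indicator
#'
#' A boundary is a transition of the active schema from one predictor to
#' another: `indicator[t] = 1` iff `labels[t] != labels[t-1]` (0-based t >= 1;
#' the first timestep is never a boundary). Hidden-state resets of the active
#' schema are event-model transitions but not, by default, boundaries; set
#' `count_resets = TRUE` to count them.
#'
#' @param labels per-timestep label vector (length >= 1).
#' @param decisions optional character vector of per-timestep decisions
#'   (`"KEEP"`, `"SWITCH"`, `"RESET"`, `"SPAWN"`), same length as `labels`.
#' @param count_resets logical; count RESET decisions as boundaries.
#' @return Integer 0/1 vector, same length as `labels`.
#' @examples
#' labels_to_boundaries(c("A", "A", "B", "B"))  # 0 0 1 0
#' @export
labels_to_boundaries <- function(labels, decisions = NULL,
                                 count_resets = FALSE) {
  n <- length(labels)
  if (n < 1L) stop("labels must have length >= 1")
  if (!is.null(decisions) && length(decisions) != n) {
    stop("decisions length ", length(decisions), " != labels length ", n)
  }
  ind <- integer(n)
  if (n > 1L) ind[-1L] <- as.integer(labels[-1L] != labels[-n])
  if (count_resets && !is.null(decisions)) {
    ind[decisions == "RESET"] <- 1L
  }
  ind
}

#' Segment lengths from a boundary indicator
#'
#' Inverse view of [labels_to_boundaries()]: the run lengths delimited by the
#' boundary positions.
#'
#' @param boundaries binary 0/1 indicator vector.
#' @return Integer vector of segment lengths summing to `length(boundaries)`.
#' @export
boundaries_to_segments <- function(boundaries) {
  n <- length(boundaries)
  if (n == 0L) return(integer(0))
  cuts <- which(boundaries[-1L] == 1L)  # boundary at t starts a new segment
  diff(c(0L, cuts, n))
}

#' Construct a rater segmentation
#'
#' One human (or simulated) rater's boundary times for one activity, in
#' seconds from activity onset.
#'
#' @param rater_id,activity_id identifiers.
#' @param boundary_times numeric vector of times in seconds; sorted
#'   internally.
#' @param grain `"fine"` or `"coarse"` segmentation grain.
#' @param span optional activity span in seconds used to check ranges.
#' @return An object of class `"sem_raterseg"`.
#' @export
rater_segmentation <- function(rater_id, activity_id, boundary_times,
                               grain = c("fine", "coarse"), span = NULL) {
  grain <- match.arg(grain)
  boundary_times <- sort(as.numeric(boundary_times))
  if (any(boundary_times < 0)) stop("negative boundary time")
  if (!is.null(span) && any(boundary_times > span)) {
    stop("boundary time beyond activity span")
  }
  structure(list(rater_id = as.character(rater_id),
                 activity_id = as.character(activity_id),
                 boundary_times = boundary_times, grain = grain),
            class = "sem_raterseg")
}
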