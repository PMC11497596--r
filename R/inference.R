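# Schema inference: sticky uniform-process prior over schemas, Gaussian
# likelihood from prediction error, local maximum a posteriori decision among
# keep / switch / reset / spawn, and the error- or uncertainty-triggered gate.

#' Control parameters for event-schema models
#'
#' Collects every tunable of the architecture in one place, in the spirit of
#' `glm.control()`.
#'
#' @param stickiness prior bias (lambda >= 0) toward keeping the active
#'   schema; its unnormalized prior weight is `1 + stickiness`.
#' @param concentration prior mass (alpha > 0) on spawning a new schema.
#' @param noise_scale sigma of the isotropic Gaussian converting prediction
#'   error to likelihood.
#' @param gate_margin additive margin m over the running baseline above which
#'   the gate fires (gated variants only); `-Inf` always fires, `Inf` never.
#' @param ema_decay decay of the exponential moving average baseline in
#'   `(0, 1)`; closer to 1 = longer memory.
#' @param dropout_rate dropout probability p in `[0, 1)` for Monte Carlo
#'   uncertainty samples.
#' @param dropout_samples number of dropout samples S (>= 2).
#' @param context_window number k of recent scenes fed to every schema.
#' @param learning_rate SGD step size for schema and generic updates.
#' @param hidden_size hidden units per layer of each predictor.
#' @param hidden_multiplier multiplies `hidden_size` for generic-only
#'   baselines (1, 2, or 3).
#' @param max_schemas cap on spawned schemas (`Inf` = unbounded).
#' @param count_resets_as_boundaries treat hidden-state resets as boundaries
#'   when converting labels to boundary indicators.
#' @return A list of class `"sem_control"`.
#' @export
sem_control <- function(stickiness = 4, concentration = 0.3,
                        noise_scale = 1, gate_margin = 0,
                        ema_decay = 0.9, dropout_rate = 0.5,
                        dropout_samples = 32L, context_window = 3L,
                        learning_rate = 0.02, hidden_size = 16L,
                        hidden_multiplier = 1L, max_schemas = Inf,
                        count_resets_as_boundaries = FALSE) {
  stopifnot(stickiness >= 0, concentration > 0, noise_scale > 0,
            ema_decay > 0, ema_decay < 1,
            dropout_rate >= 0, dropout_rate < 1, dropout_samples >= 2,
            context_window >= 1, learning_rate > 0, hidden_size >= 1,
            hidden_multiplier %in% 1:3)
  structure(list(stickiness = stickiness, concentration = concentration,
                 noise_scale = noise_scale, gate_margin = gate_margin,
                 ema_decay = ema_decay, dropout_rate = dropout_rate,
                 dropout_samples = as.integer(dropout_samples),
                 context_window = as.integer(context_window),
                 learning_rate = learning_rate,
                 hidden_size = as.integer(hidden_size),
                 hidden_multiplier = as.integer(hidden_multiplier),
                 max_schemas = max_schemas,
                 count_resets_as_boundaries = count_resets_as_boundaries),
            class = "sem_control")
}

#' Sticky uniform-process prior over schema candidates
#'
#' Unlike the rich-get-richer Chinese restaurant process, every existing
#' schema receives equal prior mass regardless of past usage: the active
#' schema gets unnormalized weight `1 + stickiness`, every other existing
#' schema 1, the reset candidate 1, and the spawn candidate `concentration`.
#'
#' @param K number of existing schemas (>= 1).
#' @param active_id id of the currently active schema.
#' @param stickiness lambda >= 0.
#' @param concentration alpha > 0.
#' @return Named probability vector of length `K + 2` over
#'   `c(schema ids, "RESET", "SPAWN")`, summing to 1.
#' @examples
#' sup_prior(1, 1, stickiness = 1, concentration = 1)  # 0.5 0.25 0.25
#' @export
sup_prior <- function(K, active_id, stickiness, concentration) {
  if (K < 1) stop("need at least one schema")
  if (stickiness < 0 || concentration <= 0) stop("invalid prior parameters")
  w <- rep(1, K)
  w[active_id] <- 1 + stickiness
  w <- c(w, RESET = 1, SPAWN = concentration)
  names(w)[seq_len(K)] <- as.character(seq_len(K))
  w / sum(w)
}

#' Log-likelihood of a prediction error under isotropic Gaussian noise
#'
#' `-error^2 / (2 sigma^2) - (D/2) log(2 pi sigma^2)`: a D-dimensional
#' spherical Gaussian density evaluated at Euclidean distance `error` from
#' its mean.
#'
#' @param error Euclidean prediction error (>= 0).
#' @param sigma noise scale (> 0).
#' @param D scene dimension.
#' @return Log-density (scalar).
#' @export
log_likelihood <- function(error, sigma, D) {
  if (sigma <= 0) stop("sigma must be > 0")
  -error^2 / (2 * sigma^2) - (D / 2) * log(2 * pi * sigma^2)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# ---- gate -------------------------------------------------------------------

#' Create an empty gate state
#'
#' Tracks, per schema, an exponential moving average of that schema's gating
#' signal (prediction error or uncertainty). A schema's baseline is
#' initialized at its first observed signal.
#'
#' @param ema_decay decay in `(0, 1)`.
#' @param margin additive firing margin m.
#' @return An object of class `"sem_gate"`.
#' @export
new_gate_state <- function(ema_decay, margin) {
  structure(list(mean = numeric(0), decay = ema_decay, margin = margin),
            class = "sem_gate")
}

#' Evaluate the gate for the active schema's current signal
#'
#' Fires iff `signal > baseline + margin`. On a schema's first observation
#' the baseline is taken to be the signal itself, so the gate fires there iff
#' `margin < 0`.
#'
#' @param signal current gating signal (scalar >= 0).
#' @param state a `"sem_gate"`.
#' @param id active schema id.
#' @return Logical.
#' @export
gate_check <- function(signal, state, id) {
  key <- as.character(id)
  base <- if (key %in% names(state$mean)) state$mean[[key]] else signal
  isTRUE(signal > base + state$margin) ||
    (state$margin == -Inf)  # always fire even on degenerate signals
}

#' Update the gate baseline with a schema's signal
#'
#' @inheritParams gate_check
#' @return Updated `"sem_gate"`.
#' @export
gate_update <- function(signal, state, id) {
  if (!is.finite(signal)) return(state)
  key <- as.character(id)
  if (key %in% names(state$mean)) {
    state$mean[[key]] <- state$decay * state$mean[[key]] +
      (1 - state$decay) * signal
  } else {
    state$mean[[key]] <- signal
  }
  state
}

# ---- local MAP inference ----------------------------------------------------

#' One schema-inference evaluation
#'
#' Every existing schema, a reset candidate (active schema with
#' re-initialized hidden state), and a spawn candidate (a would-be new schema
#' carrying the generic network's current weights) predict the observed scene
#' from the same context window. Posteriors combine the sticky
#' uniform-process prior with Gaussian likelihoods of the Euclidean
#' prediction errors; the local MAP candidate wins, with exact ties resolved
#' in the order keep > reset > lowest-id switch > spawn.
#'
#' @param lib a `"sem_library"` with at least one schema.
#' @param ctx context window matrix (see [pad_context()]).
#' @param observed observed scene vector.
#' @param control a [sem_control()].
#' @param active_id currently active schema id.
#' @param active_h0 active schema's carried-in hidden state (`NULL` = none).
#' @return List with `kind` (`"KEEP"`, `"SWITCH"`, `"RESET"`, `"SPAWN"`),
#'   `target` (schema id; for SPAWN the id the new schema will get),
#'   `posterior` (named probability vector over candidates), and `errors`
#'   (per-candidate Euclidean prediction errors).
#' @export
infer_step <- function(lib, ctx, observed, control, active_id,
                       active_h0 = NULL) {
  K <- n_schemas(lib)
  if (K < 1) stop("infer_step requires a nonempty library")
  D <- lib$generic$D
  errors <- numeric(K + 2L)
  for (j in seq_len(K)) {
    h0 <- if (j == active_id) active_h0 else NULL
    errors[j] <- prediction_error(predict_scene(lib$schemas[[j]], ctx, h0),
                                  observed)
  }
  errors[K + 1L] <- prediction_error(
    predict_scene(lib$schemas[[active_id]], ctx, NULL), observed)  # RESET
  errors[K + 2L] <- prediction_error(
    predict_scene(lib$generic, ctx, NULL), observed)               # SPAWN
  names(errors) <- c(as.character(seq_len(K)), "RESET", "SPAWN")

  errors[!is.finite(errors)] <- Inf   # diverged predictor: zero likelihood
  prior <- sup_prior(K, active_id, control$stickiness, control$concentration)
  loglik <- log_likelihood(errors, control$noise_scale, D)
  lp <- log(prior) + loglik
  if (all(!is.finite(lp))) lp <- log(prior)  # all likelihoods underflowed
  post <- exp(lp - log_sum_exp(lp))
  post <- post / sum(post)

  # Preference order for exact ties: KEEP, RESET, switches by ascending id,
  # SPAWN.
  others <- setdiff(seq_len(K), active_id)
  pref <- c(active_id, K + 1L, others, K + 2L)
  best <- pref[[1]]
  for (i in pref[-1]) if (lp[[i]] > lp[[best]]) best <- i

  if (best == active_id) {
    kind <- "KEEP"; target <- active_id
  } else if (best == K + 1L) {
    kind <- "RESET"; target <- active_id
  } else if (best == K + 2L) {
    kind <- "SPAWN"; target <- K + 1L  # id the spawned schema will receive
  } else {
    kind <- "SWITCH"; target <- best
  }
  list(kind = kind, target = target, posterior = post, errors = errors,
       log_posterior = lp - log_sum_exp(lp))
}

# Run expr with an isolated RNG stream stored in `state` (an object previously
# returned in $state, or NULL to seed from `seed`). Restores the caller's RNG.
with_rng_stream <- function(state, seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  if (is.null(state)) set.seed(seed) else
    assign(".Random.seed", state, envir = globalenv())
  value <- force(expr)
  new_state <- get(".Random.seed", envir = globalenv())
  if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv())
  list(value = value, state = new_state)
}
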