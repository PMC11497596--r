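# Recurrent event-schema predictors.
#
# Each schema is a small four-layer predictor: a fully connected input layer
# with leaky-ReLU activation, a gated recurrent unit (GRU) layer, a fully
# connected leaky-ReLU layer, and a linear output layer back to scene space.
# Forward, backprop (stochastic gradient descent on squared error), and
# Monte Carlo dropout are implemented directly in base R matrix code: the
# networks are tiny (default 16 hidden units, 30 input dims) and the whole
# architecture must be inspectable down to the weights.

LRELU_SLOPE <- 0.3

lrelu <- function(x) ifelse(x > 0, x, LRELU_SLOPE * x)
lrelu_grad <- function(x) ifelse(x > 0, 1, LRELU_SLOPE)
sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nrow, ncol) {
  s <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -s, s), nrow, ncol)
}

#' Create a schema network
#'
#' Initializes a four-layer recurrent predictor mapping a window of scene
#' vectors to a prediction of the next scene vector. Weight initialization
#' draws from the current RNG; seed the session for reproducibility.
#'
#' @param D input/output scene dimension.
#' @param H hidden size per layer.
#' @return An object of class `"sem_network"` (a list of weight matrices plus
#'   dimensions).
#' @export
new_network <- function(D, H) {
  net <- list(
    D = as.integer(D), H = as.integer(H),
    W1 = glorot(H, D), b1 = numeric(H),
    Wz = glorot(H, H), Uz = glorot(H, H), bz = numeric(H),
    Wr = glorot(H, H), Ur = glorot(H, H), br = numeric(H),
    Wn = glorot(H, H), Un = glorot(H, H), bn = numeric(H),
    W3 = glorot(H, H), b3 = numeric(H),
    W4 = glorot(D, H), b4 = numeric(D))
  class(net) <- "sem_network"
  net
}

WEIGHT_NAMES <- c("W1", "b1", "Wz", "Uz", "bz", "Wr", "Ur", "br",
                  "Wn", "Un", "bn", "W3", "b3", "W4", "b4")

#' Extract a network's weights
#' @param net a `"sem_network"`.
#' @return Named list of weight matrices/vectors.
#' @export
network_weights <- function(net) net[WEIGHT_NAMES]

#' Left-pad a context window with zero scene vectors
#'
#' Builds the k-row context matrix a schema predicts from: the k most recent
#' observed scenes, zero-padded on the left when fewer than k exist (so at the
#' first timestep the context is all padding).
#'
#' @param scenes T x D matrix of observed scenes so far (may have 0 rows).
#' @param t 0-based index of the timestep being predicted; rows
#'   `t-k .. t-1` are used.
#' @param k window length.
#' @return k x D numeric matrix, oldest row first.
#' @export
pad_context <- function(scenes, t, k) {
  D <- ncol(scenes)
  ctx <- matrix(0, k, D)
  lo <- max(0L, t - k)
  if (t > lo) {
    rows <- (lo + 1L):t                 # 1-based rows of scenes
    ctx[(k - length(rows) + 1L):k, ] <- scenes[rows, , drop = FALSE]
  }
  ctx
}

# One GRU step from hidden h (H vector or H x S matrix) with layer-1
# activation a1 (same shape). Returns the new hidden.
gru_step <- function(net, a1, h) {
  z <- sigmoid(net$Wz %*% a1 + net$Uz %*% h + net$bz)
  r <- sigmoid(net$Wr %*% a1 + net$Ur %*% h + net$br)
  n <- tanh(net$Wn %*% a1 + r * (net$Un %*% h) + net$bn)
  (1 - z) * n + z * h
}

#' Advance a stored hidden state by one observed scene
#'
#' Used to carry the active schema's pre-window memory forward as scenes age
#' out of the context window.
#'
#' @param net a `"sem_network"`.
#' @param h hidden state vector (length H).
#' @param x scene vector (length D).
#' @return Updated hidden state.
#' @export
advance_hidden <- function(net, h, x) {
  a1 <- lrelu(net$W1 %*% x + net$b1)
  as.numeric(gru_step(net, a1, h))
}

# Forward pass over a context window.
# ctx: k x D (oldest first); h0: initial hidden (numeric H, default zeros);
# masks: optional dropout masks (mx, ma1, mh, ma3; inverse-scaled, held fixed
# across the unroll) applied to the input of each weight layer.
# Returns list(out, cache) where cache holds intermediates for backprop.
net_forward <- function(net, ctx, h0 = NULL, masks = NULL) {
  H <- net$H
  k <- nrow(ctx)
  h <- if (is.null(h0)) numeric(H) else h0
  if (is.null(masks)) {
    masks <- list(mx = rep(1, net$D), ma1 = rep(1, H), mh = rep(1, H),
                  ma3 = rep(1, H))
  }
  cache <- list(x = vector("list", k), z1 = vector("list", k),
                a1 = vector("list", k), z = vector("list", k),
                r = vector("list", k), n = vector("list", k),
                hprev = vector("list", k), unh = vector("list", k),
                masks = masks)
  for (i in seq_len(k)) {
    x <- ctx[i, ] * masks$mx
    z1 <- as.numeric(net$W1 %*% x + net$b1)
    a1 <- lrelu(z1) * masks$ma1           # masked activation feeds the GRU
    unh <- as.numeric(net$Un %*% h)
    z <- as.numeric(sigmoid(net$Wz %*% a1 + net$Uz %*% h + net$bz))
    r <- as.numeric(sigmoid(net$Wr %*% a1 + net$Ur %*% h + net$br))
    n <- as.numeric(tanh(net$Wn %*% a1 + r * unh + net$bn))
    cache$x[[i]] <- x; cache$z1[[i]] <- z1; cache$a1[[i]] <- a1
    cache$z[[i]] <- z; cache$r[[i]] <- r; cache$n[[i]] <- n
    cache$hprev[[i]] <- h; cache$unh[[i]] <- unh
    h <- (1 - z) * n + z * h
  }
  hK <- h * masks$mh
  z3 <- as.numeric(net$W3 %*% hK + net$b3)
  a3 <- lrelu(z3) * masks$ma3
  out <- as.numeric(net$W4 %*% a3 + net$b4)
  cache$hK <- hK; cache$z3 <- z3; cache$a3 <- a3
  list(out = out, cache = cache)
}

draw_masks <- function(D, H, p) {
  keep <- 1 - p
  list(mx = stats::rbinom(D, 1L, keep) / keep,
       ma1 = stats::rbinom(H, 1L, keep) / keep,
       mh = stats::rbinom(H, 1L, keep) / keep,
       ma3 = stats::rbinom(H, 1L, keep) / keep)
}

#' Predict the next scene vector from a context window
#'
#' Deterministic forward pass (no dropout): the same weights and context
#' always give the same prediction.
#'
#' @param net a `"sem_network"`.
#' @param ctx k x D context matrix, oldest row first (see [pad_context()]).
#' @param h0 optional initial hidden state carried in from before the window.
#' @return Numeric vector of length D.
#' @export
predict_scene <- function(net, ctx, h0 = NULL) {
  if (ncol(ctx) != net$D) stop("context dimension != network dimension")
  net_forward(net, ctx, h0)$out
}

#' Monte Carlo dropout prediction sample
#'
#' Draws `S` predictions, each under an independent dropout mask applied to
#' the input of every weight layer (inverse scaling, masks held fixed across
#' the window unroll within a sample). With `p = 0` all samples equal the
#' deterministic prediction.
#'
#' @param net a `"sem_network"`.
#' @param ctx context window matrix.
#' @param S number of samples (>= 2).
#' @param p dropout probability in `[0, 1)`.
#' @param h0 optional initial hidden state.
#' @return S x D matrix of predicted scene vectors, class
#'   `"sem_prediction_sample"`.
#' @export
mc_predict <- function(net, ctx, S, p, h0 = NULL) {
  if (S < 2) stop("S must be >= 2")
  if (p < 0 || p >= 1) stop("p must be in [0, 1)")
  D <- net$D; H <- net$H; k <- nrow(ctx)
  keep <- 1 - p
  mask <- function(nr) {
    if (p == 0) matrix(1, nr, S)
    else matrix(stats::rbinom(nr * S, 1L, keep) / keep, nr, S)
  }
  mx <- mask(D); ma1 <- mask(H); mh <- mask(H); ma3 <- mask(H)
  h <- matrix(0, H, S)
  if (!is.null(h0)) h <- matrix(h0, H, S)
  for (i in seq_len(k)) {
    xs <- ctx[i, ] * mx                       # D x S
    a1 <- lrelu(net$W1 %*% xs + net$b1) * ma1 # H x S
    h <- gru_step(net, a1, h)
  }
  a3 <- lrelu(net$W3 %*% (h * mh) + net$b3) * ma3
  out <- t(net$W4 %*% a3 + net$b4)            # S x D
  class(out) <- c("sem_prediction_sample", class(out))
  out
}

#' Epistemic prediction uncertainty from a dropout sample
#'
#' The trace of the sample covariance of the dropout predictions:
#' `(1/(S-1)) * sum_s ||v_s - mean(v)||^2`. Zero when all samples agree;
#' scales quadratically with the samples.
#'
#' @param sample S x D matrix from [mc_predict()].
#' @return Nonnegative scalar.
#' @export
uncertainty <- function(sample) {
  S <- nrow(sample)
  if (S < 2) stop("need at least 2 samples")
  mu <- colMeans(sample)
  dev <- sweep(sample, 2, mu)
  sum(dev * dev) / (S - 1)
}

#' Prediction error between a predicted and an observed scene
#'
#' Euclidean (L2) distance.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
prediction_error <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("dimension mismatch")
  sqrt(sum((predicted - observed)^2))
}

# Gradients of L = sum((out - y)^2) w.r.t. all weights, via backprop through
# the cached forward pass (dropout masks included). h0 is a constant.
net_gradients <- function(net, ctx, y, h0 = NULL, masks = NULL) {
  fw <- net_forward(net, ctx, h0, masks)
  cache <- fw$cache
  m <- cache$masks
  k <- nrow(ctx)
  g <- lapply(network_weights(net), function(w) w * 0)  # shape-preserving

  dout <- 2 * (fw$out - y)
  g$W4 <- dout %o% cache$a3
  g$b4 <- dout
  da3 <- as.numeric(t(net$W4) %*% dout) * m$ma3
  dz3 <- da3 * lrelu_grad(cache$z3)
  g$W3 <- dz3 %o% cache$hK
  g$b3 <- dz3
  dh <- as.numeric(t(net$W3) %*% dz3) * m$mh

  for (i in rev(seq_len(k))) {
    z <- cache$z[[i]]; r <- cache$r[[i]]; n <- cache$n[[i]]
    hprev <- cache$hprev[[i]]; unh <- cache$unh[[i]]
    a1 <- cache$a1[[i]]
    dn <- dh * (1 - z)
    dz <- dh * (hprev - n)
    dhprev <- dh * z
    dn_pre <- dn * (1 - n^2)
    g$Wn <- g$Wn + dn_pre %o% a1
    g$bn <- g$bn + dn_pre
    dr <- dn_pre * unh
    dunh <- dn_pre * r
    g$Un <- g$Un + dunh %o% hprev
    dhprev <- dhprev + as.numeric(t(net$Un) %*% dunh)
    dz_pre <- dz * z * (1 - z)
    dr_pre <- dr * r * (1 - r)
    g$Wz <- g$Wz + dz_pre %o% a1
    g$Uz <- g$Uz + dz_pre %o% hprev
    g$bz <- g$bz + dz_pre
    g$Wr <- g$Wr + dr_pre %o% a1
    g$Ur <- g$Ur + dr_pre %o% hprev
    g$br <- g$br + dr_pre
    dhprev <- dhprev + as.numeric(t(net$Uz) %*% dz_pre) +
      as.numeric(t(net$Ur) %*% dr_pre)
    da1 <- as.numeric(t(net$Wz) %*% dz_pre) +
      as.numeric(t(net$Wr) %*% dr_pre) +
      as.numeric(t(net$Wn) %*% dn_pre)
    dz1 <- da1 * m$ma1 * lrelu_grad(cache$z1[[i]])
    g$W1 <- g$W1 + dz1 %o% cache$x[[i]]
    g$b1 <- g$b1 + dz1
    dh <- dhprev
  }
  list(grads = g, loss = sum((fw$out - y)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One gradient step on squared prediction error
#'
#' Updates the given network in place (functionally) by one step of plain
#' stochastic gradient descent on `||prediction - observed||^2`. A step with
#' any non-finite gradient entry is skipped and flagged.
#'
#' @param net a `"sem_network"`.
#' @param ctx context window matrix.
#' @param observed observed scene vector.
#' @param lr learning rate (> 0; 0 leaves weights untouched).
#' @param h0 optional initial hidden state.
#' @param p train-time dropout probability; `0` (the default) gives a
#'   deterministic gradient step, `p > 0` draws one set of inverse-scaled
#'   masks from the current RNG (the regularization the architecture
#'   trains with).
#' @return The updated network, with attribute `"skipped"` set if the step
#'   was skipped.
#' @export
update_network <- function(net, ctx, observed, lr, h0 = NULL, p = 0,
                           max_grad_norm = 10) {
  if (lr == 0) return(net)
  masks <- if (p > 0) draw_masks(net$D, net$H, p) else NULL
  gr <- net_gradients(net, ctx, observed, h0, masks)
  if (!all(vapply(gr$grads, function(x) all(is.finite(x)), logical(1)))) {
    attr(net, "skipped") <- TRUE
    return(net)
  }
  # clip the global gradient norm: online SGD on raw squared error sees
  # occasional large-error steps (event boundaries) that would destabilize
  # the small networks
  gn <- sqrt(sum(vapply(gr$grads, function(x) sum(x^2), numeric(1))))
  scale <- if (gn > max_grad_norm) max_grad_norm / gn else 1
  for (nm in WEIGHT_NAMES) {
    net[[nm]] <- net[[nm]] - lr * scale * gr$grads[[nm]]
  }
  net
}

# ---- schema library ---------------------------------------------------------

#' Create an empty schema library
#'
#' The library holds the always-learning generic network (trained on every
#' scene regardless of which schema is active; the source of weights for
#' newly spawned schemas) and an ordered list of spawned schema networks.
#'
#' @param D scene dimension.
#' @param H hidden size.
#' @param max_schemas cap on spawned schemas (`Inf` for unbounded).
#' @return An object of class `"sem_library"`.
#' @export
new_library <- function(D, H, max_schemas = Inf) {
  structure(list(generic = new_network(D, H), schemas = list(),
                 usage = integer(0), spawn_log = list(),
                 max_schemas = max_schemas, spawn_disabled = FALSE),
            class = "sem_library")
}

#' Number of schemas in a library
#' @param lib a `"sem_library"`.
#' @return Integer count.
#' @export
n_schemas <- function(lib) length(lib$schemas)

#' Spawn a new schema from the generic network
#'
#' The new schema's weights are a copy of the generic network's current
#' weights (so at spawn time it predicts identically to the generic); its id
#' is the next integer in spawn order.
#'
#' @param lib a `"sem_library"`.
#' @param t training timestep recorded in the spawn log.
#' @return List with `lib` (updated library) and `id` (new schema id), or
#'   `id = NA` with `spawn_disabled` set when `max_schemas` is reached.
#' @export
spawn_schema <- function(lib, t = NA_integer_) {
  if (n_schemas(lib) >= lib$max_schemas) {
    lib$spawn_disabled <- TRUE
    return(list(lib = lib, id = NA_integer_))
  }
  id <- n_schemas(lib) + 1L
  lib$schemas[[id]] <- lib$generic
  lib$usage[id] <- 0L
  lib$spawn_log[[length(lib$spawn_log) + 1L]] <- list(t = t, id = id)
  list(lib = lib, id = id)
}

#' Train the generic network on one scene transition
#'
#' The generic network takes one gradient step on every timestep regardless
#' of which schema is active; spawned schema networks are untouched.
#'
#' @inheritParams update_network
#' @param lib a `"sem_library"`.
#' @return Updated library.
#' @export
train_generic <- function(lib, ctx, observed, lr, p = 0) {
  lib$generic <- update_network(lib$generic, ctx, observed, lr, NULL, p)
  lib
}

#' Train one schema in a library
#'
#' One gradient step for the named schema only; every other schema (and the
#' generic, which is trained separately) is bit-identical before and after.
#'
#' @param lib a `"sem_library"`.
#' @param id schema id.
#' @inheritParams update_network
#' @return Updated library.
#' @export
train_schema <- function(lib, id, ctx, observed, lr, h0 = NULL, p = 0) {
  lib$schemas[[id]] <- update_network(lib$schemas[[id]], ctx, observed, lr,
                                      h0, p)
  lib
}

#' Fingerprint of all weights in a library
#'
#' MD5 of the serialized weight lists; used to assert isolation contracts
#' (frozen validation, non-active schemas untouched).
#'
#' @param lib a `"sem_library"`.
#' @return Character MD5 string.
#' @export
library_fingerprint <- function(lib) {
  ws <- c(list(network_weights(lib$generic)),
          lapply(lib$schemas, network_weights))
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(ws, f, version = 3, compress = FALSE)
  unname(tools::md5sum(f))
}
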