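test_that("prediction is deterministic and respects the padding contract", {
  set.seed(1)
  net <- new_network(30, 8)
  ctx <- matrix(rnorm(90), 3, 30)
  expect_identical(predict_scene(net, ctx), predict_scene(net, ctx))
  expect_length(predict_scene(net, ctx), 30)
  # at t = 0 the window is pure padding and still yields a valid prediction
  empty <- matrix(numeric(0), 0, 30)
  ctx0 <- pad_context(empty, 0, 3)
  expect_equal(ctx0, matrix(0, 3, 30))
  expect_length(predict_scene(net, ctx0), 30)
  # partial history is right-aligned
  scenes <- matrix(1:60 / 60, 2, 30)
  ctx2 <- pad_context(scenes, 2, 3)
  expect_equal(ctx2[1, ], rep(0, 30))
  expect_equal(ctx2[2:3, ], scenes)
  expect_error(predict_scene(net, matrix(0, 3, 29)), "dimension")
})

test_that("backprop gradients match finite differences", {
  set.seed(4)
  net <- new_network(6, 5)
  ctx <- matrix(rnorm(18), 3, 6)
  y <- rnorm(6)
  h0 <- rnorm(5) * 0.1
  for (masks in list(NULL, eventsem:::draw_masks(6, 5, 0.5))) {
    gr <- eventsem:::net_gradients(net, ctx, y, h0, masks)
    loss <- function(n) {
      sum((eventsem:::net_forward(n, ctx, h0, masks)$out - y)^2)
    }
    for (nm in eventsem:::WEIGHT_NAMES) {
      idx <- seq_len(min(4, length(net[[nm]])))
      for (i in idx) {
        eps <- 1e-6
        np <- net; np[[nm]][i] <- np[[nm]][i] + eps
        nm2 <- net; nm2[[nm]][i] <- nm2[[nm]][i] - eps
        fd <- (loss(np) - loss(nm2)) / (2 * eps)
        expect_equal(gr$grads[[nm]][i], fd, tolerance = 1e-5)
      }
    }
  }
})

test_that("MC dropout sampling degenerates correctly and is reproducible", {
  set.seed(2)
  net <- new_network(10, 6)
  ctx <- matrix(rnorm(30), 3, 10)
  s0 <- mc_predict(net, ctx, S = 5, p = 0)
  base <- predict_scene(net, ctx)
  for (s in 1:5) expect_equal(unname(s0[s, ]), base)
  set.seed(7)
  s1 <- mc_predict(net, ctx, S = 32, p = 0.5)
  set.seed(7)
  s2 <- mc_predict(net, ctx, S = 32, p = 0.5)
  expect_identical(s1, s2)
  # 32 generally distinct predictions under dropout (an occasional pair of
  # masks can coincide on the units that matter)
  expect_gte(nrow(unique(round(s1, 12))), 25)
  expect_gt(uncertainty(s1), 0)
  expect_error(mc_predict(net, ctx, S = 1, p = 0.5), "S")
  expect_error(mc_predict(net, ctx, S = 4, p = 1), "p")
})

test_that("uncertainty implements the dropout-sample variance", {
  # hand evaluation: v1 = (0,0), v2 = (2,0): mean (1,0), (1+1)/(2-1) = 2
  expect_equal(uncertainty(rbind(c(0, 0), c(2, 0))), 2)
  samp <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_equal(uncertainty(samp), 0)
  set.seed(5)
  s <- matrix(rnorm(60), 10, 6)
  expect_gte(uncertainty(s), 0)
  expect_equal(uncertainty(3 * s), 9 * uncertainty(s))
  expect_error(uncertainty(s[1, , drop = FALSE]), "2 samples")
})

test_that("prediction error is the Euclidean distance", {
  expect_equal(prediction_error(c(0, 0), c(3, 4)), 5)
  expect_equal(prediction_error(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(6)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(prediction_error(a, b), prediction_error(b, a))
  expect_error(prediction_error(1:3, 1:4), "dimension")
})

test_that("updates reduce error on a fixed pair and leave others untouched", {
  set.seed(8)
  lib <- new_library(10, 6)
  lib <- spawn_schema(lib)$lib
  lib <- spawn_schema(lib)$lib
  ctx <- matrix(rnorm(30), 3, 10)
  y <- rnorm(10)
  w2_before <- network_weights(lib$schemas[[2]])
  gen_before <- network_weights(lib$generic)
  errs <- numeric(100)
  for (i in 1:100) {
    lib <- train_schema(lib, 1L, ctx, y, lr = 0.005)
    errs[i] <- prediction_error(predict_scene(lib$schemas[[1]], ctx), y)
  }
  # monotone decreasing trend over the run
  expect_true(all(diff(errs) < 1e-12))
  expect_lt(errs[100], errs[1])
  expect_identical(network_weights(lib$schemas[[2]]), w2_before)
  expect_identical(network_weights(lib$generic), gen_before)
  # zero learning rate leaves weights bit-identical
  w1 <- network_weights(lib$schemas[[1]])
  lib <- train_schema(lib, 1L, ctx, y, lr = 0)
  expect_identical(network_weights(lib$schemas[[1]]), w1)
})

test_that("the generic network trains on every step, schemas untouched", {
  set.seed(9)
  lib <- new_library(8, 4)
  lib <- spawn_schema(lib)$lib
  ctx <- matrix(rnorm(24), 3, 8)
  y <- rnorm(8)
  s_before <- network_weights(lib$schemas[[1]])
  g_before <- network_weights(lib$generic)
  lib <- train_generic(lib, ctx, y, lr = 0.01)
  expect_false(identical(network_weights(lib$generic), g_before))
  expect_identical(network_weights(lib$schemas[[1]]), s_before)
})

test_that("spawning copies generic weights and ids increase", {
  set.seed(10)
  lib <- new_library(8, 4)
  ctx <- matrix(rnorm(24), 3, 8)
  r1 <- spawn_schema(lib, t = 0L)
  expect_equal(r1$id, 1L)
  expect_equal(predict_scene(r1$lib$schemas[[1]], ctx),
               predict_scene(r1$lib$generic, ctx))
  lib <- train_generic(r1$lib, ctx, rnorm(8), lr = 0.05)
  r2 <- spawn_schema(lib, t = 5L)
  expect_equal(r2$id, 2L)
  # later spawn copies the *current* generic, so the two schemas differ
  expect_false(identical(network_weights(r2$lib$schemas[[1]]),
                         network_weights(r2$lib$schemas[[2]])))
  # training the spawned schema leaves the generic untouched
  g <- network_weights(r2$lib$generic)
  lib2 <- train_schema(r2$lib, 2L, ctx, rnorm(8), lr = 0.05)
  expect_identical(network_weights(lib2$generic), g)
  expect_equal(vapply(r2$lib$spawn_log, function(s) s$id, integer(1)),
               c(1L, 2L))
  # max_schemas cap disables spawning
  lib3 <- new_library(8, 4, max_schemas = 1)
  lib3 <- spawn_schema(lib3)$lib
  r3 <- spawn_schema(lib3)
  expect_true(is.na(r3$id))
  expect_true(r3$lib$spawn_disabled)
})

test_that("carried-in hidden state changes predictions but not shape", {
  set.seed(11)
  net <- new_network(10, 6)
  ctx <- matrix(rnorm(30), 3, 10)
  h <- advance_hidden(net, numeric(6), rnorm(10))
  expect_length(h, 6)
  p0 <- predict_scene(net, ctx)
  ph <- predict_scene(net, ctx, h)
  expect_length(ph, 10)
  expect_false(isTRUE(all.equal(p0, ph)))
})
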