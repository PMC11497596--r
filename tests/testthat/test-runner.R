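test_that("validation passes are frozen: library fingerprint unchanged", {
  corp <- small_gen_corpus()
  fit <- event_sem(corp, "sem2", seed = 4, checkpoint_every = 3)
  fp <- library_fingerprint(fit$library)
  # re-running validation on the final library changes nothing
  pred <- predict(fit, corp$activities[[names(
    corp$split)[corp$split == "validation"][1]]])
  expect_equal(library_fingerprint(fit$library), fp)
  expect_s3_class(pred, "data.frame")
  expect_true(all(pred$pe >= 0))
})

test_that("training order matters and seeds reproduce results exactly", {
  corp <- small_gen_corpus(n_train = 3, n_val = 1)
  ids <- names(corp$split)[corp$split == "train"]
  f1 <- event_sem(corp, "sem2", seed = 5, order = ids,
                  checkpoint_every = 3)
  f2 <- event_sem(corp, "sem2", seed = 5, order = ids,
                  checkpoint_every = 3)
  expect_identical(checkpoint_table(f1), checkpoint_table(f2))
  expect_identical(decision_sequence(f1), decision_sequence(f2))
  f3 <- event_sem(corp, "sem2", seed = 5, order = rev(ids),
                  checkpoint_every = 3)
  expect_false(identical(
    unname(unlist(lapply(f1$train_traces, function(tr) tr$pe))),
    unname(unlist(lapply(f3$train_traces, function(tr) tr$pe)))))
})

test_that("run_simulations yields one metric value per sim per checkpoint", {
  corp <- small_gen_corpus(n_train = 2, n_val = 1)
  sims <- run_simulations(corp, "pe", n_sims = 3, seed = 6,
                          checkpoint_every = 2)
  tab <- checkpoint_table(sims)
  expect_equal(sort(unique(tab$simulation)), 1:3)
  expect_true(all(table(tab$simulation) == max(tab$checkpoint)))
  sims2 <- run_simulations(corp, "pe", n_sims = 3, seed = 6,
                           checkpoint_every = 2)
  expect_identical(checkpoint_table(sims), checkpoint_table(sims2))
  # distinct seeds give distinct weight trajectories
  expect_false(identical(
    unlist(lapply(sims[[1]]$train_traces, function(tr) tr$pe)),
    unlist(lapply(sims[[2]]$train_traces, function(tr) tr$pe))))
})

test_that("checkpoint cadence is every 10 activities plus a final one", {
  corp <- generate_corpus(generator_config(n_train = 12, n_validation = 1,
                                           seed = 15))
  fit <- event_sem(corp, "pe", seed = 7, checkpoint_every = 5)
  tab <- checkpoint_table(fit)
  expect_equal(tab$after_activities, c(5, 10, 12))
})

test_that("boundary-rate tuning returns the argmin with grid-order ties", {
  corp <- small_gen_corpus(n_train = 3, n_val = 2)
  grid <- data.frame(stickiness = c(0.5, 4, 50))
  res <- tune_boundary_rate(corpus = corp, grid = grid, target = 5,
                            variant = "sem2", n_train = 3, seed = 8)
  expect_equal(res$best_index, which.min(res$table$objective))
  expect_equal(res$best$stickiness, grid$stickiness[res$best_index])
  # single-point grid returns that point
  res1 <- tune_boundary_rate(corp, data.frame(stickiness = 2), target = 5,
                             variant = "sem2", n_train = 2, seed = 8)
  expect_equal(res1$best_index, 1L)
  expect_equal(res1$best$stickiness, 2)
  expect_error(tune_boundary_rate(corp, data.frame(), 5), "empty")
})

test_that("input ablation zeroes exactly the named block", {
  corp <- small_gen_corpus(n_train = 2, n_val = 1)
  abl <- ablate_inputs(corp, "semantic")
  lay <- corp$activities[[1]]$layout
  s_idx <- block_indices(lay, "semantic")
  m_idx <- block_indices(lay, "motion")
  for (id in names(corp$activities)) {
    expect_true(all(abl$activities[[id]]$scenes[, s_idx] == 0))
    expect_identical(abl$activities[[id]]$scenes[, m_idx],
                     corp$activities[[id]]$scenes[, m_idx])
  }
  # idempotent on an already-zero block
  expect_identical(ablate_inputs(abl, "semantic")$activities[[1]]$scenes,
                   abl$activities[[1]]$scenes)
  expect_error(ablate_inputs(corp, "audio"), "unknown")
})

test_that("the generic baseline emits no boundaries and tracks PE", {
  corp <- small_gen_corpus(n_train = 2, n_val = 1)
  gb <- generic_baseline(corp, seed = 9, checkpoint_every = 2)
  expect_equal(nrow(gb$checkpoints), 1)
  expect_true(all(gb$checkpoints$validation_pe > 0))
  expect_equal(n_schemas(gb$library), 0)  # single model, never spawns
  gb3 <- generic_baseline(corp, seed = 9, hidden_multiplier = 3,
                          checkpoint_every = 2)
  expect_equal(gb3$library$generic$H, 3 * sem_control()$hidden_size)
})

test_that("model methods expose the fit coherently", {
  corp <- small_gen_corpus()
  fit <- event_sem(corp, "sem2", seed = 10, checkpoint_every = 3)
  expect_output(print(fit), "variant: sem2")
  s <- summary(fit)
  expect_s3_class(s, "summary.event_sem")
  expect_output(print(s), "Training decisions")
  cf <- coef(fit)
  expect_named(cf, c("generic", "schemas"))
  expect_length(cf$schemas, n_schemas(fit$library))
  r <- residuals(fit)
  expect_true(all(r >= 0))
  expect_equal(length(r),
               sum(vapply(fit$train_traces, nrow, integer(1))))
  sims <- simulate(fit, nsim = 2, seed = 1, T = 8)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), c(8, 30))
  vl <- validation_labels(fit)
  expect_equal(length(vl$labels), length(vl$boundaries))
  expect_equal(vl$offsets[1], 0)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
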