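test_that("validation PE matches hand evaluation and brute force", {
  tr1 <- data.frame(pe = c(3, 4))
  expect_equal(validation_pe(list(tr1)), 12.5)
  tr2 <- data.frame(pe = c(0, 0))
  expect_equal(validation_pe(list(tr1, tr2)), 6.25)
  expect_equal(validation_pe(list(tr2, tr1)), 6.25)  # order invariance
  # brute-force double loop on random traces
  set.seed(1)
  traces <- lapply(1:4, function(i) data.frame(pe = abs(rnorm(i + 3))))
  acc <- 0
  for (tr in traces) {
    s <- 0
    for (e in tr$pe) s <- s + e^2
    acc <- acc + s / length(tr$pe)
  }
  expect_equal(validation_pe(traces), acc / 4)
})

test_that("normative series bins rater times onto the timestep grid", {
  r1 <- rater_segmentation("r1", "a", 1.0)
  expect_equal(normative_series(list(r1), T = 6, dt = 1 / 3),
               c(0, 0, 0, 1, 0, 0))
  # 2 of 4 raters at timestep 5
  rs <- c(lapply(1:2, function(i)
           rater_segmentation(paste0("r", i), "a", 5 * 0.5 + 0.1)),
          lapply(3:4, function(i)
           rater_segmentation(paste0("r", i), "a", 0.2)))
  ns <- normative_series(rs, T = 8, dt = 0.5)
  expect_equal(ns[6], 0.5)
  expect_equal(ns[1], 0.5)
  # identical raters give a 0/1 series; times beyond span clip to last bin
  same <- lapply(1:5, function(i)
    rater_segmentation(paste0("r", i), "a", c(0.4, 99)))
  ns2 <- normative_series(same, T = 4, dt = 0.5)
  expect_true(all(ns2 %in% c(0, 1)))
  expect_equal(ns2[4], 1)
})

test_that("scaled point-biserial hits its bounds and the derived fixture", {
  norm <- c(0.9, 0.1, 0.5, 0.2)
  # optimal and pessimal single placements
  expect_equal(scaled_point_biserial(c(1, 0, 0, 0), norm), 1)
  expect_equal(scaled_point_biserial(c(0, 1, 0, 0), norm), 0)
  # boundary at the third timestep: (0.5 - 0.1) / (0.9 - 0.1) = 0.5
  expect_equal(scaled_point_biserial(c(0, 0, 1, 0), norm), 0.5)
  # brute force: for B = 1 the scaled value is linear in the selected
  # normative value
  for (i in 1:4) {
    b <- integer(4); b[i] <- 1L
    expect_equal(scaled_point_biserial(b, norm),
                 (norm[i] - 0.1) / (0.9 - 0.1))
  }
  # in [0, 1] whenever defined, 1 iff optimal for its count
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    nv <- runif(n)
    B <- sample(1:(n - 1), 1)
    b <- integer(n); b[sample(n, B)] <- 1L
    v <- scaled_point_biserial(b, nv)
    expect_gte(v, 0); expect_lte(v, 1)
    opt <- integer(n); opt[order(nv, decreasing = TRUE)[1:B]] <- 1L
    expect_equal(scaled_point_biserial(opt, nv), 1)
  }
  expect_warning(scaled_point_biserial(c(0, 0, 0, 0), norm), "undefined")
  expect_warning(scaled_point_biserial(c(1, 0, 0, 0), rep(0.5, 4)),
                 "undefined")
})

test_that("adjusted mutual information matches enumeration and reference", {
  a <- c(0, 0, 1, 1)
  b <- c(0, 0, 1, 2)
  # independent oracle: expected MI by averaging over all 4! permutations
  # of one labeling (the permutation model the adjustment is defined by)
  mi_nat <- function(x, y) {
    tab <- table(x, y); N <- length(x)
    s <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      nij <- tab[i, j]
      if (nij > 0) {
        s <- s + (nij / N) *
          log(N * nij / (sum(tab[i, ]) * sum(tab[, j])))
      }
    }
    s
  }
  perms <- rbind(
    c(1,2,3,4),c(1,2,4,3),c(1,3,2,4),c(1,3,4,2),c(1,4,2,3),c(1,4,3,2),
    c(2,1,3,4),c(2,1,4,3),c(2,3,1,4),c(2,3,4,1),c(2,4,1,3),c(2,4,3,1),
    c(3,1,2,4),c(3,1,4,2),c(3,2,1,4),c(3,2,4,1),c(3,4,1,2),c(3,4,2,1),
    c(4,1,2,3),c(4,1,3,2),c(4,2,1,3),c(4,2,3,1),c(4,3,1,2),c(4,3,2,1))
  emi_enum <- mean(apply(perms, 1, function(p) mi_nat(a, b[p])))
  h <- function(x) { p <- table(x) / length(x); -sum(p * log(p)) }
  ami_enum <- (mi_nat(a, b) - emi_enum) / (max(h(a), h(b)) - emi_enum)
  expect_equal(adjusted_mutual_information(a, b), ami_enum,
               tolerance = 1e-12)
  # frozen reference values (hypergeometric model, max normalization)
  expect_equal(adjusted_mutual_information(a, b), 0.4, tolerance = 1e-9)
  expect_equal(adjusted_mutual_information(c(0, 0, 1, 1, 2, 2),
                                           c(0, 0, 0, 1, 1, 1)),
               0.22504228319830902, tolerance = 1e-9)
})

test_that("AMI is 1 on identical partitions, symmetric, label-invariant", {
  set.seed(3)
  for (rep in 1:10) {
    x <- sample(letters[1:3], 30, replace = TRUE)
    y <- sample(letters[1:4], 30, replace = TRUE)
    expect_equal(adjusted_mutual_information(x, x), 1)
    expect_equal(adjusted_mutual_information(x, y),
                 adjusted_mutual_information(y, x), tolerance = 1e-12)
    relab <- c(a = "z", b = "q", c = "m")[x]
    expect_equal(adjusted_mutual_information(x, y),
                 adjusted_mutual_information(relab, y), tolerance = 1e-12)
  }
  expect_error(adjusted_mutual_information(1:3, 1:4), "mismatch")
})

test_that("purity and coverage match hand counts and refinement property", {
  model <- c("A", "A", "B", "B", "C", "C")
  truth <- c("x", "x", "x", "y", "y", "y")
  pc <- purity_coverage(model, truth)
  expect_equal(unname(pc["purity"]), 5 / 6)
  expect_equal(unname(pc["coverage"]), 2 / 3)
  expect_equal(unname(purity_coverage(truth, truth)), c(1, 1))
  # strict refinement: purity 1, coverage < 1
  fine <- c("a", "b", "b", "c", "c", "d")
  pc2 <- purity_coverage(fine, truth)
  expect_equal(unname(pc2["purity"]), 1)
  expect_lt(pc2["coverage"], 1)
})

test_that("event permutations preserve run-length multisets", {
  labels <- c("A", "A", "B", "C", "C", "C")
  null <- permute_events(labels, offsets = 0L, n = 30, seed = 4)
  all_orders <- list(
    c("A","A","B","C","C","C"), c("A","A","C","C","C","B"),
    c("B","A","A","C","C","C"), c("B","C","C","C","A","A"),
    c("C","C","C","A","A","B"), c("C","C","C","B","A","A"))
  for (p in null$perms) {
    expect_equal(sort(table(rle(p)$lengths)), sort(table(c(2, 1, 3))))
    expect_true(any(vapply(all_orders, identical, logical(1), y = p)))
  }
  # single run: permutation equals the original
  one <- permute_events(rep("Z", 5), 0L, n = 3, seed = 5)
  for (p in one$perms) expect_equal(p, rep("Z", 5))
})

test_that("permutations keep boundaries out of activity gap intervals", {
  # two activities of 6 steps; runs straddle the join
  labels <- c("A", "A", "A", "B", "B", "B", "C", "C", "D", "D", "D", "D")
  off <- c(0L, 6L)
  null <- permute_events(labels, off, n = 50, seed = 6)
  expect_false(any(null$unsatisfied))
  gi <- null$gap_intervals
  expect_equal(unname(gi[1, ]), c(3, 6))  # last onset of act 1 to act 2 start
  for (p in null$perms) {
    b <- which(labels_to_boundaries(p) == 1) - 1  # 0-based positions
    expect_false(any(b > gi[1, 1] & b < gi[1, 2]))
  }
})

test_that("boundary interval statistics match hand arithmetic", {
  b <- integer(31)
  b[c(1, 2, 3, 31)] <- 1L  # boundaries at t = 0, 1, 2, 30
  st <- boundary_interval_stats(b, dt = 1 / 3)
  expect_equal(st$intervals, c(1 / 3, 1 / 3, 28 / 3))
  expect_equal(st$fraction_below, 2 / 3)
  expect_equal(boundary_interval_stats(integer(10), 1 / 3)$intervals,
               numeric(0))
  one <- integer(10); one[4] <- 1L
  st1 <- boundary_interval_stats(one, 1 / 3)
  expect_equal(st1$intervals, numeric(0))
  expect_true(is.na(st1$fraction_below))
  # strict inequality at the threshold
  b2 <- integer(10); b2[c(1, 4)] <- 1L
  expect_equal(boundary_interval_stats(b2, dt = 1 / 3,
                                       threshold_s = 1)$fraction_below, 0)
})

test_that("schema usage curves count spawns and reuse per bin", {
  mk <- function(dec) data.frame(decision = dec)
  # bin 1: two spawns; bin 2: four switches to old ids
  traces <- list(mk(c("SPAWN", "KEEP", "SPAWN")), mk(c("KEEP", "KEEP")),
                 mk(c("SWITCH", "SWITCH")), mk(c("SWITCH", "SWITCH")))
  uc <- schema_usage_curves(traces, bin_activities = 2)
  expect_equal(uc$spawn_rate, c(1, 0))
  expect_equal(uc$reuse_rate, c(0, 1))
  # all KEEP: no spawns, reuse undefined
  uc2 <- schema_usage_curves(list(mk(rep("KEEP", 5))), 10)
  expect_equal(uc2$spawn_rate, 0)
  expect_true(is.na(uc2$reuse_rate))
})

test_that("leave-one-out rater agreement is high for consistent raters", {
  act <- small_gen_corpus()$activities[[1]]
  raters <- simulate_raters(act, n_raters = 20, jitter_sd_s = 0.2,
                            miss_prob = 0.05, false_alarm_rate = 0.5,
                            seed = 8)
  agr <- rater_agreement(raters, nrow(act$scenes), act$dt)
  expect_gt(mean(agr, na.rm = TRUE), 0.5)
})
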