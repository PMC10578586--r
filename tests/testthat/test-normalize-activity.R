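test_that("size factors follow the median-of-ratios formula", {
  c1 <- c(10, 20, 40)
  m <- cbind(s1 = c1, s2 = 2 * c1)
  f <- size_factors(m)
  expect_equal(unname(f[2] / f[1]), 2)
  # geometric-mean-1 rescaling gives (1/sqrt(2), sqrt(2))
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(size_factors(cbind(a = c1, b = c1))), c(1, 1))
  expect_error(size_factors(cbind(a = c(0, 1), b = c(1, 0))), "pseudocount")
})

test_that("log normalization behaves and is scale-consistent", {
  m <- matrix(c(0, 15), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  nm <- normalize_log(m, c(1, 1))
  expect_equal(nm["g1", "a"], 0)
  expect_equal(nm["g2", "a"], 4)
  expect_equal(normalize_log(2 * m, c(2, 2)), nm)
  expect_error(normalize_log(m, c(1, -1)), "> 0")
})

test_that("single-target regulons reproduce the activator/repressor rule", {
  nm <- rbind(g1 = c(1, 5, 3, 2), g2 = c(2, 2, 2, 9))
  colnames(nm) <- paste0("s", 1:4)
  z1 <- (nm["g1", ] - mean(nm["g1", ])) / sd(nm["g1", ])
  act <- regulator_activity(
    nm, regulon_set(c("A", "R"), c("activator", "repressor"),
                    list("g1", "g1")))
  expect_equal(act["A", ], z1)
  expect_equal(act["R", ], -z1)
  # multi-target: mean of per-gene z-scores
  z2 <- (nm["g2", ] - mean(nm["g2", ])) / sd(nm["g2", ])
  act2 <- regulator_activity(
    nm, regulon_set("A", "activator", list(c("g1", "g2"))))
  expect_equal(act2["A", ], (z1 + z2) / 2)
  # per-regulator mean over the reference set is zero by construction
  expect_equal(unname(rowMeans(act)), c(0, 0))
})

test_that("activities ignore global count rescaling and flag empty regulons", {
  tx <- default_tx()
  act <- default_activity()
  # exact up to the pseudocount, which is negligible at this depth
  nm2 <- normalize_log(tx$counts * 4L, size_factors(tx$counts * 4L))
  act2 <- suppressMessages(regulator_activity(nm2, tx$truth$regulons))
  expect_equal(unclass(act2), unclass(act), tolerance = 0.01,
               ignore_attr = TRUE)

  nm <- default_norm()
  bad <- regulon_set("X", "activator", list("not_a_gene"))
  out <- suppressMessages(regulator_activity(nm, bad))
  expect_true("X" %in% attr(out, "undefined"))
  expect_true(all(is.na(out["X", ])))
})

test_that("inferred activities recover the planted ground truth", {
  tx <- default_tx()
  act <- default_activity()
  rec <- vapply(rownames(act), function(r)
    cor(act[r, ], tx$truth$activity[r, ]), 0)
  expect_true(all(rec >= 0.9))
})

test_that("coactivation captures affine and inverted relations", {
  A <- c(0.3, -1, 2, 0.7, -0.2, 1.5)
  act <- rbind(A = A, B = 2 * A + 1, C = -A)
  colnames(act) <- paste0("s", 1:6)
  co <- coactivation(act)
  expect_equal(co["A", "B"], 1)
  expect_equal(co["A", "C"], -1)
  expect_lt(max(abs(co - t(co))), 1e-12)
  expect_true(all(diag(co) == 1))
  # independent activities decorrelate at large n
  set.seed(42)
  r2 <- coactivation(matrix(rnorm(2 * 200), 2,
                            dimnames = list(c("a", "b"),
                                            paste0("s", 1:200))))
  expect_lt(abs(r2["a", "b"]), 0.2)
  expect_error(coactivation(act[, 1:2]), ">= 3")
})

test_that("coactivation matrices are positive semidefinite", {
  co <- coactivation(default_activity())
  ev <- eigen(co, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
})

test_that("module partitioning recovers planted blocks and nests splits", {
  regs <- paste0("r", 1:8)
  co <- matrix(-0.8, 8, 8, dimnames = list(regs, regs))
  co[1:4, 1:4] <- 0.9
  co[5:8, 5:8] <- 0.9
  diag(co) <- 1
  class(co) <- c("coactivation_matrix", "matrix", "array")
  attr(co, "masked") <- character(0)
  pm <- partition_modules(co)
  expect_equal(pm$k, 2L)
  expect_equal(length(unique(pm$modules[1:4])), 1)
  expect_equal(length(unique(pm$modules[5:8])), 1)
  expect_false(pm$modules[1] == pm$modules[5])
  # forcing k = 3 splits one block but still nests the two-block structure
  pm3 <- partition_modules(co, k = 3)
  expect_equal(pm3$k, 3L)
  expect_true(length(intersect(unique(pm3$modules[1:4]),
                               unique(pm3$modules[5:8]))) == 0)
  # all-alike matrix: degenerate silhouette is flagged
  co2 <- matrix(0.95, 6, 6, dimnames = list(regs[1:6], regs[1:6]))
  diag(co2) <- 1
  class(co2) <- class(co); attr(co2, "masked") <- character(0)
  expect_warning(pm2 <- partition_modules(co2), "degenerate")
  expect_true(pm2$degenerate)
})

test_that("planted vegetative/dormancy split is recovered exactly", {
  tx <- default_tx()
  pm <- partition_modules(coactivation(default_activity()))
  expect_equal(pm$k, 2L)
  split_pure <- vapply(split(tx$truth$regulons$module, pm$modules),
                       function(x) length(unique(x)) == 1, TRUE)
  expect_true(all(split_pure))
})

test_that("activity regressions report R-squared as the squared correlation", {
  set.seed(7)
  x <- rnorm(20)
  act <- rbind(perfect = 3 * x + 1, noisy = rnorm(20))
  colnames(act) <- paste0("s", 1:20)
  cov <- stats::setNames(x, colnames(act))
  fits <- suppressWarnings(activity_fits(act, cov))  # noiseless fit warns
  per <- fits$per_regulator
  expect_equal(per$r_squared[per$regulator == "perfect"], 1)
  expect_lt(per$r_squared[per$regulator == "noisy"], 0.2)
  expect_equal(per$r_squared[1], cor(act["perfect", ], x)^2,
               tolerance = 1e-10)
  # constant covariate is flagged undefined
  fits2 <- activity_fits(act, stats::setNames(rep(1, 20), colnames(act)))
  expect_true(all(fits2$per_regulator$flag == "constant_covariate"))
})

test_that("activity tracks cell-type composition on synthetic data", {
  tx <- default_tx()
  act <- default_activity()
  # the spore fraction is monotone in the dormancy axis, so activities of
  # both modules regress strongly on it
  spores <- stats::setNames(tx$truth$composition$spores,
                            tx$truth$composition$sample_id)
  fits <- activity_fits(act, spores)
  expect_gt(fits$mean_r2, 0.5)
  expect_true(is.finite(fits$se_r2))
  # the sporulating-cell fraction peaks at intermediate dormancy, so the
  # linear fit is defined but weaker; the operation still reports it
  spor <- stats::setNames(tx$truth$composition$sporulating,
                          tx$truth$composition$sample_id)
  fits2 <- activity_fits(act, spor)
  expect_true(all(fits2$per_regulator$flag == "ok"))
  expect_true(all(fits2$per_regulator$r_squared >= 0 &
                    fits2$per_regulator$r_squared <= 1))
})
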