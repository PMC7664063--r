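test_that("dice matches brute-force set arithmetic and its conventions", {
  a <- random_label_volume(seed = 1)
  expect_identical(dice(a, a, "tibia"), 1)

  g <- voxel_grid(c(4, 4, 4), c(1, 1, 1))
  lm <- c(background = 0L, tibia = 1L)
  m1 <- array(0L, dim = c(4, 4, 4)); m1[1:2, , ] <- 1L
  m2 <- array(0L, dim = c(4, 4, 4)); m2[3:4, , ] <- 1L
  expect_identical(dice(label_volume(m1, g, lm), label_volume(m2, g, lm),
                        "tibia"), 0)

  # 2x2x2 cube against itself shifted to overlap in half its voxels
  c1 <- array(0L, dim = c(4, 4, 4)); c1[1:2, 1:2, 1:2] <- 1L
  c2 <- array(0L, dim = c(4, 4, 4)); c2[2:3, 1:2, 1:2] <- 1L
  expect_identical(dice(label_volume(c1, g, lm), label_volume(c2, g, lm),
                        "tibia"), 2 * 4 / (8 + 8))

  # both empty -> 1; one empty -> 0
  z <- label_volume(array(0L, dim = c(4, 4, 4)), g, lm)
  expect_identical(dice(z, z, "tibia"), 1)
  expect_identical(dice(z, label_volume(c1, g, lm), "tibia"), 0)

  expect_error(dice(a, random_label_volume(shape = c(5, 6, 6), seed = 2), "tibia"),
               "different grids")
})

test_that("dice equals the brute-force oracle on random mask pairs, symmetrically", {
  for (seed in 1:50) {
    a <- random_label_volume(seed = seed)
    b <- random_label_volume(seed = seed + 1000)
    for (role in c("tibia", "tibial_cartilage")) {
      ma <- a$labels == a$label_map[[role]]
      mb <- b$labels == b$label_map[[role]]
      oracle <- 2 * sum(ma & mb) / (sum(ma) + sum(mb))
      expect_identical(dice(a, b, role), oracle)
      expect_identical(dice(a, b, role), dice(b, a, role))
    }
  }
})

test_that("split plans draw disjoint test sets and validate sizes", {
  plan <- split_plan(20, 5, 3, seed = 4)
  sets <- kneemorph:::.plan_test_sets(plan)
  expect_identical(length(sets), 3L)
  all_idx <- unlist(sets)
  expect_identical(length(all_idx), 15L)
  expect_identical(anyDuplicated(all_idx), 0L)
  expect_identical(sets, kneemorph:::.plan_test_sets(plan))
  expect_error(split_plan(12, 5, 3), "plan error")
})

test_that("hold-out harness with a ground-truth oracle trainer gives DSC 1", {
  set.seed(2)
  ds <- lapply(1:8, function(i) {
    lv <- random_label_volume(shape = c(6, 6, 6), seed = i)
    list(intensity = intensity_volume(array(rnorm(216), dim = c(6, 6, 6)),
                                      lv$grid),
         labels = lv)
  })
  oracle_trainer <- function(train_subjects) {
    truth_by_sum <- ds
    function(iv) {
      for (s in truth_by_sum)
        if (isTRUE(all.equal(s$intensity$values, iv$values))) return(s$labels)
      stop("unknown subject")
    }
  }
  plan <- split_plan(8, 2, 3, seed = 1)
  rep <- run_holdout_validation(ds, oracle_trainer, plan, c("tibia"))
  expect_true(all(rep$per_subject$dsc == 1))
  summ <- rep$summary
  expect_identical(summ$mean_dsc, rep(1, 4))
  expect_identical(summ$sd_dsc[summ$repeat_id == "total"], 0)
  expect_identical(summ$n[summ$repeat_id == "total"], 6L)
})

test_that("spearman handles perfect monotone association and errors", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman(x, 2 * x + 1)$rs, 1)
  expect_equal(spearman(x, -x^3)$rs, -1)
  expect_error(spearman(1:5, rep(2, 5)), "undefined-correlation")
  expect_error(spearman(1:4, 1:5), "length")
})

test_that("worked 5-point example: rs 0.8 with the exact permutation p-value", {
  x <- 1:5; y <- c(1, 3, 2, 5, 4)
  sp <- spearman(x, y)
  expect_equal(sp$rs, 0.8)
  expect_identical(sp$method, "exact permutation")
  # independent oracle: enumerate all 120 orderings with stats::cor
  perms <- kneemorph:::.all_permutations(5)
  rs_all <- apply(perms, 1, function(p) stats::cor(x, y[p], method = "spearman"))
  p_oracle <- mean(abs(rs_all) >= 0.8 - 1e-9)
  expect_equal(sp$p_value, p_oracle)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rnorm(25); y <- rnorm(25)
  base <- spearman(x, y)
  expect_equal(spearman(exp(x), y)$rs, base$rs)
  expect_equal(spearman(x, rank(y)^3)$rs, base$rs)
  expect_equal(spearman(exp(x), y)$p_value, base$p_value)
  expect_identical(base$method, "t approximation")
})

test_that("exact permutation p-values are calibrated under the null", {
  set.seed(31)
  n_rep <- 2000
  p <- vapply(seq_len(n_rep), function(i)
    spearman(runif(7), runif(7))$p_value, numeric(1))
  rate <- mean(p <= 0.05)
  ci <- 0.05 + c(-1, 1) * 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(rate, ci[1])
  expect_lt(rate, ci[2])
})

test_that("correlate_measurements recovers planted cohort structure", {
  co <- generate_cohort(cohort_spec(561, target_rs = c(VC = 0.4, PCAR = 0),
                                    seed = 5))
  out <- correlate_measurements(co, data.frame(measurement = c("VC", "PCAR"),
                                               covariate = "height_cm"))
  expect_lt(abs(out$rs[out$measurement == "VC"] - 0.4), 0.08)
  expect_true(out$significant[out$measurement == "VC"])
  expect_lt(abs(out$rs[out$measurement == "PCAR"]), 0.1)
  expect_error(correlate_measurements(co, data.frame(measurement = "nope",
                                                     covariate = "height_cm")),
               "schema error")
})

test_that("a planted null is flagged non-significant in most replicates", {
  hits <- vapply(1:40, function(s) {
    co <- generate_cohort(cohort_spec(561, target_rs = c(PCAR = 0), seed = s))
    out <- correlate_measurements(co, data.frame(measurement = "PCAR",
                                                 covariate = "height_cm"))
    out$significant
  }, logical(1))
  expect_lt(mean(hits), 0.15)
})

test_that("stratified correlation reports one row per stratum", {
  co <- generate_cohort(cohort_spec(200, target_rs = c(VC = 0.4), seed = 2))
  co$sex <- rep(c("F", "M"), 100)
  out <- correlate_measurements(co, data.frame(measurement = "VC",
                                               covariate = "height_cm"),
                                strata = "sex")
  expect_identical(nrow(out), 2L)
  expect_setequal(out$stratum, c("F", "M"))
  expect_identical(out$n, c(100L, 100L))
})
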