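# Segmentation accuracy (DSC), the repeated hold-out validation harness,
# and Spearman rank-correlation reporting.

#' Dice similarity coefficient between two segmentations
#'
#' `DSC = 2|A n B| / (|A| + |B|)` for the binary masks of one structure
#' role in two label volumes on the same grid. Conventions for empty masks:
#' both empty is perfect agreement (1); exactly one empty is complete
#' disagreement (0).
#'
#' @param a,b [label_volume()] objects on the same grid, both carrying
#'   `role` in their label maps.
#' @param role Structure role to compare.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, b, role) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  if (!check_same_grid(a$grid, b$grid))
    stop("dice: volumes are on different grids (contract error)")
  ma <- .role_mask(a, role)
  mb <- .role_mask(b, role)
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) return(1)
  2 * sum(ma & mb) / (na + nb)
}

#' Hold-out split plan
#'
#' Repeated hold-out protocol: from `n_total` subjects, each repeat holds
#' out `n_test` subjects for testing and trains on the rest. Test sets are
#' disjoint across repeats (each repeat tests different subjects), sampled
#' without replacement under the plan seed.
#'
#' @param n_total Total number of subjects.
#' @param n_test Held-out subjects per repeat.
#' @param n_repeats Number of repeats.
#' @param seed Integer seed.
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(n_total, n_test = 5, n_repeats = 3, seed = 1L) {
  stopifnot(n_total > n_test, n_repeats >= 1)
  if (n_repeats * n_test > n_total)
    stop("split_plan: n_repeats * n_test exceeds n_total, disjoint test sets impossible (plan error)")
  structure(list(n_total = as.integer(n_total), n_test = as.integer(n_test),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "split_plan")
}

.plan_test_sets <- function(plan) {
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(plan$seed)
  drawn <- sample.int(plan$n_total, plan$n_repeats * plan$n_test)
  split(drawn, rep(seq_len(plan$n_repeats), each = plan$n_test))
}

#' Run repeated hold-out segmentation validation
#'
#' For each repeat of the plan, trains `trainer` on the training subjects
#' and computes per-structure DSC on the held-out subjects; reports
#' mean and SD of DSC per structure per repeat plus a pooled total row over
#' all repeats' test subjects.
#'
#' @param dataset List of subjects, each a list with elements `intensity`
#'   (an [intensity_volume()]) and `labels` (a [label_volume()]).
#' @param trainer Function `(train_subjects) -> function(intensity) ->
#'   label_volume`; e.g. the closure returned by [unet_trainer()].
#' @param plan A [split_plan()] with `n_total = length(dataset)`.
#' @param roles Structure roles to score.
#' @return An object of class `dice_report`: data frame `per_subject`
#'   (repeat, subject, role, dsc) and data frame `summary` (role, repeat
#'   or "total", mean, sd, n).
#' @export
run_holdout_validation <- function(dataset, trainer, plan, roles) {
  stopifnot(inherits(plan, "split_plan"), length(dataset) == plan$n_total)
  test_sets <- .plan_test_sets(plan)
  per <- list()
  for (r in seq_len(plan$n_repeats)) {
    test_idx <- test_sets[[r]]
    model <- trainer(dataset[-test_idx])
    for (s in test_idx) {
      pred <- model(dataset[[s]]$intensity)
      for (role in roles)
        per[[length(per) + 1]] <- data.frame(
          repeat_id = r, subject = s, role = role,
          dsc = dice(pred, dataset[[s]]$labels, role))
    }
  }
  per <- do.call(rbind, per)
  summ <- do.call(rbind, lapply(roles, function(role) {
    rows <- lapply(c(seq_len(plan$n_repeats), 0L), function(r) {
      v <- if (r == 0) per$dsc[per$role == role]
           else per$dsc[per$role == role & per$repeat_id == r]
      data.frame(role = role, repeat_id = if (r == 0) "total" else as.character(r),
                 mean_dsc = mean(v), sd_dsc = stats::sd(v), n = length(v))
    })
    do.call(rbind, rows)
  }))
  rownames(summ) <- NULL
  structure(list(per_subject = per, summary = summ, plan = plan),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("dice_report: %d repeats x %d test subjects\n",
              x$plan$n_repeats, x$plan$n_test))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# exact null distribution of the Spearman statistic sum over permutations
# of mid-ranks ry against fixed rx; cached per (n, tie pattern free) call.
.perm_matrix_env <- new.env(parent = emptyenv())

.all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_matrix_env[[key]])) return(.perm_matrix_env[[key]])
  perms <- matrix(1L, 1, 1)
  for (k in 2:n) {
    m <- nrow(perms)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1) * m + seq_len(m)
      out[rows, pos] <- k
      out[rows, -pos] <- perms
    }
    perms <- out
  }
  .perm_matrix_env[[key]] <- perms
  perms
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes `rs` as the Pearson correlation of mid-ranks (average ranks for
#' ties). The two-sided p-value is obtained from the exact permutation
#' distribution of `rs` (all `n!` orderings of one variable's ranks) for
#' `n <= 9`, where full enumeration is tractable, and otherwise from the
#' t approximation `t = rs * sqrt((n-2) / (1-rs^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, no missing values.
#' @return List with elements `rs`, `p_value`, `n`, `method`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("spearman: need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("spearman: missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman: constant input, correlation undefined (undefined-correlation error)")
  rx <- rank(x); ry <- rank(y)
  rs <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- .all_permutations(n)
    # rs is monotone in sum(rx * ry_perm) for fixed marginal ranks
    obs <- sum(rx * ry)
    stat <- as.vector(matrix(ry[perms], nrow(perms)) %*% rx)
    mu <- mean(stat)
    p <- mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
    method <- "exact permutation"
  } else {
    tval <- rs * sqrt((n - 2) / max(1 - rs^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t approximation"
  }
  list(rs = rs, p_value = min(p, 1), n = n, method = method)
}

#' Correlate measurements across a cohort table
#'
#' One Spearman test per (measurement, covariate) pair, optionally within
#' strata (e.g. sex), mirroring the layout of cohort correlation tables.
#' Raw p-values are reported and flagged at `p < alpha`; no multiple-testing
#' correction is applied by default (`adjust = "BH"` adds a
#' Benjamini-Hochberg column).
#'
#' @param table Data frame of per-subject measurements.
#' @param pairs Data frame with columns `measurement`, `covariate` (column
#'   names of `table`).
#' @param strata Optional column name to stratify by.
#' @param alpha Significance level for the flag, default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame: stratum, measurement, covariate, rs, p_value, n,
#'   significant (+ p_adjusted when requested).
#' @export
correlate_measurements <- function(table, pairs, strata = NULL, alpha = 0.05,
                                   adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  need <- unique(c(pairs$measurement, pairs$covariate, strata))
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("correlate_measurements: column(s) not in table: ",
         paste(missing, collapse = ", "), " (schema error)")
  groups <- if (is.null(strata)) list(all = table)
            else split(table, table[[strata]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    df <- groups[[g]]
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      sp <- spearman(df[[pairs$measurement[i]]], df[[pairs$covariate[i]]])
      data.frame(stratum = g, measurement = pairs$measurement[i],
                 covariate = pairs$covariate[i],
                 rs = sp$rs, p_value = sp$p_value, n = sp$n)
    }))
  }))
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out$significant <- (if (adjust == "BH") out$p_adjusted else out$p_value) < alpha
  rownames(out) <- NULL
  out
}
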