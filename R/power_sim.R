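# Monte-Carlo power analysis for the group x manipulation interaction in
# the trial-level random-intercept LMM.

#' Power-simulation configuration
#'
#' The data-generating process draws standardized trial outcomes with a
#' subject random intercept carrying `icc` of the total variance, unit total
#' noise variance, and a standardized effect `effect_beta` on a single
#' group-vs-reference x after-vs-before interaction contrast (applied to
#' `effect_group` in the after-manipulation half of each subject's trials).
#' The omnibus Wald test of the group x manipulation interaction is
#' evaluated at `alpha`.
#'
#' @param effect_beta Standardized interaction effect (default 0.2).
#' @param group_sizes Named subject counts (default `c(ASD = 52, CON = 55,
#'   MHC = 43)`, n = 150).
#' @param trials_per_subject Trials per subject (default 412, i.e. 4 blocks
#'   of 103); the first half falls before, the second half after the
#'   manipulation.
#' @param icc Random-intercept share of total variance (default 0.3).
#' @param alpha Test level (default 0.05).
#' @param reps Monte-Carlo replicates (default 200).
#' @param seed Master seed.
#' @param effect_group Group receiving the interaction effect
#'   (default `"ASD"`; reference is `"CON"`).
#' @return A list of class `power_config`.
#' @export
power_config <- function(effect_beta = 0.2,
                         group_sizes = c(ASD = 52, CON = 55, MHC = 43),
                         trials_per_subject = 412L, icc = 0.3,
                         alpha = 0.05, reps = 200L, seed = 1L,
                         effect_group = "ASD") {
  stopifnot(icc >= 0, icc < 1, reps >= 1, alpha > 0, alpha < 1,
            trials_per_subject >= 2, all(group_sizes >= 1),
            effect_group %in% names(group_sizes))
  structure(list(effect_beta = effect_beta, group_sizes = group_sizes,
                 n_subjects = sum(group_sizes),
                 trials_per_subject = as.integer(trials_per_subject),
                 icc = icc, alpha = alpha, reps = as.integer(reps),
                 seed = seed, effect_group = effect_group),
            class = "power_config")
}

# one replicate's trial table
simulate_power_table <- function(config) {
  n_sub <- config$n_subjects
  nt <- config$trials_per_subject
  group <- rep(names(config$group_sizes), config$group_sizes)
  id <- rep(seq_len(n_sub), each = nt)
  manip <- rep(rep(c("before", "after"), each = ceiling(nt / 2))[seq_len(nt)],
               n_sub)
  b <- rnorm(n_sub, 0, sqrt(config$icc))[id]
  y <- config$effect_beta *
    (group[id] == config$effect_group & manip == "after") +
    b + rnorm(n_sub * nt, 0, sqrt(1 - config$icc))
  data.frame(subject_id = id, group = group[id],
             manipulation = manip, y = y, stringsAsFactors = FALSE)
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(centre - half, centre + half)
}

#' Monte-Carlo power for the group x manipulation interaction
#'
#' Per replicate: generate a trial table under the configured
#' data-generating process, fit the trial-level random-intercept LMM
#' `y ~ group * manipulation + (1 | subject_id)` by REML, and test the
#' omnibus group x manipulation interaction (Wald chi-square, 2 df) at
#' `alpha`. Power is the rejection fraction with a Wilson 95% CI.
#'
#' @param config A `power_config`.
#' @param progress Print a dot per replicate (default FALSE).
#' @return A list of class `power_result`: `power`, `ci95`, `reps_used`,
#'   `rejections`, `alpha`, `config`, and `warnings` (e.g. when `reps` is
#'   too small for a precise interval).
#' @export
simulate_power <- function(config = power_config(), progress = FALSE) {
  stopifnot(inherits(config, "power_config"))
  reject <- logical(config$reps)
  for (r in seq_len(config$reps)) {
    reject[r] <- with_seed(derive_seed(config$seed, r), {
      tab <- simulate_power_table(config)
      res <- fit_lmm(tab, "y",
                     formula_spec = y ~ group * manipulation + (1 | subject_id))
      p <- res$tests$p_value[res$tests$term == "group:manipulation"]
      p < config$alpha
    })
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  warnings <- character(0)
  if (config$reps < 100L)
    warnings <- "fewer than 100 replicates: the power CI will be wide"
  structure(list(power = mean(reject),
                 ci95 = wilson_ci(sum(reject), config$reps),
                 reps_used = config$reps, rejections = sum(reject),
                 alpha = config$alpha, config = config,
                 warnings = warnings),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "<power_result> power = %.1f%% [%.2f, %.2f] (%d/%d rejections, alpha = %g)\n",
    100 * x$power, 100 * x$ci95[1L], 100 * x$ci95[2L],
    x$rejections, x$reps_used, x$alpha))
  invisible(x)
}
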