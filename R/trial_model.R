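# Trial-level and aggregated linear mixed-effects modelling: participant
# random intercept, stimulus x group x manipulation fixed effects plus block
# direction, age and gender; REML estimation (delegated to lme4), Wald term
# tests, equal-weight marginal contrasts and Nakagawa marginal/conditional
# R-squared.

# reference levels: CON, standard, before, forward, m (treatment coding;
# contrasts are computed from marginal means, so reported deltas are
# coding-invariant)
factor_level_sets <- list(
  stimulus = c("standard", "oddball"),
  group = c("CON", "ASD", "MHC"),
  manipulation = c("before", "after"),
  block_direction = c("forward", "reverse"),
  gender = c("m", "f")
)

#' Centre and scale a column
#'
#' `(x - mean) / sd` over non-missing entries (sample SD, n-1 denominator);
#' missing values are preserved.
#'
#' @param x Numeric vector.
#' @return Standardized vector.
#' @export
standardize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L)
    stop("standardize() needs at least 2 non-missing values", call. = FALSE)
  s <- sd(x[ok])
  if (!is.finite(s) || s == 0)
    stop("standardize() undefined for zero-variance input", call. = FALSE)
  (x - mean(x[ok])) / s
}

#' Aggregate trial features per condition and participant
#'
#' One row per subject x stimulus x manipulation x block direction, holding
#' the mean of each measure over included trials (missing values dropped per
#' measure).
#'
#' @param table A trial table (see [cohort_trial_table()]).
#' @param measures Measure columns to aggregate.
#' @return Aggregated `data.frame`.
#' @export
aggregate_by_condition <- function(table,
                                   measures = intersect(
                                     c("bps", "sepr", "mmn_amp", "mmn_lat",
                                       "p3a_amp", "p3a_lat"), names(table))) {
  dt <- data.table::as.data.table(table)
  by_cols <- intersect(c("subject_id", "group", "age", "gender",
                         "stimulus", "manipulation", "block_direction"),
                       names(dt))
  agg <- dt[, lapply(.SD, function(x) mean(x, na.rm = TRUE)),
            by = by_cols, .SDcols = measures]
  for (m in measures) agg[[m]][is.nan(agg[[m]])] <- NA_real_
  as.data.frame(agg)
}

# candidate model variables that are present and estimable (factors need
# at least two observed levels)
design_terms <- function(data, candidates) {
  usable <- vapply(candidates, function(v) {
    v %in% names(data) &&
      (!v %in% names(factor_level_sets) ||
         length(unique(data[[v]][!is.na(data[[v]])])) >= 2L)
  }, logical(1L))
  candidates[usable]
}

as_model_factors <- function(data) {
  for (nm in names(factor_level_sets)) {
    if (!nm %in% names(data)) next
    bad <- setdiff(unique(as.character(data[[nm]])), factor_level_sets[[nm]])
    if (length(bad))
      stop("unknown level(s) in `", nm, "`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    data[[nm]] <- factor(data[[nm]], levels = factor_level_sets[[nm]])
    data[[nm]] <- droplevels(data[[nm]])
  }
  data
}

# Wald chi-square test for each fixed-effects term (large-sample; reported
# as F = W / df against a chi-square reference, df method "wald-chisq")
term_wald_tests <- function(fit) {
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  asgn <- attr(model.matrix(fit), "assign")
  labels <- attr(terms(fit, fixed.only = TRUE), "term.labels")
  out <- lapply(seq_along(labels), function(i) {
    idx <- which(asgn == i)
    if (!length(idx)) return(NULL)
    b <- beta[idx]
    W <- drop(t(b) %*% solve(V[idx, idx, drop = FALSE]) %*% b)
    df <- length(idx)
    data.frame(term = labels[i], wald_chisq = W, df = df, f_value = W / df,
               p_value = pchisq(W, df, lower.tail = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit the trial-level (or aggregated) linear mixed-effects model
#'
#' REML fit of `outcome ~ stimulus * group * manipulation + block_direction +
#' age + gender + (1 | subject_id)` (terms absent from the table are dropped
#' from the default formula). The outcome is centred and scaled across all
#' non-missing rows before fitting; rows with missing values in any model
#' variable are dropped listwise.
#'
#' @param table Trial table or aggregated table.
#' @param outcome Name of the outcome column.
#' @param formula_spec Optional full model formula overriding the default;
#'   use `.outcome` on the left-hand side or the outcome name itself.
#' @param standardize_outcome Centre/scale the outcome first (default TRUE).
#' @param reml Use REML (default TRUE).
#' @return An object of class `lmm_result`: the lme4 fit plus `fixed`
#'   (estimates, SE, 95% CI), `vc` (variance components `sigma2_subject`,
#'   `sigma2_residual`, `sigma2_fixed`), `tests` (Wald term tests), `r2`
#'   (Nakagawa marginal/conditional), `fit_method` and `df_method`.
#' @export
fit_lmm <- function(table, outcome, formula_spec = NULL,
                    standardize_outcome = TRUE, reml = TRUE) {
  data <- as.data.frame(table)
  stopifnot(outcome %in% names(data), "subject_id" %in% names(data))
  if (length(unique(data$subject_id)) < 2L)
    stop("need at least 2 subjects", call. = FALSE)

  if (is.null(formula_spec)) {
    # default structure; factors observed at a single level are dropped
    # (they are unestimable) rather than failing the fit
    design <- design_terms(data, c("stimulus", "group", "manipulation"))
    covars <- design_terms(data, c("block_direction", "age", "gender"))
    fixed_terms <- c(
      if (length(design)) paste(design, collapse = " * "),
      covars
    )
    if (!length(fixed_terms)) fixed_terms <- "1"
    formula_spec <- as.formula(paste(
      outcome, "~", paste(fixed_terms, collapse = " + "), "+ (1 | subject_id)"))
  } else {
    fstr <- deparse1(formula_spec)
    formula_spec <- as.formula(sub("^\\.outcome", outcome, fstr))
  }

  data <- as_model_factors(data)
  vars <- all.vars(formula_spec)
  data <- data[complete.cases(data[intersect(vars, names(data))]), , drop = FALSE]
  if (standardize_outcome) data[[outcome]] <- standardize(data[[outcome]])

  # detect aliased (rank-deficient) fixed-effects columns before fitting;
  # the decomposition runs on the p x p cross-product, not the n x p matrix
  fixed_only <- lme4::nobars(formula_spec)
  X <- model.matrix(delete.response(terms(fixed_only)), data)
  qrX <- qr(crossprod(X))
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular fixed-effects design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  fit <- lme4::lmer(formula_spec, data = data, REML = reml,
                    control = lme4::lmerControl(calc.derivs = FALSE))

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- qnorm(0.975)
  fixed <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se),
                      ci_lower = unname(beta - z * se),
                      ci_upper = unname(beta + z * se))
  vc_list <- lme4::VarCorr(fit)
  sigma2_subject <- as.numeric(vc_list$subject_id[1L, 1L])
  sigma2_residual <- attr(vc_list, "sc")^2
  sigma2_fixed <- var(drop(model.matrix(fit) %*% beta))

  result <- structure(
    list(fit = fit, formula = formula_spec, outcome = outcome,
         fixed = fixed,
         vc = c(sigma2_subject = sigma2_subject,
                sigma2_residual = sigma2_residual,
                sigma2_fixed = sigma2_fixed),
         tests = term_wald_tests(fit),
         n_obs = nrow(data), n_subjects = length(unique(data$subject_id)),
         fit_method = if (reml) "REML" else "ML",
         df_method = "wald-chisq"),
    class = "lmm_result"
  )
  result$r2 <- nakagawa_r2(result)
  result
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("<lmm_result>", deparse1(x$formula), "\n")
  cat(sprintf("  %s fit, %d obs / %d subjects; mR2 = %.3f, cR2 = %.3f\n",
              x$fit_method, x$n_obs, x$n_subjects, x$r2[["mR2"]],
              x$r2[["cR2"]]))
  print(x$tests)
  invisible(x)
}

#' Nakagawa marginal and conditional R-squared
#'
#' For a random-intercept model: `mR2 = s2_f / (s2_f + s2_a + s2_e)` and
#' `cR2 = (s2_f + s2_a) / (s2_f + s2_a + s2_e)`, where `s2_f` is the
#' variance of the fixed-effects linear predictor over the data, `s2_a` the
#' random-intercept variance and `s2_e` the residual variance.
#'
#' @param result An `lmm_result`, or a named vector with `sigma2_fixed`,
#'   `sigma2_subject`, `sigma2_residual`.
#' @return Named vector `c(mR2, cR2)`.
#' @export
nakagawa_r2 <- function(result) {
  vc <- if (inherits(result, "lmm_result")) result$vc else result
  total <- vc[["sigma2_fixed"]] + vc[["sigma2_subject"]] +
    vc[["sigma2_residual"]]
  c(mR2 = vc[["sigma2_fixed"]] / total,
    cR2 = (vc[["sigma2_fixed"]] + vc[["sigma2_subject"]]) / total)
}

# equal-weight reference grid over the model's factor levels, numeric
# covariates fixed at their observed mean
reference_grid <- function(result, within = list()) {
  fit <- result$fit
  frame <- model.frame(fit)
  tt <- delete.response(terms(fit, fixed.only = TRUE))
  vars <- all.vars(tt)
  cells <- list()
  for (v in vars) {
    col <- frame[[v]]
    cells[[v]] <- if (is.factor(col)) levels(col) else mean(col)
  }
  for (v in names(within)) {
    if (!v %in% names(cells))
      stop("`within` names unknown model variable: ", v, call. = FALSE)
    if (is.character(cells[[v]]) && !all(within[[v]] %in% cells[[v]]))
      stop("unknown level for `", v, "`: ",
           paste(setdiff(within[[v]], cells[[v]]), collapse = ", "),
           call. = FALSE)
    cells[[v]] <- within[[v]]
  }
  grid <- expand.grid(cells, stringsAsFactors = FALSE)
  for (v in vars) if (is.factor(frame[[v]]))
    grid[[v]] <- factor(grid[[v]], levels = levels(frame[[v]]))
  list(grid = grid, terms = tt)
}

#' Post-hoc contrast of marginalized means
#'
#' Difference of model-implied means between two levels of a factor,
#' averaged with equal weights over the levels of all non-involved factors
#' (numeric covariates at their mean), with a delta-method 95% CI.
#'
#' @param result An `lmm_result`.
#' @param factor Name of the factor to contrast.
#' @param levels Character vector of length 2: the contrast is
#'   `levels[1] - levels[2]`. Defaults to the factor's first two levels.
#' @param within Named list restricting non-involved variables to fixed
#'   levels (e.g. `list(group = "ASD")` for a within-group contrast).
#' @return A list of class `contrast_result`: `delta`, `se`, `ci95`,
#'   `factor`, `levels`, `within`.
#' @export
marginal_contrast <- function(result, factor, levels = NULL,
                              within = list()) {
  stopifnot(inherits(result, "lmm_result"))
  frame <- model.frame(result$fit)
  if (!factor %in% names(frame) || !is.factor(frame[[factor]]))
    stop("`", factor, "` is not a factor in the model", call. = FALSE)
  all_levels <- base::levels(frame[[factor]])
  if (is.null(levels)) levels <- all_levels[1:2]
  if (!all(levels %in% all_levels))
    stop("unknown level(s) for `", factor, "`: ",
         paste(setdiff(levels, all_levels), collapse = ", "), call. = FALSE)

  rg <- reference_grid(result, within)
  beta <- lme4::fixef(result$fit)
  V <- as.matrix(vcov(result$fit))
  xlev <- lapply(frame[vapply(frame, is.factor, logical(1L))], base::levels)

  row_for <- function(level) {
    g <- rg$grid[rg$grid[[factor]] == level, , drop = FALSE]
    X <- model.matrix(rg$terms, g, xlev = xlev[names(xlev) %in% names(g)])
    colMeans(X)
  }
  d <- row_for(levels[1L]) - row_for(levels[2L])
  delta <- drop(d %*% beta)
  se <- drop(sqrt(t(d) %*% V %*% d))
  z <- qnorm(0.975)
  structure(list(delta = delta, se = se,
                 ci95 = c(delta - z * se, delta + z * se),
                 factor = factor, levels = levels, within = within),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast> %s: %s - %s = %.3f [%.3f, %.3f]%s\n",
              x$factor, x$levels[1L], x$levels[2L], x$delta,
              x$ci95[1L], x$ci95[2L],
              if (length(x$within))
                paste0(" (within ", paste(names(x$within), unlist(x$within),
                                          sep = "=", collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Model ERP outcomes with pupillometric predictors
#'
#' Adds standardized BPS and/or SEPR as covariates to the established fixed
#' structure (stimulus x group x manipulation + block direction + age +
#' gender), optionally interacting the pupil predictors with group.
#'
#' @param table Trial table.
#' @param erp_outcome ERP outcome column (e.g. `"mmn_amp"`).
#' @param pupil_predictors Subset of `c("bps", "sepr")`.
#' @param group_interactions Add predictor-by-group interactions
#'   (default FALSE).
#' @return An `lmm_result`.
#' @export
pupil_erp_model <- function(table, erp_outcome,
                            pupil_predictors = c("bps", "sepr"),
                            group_interactions = FALSE) {
  pupil_predictors <- match.arg(pupil_predictors, several.ok = TRUE)
  data <- as.data.frame(table)
  for (p in pupil_predictors) data[[p]] <- standardize(data[[p]])
  pred_terms <- if (group_interactions)
    paste0(pupil_predictors, " * group") else pupil_predictors
  covars <- design_terms(data, c("block_direction", "age", "gender"))
  f <- as.formula(paste(
    erp_outcome, "~ stimulus * group * manipulation +",
    paste(c(pred_terms, covars), collapse = " + "),
    "+ (1 | subject_id)"))
  fit_lmm(data, erp_outcome, formula_spec = f)
}
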