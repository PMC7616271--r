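#' Scale responses into the open unit interval
#'
#' Proportion-type responses are prepared for beta regression by dividing by
#' the sample maximum and then squeezing away the boundary values:
#' `y2 = (y1 * (n - 1) + 0.5) / n`, so every value lies strictly inside
#' (0, 1). `unsqueeze_unit_interval()` inverts the squeeze.
#'
#' @param values non-negative finite numeric vector, length >= 2.
#' @return numeric vector strictly inside (0, 1).
#' @export
scale_unit_interval <- function(values) {
  stopifnot(length(values) >= 2, all(is.finite(values)), all(values >= 0))
  mx <- max(values)
  if (mx == 0) stop("all values are zero; cannot scale by the maximum")
  y1 <- values / mx
  n <- length(values)
  (y1 * (n - 1) + 0.5) / n
}

#' @rdname scale_unit_interval
#' @param squeezed values previously squeezed with the same `n`.
#' @param n the sample size used in the squeeze.
#' @export
unsqueeze_unit_interval <- function(squeezed, n) {
  (squeezed * n - 0.5) / (n - 1)
}

#' Observation weights for the condition models
#'
#' Trial-level models are weighted by tracking quality: by default the
#' weight equals the proportion of tracked data, so better-tracked trials
#' count more. A literal-inversion switch (`1 - p` or `1 / p`) is provided.
#' The tail-angle model is instead weighted by the tail-wagging index (the
#' wag ratio max-scaled to \[0, 1\]), concentrating inference on trials where
#' the tail actually moved.
#'
#' @param x proportions tracked (for `source = "prop_tracked"`) or tail-wag
#'   ratios (for `source = "wag_index"`).
#' @param source which weighting scheme to use.
#' @param mode for `prop_tracked`: `"direct"` (weight = p), `"one_minus"`
#'   (1 - p) or `"inverse"` (1 / p).
#' @return non-negative numeric weight vector.
#' @export
model_weights <- function(x, source = c("prop_tracked", "wag_index", "none"),
                          mode = c("direct", "one_minus", "inverse")) {
  source <- match.arg(source)
  mode <- match.arg(mode)
  w <- switch(source,
    none = rep(1, length(x)),
    prop_tracked = switch(mode,
      direct = x,
      one_minus = 1 - x,
      inverse = 1 / x),
    wag_index = x / max(x, na.rm = TRUE))
  if (any(w < 0, na.rm = TRUE)) stop("negative weights")
  w
}

#' Declare a condition model
#'
#' The analysis model for one response variable: test predictors owner
#' presence, stranger presence and their interaction, control predictors
#' trial number, age and sex (trial and age centred and scaled to SD 1;
#' reference categories owner/stranger absent and female), random intercept
#' per dog plus, optionally, random slopes of owner, stranger and trial.
#'
#' @param response column name of the response in the metrics table.
#' @param transform `"log"`, `"beta"` (max-scaling plus boundary squeeze,
#'   see [scale_unit_interval()]) or `"identity"`.
#' @param weights,weight_mode see [model_weights()].
#' @param interaction include the owner x stranger interaction.
#' @param random_slopes start from the full random-slope structure.
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, transform = c("identity", "log", "beta"),
                       weights = c("none", "prop_tracked", "wag_index"),
                       weight_mode = "direct", interaction = TRUE,
                       random_slopes = TRUE) {
  structure(list(response = response, transform = match.arg(transform),
                 weights = match.arg(weights), weight_mode = weight_mode,
                 interaction = interaction, random_slopes = random_slopes),
            class = "model_spec")
}

prepare_model_frame <- function(metrics, spec) {
  df <- data.frame(
    dog_id = factor(metrics$dog_id),
    owner = factor(ifelse(metrics$owner_present, "present", "absent"),
                   levels = c("absent", "present")),
    stranger = factor(ifelse(metrics$stranger_present, "present", "absent"),
                      levels = c("absent", "present")),
    trial_z = as.numeric(scale(metrics$trial)),
    age_z = if (all(is.na(metrics$age_months))) 0 else
      as.numeric(scale(metrics$age_months)),
    sex = factor(metrics$sex, levels = c("F", "M")))
  y <- metrics[[spec$response]]
  df$response <- switch(spec$transform,
    identity = y,
    log = {
      if (any(y <= 0)) stop("log transform requires positive responses")
      log(y)
    },
    beta = scale_unit_interval(y))
  df$w <- switch(spec$weights,
    none = rep(1, nrow(df)),
    prop_tracked = model_weights(metrics$prop_tracked_head_centre,
                                 "prop_tracked", spec$weight_mode),
    wag_index = model_weights(metrics$tail_wag_ratio, "wag_index"))
  df
}

# pruning ladder: progressively simpler model structures, applied in order
# on convergence failure
pruning_ladder <- function(spec) {
  fe <- c("owner", "stranger",
          if (spec$interaction) "owner:stranger", "trial_z", "age_z", "sex")
  re_full <- "(1 + owner + stranger + trial_z | dog_id)"
  re_cond <- "(1 + owner + stranger | dog_id)"
  re_int <- "(1 | dog_id)"
  steps <- list(list(step = "none", fixed = fe,
                     re = if (spec$random_slopes) re_full else re_int))
  if (spec$random_slopes) {
    steps <- c(steps, list(
      list(step = "drop_trial_slope", fixed = fe, re = re_cond),
      list(step = "drop_sex", fixed = setdiff(fe, "sex"), re = re_cond),
      list(step = "drop_age", fixed = setdiff(fe, c("sex", "age_z")),
           re = re_cond),
      list(step = "drop_condition_slopes",
           fixed = setdiff(fe, c("sex", "age_z")), re = re_int)))
  }
  steps
}

fit_backend <- function(formula, data, backend, weights) {
  warn <- character(0)
  fit <- withCallingHandlers(
    tryCatch(suppressMessages({
      if (backend == "lmer") {
        lme4::lmer(formula, data = data, weights = weights, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = TRUE))
      } else {
        glmmTMB::glmmTMB(formula, data = data, weights = weights,
                         family = glmmTMB::beta_family())
      }
    }), error = function(e) e),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error"))
    return(list(model = NULL, converged = FALSE, messages = conditionMessage(fit)))
  converged <- if (backend == "lmer") {
    !any(grepl("failed to converge|unable to evaluate|degenerate",
               warn, ignore.case = TRUE))
  } else {
    isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  }
  list(model = fit, converged = converged, messages = warn)
}

#' Fit a condition model with the convergence pruning ladder
#'
#' Fits the declared mixed model for one response. Gaussian responses
#' (identity or log transform) use `lme4::lmer` (ML); proportion responses
#' (beta transform) use a beta-family GLMM via `glmmTMB`. On convergence
#' failure the model is pruned in a fixed order — drop the random slope of
#' trial; drop sex; drop age; drop the condition random slopes — and each
#' applied step is recorded. The full model is always compared with a null
#' model containing only control predictors and the same random effects via
#' a likelihood ratio test; per-term tests use single-term deletion LRTs,
#' falling back to Wald z tests when a deletion refit fails.
#'
#' @param metrics metrics table (one row per dog x condition).
#' @param spec a [model_spec()].
#' @param backend `"auto"` (beta transform to glmmTMB, otherwise lmer),
#'   `"lmer"` or `"glmmTMB"`. A backend that cannot express the requested
#'   family is an explicit error, never a silent fallback.
#' @return A `wag_fit`: list with the fitted `model`, `null_model`,
#'   `backend`, `pruning` steps applied, `converged`, the coefficient table
#'   `coefficients`, `lrt` (full-null statistic, df, p) and `term_tests`.
#' @export
fit_condition_model <- function(metrics, spec, backend = c("auto", "lmer",
                                                           "glmmTMB")) {
  backend <- match.arg(backend)
  if (backend == "auto")
    backend <- if (spec$transform == "beta") "glmmTMB" else "lmer"
  if (backend == "lmer" && spec$transform == "beta")
    stop("unsupported model: lme4 cannot fit a beta error structure; ",
         "use the glmmTMB backend")
  if (length(unique(metrics$dog_id)) < 2)
    stop("need at least two dogs")
  df <- prepare_model_frame(metrics, spec)
  controls <- c("trial_z", "age_z", "sex")
  applied <- character(0)
  res <- NULL
  for (cand in pruning_ladder(spec)) {
    if (cand$step != "none") applied <- c(applied, cand$step)
    f_full <- stats::reformulate(c(cand$fixed, cand$re), response = "response")
    fe_null <- intersect(controls, cand$fixed)
    f_null <- stats::reformulate(c(if (length(fe_null)) fe_null else "1",
                                   cand$re), response = "response")
    full <- fit_backend(f_full, df, backend, df$w)
    if (!full$converged) next
    null <- fit_backend(f_null, df, backend, df$w)
    if (!null$converged) next
    res <- list(full = full, null = null, formula = f_full,
                fixed = cand$fixed, re = cand$re)
    break
  }
  if (is.null(res))
    stop("model did not converge at any rung of the pruning ladder")
  fit <- res$full$model
  co <- if (inherits(fit, "glmmTMB")) {
    summary(fit)$coefficients$cond
  } else {
    summary(fit)$coefficients
  }
  coefs <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                      z = co[, 1] / co[, 2], row.names = NULL,
                      stringsAsFactors = FALSE)
  lrt <- lrt_full_null(fit, res$null$model)
  term_tests <- tryCatch({
    d1 <- stats::drop1(fit, test = "Chisq")
    tt <- data.frame(term = rownames(d1), stringsAsFactors = FALSE)
    stat_col <- intersect(c("LRT", "Chisq"), colnames(d1))[1]
    tt$chisq <- d1[[stat_col]]
    tt$df <- d1$Df
    tt$p <- d1$`Pr(Chi)` %||% d1$`Pr(>Chi)` %||% d1$`Pr(>Chisq)`
    tt$method <- "lrt"
    tt[!is.na(tt$p), ]
  }, error = function(e) {
    data.frame(term = coefs$term, chisq = coefs$z^2, df = 1,
               p = 2 * stats::pnorm(-abs(coefs$z)), method = "wald",
               stringsAsFactors = FALSE)
  })
  structure(list(model = fit, null_model = res$null$model, backend = backend,
                 spec = spec, formula = res$formula, pruning = applied,
                 converged = TRUE, coefficients = coefs, lrt = lrt,
                 term_tests = term_tests, data = df),
            class = "wag_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Likelihood ratio test between nested fits
#'
#' Twice the log-likelihood difference, compared against a chi-square with
#' the parameter-count difference as degrees of freedom. Identical models
#' give statistic 0 and p = 1; a null that is not nested in the full model
#' (more parameters, or a different number of observations) is an error.
#'
#' @param full,null fitted models supporting [logLik()] (the null nested in
#'   the full, same data and weights).
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt_full_null <- function(full, null) {
  ll_f <- logLik(full)
  ll_n <- logLik(null)
  if (attr(ll_f, "nobs") != attr(ll_n, "nobs"))
    stop("models were fitted to different numbers of observations")
  df <- attr(ll_f, "df") - attr(ll_n, "df")
  if (df < 0) stop("null model has more parameters than the full model")
  stat <- max(0, 2 * (as.numeric(ll_f) - as.numeric(ll_n)))
  p <- if (df == 0) {
    if (stat < 1e-8) 1 else NA_real_
  } else {
    pchisq(stat, df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p = p)
}

#' Variance inflation factors
#'
#' VIF of each predictor in a fixed-effects design matrix:
#' `1 / (1 - R^2_j)` from regressing predictor j on all others. Perfectly
#' collinear predictors are reported as `Inf`.
#'
#' @param x numeric design matrix or data frame of predictors (an intercept
#'   column, if present, is ignored).
#' @return named numeric vector of VIFs.
#' @export
vif_check <- function(x) {
  x <- as.matrix(x)
  keep <- apply(x, 2, function(col) var(col) > 0)
  x <- x[, keep, drop = FALSE]
  if (nrow(x) <= ncol(x)) stop("need more observations than predictors")
  vapply(seq_len(ncol(x)), function(j) {
    fit <- lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> setNames(colnames(x))
}

#' Holm-corrected C-BARQ correlations
#'
#' Pearson correlations between each C-BARQ subscale and each interest-area
#' occupancy variable within each condition, with Holm step-down adjusted
#' p-values across the whole family.
#'
#' @param metrics metrics table (one row per dog x condition).
#' @param cbarq C-BARQ table (one row per dog).
#' @return data frame: `subscale`, `variable`, `condition`, `r`, `n`, `p`,
#'   `p_holm`.
#' @export
cbarq_correlations <- function(metrics, cbarq) {
  subs <- c("nonsocial_fear", "stranger_fear", "separation_problems",
            "attachment_attention")
  if (length(unique(cbarq$dog_id)) < 4) stop("need at least four dogs")
  vars <- c("prop_owner_ia", "prop_stranger_ia", "prop_door_ia")
  merged <- merge(metrics, cbarq, by = "dog_id")
  rows <- list()
  for (cond in intersect(condition_levels(), unique(merged$condition))) {
    sub <- merged[merged$condition == cond, ]
    for (sc in subs) for (v in vars) {
      ok <- is.finite(sub[[sc]]) & is.finite(sub[[v]])
      n <- sum(ok)
      if (n >= 4 && sd(sub[[sc]][ok]) > 0 && sd(sub[[v]][ok]) > 0) {
        ct <- cor.test(sub[[sc]][ok], sub[[v]][ok])
        rows[[length(rows) + 1]] <- data.frame(
          subscale = sc, variable = v, condition = cond,
          r = unname(ct$estimate), n = n, p = ct$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_holm <- p.adjust(out$p, method = "holm")
  out
}

#' Sample summary of C-BARQ subscales
#'
#' Mean, SD and range per subscale, next to configurable general-population
#' reference values.
#'
#' @param cbarq C-BARQ table.
#' @param population named list of `c(mean, sd)` reference values per
#'   subscale.
#' @return data frame with one row per subscale.
#' @export
cbarq_summary <- function(cbarq,
                          population = list(
                            nonsocial_fear = c(0.84, 0.77),
                            stranger_fear = c(0.67, 0.95),
                            separation_problems = c(0.60, 0.66),
                            attachment_attention = c(2.01, 0.81))) {
  subs <- names(population)
  do.call(rbind, lapply(subs, function(sc) {
    v <- cbarq[[sc]]
    data.frame(subscale = sc, mean = mean(v),
               sd = if (length(v) > 1) sd(v) else NA_real_,
               min = min(v), max = max(v),
               pop_mean = population[[sc]][1], pop_sd = population[[sc]][2],
               stringsAsFactors = FALSE)
  }))
}
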