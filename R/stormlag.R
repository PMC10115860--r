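#' Fit the distributed-lag mixed Poisson hospitalization model
#'
#' Fits, on a matched model table from [build_model_table()], the regression
#' \deqn{\log E[Y_{zt}] = \alpha + \alpha_z + \sum_{l=-2}^{7}\beta_l x_{t+l,z}
#'   + \log n_{zy} + \delta'\mathrm{DOW}_t + \gamma'\mathrm{Year}_t,}
#' a Poisson model of daily cause-specific hospitalization counts with a
#' random intercept \eqn{\alpha_z} per ZCTA, a distributed lag over the
#' 10-day storm window (2 days before to 7 days after closest approach), a
#' log beneficiary offset, and categorical day-of-week (reference Monday) and
#' calendar-year (reference: earliest year present) controls.
#'
#' The random intercept is estimated by Laplace-approximated maximum
#' likelihood ([lme4::glmer()]). When the mixed-model optimizer fails, or
#' when `random_intercept = "never"`, the model falls back to a fixed-effect
#' Poisson GLM with ZCTA indicator terms (a conditional-style adjustment);
#' the fallback is flagged in the fit. With fewer than two ZCTAs the ZCTA
#' terms are omitted entirely.
#'
#' A lag whose indicator rows carry only zero counts is separated: its
#' coefficient diverges and its standard error is reported as infinite; such
#' lags are flagged rather than hidden.
#'
#' @param table a model table from [build_model_table()].
#' @param random_intercept "auto" (default: mixed model with GLM fallback),
#'   "always" (mixed model, error on failure) or "never" (ZCTA fixed-effect
#'   GLM).
#' @param quasi if `TRUE`, a quasi-Poisson scale is estimated on the GLM
#'   route (ignored, with a warning, on the mixed-model route).
#' @param glmer_control a [lme4::glmerControl()] object for the mixed fit.
#' @return an object of class `stormlag` with components `beta` (10 lag log
#'   rate ratios), `vcov_beta`, `se_beta`, `nuisance` (intercept, DOW, year,
#'   and any ZCTA fixed effects), `ranef_variance`, `separated`, `method`
#'   ("glmm", "glm_fixed" or "glm"), `fallback`, `converged`, `messages`,
#'   `lags`, `nobs`, `n_sets`, `n_zctas` and the underlying `fit`.
#' @seealso [lag_rr()], [cumulative_rr()], [stratify_community()]
#' @export
stormlag <- function(table, random_intercept = c("auto", "always", "never"),
                     quasi = FALSE, glmer_control = NULL) {
  random_intercept <- match.arg(random_intercept)
  lags <- attr(table, "lags") %||% .LAGS
  lag_cols <- lag_col_names(lags)
  needed <- c(lag_cols, "count", "log_denom", "dow", "year", "zcta_id")
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("`table` must be a nonempty model table")
  }
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0L) {
    stop("model table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(table$log_denom))) stop("offsets must be finite")

  dat <- table
  dat$dowf <- factor(dat$dow, levels = .DOW_LEVELS)
  dat$dowf <- droplevels(dat$dowf)
  dat$yearf <- factor(dat$year)
  dat$zcta <- factor(dat$zcta_id)
  n_zctas <- nlevels(dat$zcta)

  # separation: a lag indicator whose rows are all zero-count cannot be
  # estimated away from the boundary
  separated <- vapply(lag_cols, function(cl) {
    on <- dat[[cl]] == 1L
    any(on) && sum(dat$count[on]) == 0L
  }, logical(1))
  inestimable <- vapply(lag_cols, function(cl) all(dat[[cl]] == 0L), logical(1))

  rhs <- lag_cols
  if (nlevels(dat$dowf) > 1L) rhs <- c(rhs, "dowf")
  if (nlevels(dat$yearf) > 1L) rhs <- c(rhs, "yearf")
  rhs <- c(rhs, "offset(log_denom)")
  base_formula <- stats::reformulate(rhs, response = "count")

  use_glmm <- random_intercept %in% c("auto", "always") && n_zctas >= 2L
  if (random_intercept == "always" && n_zctas < 2L) {
    warning("fewer than 2 ZCTAs: random intercept dropped", call. = FALSE)
    use_glmm <- FALSE
  }

  messages <- character()
  fit <- NULL
  method <- NULL
  fallback <- FALSE

  if (use_glmm) {
    if (quasi) {
      warning("quasi-Poisson scale is not available on the mixed-model route; ignored",
              call. = FALSE)
    }
    mixed_formula <- stats::update.formula(base_formula, . ~ . + (1 | zcta))
    ctrl <- glmer_control %||%
      lme4::glmerControl(check.conv.singular = "ignore", calc.derivs = FALSE,
                         optimizer = "nloptwrap")
    fit <- tryCatch(
      withCallingHandlers(
        lme4::glmer(mixed_formula, data = dat, family = stats::poisson(),
                    nAGQ = 1L, control = ctrl),
        warning = function(w) {
          messages <<- c(messages, conditionMessage(w))
          invokeRestart("muffleWarning")
        },
        message = function(m) {
          messages <<- c(messages, conditionMessage(m))
          invokeRestart("muffleMessage")
        }),
      error = function(e) {
        messages <<- c(messages, conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) method <- "glmm"
    if (is.null(fit) && random_intercept == "always") {
      stop("mixed-model fit failed: ", paste(messages, collapse = "; "))
    }
  }

  if (is.null(fit)) {
    fallback <- use_glmm  # we wanted a GLMM but are falling back
    rhs_glm <- if (n_zctas >= 2L) c(rhs, "zcta") else rhs
    glm_formula <- stats::reformulate(rhs_glm, response = "count")
    fam <- if (quasi) stats::quasipoisson() else stats::poisson()
    fit <- stats::glm(glm_formula, data = dat, family = fam,
                      control = stats::glm.control(epsilon = 1e-8, maxit = 200L))
    method <- if (n_zctas >= 2L) "glm_fixed" else "glm"
  }

  est <- extract_lag_estimates(fit, lag_cols, separated, inestimable)
  obj <- structure(list(
    beta = est$beta, se_beta = est$se, vcov_beta = est$vcov,
    nuisance = est$nuisance,
    ranef_variance = if (method == "glmm") {
      vc <- as.data.frame(lme4::VarCorr(fit))
      vc$vcov[1L]
    } else NA_real_,
    separated = separated | inestimable,
    method = method, fallback = fallback,
    converged = fit_converged(fit),
    iterations = fit_iterations(fit),
    control = list(epsilon = 1e-8, maxit = 200L),
    messages = messages,
    lags = lags, nobs = nrow(dat),
    n_sets = if ("set_id" %in% names(dat)) length(unique(dat$set_id)) else NA_integer_,
    n_zctas = n_zctas,
    fit = fit, call = match.call()
  ), class = "stormlag")
  obj
}

extract_lag_estimates <- function(fit, lag_cols, separated, inestimable) {
  cf <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  v <- as.matrix(stats::vcov(fit))
  beta <- stats::setNames(rep(NA_real_, length(lag_cols)), lag_cols)
  se <- beta
  present <- intersect(lag_cols, names(cf)[!is.na(cf)])
  beta[present] <- cf[present]
  vout <- matrix(NA_real_, length(lag_cols), length(lag_cols),
                 dimnames = list(lag_cols, lag_cols))
  in_v <- intersect(present, rownames(v))
  vout[in_v, in_v] <- v[in_v, in_v]
  se[in_v] <- sqrt(diag(v)[in_v])
  se[separated] <- Inf
  beta[inestimable] <- NA_real_
  se[inestimable] <- Inf
  nuis <- cf[setdiff(names(cf), lag_cols)]
  list(beta = beta, se = se, vcov = vout, nuisance = nuis)
}

fit_converged <- function(fit) {
  if (inherits(fit, "merMod")) {
    opt <- fit@optinfo
    is.null(opt$conv$opt) || opt$conv$opt == 0L
  } else {
    isTRUE(fit$converged)
  }
}

fit_iterations <- function(fit) {
  if (inherits(fit, "merMod")) {
    as.integer(fit@optinfo$feval %||% NA_integer_)
  } else {
    as.integer(fit$iter %||% NA_integer_)
  }
}

#' @export
print.stormlag <- function(x, ...) {
  cat("Distributed-lag Poisson model of storm-period hospitalization risk\n")
  cat(sprintf("  method: %s%s   rows: %d   matched sets: %s   ZCTAs: %d\n",
              x$method, if (x$fallback) " (fallback from glmm)" else "",
              x$nobs, format(x$n_sets), x$n_zctas))
  if (x$method == "glmm") {
    cat(sprintf("  random intercept variance: %.4g\n", x$ranef_variance))
  }
  cum <- tryCatch(cumulative_rr(x), error = function(e) NULL)
  if (!is.null(cum) && is.finite(cum$rr)) {
    cat(sprintf("  cumulative RR over the 10-day window: %.3f (95%% CI %.3f, %.3f)\n",
                cum$rr, cum$ci_low, cum$ci_high))
  }
  if (any(x$separated)) {
    cat("  separated lag(s): ",
        paste(names(x$separated)[x$separated], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.stormlag <- function(object, level = 0.95, ...) {
  out <- list(lag_table = lag_rr(object, level = level),
              cumulative = cumulative_rr(object, level = level),
              method = object$method, fallback = object$fallback,
              ranef_variance = object$ranef_variance,
              converged = object$converged, nobs = object$nobs,
              n_sets = object$n_sets, n_zctas = object$n_zctas)
  class(out) <- "summary.stormlag"
  out
}

#' @export
print.summary.stormlag <- function(x, digits = 3, ...) {
  cat("Distributed-lag Poisson model: relative risks by lag\n\n")
  tab <- x$lag_table[, c("label", "rr", "ci_low", "ci_high", "log_rr", "se_log_rr")]
  print(format(tab, digits = digits), row.names = FALSE)
  cat("\nCumulative (10-day window): ")
  if (is.finite(x$cumulative$rr)) {
    cat(sprintf("RR %.3f (95%% CI %.3f, %.3f)\n",
                x$cumulative$rr, x$cumulative$ci_low, x$cumulative$ci_high))
  } else {
    cat("unavailable (separated lag)\n")
  }
  cat(sprintf("Method: %s%s; rows %d; ZCTAs %d; converged: %s\n",
              x$method, if (x$fallback) " (fallback)" else "",
              x$nobs, x$n_zctas, x$converged))
  invisible(x)
}

#' @export
coef.stormlag <- function(object, which = c("lag", "all"), ...) {
  which <- match.arg(which)
  if (which == "lag") object$beta else c(object$beta, object$nuisance)
}

#' @export
vcov.stormlag <- function(object, ...) object$vcov_beta

#' @export
confint.stormlag <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$beta - z * object$se_beta, object$beta + z * object$se_beta)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.stormlag <- function(object, ...) stats::fitted(object$fit)

#' @export
residuals.stormlag <- function(object, type = "deviance", ...) {
  stats::residuals(object$fit, type = type)
}

#' @export
predict.stormlag <- function(object, newdata = NULL, type = "response", ...) {
  if (is.null(newdata)) return(stats::predict(object$fit, type = type, ...))
  newdata$dowf <- factor(newdata$dow, levels = .DOW_LEVELS)
  newdata$yearf <- factor(newdata$year)
  newdata$zcta <- factor(newdata$zcta_id)
  stats::predict(object$fit, newdata = newdata, type = type, ...)
}

#' @export
simulate.stormlag <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::fitted(object$fit)
  as.data.frame(replicate(nsim, stats::rpois(length(mu), mu)))
}

#' @export
logLik.stormlag <- function(object, ...) stats::logLik(object$fit)

#' @export
nobs.stormlag <- function(object, ...) object$nobs

#' Plot lag-specific relative risks
#'
#' Point estimates and Wald confidence intervals for each lag, with the null
#' line at RR = 1.
#'
#' @param x a `stormlag` fit.
#' @param level confidence level.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the lag RR table.
#' @export
plot.stormlag <- function(x, level = 0.95, ...) {
  tab <- lag_rr(x, level = level)
  finite <- is.finite(tab$ci_high)
  ylim <- range(c(1, tab$rr[finite], tab$ci_low[finite], tab$ci_high[finite]),
                na.rm = TRUE)
  graphics::plot(x$lags, tab$rr, xlab = "lag (days from closest approach)",
                 ylab = "relative risk", ylim = ylim, pch = 16, ...)
  graphics::segments(x$lags, tab$ci_low, x$lags, tab$ci_high)
  graphics::abline(h = 1, lty = 2)
  invisible(tab)
}
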