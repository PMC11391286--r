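#' Logit transform for proportion responses
#'
#' `log(p' / (1 - p'))` with `p'` clamped to `[eps, 1 - eps]` so exact zeros
#' and ones (possible for calling proportions on very quiet or saturated
#' nights) remain finite.
#'
#' @param p Proportions in \[0, 1\].
#' @param eps Clamping constant.
#' @return Numeric vector of logits.
#' @export
logit_transform <- function(p, eps = 1e-3) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("proportions must lie in [0, 1]")
  p2 <- pmin(pmax(p, eps), 1 - eps)
  log(p2 / (1 - p2))
}

#' @rdname logit_transform
#' @param x Values on the logit scale.
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Centre and scale predictor columns
#'
#' Each named column is centred to mean 0 and scaled to sample SD 1 so that
#' coefficient magnitudes are comparable across predictors; the binary rain
#' indicator is scaled like any other column. The scaling constants are
#' attached as attribute `"scaling"`.
#'
#' @param table A data frame.
#' @param columns Character vector of numeric columns to scale.
#' @return The table with scaled columns.
#' @export
scale_predictors <- function(table, columns) {
  miss <- setdiff(columns, names(table))
  if (length(miss)) stop("columns not in table: ", paste(miss, collapse = ", "))
  scaling <- list()
  for (col in columns) {
    x <- table[[col]]
    if (!is.numeric(x)) stop("column is not numeric: ", col)
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("zero-variance column cannot be scaled: ", col)
    table[[col]] <- (x - m) / s
    scaling[[col]] <- c(mean = m, sd = s)
  }
  attr(table, "scaling") <- scaling
  table
}

#' Specify one prediction model
#'
#' @param response Response column name.
#' @param predictors Character vector of fixed-effect predictor columns.
#' @param transform `"identity"` or `"logit"` (for proportion responses).
#' @param random Random-intercept grouping columns (crossed).
#' @param exclude_sites Sites to drop before fitting (e.g. the most urban
#'   site, for the light-level analyses).
#' @param name Optional label for reports.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response, predictors,
                       transform = c("identity", "logit"),
                       random = c("site", "month"),
                       exclude_sites = NULL, name = NULL) {
  transform <- match.arg(transform)
  if (response %in% predictors)
    stop("response must not be among the predictors")
  structure(
    list(response = response, predictors = predictors,
         transform = transform, random = random,
         exclude_sites = exclude_sites,
         name = name %||% response),
    class = "model_spec"
  )
}

# Prepare the analysis frame for a spec: drop excluded sites, keep complete
# cases, transform the response and scale the predictors.
prepare_model_frame <- function(table, spec) {
  cols <- unique(c(spec$response, spec$predictors, spec$random))
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("variables missing from table: ",
                         paste(miss, collapse = ", "))
  dat <- table
  if (!is.null(spec$exclude_sites) && "site" %in% names(dat))
    dat <- dat[!(dat$site %in% spec$exclude_sites), , drop = FALSE]
  dat <- dat[, cols, drop = FALSE]
  cc <- stats::complete.cases(dat)
  n_dropped <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  if (spec$transform == "logit")
    dat[[spec$response]] <- logit_transform(dat[[spec$response]])
  dat <- scale_predictors(dat, spec$predictors)
  for (g in spec$random) dat[[g]] <- factor(dat[[g]])
  attr(dat, "n_dropped") <- n_dropped
  dat
}

lmm_formula <- function(response, predictors, random) {
  rhs <- c(if (length(predictors)) predictors else "1",
           sprintf("(1 | %s)", random))
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

# Fit by ML, flagging convergence problems instead of failing.
fit_lmer_ml <- function(formula, data) {
  converged <- TRUE
  messages <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(formula, data = data, REML = FALSE),
    warning = function(w) {
      converged <<- FALSE
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      # boundary (singular) fits are legitimate (a variance estimated at 0)
      messages <<- c(messages, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  list(fit = fit, converged = converged, messages = messages)
}

#' Fit a prediction model as a linear mixed model
#'
#' Gaussian linear mixed model with crossed random intercepts (site and
#' month by default), fitted by maximum likelihood — not REML — so that the
#' single-term-deletion likelihood-ratio tests of [drop1_lrt()] are valid.
#' Predictors are centred and scaled, proportion responses logit
#' transformed, incomplete rows dropped (and counted). Variance inflation
#' factors are computed from the fixed-effects design.
#'
#' @param table Per-night data (e.g. from [assemble_night_metrics()] or
#'   [simulate_season()]).
#' @param spec A [model_spec()].
#' @return An object of class `roost_lmm` with components `model` (the
#'   lme4 fit), `coefficients` (estimate/SE/t on the scaled scale), `vif`,
#'   `n_obs`, `n_dropped`, `converged` and `spec`. Methods: `print`,
#'   `summary`, `coef`.
#' @export
fit_lmm <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  dat <- prepare_model_frame(table, spec)
  if (nrow(dat) < length(spec$predictors) + 2L)
    stop("too few complete cases to fit the model")
  random <- spec$random[vapply(spec$random,
                               function(g) nlevels(dat[[g]]) > 1, logical(1))]
  if (length(random) == 0)
    stop("all random-effect factors have a single level")
  f <- lmm_formula(spec$response, spec$predictors, random)
  res <- fit_lmer_ml(f, dat)
  ct <- as.data.frame(summary(res$fit)$coefficients)
  names(ct) <- c("estimate", "se", "t")[seq_len(ncol(ct))]
  vif <- vif_values(dat, spec)
  structure(
    list(model = res$fit, coefficients = ct, vif = vif,
         n_obs = nrow(dat), n_dropped = attr(dat, "n_dropped"),
         converged = res$converged, messages = res$messages,
         random_used = random, data = dat, spec = spec),
    class = "roost_lmm"
  )
}

# VIFs from the fixed-effects design matrix via an auxiliary OLS fit.
vif_values <- function(dat, spec) {
  if (length(spec$predictors) < 2)
    return(stats::setNames(rep(NA_real_, length(spec$predictors)),
                           spec$predictors))
  f <- stats::as.formula(paste(spec$response, "~",
                               paste(spec$predictors, collapse = " + ")))
  v <- car::vif(stats::lm(f, data = dat))
  if (is.matrix(v)) v <- v[, 1]
  v
}

#' @method print roost_lmm
#' @export
print.roost_lmm <- function(x, ...) {
  cat(sprintf("<roost_lmm> %s (%s response), n = %d%s\n",
              x$spec$name, x$spec$transform, x$n_obs,
              if (x$converged) "" else " [convergence flagged]"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @method summary roost_lmm
#' @export
summary.roost_lmm <- function(object, ...) summary(object$model, ...)

#' @export
coef.roost_lmm <- function(object, ...) lme4::fixef(object$model)

#' Single-term-deletion likelihood-ratio tests
#'
#' Each fixed-effect predictor is dropped in turn from the full
#' ML-fitted model; the table reports the likelihood-ratio chi-square
#' `2 * (logLik_full - logLik_reduced)`, its degrees of freedom, the
#' chi-square p-value, and the AIC change on deletion (positive `delta_aic`
#' means deleting the term worsens the model).
#'
#' @param fit A [fit_lmm()] result.
#' @return A data frame with one row per predictor: `chisq`, `df`,
#'   `p_value`, `delta_aic`, `converged`.
#' @export
drop1_lrt <- function(fit) {
  stopifnot(inherits(fit, "roost_lmm"))
  full <- fit$model
  ll_full <- as.numeric(stats::logLik(full))
  df_full <- attr(stats::logLik(full), "df")
  rows <- lapply(fit$spec$predictors, function(term) {
    keep <- setdiff(fit$spec$predictors, term)
    f <- lmm_formula(fit$spec$response, keep, fit$random_used)
    red <- fit_lmer_ml(f, fit$data)
    ll_red <- as.numeric(stats::logLik(red$fit))
    df <- df_full - attr(stats::logLik(red$fit), "df")
    chisq <- max(0, 2 * (ll_full - ll_red))
    data.frame(
      term = term, chisq = chisq, df = df,
      p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
      delta_aic = stats::AIC(red$fit) - stats::AIC(full),
      converged = red$converged,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the five prediction models
#'
#' Fits the per-night mixed models for the five roost predictions:
#' (1) settling slope ~ pre-arrival noise, (2) logit overnight calling
#' proportion ~ overnight noise, (3) pre-departure slope, (4) departure
#' cohesion (largest-group proportion) and (5) roost-emptying time, the
#' latter three with pre-departure noise and overnight calling (logit) as
#' focal predictors. All models add roost size, mean temperature, mean
#' windspeed and rain, with site and month random intercepts. When light
#' data are present, additional variants of models 1-3 include mean light
#' and exclude the most-urban site (the site without a light logger).
#'
#' @param metrics Per-night metrics table (see [assemble_night_metrics()]
#'   or [simulate_season()]). If `night_call_prop` uses the conservative
#'   threshold variant, pass that column name via `threshold_column`.
#' @param departures Optional per-night departure summaries with `site`,
#'   `date`, `largest_group_prop`, `time_to_empty_s`; joined on site +
#'   date. If `NULL`, those columns are taken from `metrics` when present.
#' @param exclude_site Site excluded from the light-level variants; by
#'   default the site with the highest mean overnight noise (the most urban
#'   site).
#' @param threshold_column Column holding the overnight calling proportion.
#' @return An object of class `roost_suite`: a named list of reports, each
#'   with the fitted `roost_lmm` and its [drop1_lrt()] table.
#' @export
run_prediction_suite <- function(metrics, departures = NULL,
                                 exclude_site = NULL,
                                 threshold_column = "night_call_prop") {
  dat <- as.data.frame(metrics)
  if (!is.null(departures)) {
    keys <- c("site", "date")
    if (!all(keys %in% names(departures)))
      stop("departures table must carry join keys: site, date")
    dep_cols <- intersect(c("largest_group_prop", "time_to_empty_s",
                            "roost_size"), names(departures))
    dat <- merge(dat[, setdiff(names(dat), setdiff(dep_cols, "roost_size")),
                     drop = FALSE],
                 departures[, c(keys, dep_cols), drop = FALSE],
                 by = keys, suffixes = c("", ".dep"))
    if ("roost_size.dep" %in% names(dat)) {
      dat$roost_size <- ifelse(is.na(dat$roost_size), dat$roost_size.dep,
                               dat$roost_size)
      dat$roost_size.dep <- NULL
    }
  }
  dat$night_call_logit <- logit_transform(dat[[threshold_column]])
  base <- c("roost_size", "temp_mean", "wind_mean", "rain")
  specs <- list(
    settling = model_spec("settle_slope",
                          c("noise_prearrival", base), name = "settling"),
    night_calling = model_spec(threshold_column,
                               c("noise_overnight", base),
                               transform = "logit", name = "night_calling"),
    predeparture = model_spec("predeparture_slope",
                              c("noise_predeparture", "night_call_logit",
                                base), name = "predeparture")
  )
  if ("largest_group_prop" %in% names(dat))
    specs$cohesion <- model_spec("largest_group_prop",
                                 c("noise_predeparture", "night_call_logit",
                                   base), name = "cohesion")
  if ("time_to_empty_s" %in% names(dat))
    specs$emptying <- model_spec("time_to_empty_s",
                                 c("noise_predeparture", "night_call_logit",
                                   base), name = "emptying")
  has_light <- "light_mean" %in% names(dat) && any(!is.na(dat$light_mean))
  if (has_light) {
    exclude_site <- exclude_site %||% {
      m <- tapply(dat$noise_overnight, dat$site, mean, na.rm = TRUE)
      names(m)[which.max(m)]
    }
    for (nm in c("settling", "night_calling", "predeparture")) {
      s <- specs[[nm]]
      specs[[paste0(nm, "_light")]] <- model_spec(
        s$response, c(s$predictors, "light_mean"), transform = s$transform,
        exclude_sites = exclude_site, name = paste0(nm, "_light"))
    }
  }
  reports <- lapply(specs, function(s) {
    fit <- fit_lmm(dat, s)
    list(fit = fit, lrt = drop1_lrt(fit))
  })
  structure(list(reports = reports, data = dat,
                 exclude_site = if (has_light) exclude_site else NULL),
            class = "roost_suite")
}

#' @method print roost_suite
#' @export
print.roost_suite <- function(x, ...) {
  cat(sprintf("<roost_suite> %d fitted models on %d nights\n",
              length(x$reports), nrow(x$data)))
  for (nm in names(x$reports)) {
    rep <- x$reports[[nm]]
    cat("\n--", nm, sprintf("(n = %d)", rep$fit$n_obs), "--\n")
    tab <- cbind(round(rep$fit$coefficients[rep$lrt$term, , drop = FALSE], 3),
                 chisq = round(rep$lrt$chisq, 3),
                 df = rep$lrt$df,
                 p = signif(rep$lrt$p_value, 3))
    print(tab)
  }
  invisible(x)
}

#' Serialise a suite of model reports as JSON
#'
#' @param suite A [run_prediction_suite()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_suite_json <- function(suite, path) {
  stopifnot(inherits(suite, "roost_suite"))
  out <- lapply(suite$reports, function(rep) {
    list(
      n_obs = rep$fit$n_obs,
      n_dropped = rep$fit$n_dropped,
      converged = rep$fit$converged,
      coefficients = cbind(term = rownames(rep$fit$coefficients),
                           rep$fit$coefficients),
      vif = as.list(rep$fit$vif),
      lrt = rep$lrt
    )
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
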