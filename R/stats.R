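#' Tukey-fence outlier filter
#'
#' Removes values below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`. Quartiles
#' use linear interpolation between order statistics (type 7). With fewer
#' than 4 values the input passes through unchanged with a warning.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @return A list with `kept`, `removed`, and the logical index `keep`.
#' @export
tukey_filter <- function(values, k = 1.5) {
  if (length(values) < 4L) {
    warning("fewer than 4 values; Tukey filter passes all through")
    return(list(kept = values, removed = values[0], keep = rep(TRUE, length(values))))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, na.rm = TRUE)
  iqr <- q[2] - q[1]
  keep <- values >= q[1] - k * iqr & values <= q[2] + k * iqr
  keep[is.na(keep)] <- FALSE
  list(kept = values[keep], removed = values[!keep], keep = keep)
}

#' Per-well summary statistics after outlier filtering
#'
#' Applies the Tukey fences to body length and (when given) autofluorescence
#' per unit length; a worm flagged by either criterion is removed entirely.
#' Remaining worms yield the well mean, sample standard deviation, standard
#' error, and coefficient of variation per endpoint.
#'
#' @param phenotypes A data.frame with columns `length_um`, `area_um2`,
#'   `volume_um3` and optionally `af_per_length`.
#' @param filter Apply the Tukey filter before summarising (default TRUE).
#' @return A list of class `well_summary` with `n_raw`, `n_kept` and, per
#'   endpoint, `mean`, `sd`, `sem`, `cv`.
#' @export
summarize_well <- function(phenotypes, filter = TRUE) {
  n_raw <- nrow(phenotypes)
  keep <- rep(TRUE, n_raw)
  if (filter && n_raw >= 4L) {
    keep <- tukey_filter(phenotypes$length_um)$keep
    if (!is.null(phenotypes$af_per_length) &&
        any(!is.na(phenotypes$af_per_length))) {
      keep <- keep & tukey_filter(phenotypes$af_per_length)$keep
    }
  }
  kept <- phenotypes[keep, , drop = FALSE]
  endpoints <- intersect(c("length_um", "area_um2", "volume_um3", "af_per_length",
                           "af_per_area"),
                         names(kept))
  stats_for <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(list(mean = NA_real_, sd = NA_real_,
                                     sem = NA_real_, cv = NA_real_))
    m <- mean(x); s <- stats::sd(x)
    list(mean = m, sd = s, sem = s / sqrt(length(x)),
         cv = if (m != 0) s / m else NA_real_)
  }
  out <- lapply(kept[endpoints], stats_for)
  structure(list(n_raw = n_raw, n_kept = nrow(kept), endpoints = out,
                 keep = keep),
            class = "well_summary")
}

#' Four-parameter variable-slope Hill fit with EC10
#'
#' Fits `Y = Bottom + (Top - Bottom) / (1 + (X / EC50)^h)` by nonlinear
#' least squares. With `constraint_mode = "body"` the Bottom is fixed at 0
#' (body-size endpoints); `"af"` leaves all four parameters free
#' (autofluorescence). Controls (dose 0) are included via a dose
#' substitution `X0 = min(positive dose) * control_dose_factor`, mirroring
#' their placement on a log-dose axis.
#'
#' ECf for any f is obtained from the fitted parameters as
#' `ECf = (f / (100 - f))^(1 / |h|) * EC50`; EC10 uses f = 10. The 95%
#' confidence interval is a normal-theory (delta-method) interval on
#' `log(EC10)` from the fit covariance; a parametric bootstrap is available.
#'
#' @param doses Dose vector (may include 0 for controls).
#' @param responses Response vector (well means), same length.
#' @param constraint_mode `"body"` (Bottom = 0) or `"af"` (all free).
#' @param f Effect percentage for ECf (default 10).
#' @param ci One of `"delta"` or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `ci = "bootstrap"`.
#' @param control_dose_factor Dose-0 substitution factor (default 0.01
#'   times the smallest positive dose).
#' @param seed Seed for the bootstrap.
#' @return A list of class `dose_response_fit`: `top`, `bottom`, `ec50`,
#'   `hill_slope`, `ec10`, `ec10_ci` (length 2), `converged`, `fit` (the
#'   Levenberg-Marquardt fit object), `constraint_mode`.
#' @export
hill_fit <- function(doses, responses, constraint_mode = c("body", "af"),
                     f = 10, ci = c("delta", "bootstrap"), n_boot = 200L,
                     control_dose_factor = 0.01, seed = 1L) {
  constraint_mode <- match.arg(constraint_mode)
  ci <- match.arg(ci)
  ok <- !is.na(doses) & !is.na(responses)
  doses <- doses[ok]; responses <- responses[ok]
  pos <- doses[doses > 0]
  if (length(unique(doses)) < 4L) stop("need at least 4 distinct doses")
  x <- ifelse(doses == 0, min(pos) * control_dose_factor, doses)
  top0 <- max(responses); bot0 <- min(responses)
  ec0 <- exp(mean(log(range(pos))))
  model_fn <- function(p) {
    bottom <- if (constraint_mode == "body") 0 else p[["bottom"]]
    bottom + (p[["top"]] - bottom) / (1 + (x / exp(p[["lec50"]]))^p[["h"]])
  }
  start <- if (constraint_mode == "body")
    c(top = top0, lec50 = log(ec0), h = 1.5)
  else c(bottom = bot0, top = top0, lec50 = log(ec0), h = 1.5)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start,
                       fn = function(p) responses - model_fn(p),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error") || !fit$info %in% 1:4) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else fit$message
    return(structure(list(converged = FALSE, message = msg,
                          constraint_mode = constraint_mode),
                     class = "dose_response_fit"))
  }
  cf <- unlist(fit$par)
  h <- cf[["h"]]
  lec50 <- cf[["lec50"]]
  ratio <- log(f / (100 - f))
  lec10 <- lec50 + ratio / abs(h)
  npar <- length(cf)
  sig2 <- fit$deviance / max(length(responses) - npar, 1)
  vc <- tryCatch(sig2 * chol2inv(chol(fit$hessian)), error = function(e) NULL)
  ci_vals <- c(NA_real_, NA_real_)
  if (ci == "delta" && !is.null(vc)) {
    # gradient of log(ECf) wrt (lec50, h): (1, -ratio * sign(h) / h^2)
    gnames <- names(cf)
    grad <- numeric(npar)
    grad[match("lec50", gnames)] <- 1
    grad[match("h", gnames)] <- -ratio * sign(h) / h^2
    se <- sqrt(max(drop(t(grad) %*% vc %*% grad), 0))
    ci_vals <- exp(lec10 + c(-1, 1) * stats::qnorm(0.975) * se)
  } else if (ci == "bootstrap") {
    sig <- sqrt(sig2)
    yhat <- model_fn(fit$par)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        yb <- yhat + stats::rnorm(length(yhat), 0, sig)
        fb <- tryCatch(
          hill_fit(doses, yb, constraint_mode, f = f, ci = "delta",
                   control_dose_factor = control_dose_factor),
          error = function(e) NULL)
        if (is.null(fb) || !isTRUE(fb$converged)) NA_real_ else fb$ec10
      }, 0)
    })
    ci_vals <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(top = cf[["top"]],
                 bottom = if (constraint_mode == "body") 0 else cf[["bottom"]],
                 ec50 = exp(lec50), hill_slope = h,
                 ec10 = exp(lec10), ec10_ci = ci_vals,
                 converged = TRUE, fit = fit,
                 constraint_mode = constraint_mode),
            class = "dose_response_fit")
}

#' ECf transform of a fitted Hill curve
#'
#' `ECf = (f / (100 - f))^(1 / |h|) * EC50`; `f = 50` returns EC50 for any
#' slope.
#'
#' @param ec50 Fitted EC50.
#' @param h Fitted Hill slope.
#' @param f Effect percentage.
#' @export
ec_anything <- function(ec50, h, f) {
  (f / (100 - f))^(1 / abs(h)) * ec50
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Computed from the published formulas: weights `w_i = n_i / s_i^2`,
#' Welch's F with Satterthwaite-style denominator degrees of freedom.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping factor/vector.
#' @return A list with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
welch_anova <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups")
  n <- tapply(values, groups, length)
  if (any(n < 2L)) stop("each group needs at least 2 observations")
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  w <- n / v
  sw <- sum(w)
  mw <- sum(w * m) / sw
  a <- sum(w * (m - mw)^2) / (k - 1)
  lambda <- sum((1 - w / sw)^2 / (n - 1))
  b <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  fstat <- a / b
  df2 <- (k^2 - 1) / (3 * lambda)
  list(statistic = unname(fstat), df1 = k - 1, df2 = unname(df2),
       p_value = stats::pf(fstat, k - 1, df2, lower.tail = FALSE))
}

# Upper tail of the studentized maximum modulus distribution for m
# independent comparisons with df degrees of freedom:
# P(max_j |T_j| > t) = 1 - (2 F_df(t) - 1)^m.
smm_p <- function(t, m, df) {
  1 - pmax(2 * stats::pt(t, df) - 1, 0)^m
}

smm_p_mc <- function(t, m, df, n_mc = 100000L, seed = 1L) {
  with_seed(seed, {
    draws <- matrix(abs(stats::rt(n_mc * m, df)), n_mc, m)
    mean(apply(draws, 1, max) > t)
  })
}

#' Dunnett's T3 comparisons against control
#'
#' Pairwise Welch t statistics of each treated group against the control,
#' with Satterthwaite degrees of freedom, adjusted using the studentized
#' maximum modulus (SMM) distribution over the number of comparisons.
#'
#' @param values,groups Observations and group labels.
#' @param control The label of the control group.
#' @param mc Use a Monte-Carlo SMM tail instead of the closed form.
#' @param seed Seed for the Monte-Carlo tail.
#' @return A data.frame: group, t, df, p_adj.
#' @export
dunnett_t3 <- function(values, groups, control, mc = FALSE, seed = 1L) {
  groups <- as.character(groups)
  if (!control %in% groups) stop("control group not found")
  others <- setdiff(unique(groups), control)
  m <- length(others)
  x0 <- values[groups == control]
  res <- lapply(others, function(g) {
    x1 <- values[groups == g]
    n0 <- length(x0); n1 <- length(x1)
    v0 <- stats::var(x0) / n0; v1 <- stats::var(x1) / n1
    tstat <- (mean(x1) - mean(x0)) / sqrt(v0 + v1)
    df <- (v0 + v1)^2 / (v0^2 / (n0 - 1) + v1^2 / (n1 - 1))
    p <- if (mc) smm_p_mc(abs(tstat), m, df, seed = seed)
         else smm_p(abs(tstat), m, df)
    data.frame(group = g, t = tstat, df = df, p_adj = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' LOAEL determination by Welch ANOVA and Dunnett T3
#'
#' Shapiro-Wilk normality p-values are reported per group (they do not
#' change the test choice); a Welch ANOVA is run across all groups, then
#' Dunnett T3 comparisons of each dose against the control. The LOAEL is
#' the smallest dose whose adjusted p-value is below `alpha`.
#'
#' @param values_by_dose A named list: names are doses (numbers as strings
#'   or numerics), values are per-worm measurements; must include the
#'   control.
#' @param control_dose The control dose (default 0).
#' @param alpha Significance level (default 0.05).
#' @param mc Monte-Carlo SMM tail (see [dunnett_t3()]).
#' @return A list of class `loael_result`: `loael_dose_um` (or `NA`),
#'   `comparisons` (per-dose adjusted p), `welch` (ANOVA result),
#'   `shapiro_p` (per group), `test = "welch_anova_dunnett_t3"`.
#' @export
loael <- function(values_by_dose, control_dose = 0, alpha = 0.05, mc = FALSE) {
  doses <- as.numeric(names(values_by_dose))
  if (anyNA(doses)) stop("names of values_by_dose must be numeric doses")
  if (!control_dose %in% doses) stop("control dose not present")
  sizes <- vapply(values_by_dose, length, 0L)
  if (any(sizes < 3L))
    stop(paste("groups with fewer than 3 worms:",
               paste(names(values_by_dose)[sizes < 3L], collapse = ", ")))
  values <- unlist(values_by_dose, use.names = FALSE)
  groups <- rep(names(values_by_dose), sizes)
  shap <- vapply(values_by_dose, function(x) {
    if (length(unique(x)) < 3L) return(NA_real_)
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  }, 0)
  wa <- welch_anova(values, groups)
  cmp <- dunnett_t3(values, groups, control = as.character(control_dose), mc = mc)
  cmp$dose_um <- as.numeric(cmp$group)
  cmp <- cmp[order(cmp$dose_um), ]
  sig <- cmp$dose_um[cmp$p_adj < alpha]
  structure(list(loael_dose_um = if (length(sig)) min(sig) else NA_real_,
                 comparisons = cmp, welch = wa, shapiro_p = shap,
                 test = "welch_anova_dunnett_t3"),
            class = "loael_result")
}

#' Coefficient of variation across control wells
#'
#' The CV of the control well means across replicates, per endpoint: the
#' reproducibility figure of a device run.
#'
#' @param control_means A data.frame (or named list of vectors) of per-well
#'   endpoint means, one row/entry per control well.
#' @return Named numeric vector of CVs (sd / mean per endpoint).
#' @export
control_cv <- function(control_means) {
  df <- as.data.frame(control_means)
  if (nrow(df) < 2L) stop("need at least 2 control wells")
  vapply(df, function(x) stats::sd(x) / mean(x), 0)
}

#' Full developmental-toxicity statistics report
#'
#' From a per-worm phenotype table: Tukey-filtered per-well summaries, the
#' control coefficient of variation per endpoint, a Hill fit with EC10 and
#' 95% CI per endpoint (Bottom constrained to 0 for body endpoints, all
#' parameters free for autofluorescence endpoints), and the LOAEL by Welch
#' ANOVA with Dunnett T3 comparisons against control.
#'
#' @param phenotypes Data.frame with columns `well`, `dose_um` and the
#'   endpoint columns (`length_um`, `area_um2`, `volume_um3`, optionally
#'   `af_per_length`, `af_per_area`).
#' @param endpoints Body endpoints to analyse.
#' @param af_endpoints Autofluorescence endpoints to analyse.
#' @param alpha LOAEL significance level.
#' @return A list of class `devtox_report`: `well_summaries`, `control_cv`,
#'   `fits` (per endpoint), `loael` (per endpoint).
#' @export
devtox_report <- function(phenotypes,
                          endpoints = c("length_um", "area_um2", "volume_um3"),
                          af_endpoints = intersect(c("af_per_length", "af_per_area"),
                                                   names(phenotypes)),
                          alpha = 0.05) {
  phenotypes <- phenotypes[!is.na(phenotypes$length_um), , drop = FALSE]
  wells <- split(phenotypes, phenotypes$well)
  summaries <- lapply(wells, summarize_well)
  well_dose <- vapply(wells, function(w) w$dose_um[1], 0)
  all_eps <- c(endpoints, af_endpoints)
  well_means <- do.call(rbind, lapply(names(wells), function(w) {
    s <- summaries[[w]]
    row <- data.frame(well = w, dose_um = well_dose[[w]], n = s$n_kept)
    for (ep in all_eps) row[[ep]] <- s$endpoints[[ep]]$mean
    row
  }))
  ctrl <- well_means[well_means$dose_um == 0, all_eps, drop = FALSE]
  cvs <- if (nrow(ctrl) >= 2L) control_cv(ctrl) else
    stats::setNames(rep(NA_real_, length(all_eps)), all_eps)
  fits <- lapply(stats::setNames(all_eps, all_eps), function(ep) {
    mode <- if (ep %in% af_endpoints) "af" else "body"
    ok <- !is.na(well_means[[ep]])
    tryCatch(hill_fit(well_means$dose_um[ok], well_means[[ep]][ok],
                      constraint_mode = mode),
             error = function(e)
               structure(list(converged = FALSE, message = conditionMessage(e),
                              constraint_mode = mode),
                         class = "dose_response_fit"))
  })
  loaels <- lapply(stats::setNames(all_eps, all_eps), function(ep) {
    keep_rows <- do.call(rbind, lapply(names(wells), function(w) {
      kw <- wells[[w]][summaries[[w]]$keep, , drop = FALSE]
      kw[, c("dose_um", ep)]
    }))
    keep_rows <- keep_rows[!is.na(keep_rows[[ep]]), , drop = FALSE]
    vbd <- split(keep_rows[[ep]], keep_rows$dose_um)
    sizes <- vapply(vbd, length, 0L)
    vbd <- vbd[sizes >= 3L]
    if (length(vbd) < 2L || !("0" %in% names(vbd)))
      return(NULL)
    tryCatch(loael(vbd, control_dose = 0, alpha = alpha),
             error = function(e) NULL)
  })
  structure(list(well_summaries = summaries, well_means = well_means,
                 control_cv = cvs, fits = fits, loael = loaels),
            class = "devtox_report")
}
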