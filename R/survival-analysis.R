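# Survival stage: entropy-balancing inverse-probability weights that
# decorrelate a target LGE metric from baseline confounders, weighted Cox
# regressions with robust (sandwich) standard errors and per-SD hazard
# ratios, a time-varying ICD model, tercile stratification, Kaplan-Meier
# curves and the log-rank test. Cox/KM machinery is delegated to the
# survival package; the decorrelating weights are computed here.

#' Standardize columns to zero mean and unit SD
#'
#' Centers each named column and divides by its unweighted sample SD
#' (denominator n - 1), so Cox coefficients on these columns are per-SD
#' log hazard ratios.
#'
#' @param frame a data.frame.
#' @param columns character vector of numeric column names.
#' @return The frame with the named columns standardized.
#' @export
standardize_per_sd <- function(frame, columns) {
  for (cl in columns) {
    v <- as.numeric(frame[[cl]])
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("cannot standardize column with zero SD: ", cl)
    frame[[cl]] <- (v - mean(v)) / s
  }
  frame
}

#' Decorrelating inverse-probability weights (entropy balancing)
#'
#' Finds positive per-patient weights, summing to n, that make the weighted
#' Pearson correlation between the target column and every confounder
#' exactly zero, while staying as close as possible to uniform weights in
#' the Kullback-Leibler sense: minimize `sum(w_i log(n w_i))` subject to
#' `sum(w) = n` and the zero-correlation moment constraints (weighted means
#' of the centered target, each centered confounder, and each centered
#' cross-product are held at zero). The convex dual is solved by damped
#' Newton iteration.
#'
#' @param frame a data.frame.
#' @param target_column name of the LGE metric column.
#' @param confounder_columns names of confounder columns (logicals are
#'   treated as 0/1).
#' @param tol maximum absolute weighted correlation accepted (default 1e-8).
#' @param max_iter Newton iteration cap.
#' @return Numeric weight vector (length nrow(frame), sums to n), with
#'   attribute `"max_abs_correlation"`.
#' @export
ipw_weights <- function(frame, target_column, confounder_columns,
                        tol = 1e-8, max_iter = 200L) {
  n <- nrow(frame)
  t_raw <- as.numeric(frame[[target_column]])
  X <- sapply(confounder_columns, function(cl) as.numeric(frame[[cl]]))
  X <- matrix(X, nrow = n)
  if (n <= ncol(X) * 2 + 1)
    stop("too few rows for the number of constraints")
  tc <- t_raw - mean(t_raw)
  Xc <- sweep(X, 2, colMeans(X))
  # constraint matrix: centered target, centered confounders, cross-products
  C <- cbind(tc, Xc, Xc * tc)
  # drop degenerate constraints, detect collinearity
  sds <- apply(C, 2, stats::sd)
  if (any(sds == 0))
    stop("infeasible constraints: a constraint column is constant")
  Cs <- sweep(C, 2, sds, `/`)
  qrC <- qr(Cs)
  if (qrC$rank < ncol(Cs))
    stop("infeasible constraints: target and confounders are collinear")
  m <- ncol(Cs)
  lambda <- numeric(m)
  # dual: f(lambda) = log mean exp(Cs lambda); gradient = weighted mean of Cs
  fval <- function(lam) {
    e <- as.numeric(Cs %*% lam)
    mx <- max(e)
    log(mean(exp(e - mx))) + mx
  }
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Cs %*% lambda)
    w <- exp(eta - max(eta))
    w <- w / sum(w)
    g <- as.numeric(crossprod(Cs, w))
    if (max(abs(g)) < 1e-13) break
    H <- crossprod(Cs * sqrt(w)) - tcrossprod(g)
    step <- tryCatch(solve(H + diag(1e-10, m), g),
                     error = function(e) g)   # gradient fallback
    # damped backtracking on the dual objective
    f0 <- fval(lambda)
    alpha <- 1
    repeat {
      lam_new <- lambda - alpha * step
      if (fval(lam_new) <= f0 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    lambda <- lam_new
    if (max(abs(step)) * alpha < 1e-14) break
  }
  eta <- as.numeric(Cs %*% lambda)
  eta <- eta - max(eta)
  w <- exp(eta); w <- n * w / sum(w)
  # verify the post-condition on actual weighted correlations
  wcor <- function(a, b) {
    ma <- sum(w * a) / n; mb <- sum(w * b) / n
    va <- sum(w * (a - ma)^2); vb <- sum(w * (b - mb)^2)
    sum(w * (a - ma) * (b - mb)) / sqrt(va * vb)
  }
  corrs <- apply(X, 2, function(x) wcor(t_raw, x))
  if (max(abs(corrs)) > max(tol, 1e-6))
    stop("IPW did not converge: max |weighted correlation| = ",
         format(max(abs(corrs))))
  structure(w, max_abs_correlation = max(abs(corrs)))
}

#' Weighted Cox regression with robust standard errors
#'
#' Fits a weighted Cox proportional-hazards model (Efron ties) and reports
#' hazard ratios with Wald 95% confidence intervals on the log scale, using
#' the sandwich (robust) variance by default. Continuous terms should be
#' standardized first ([standardize_per_sd()]) so HRs are per SD.
#'
#' @param frame data.frame with `time` and `event` columns (or names given
#'   in `time_col` / `event_col`).
#' @param terms character vector of model terms.
#' @param weights optional positive case weights (e.g. [ipw_weights()]).
#' @param robust use the sandwich variance (default TRUE).
#' @param time_col,event_col column names for follow-up time and event flag.
#' @return Object of class `lge_cox`: data.frame `table` (term, hazard_ratio,
#'   ci95_low, ci95_high, p_value), `n`, `events`, `converged`, and the
#'   underlying `coxph` fit.
#' @export
cox_fit <- function(frame, terms, weights = NULL, robust = TRUE,
                    time_col = "followup_days", event_col = "event") {
  if (sum(frame[[event_col]]) < 1) stop("no events in the data")
  f <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(terms, collapse = " + ")))
  frame$.w <- if (is.null(weights)) rep(1, nrow(frame)) else weights
  fit <- withCallingHandlers(
    survival::coxph(f, data = frame, weights = .w, robust = robust,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|Ran out of iterations",
                conditionMessage(w)))
        stop("Cox fit did not converge (possible separation): ",
             conditionMessage(w), call. = FALSE)
    })
  if (!is.null(fit$fail)) stop("Cox fit failed: ", fit$fail)
  beta <- stats::coef(fit)
  se <- if (robust && !is.null(fit$var))
    sqrt(diag(fit$var)) else sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  tab <- data.frame(term = names(beta), hazard_ratio = exp(beta),
                    ci95_low = exp(beta - 1.96 * se),
                    ci95_high = exp(beta + 1.96 * se),
                    p_value = 2 * stats::pnorm(-abs(z)),
                    log_hr = beta, se = se, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n = fit$n, events = fit$nevent,
                 converged = TRUE, fit = fit),
            class = "lge_cox")
}

#' @export
#' @method print lge_cox
print.lge_cox <- function(x, ...) {
  cat(sprintf("Weighted Cox model: n = %d, events = %d\n", x$n, x$events))
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-24s HR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
                tab$term[i], tab$hazard_ratio[i], tab$ci95_low[i],
                tab$ci95_high[i], tab$p_value[i]))
  invisible(x)
}

#' @export
coef.lge_cox <- function(object, ...) {
  stats::setNames(object$table$log_hr, object$table$term)
}

#' Cox model with ICD placement as a time-varying covariate
#'
#' Expands each patient into counting-process rows: a patient with an ICD
#' at day `d` contributes `(0, d]` with indicator 0 and `(d, time]` with
#' indicator 1; patients without ICD contribute a single row. The expanded
#' data are fit like [cox_fit()].
#'
#' @param frame data.frame with time/event columns and an ICD day column
#'   (NA for patients without ICD).
#' @param terms model terms beside the ICD indicator.
#' @param icd_column name of the ICD day column (default `"icd_day"`).
#' @param weights optional per-patient weights.
#' @param robust sandwich variance (default TRUE).
#' @param time_col,event_col column names.
#' @return An `lge_cox` object; the ICD indicator term is `icd_on`. The
#'   expanded frame is attached as `$expanded`.
#' @export
cox_time_varying <- function(frame, terms, icd_column = "icd_day",
                             weights = NULL, robust = TRUE,
                             time_col = "followup_days", event_col = "event") {
  n <- nrow(frame)
  frame$.w <- if (is.null(weights)) rep(1, n) else weights
  icd <- frame[[icd_column]]
  tt <- frame[[time_col]]; ev <- frame[[event_col]]
  if (any(!is.na(icd) & icd > tt)) stop("icd_day exceeds follow-up time")
  rows <- lapply(seq_len(n), function(i) {
    base <- frame[i, , drop = FALSE]
    if (is.na(icd[i]) || icd[i] <= 0 || icd[i] >= tt[i]) {
      base$.tstart <- 0; base$.tstop <- tt[i]; base$.ev <- ev[i]
      base$icd_on <- as.integer(!is.na(icd[i]) && icd[i] <= 0)
      base
    } else {
      r1 <- base; r1$.tstart <- 0; r1$.tstop <- icd[i]; r1$.ev <- FALSE
      r1$icd_on <- 0L
      r2 <- base; r2$.tstart <- icd[i]; r2$.tstop <- tt[i]; r2$.ev <- ev[i]
      r2$icd_on <- 1L
      rbind(r1, r2)
    }
  })
  ex <- do.call(rbind, rows)
  # with no ICD exposure the indicator is inestimable; drop it so the fit
  # reduces to the ordinary model
  use_icd <- any(ex$icd_on > 0)
  f <- stats::as.formula(paste0(
    "survival::Surv(.tstart, .tstop, .ev) ~ ",
    paste(c(terms, if (use_icd) "icd_on",
            if (robust) "cluster(patient_id)"), collapse = " + ")))
  fit <- survival::coxph(f, data = ex, weights = .w, robust = robust,
                         ties = "efron")
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  z <- beta / se
  tab <- data.frame(term = names(beta), hazard_ratio = exp(beta),
                    ci95_low = exp(beta - 1.96 * se),
                    ci95_high = exp(beta + 1.96 * se),
                    p_value = 2 * stats::pnorm(-abs(z)),
                    log_hr = beta, se = se, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n = n, events = sum(ev), converged = TRUE,
                 fit = fit, expanded = ex),
            class = "lge_cox")
}

#' Tercile stratification of a metric
#'
#' Splits patients into three equal-thirds groups at the nearest-rank 33.3
#' and 66.7 percentiles of `column` (groups of size floor(n/3) or
#' ceiling(n/3); ties straddling a cutpoint are broken by stable sort order
#' on value then patient id), reports per-group event counts and rates, and
#' hazard ratios of the middle and upper terciles versus the lowest.
#'
#' @param frame data.frame with the metric, time and event columns and a
#'   `patient_id` column.
#' @param column metric column name.
#' @param weights optional weights passed to the Cox fit.
#' @param time_col,event_col column names.
#' @return List of class `tercile_summary`: `group` (factor per patient),
#'   `cutpoints`, `summary` data.frame (n, events, event_rate_pct), and
#'   `cox` (an `lge_cox` of tercile indicators, NULL if inestimable).
#' @export
tercile_stratify <- function(frame, column, weights = NULL,
                             time_col = "followup_days", event_col = "event") {
  n <- nrow(frame)
  if (n < 3) stop("need at least 3 patients for terciles")
  ord <- order(frame[[column]], frame$patient_id)
  sizes <- diff(floor(n * (0:3) / 3))
  grp <- integer(n)
  grp[ord] <- rep(1:3, times = sizes)
  group <- factor(grp, levels = 1:3, labels = c("low", "mid", "high"))
  v <- sort(frame[[column]])
  cutpoints <- c(v[ceiling(n / 3)], v[ceiling(2 * n / 3)])  # nearest-rank
  ev <- frame[[event_col]]
  summ <- data.frame(tercile = levels(group),
                     n = as.integer(table(group)),
                     events = as.integer(tapply(ev, group, sum)),
                     row.names = NULL)
  summ$event_rate_pct <- mapply(event_rates, summ$events, summ$n)
  frame$.t_mid <- as.integer(group == "mid")
  frame$.t_high <- as.integer(group == "high")
  cox <- tryCatch(
    cox_fit(frame, c(".t_mid", ".t_high"), weights = weights,
            time_col = time_col, event_col = event_col),
    error = function(e) NULL)
  structure(list(group = group, cutpoints = cutpoints, summary = summ,
                 cox = cox),
            class = "tercile_summary")
}

#' @export
#' @method print tercile_summary
print.tercile_summary <- function(x, ...) {
  cat("Tercile stratification (cutpoints:",
      paste(signif(x$cutpoints, 4), collapse = ", "), ")\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$cox)) print(x$cox)
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimate per group plus the standard log-rank
#' chi-square test with k - 1 degrees of freedom.
#'
#' @param frame data.frame with time and event columns.
#' @param groups factor (or coercible) of group membership, every level
#'   nonempty.
#' @param time_col,event_col column names.
#' @return List: `survfit` (the survival::survfit object), `chisq`, `df`,
#'   `p_value`.
#' @export
km_logrank <- function(frame, groups, time_col = "followup_days",
                       event_col = "event") {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("a group has zero subjects")
  d <- data.frame(.t = frame[[time_col]], .e = as.integer(frame[[event_col]]),
                  .g = groups)
  sf <- survival::survfit(survival::Surv(.t, .e) ~ .g, data = d)
  sd <- survival::survdiff(survival::Surv(.t, .e) ~ .g, data = d)
  df <- nlevels(groups) - 1
  list(survfit = sf, chisq = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Event rate as a printed percentage
#'
#' `100 * events / n`, rounded to one decimal (the convention used for
#' reporting cohort event rates).
#'
#' @param events number of events.
#' @param n group size (> 0).
#' @return Percentage rounded to one decimal.
#' @export
event_rates <- function(events, n) {
  if (n == 0) stop("n must be positive")
  if (events > n) stop("events cannot exceed n")
  round(100 * events / n, 1)
}
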