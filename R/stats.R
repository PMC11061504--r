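#' Analysis of feasible versus infeasible perturbations
#'
#' Descriptive statistics and kernel densities of the sampled perturbations
#' by feasibility class, and stepwise logistic regression of feasibility on
#' the centred perturbations with McFadden's adjusted pseudo R-squared as
#' the inclusion criterion.
#'
#' @name feasibility-stats
NULL

#' Centre perturbation percentages about the unperturbed value
#'
#' `x = p - 100`: 0 means unperturbed, -40 a 40-point reduction. Regression
#' coefficients on centred covariates are odds-ratio changes per 1%
#' perturbation.
#'
#' @param percentages Numeric vector/matrix/data frame of percentages.
#' @return Same shape, centred.
#' @export
centre_perturbations <- function(percentages) {
  percentages - 100
}

#' Descriptive statistics by group x parameter and feasibility class
#'
#' Median, IQR (Q3 - Q1, linear-interpolation quartiles), percentile
#' bootstrap 95% CI of the median, min and max, computed per parameter
#' separately over feasible and infeasible records.
#'
#' @param records Campaign record data frame.
#' @param n_boot Bootstrap resamples for the median CI.
#' @param seed Seed for the bootstrap.
#' @return Data frame with one row per class x parameter.
#' @export
descriptive_stats <- function(records, n_boot = 2000, seed = 1) {
  nms <- perturbation_names()
  out <- list()
  .with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      sub <- records[records$feasible == cls, nms, drop = FALSE]
      if (nrow(sub) == 0) {
        warning("no ", if (cls) "feasible" else "infeasible",
                " records; class omitted", call. = FALSE)
        next
      }
      for (nm in nms) {
        x <- sub[[nm]]
        meds <- vapply(seq_len(n_boot), function(b) {
          stats::median(sample(x, replace = TRUE))
        }, numeric(1))
        ci <- stats::quantile(meds, c(0.025, 0.975), names = FALSE)
        out[[length(out) + 1]] <- data.frame(
          class = if (cls) "feasible" else "infeasible",
          group = sub("_.*", "", nm), parameter = sub(".*_", "", nm),
          n = length(x),
          median = stats::median(x),
          iqr = diff(stats::quantile(x, c(0.25, 0.75), names = FALSE)),
          ci_lo = ci[1], ci_hi = ci[2],
          min = min(x), max = max(x))
      }
    }
  })
  do.call(rbind, out)
}

#' Gaussian kernel density with Silverman bandwidth
#'
#' Evaluated on a caller-supplied grid; a bandwidth floor handles
#' degenerate (zero-variance) input by producing a narrow spike instead of
#' failing.
#'
#' @param values Numeric sample (>= 5 values).
#' @param grid Evaluation grid.
#' @param bw Bandwidth; default Silverman's rule-of-thumb
#'   (`stats::bw.nrd0`).
#' @return Data frame (`x`, `density`).
#' @export
kernel_density <- function(values, grid, bw = NULL) {
  if (length(values) < 5) stop("need at least 5 values", call. = FALSE)
  if (is.null(bw)) {
    bw <- tryCatch(stats::bw.nrd0(values), error = function(e) 0)
    span <- diff(range(values))
    bw <- max(bw, 1e-3 * max(span, 1))   # floor for degenerate input
  }
  dens <- vapply(grid, function(g) mean(stats::dnorm((g - values) / bw)) / bw,
                 numeric(1))
  data.frame(x = grid, density = dens)
}

#' McFadden's adjusted pseudo R-squared
#'
#' `1 - (loglik - n_params) / loglik_null`.
#'
#' @param loglik Fitted model log-likelihood.
#' @param loglik_null Intercept-only log-likelihood (< 0).
#' @param n_params Number of fitted covariates (penalty).
#' @return Adjusted pseudo R-squared.
#' @export
mcfadden_adjusted_r2 <- function(loglik, loglik_null, n_params) {
  if (loglik_null >= 0) stop("loglik_null must be < 0", call. = FALSE)
  1 - (loglik - n_params) / loglik_null
}

#' Odds ratio and Wald confidence interval from a log-odds estimate
#'
#' @param log_odds Coefficient on the log-odds scale.
#' @param std_err Standard error (> 0).
#' @param level Confidence level (default 0.99).
#' @return List with `or`, `lower`, `upper`.
#' @export
odds_ratio_ci <- function(log_odds, std_err, level = 0.99) {
  if (any(std_err <= 0)) stop("std_err must be > 0", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = exp(log_odds),
       lower = exp(log_odds - z * std_err),
       upper = exp(log_odds + z * std_err))
}

#' Forward stepwise logistic regression on centred perturbations
#'
#' Candidates are the 15 centred main effects and (optionally) all pairwise
#' interaction products. At each step the candidate giving the largest
#' increase in McFadden's adjusted pseudo R-squared enters; selection stops
#' when no candidate adds at least `delta` (default 2.5 percentage points).
#' Ties break by candidate order (mains first, then interactions, both in
#' [perturbation_names()] order). An interaction may only enter once both
#' parents are in the model (hierarchy rule; switchable). Coefficients are
#' reported as log-odds and odds ratios per 1% perturbation with Wald 99%
#' CIs; a term is significant when its odds-ratio CI excludes 1.
#'
#' @param records Campaign records (needs the 15 parameter columns and
#'   `feasible`).
#' @param delta Adjusted pseudo R-squared inclusion threshold.
#' @param interactions Include pairwise interaction candidates.
#' @param hierarchy Require both parents before an interaction.
#' @param level CI level.
#' @param max_terms Safety cap on selected terms.
#' @return A `regression_report` list: `terms` (data frame with log-odds,
#'   SE, odds ratios, CI, significance), `r2_trace`, `loglik`,
#'   `loglik_null`, `n`, `n_feasible`, `separation` flag.
#' @export
stepwise_logistic <- function(records, delta = 0.025, interactions = TRUE,
                              hierarchy = TRUE, level = 0.99,
                              max_terms = 10) {
  nms <- perturbation_names()
  y <- records$feasible
  if (length(unique(y)) < 2) {
    stop("both feasibility classes must be present", call. = FALSE)
  }
  X <- centre_perturbations(as.matrix(records[, nms, drop = FALSE]))
  cand <- stats::setNames(lapply(nms, function(nm) X[, nm]), nms)
  if (interactions) {
    for (i in seq_along(nms)) {
      for (j in seq_along(nms)) {
        if (j > i) {
          cand[[paste0(nms[i], ":", nms[j])]] <- X[, i] * X[, j]
        }
      }
    }
  }
  n <- length(y)
  fit_ll <- function(vars) {
    df <- data.frame(y = y)
    for (v in vars) df[[make.names(v)]] <- cand[[v]]
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    list(fit = fit, ll = as.numeric(stats::logLik(fit)))
  }
  null_fit <- fit_ll(character(0))
  ll0 <- null_fit$ll
  selected <- character(0)
  r2_trace <- data.frame(step = 0L, term = "(intercept only)",
                         adj_r2 = 0)
  current_r2 <- 0
  sep_flag <- FALSE
  repeat {
    remaining <- setdiff(names(cand), selected)
    if (hierarchy) {
      remaining <- remaining[vapply(remaining, function(v) {
        if (!grepl(":", v)) return(TRUE)
        all(strsplit(v, ":")[[1]] %in% selected)
      }, logical(1))]
    }
    if (length(remaining) == 0 || length(selected) >= max_terms) break
    gains <- vapply(remaining, function(v) {
      f <- fit_ll(c(selected, v))
      mcfadden_adjusted_r2(f$ll, ll0, length(selected) + 1) - current_r2
    }, numeric(1))
    best <- which.max(gains)   # ties break by candidate order
    if (gains[best] < delta) break
    selected <- c(selected, remaining[best])
    current_r2 <- current_r2 + gains[best]
    r2_trace <- rbind(r2_trace,
                      data.frame(step = length(selected),
                                 term = remaining[best],
                                 adj_r2 = current_r2))
  }
  final <- fit_ll(selected)
  fit <- final$fit
  if (!fit$converged || any(abs(stats::coef(fit)) > 50)) {
    sep_flag <- TRUE
    warning("possible separation: coefficients may be unstable",
            call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  term_names <- c("(Intercept)", selected)
  ci <- odds_ratio_ci(cf[, 1], cf[, 2], level)
  terms <- data.frame(term = term_names,
                      log_odds = unname(cf[, 1]),
                      std_err = unname(cf[, 2]),
                      odds_ratio = unname(ci$or),
                      ci_lower = unname(ci$lower),
                      ci_upper = unname(ci$upper))
  terms$significant <- terms$ci_lower > 1 | terms$ci_upper < 1
  structure(list(terms = terms, r2_trace = r2_trace,
                 loglik = final$ll, loglik_null = ll0,
                 adj_r2 = mcfadden_adjusted_r2(final$ll, ll0,
                                               length(selected)),
                 n = n, n_feasible = sum(y), separation = sep_flag,
                 fit = fit, selected = selected),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "Stepwise logistic regression: %d records (%d feasible), adjusted McFadden R2 = %.3f\n",
    x$n, x$n_feasible, x$adj_r2))
  df <- x$terms
  df[-1] <- lapply(df[-1], function(v) if (is.numeric(v)) round(v, 3) else v)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write the two analysis tables as CSV
#'
#' @param descriptives Output of [descriptive_stats()].
#' @param report Output of [stepwise_logistic()].
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_analysis_tables <- function(descriptives, report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(descriptives, file.path(dir, "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(report$terms, file.path(dir, "regression.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(list(adj_r2 = report$adj_r2,
                                   r2_trace = report$r2_trace,
                                   n = report$n,
                                   n_feasible = report$n_feasible),
                              auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"),
             file.path(dir, "regression_report.json"))
  invisible(dir)
}
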