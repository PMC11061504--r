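#' Monte Carlo perturbation campaign
#'
#' Uniform sampling of the 15 grouped parameter perturbations (3 muscle
#' groups x 5 parameters), expansion to per-MTU perturbations, batched
#' solution of the tracking OCP, feasibility labelling, and campaign
#' convergence monitoring.
#'
#' @name perturbation-campaign
NULL

#' Perturbation boundaries
#'
#' Literature-informed unloading bounds, percentages of baseline:
#' MIF 40-100, OFL 60-100, OPA 75-100, MSV 50-200, TC 40-100.
#'
#' @return Named list of length-2 numeric bounds.
#' @export
perturbation_bounds <- function() {
  list(MIF = c(40, 100), OFL = c(60, 100), OPA = c(75, 100),
       MSV = c(50, 200), TC = c(40, 100))
}

#' Names of the 15 campaign parameters
#'
#' Groups KE (knee extensors), KF (knee flexors), NK (non-knee) crossed with
#' parameters MIF, OFL, OPA, MSV, TC.
#'
#' @return Character vector of 15 names (`KE_MIF`, ..., `NK_TC`).
#' @export
perturbation_names <- function() {
  as.vector(t(outer(c("KE", "KF", "NK"), c("MIF", "OFL", "OPA", "MSV", "TC"),
                    paste, sep = "_")))
}

#' Sample grouped perturbations uniformly within bounds
#'
#' Each of the 15 columns is i.i.d. uniform on its parameter's bound
#' interval (equal probability across the physiological range).
#'
#' @param n Number of draws (>= 1).
#' @param bounds Bounds from [perturbation_bounds()].
#' @param seed Integer seed (reproducible draws).
#' @return `n x 15` matrix with columns named as [perturbation_names()].
#' @export
sample_perturbations <- function(n, bounds = perturbation_bounds(),
                                 seed = 1) {
  stopifnot(n >= 1)
  nms <- perturbation_names()
  .with_seed(seed, {
    u <- matrix(stats::runif(n * 15), n, 15, dimnames = list(NULL, nms))
    for (j in seq_len(15)) {
      par <- sub("^[A-Z]+_", "", nms[j])
      b <- bounds[[par]]
      u[, j] <- b[1] + (b[2] - b[1]) * u[, j]
    }
    u
  })
}

#' Expand a 15-parameter row to per-MTU group perturbations
#'
#' Every MTU receives its group's five percentages (uniform adaptation
#' within a group); with 40 MTUs the 15 inputs cover 40 x 5 = 200 per-MTU
#' parameter slots.
#'
#' @param row Named 15-vector (names as [perturbation_names()]).
#' @param model A `limb_model` with group labels.
#' @return List of [group_perturbation()] objects, one per MTU in model
#'   order.
#' @export
expand_to_mtus <- function(row, model) {
  row <- unlist(row)
  nms <- perturbation_names()
  if (is.null(names(row)) && length(row) == 15) names(row) <- nms
  if (!all(nms %in% names(row))) {
    stop("row must carry the 15 names ", paste(nms, collapse = ", "),
         call. = FALSE)
  }
  code <- c(knee_extensor = "KE", knee_flexor = "KF", non_knee = "NK")
  lapply(model$mtus, function(m) {
    if (is.na(m$group) || !m$group %in% names(code)) {
      stop("MTU '", m$name, "' has no group label", call. = FALSE)
    }
    g <- code[[m$group]]
    group_perturbation(mif_pct = row[[paste0(g, "_MIF")]],
                       ofl_pct = row[[paste0(g, "_OFL")]],
                       opa_pct = row[[paste0(g, "_OPA")]],
                       msv_pct = row[[paste0(g, "_MSV")]],
                       tc_pct = row[[paste0(g, "_TC")]])
  })
}

# counter-based per-draw seed so parallel/out-of-order execution gives
# identical records; result kept inside 32-bit signed range
.draw_seed <- function(campaign_seed, draw) {
  (as.numeric(campaign_seed) * 48271 + draw * 7919) %% 2147483647
}

#' Run a Monte Carlo feasibility campaign
#'
#' For each draw: perturb all MTUs by their group's sampled percentages,
#' transcribe and solve the tracking OCP against the post-unloading
#' reference, classify feasibility from the knee reserve trace, and append
#' the record. Individual solver failures are recorded as infeasible draws,
#' never raised.
#'
#' @param model A `limb_model`.
#' @param reference Post-unloading `moment_profile` to track.
#' @param n Number of draws.
#' @param seed Campaign seed; per-draw seeds are derived by a counter-based
#'   scheme so records do not depend on execution order.
#' @param settings [ocp_settings()] for the solves.
#' @param record_file Optional CSV path; records are appended incrementally.
#' @param verbose Print one status line per draw.
#' @return Data frame of campaign records (one row per draw).
#' @export
run_campaign <- function(model, reference, n, seed = 1,
                         settings = ocp_settings(), record_file = NULL,
                         verbose = FALSE) {
  stopifnot(n >= 0)
  samples <- if (n > 0) sample_perturbations(n, seed = seed) else
    matrix(numeric(0), 0, 15, dimnames = list(NULL, perturbation_names()))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- run_draw(model, reference, samples[i, ], settings,
                    draw_index = i, seed = .draw_seed(seed, i))
    records[[i]] <- rec
    if (!is.null(record_file)) {
      utils::write.table(rec, record_file, sep = ",", append = i > 1,
                         col.names = i == 1, row.names = FALSE)
    }
    if (verbose) {
      message(sprintf("draw %d/%d: %s, max knee reserve %.1f%%",
                      i, n, rec$status, rec$max_reserve_pct))
    }
  }
  out <- do.call(rbind, records)
  if (is.null(out)) {
    out <- utils::read.csv(text = paste(c("draw",
                                          perturbation_names(), "status",
                                          "feasible", "max_reserve_pct",
                                          "J", "J_effort", "J_reserves",
                                          "J_controls", "seed"),
                                        collapse = ","))
  }
  out
}

#' Solve and classify one campaign draw
#'
#' @inheritParams run_campaign
#' @param row Named 15-vector of percentages.
#' @param draw_index Index recorded in the output.
#' @return One-row data frame (a `PerturbationRecord`).
#' @export
run_draw <- function(model, reference, row, settings = ocp_settings(),
                     draw_index = 1L, seed = 1L) {
  pmodel <- perturb_model(model, row)
  sol <- tryCatch(
    solve_tracking_ocp(pmodel, reference, settings, seed = seed),
    error = function(e) list(status = "failed", objective = NA_real_,
                             terms = c(J_effort = NA_real_,
                                       J_reserves = NA_real_,
                                       J_controls = NA_real_),
                             error = conditionMessage(e)))
  cls <- if (identical(sol$status, "failed") && is.null(sol$reserves)) {
    list(feasible = FALSE, max_reserve_pct = NA_real_)
  } else {
    classify_feasibility(sol, reference,
                         threshold_pct = settings$feasibility_threshold_pct)
  }
  out <- data.frame(draw = draw_index, t(row), status = sol$status,
                    feasible = cls$feasible,
                    max_reserve_pct = cls$max_reserve_pct,
                    J = sol$objective,
                    J_effort = sol$terms[["J_effort"]],
                    J_reserves = sol$terms[["J_reserves"]],
                    J_controls = sol$terms[["J_controls"]],
                    seed = seed)
  rownames(out) <- NULL
  out
}

#' Apply a 15-parameter perturbation row to a whole model
#'
#' @param model A `limb_model`.
#' @param row Named 15-vector of percentages.
#' @return Perturbed `limb_model` (groups and geometry unchanged).
#' @export
perturb_model <- function(model, row) {
  pmap <- expand_to_mtus(row, model)
  for (j in seq_along(model$mtus)) {
    model$mtus[[j]]$params <- apply_perturbation(model$mtus[[j]]$params,
                                                 pmap[[j]])
  }
  model
}

#' Campaign convergence rule
#'
#' The campaign is converged when, for each of the 15 parameters among the
#' feasible records, the mean and the coefficient of variation of the final
#' 10% of simulations are within 2% (relative) of the overall mean and
#' coefficient of variation.
#'
#' @param records Campaign record data frame (>= 20 records).
#' @param rel_tol Relative tolerance (default 0.02).
#' @param use_feasible_only Compute over feasible records (default TRUE).
#' @return List with `converged` (logical) and `diagnostics` (per-parameter
#'   data frame).
#' @export
campaign_converged <- function(records, rel_tol = 0.02,
                               use_feasible_only = TRUE) {
  if (nrow(records) < 20) {
    stop("need at least 20 records to assess convergence", call. = FALSE)
  }
  sub <- if (use_feasible_only) records[records$feasible, , drop = FALSE]
         else records
  if (nrow(sub) < 2) {
    return(list(converged = FALSE, diagnostics = NULL,
                reason = "no feasible records"))
  }
  nms <- perturbation_names()
  n_tail <- max(2L, ceiling(0.10 * nrow(sub)))
  tail_idx <- seq.int(nrow(sub) - n_tail + 1L, nrow(sub))
  # population moments: a tail that replicates the overall distribution
  # exactly must pass the check regardless of window size
  cv <- function(x) sqrt(mean((x - mean(x))^2)) / abs(mean(x))
  diag <- do.call(rbind, lapply(nms, function(nm) {
    x <- sub[[nm]]
    xt <- x[tail_idx]
    data.frame(parameter = nm,
               mean_all = mean(x), mean_tail = mean(xt),
               cv_all = cv(x), cv_tail = cv(xt))
  }))
  diag$mean_ok <- abs(diag$mean_tail - diag$mean_all) <=
    rel_tol * abs(diag$mean_all)
  diag$cv_ok <- abs(diag$cv_tail - diag$cv_all) <= rel_tol * abs(diag$cv_all)
  list(converged = all(diag$mean_ok & diag$cv_ok), diagnostics = diag)
}

#' Read / write campaign records
#'
#' Lossless CSV round-trip of the campaign record table.
#'
#' @param records Record data frame.
#' @param path CSV path.
#' @return `path` invisibly / the record data frame.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  utils::read.csv(path)
}
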