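# Synthetic sparse naive-pooled datasets with the study's statistical
# structure: lognormal between-subject variability around a typical
# one-compartment profile, combined proportional + additive residual error,
# and a randomized sparse allocation honouring the per-time quota and the
# per-subject draw cap.

#' Population PK generative model
#'
#' @param typical typical-value [onecomp_params()]; defaults emulate the
#'   feline enrofloxacin bead study (ka 1.2 1/h, ke 0.12 1/h, V/F 3 L/kg,
#'   10 mg/kg).
#' @param iiv_cv named lognormal between-subject CV fractions for `ka`,
#'   `ke`, `v_over_f`.
#' @param residual `c(prop = , add = )` residual error: proportional CV
#'   fraction and additive SD (ug/mL); observations are truncated at 0.
#' @param lloq lower limit of quantification (ug/mL).
#' @return object of class `pop_pk_model`.
#' @export
pop_pk_model <- function(typical = onecomp_params(ka = 1.2, ke = 0.12,
                                                  v_over_f = 3.0,
                                                  dose_mg_per_kg = 10),
                         iiv_cv = c(ka = 0.25, ke = 0.25, v_over_f = 0.20),
                         residual = c(prop = 0.10, add = 0.02),
                         lloq = 0.01) {
  if (any(iiv_cv < 0) || any(residual < 0) || lloq < 0)
    stop_domain("CVs, residual components and lloq must be non-negative")
  iiv_cv <- iiv_cv[c("ka", "ke", "v_over_f")]
  if (anyNA(iiv_cv)) stop_validation("iiv_cv needs names ka, ke, v_over_f")
  structure(list(typical = typical, iiv_cv = iiv_cv,
                 residual = c(prop = unname(residual["prop"]),
                              add = unname(residual["add"])),
                 lloq = lloq), class = "pop_pk_model")
}

#' Draw a cohort of subject-level parameters
#'
#' Lognormal perturbation of the typical values (geometric mean preserved).
#'
#' @param model a [pop_pk_model()].
#' @param n_subjects cohort size.
#' @param seed RNG seed.
#' @return data.frame with columns `subject`, `ka`, `ke`, `v_over_f`.
#' @export
draw_subjects <- function(model, n_subjects, seed = 1L) {
  if (n_subjects < 1) stop_validation("n_subjects must be at least 1")
  set.seed(seed)
  draw <- function(gm, cv) {
    if (cv == 0) rep(gm, n_subjects)
    else gm * exp(stats::rnorm(n_subjects, 0, sqrt(log1p(cv^2))))
  }
  data.frame(subject = sprintf("sub_%02d", seq_len(n_subjects)),
             ka = draw(model$typical$ka, model$iiv_cv[["ka"]]),
             ke = draw(model$typical$ke, model$iiv_cv[["ke"]]),
             v_over_f = draw(model$typical$v_over_f, model$iiv_cv[["v_over_f"]]))
}

#' Randomized sparse sampling allocation
#'
#' Assigns subjects to scheduled post-dose times so that every time is
#' covered by exactly `n_per_time` subjects and no subject exceeds
#' `max_draws_per_subject`, via a randomized least-loaded greedy pass
#' (times visited in random order; at each time the least-sampled eligible
#' subjects are chosen with random tie-breaking). All subjects are sampled
#' at baseline in addition.
#'
#' @param design a [study_design()].
#' @param n_subjects cohort size.
#' @param seed RNG seed.
#' @return object of class `allocation_plan`: data.frame `assignment`
#'   (subject index, time) plus the design.
#' @export
allocate_sparse <- function(design, n_subjects, seed = 1L) {
  n_times <- length(design$scheduled_times)
  need <- n_times * design$n_per_time
  if (design$n_per_time > n_subjects)
    stop_capacity("n_per_time (%d) exceeds the number of subjects (%d)",
                  design$n_per_time, n_subjects)
  if (n_subjects * design$max_draws_per_subject < need)
    stop_capacity(
      "capacity %d (= %d subjects x %d draws) below the %d draws required (%d times x %d per time)",
      n_subjects * design$max_draws_per_subject, n_subjects,
      design$max_draws_per_subject, need, n_times, design$n_per_time)
  set.seed(seed)
  load <- integer(n_subjects)
  rows <- vector("list", n_times)
  for (t in sample(seq_len(n_times))) {
    pick <- order(load, stats::runif(n_subjects))[seq_len(design$n_per_time)]
    load[pick] <- load[pick] + 1L
    rows[[t]] <- data.frame(subject_idx = sort(pick),
                            time = design$scheduled_times[t])
  }
  assignment <- do.call(rbind, rows)
  assignment <- assignment[order(assignment$time, assignment$subject_idx), ]
  rownames(assignment) <- NULL
  stopifnot(max(load) <= design$max_draws_per_subject)
  structure(list(assignment = assignment, design = design,
                 n_subjects = n_subjects, seed = seed),
            class = "allocation_plan")
}

#' @export
print.allocation_plan <- function(x, ...) {
  draws <- tabulate(x$assignment$subject_idx, x$n_subjects)
  cat(sprintf("Sparse allocation: %d draws over %d subjects (per-subject draws: %s)\n",
              nrow(x$assignment), x$n_subjects,
              paste(names(table(draws)), table(draws), sep = "x", collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic sparse dataset
#'
#' Simulates each subject's true concentration curve, samples it under a
#' random sparse allocation, applies residual error (proportional +
#' additive, truncated at 0), censors values below the LLOQ, and emits the
#' full (subject x time) grid with not-sampled markers for unallocated
#' cells plus a baseline zero for every subject — the same shape as the
#' study table. One seed governs cohort, allocation and noise through
#' independent derived streams.
#'
#' @param model a [pop_pk_model()].
#' @param design a [study_design()].
#' @param n_subjects cohort size (default 14).
#' @param seed RNG seed.
#' @param blq `"censor"` (below-LLOQ cells become not-sampled) or `"zero"`.
#' @return a [concentration_records()] table.
#' @export
generate_dataset <- function(model, design, n_subjects = 14, seed = 1L,
                             blq = c("censor", "zero")) {
  blq <- match.arg(blq)
  cohort <- draw_subjects(model, n_subjects, derive_seed(seed, 0))
  plan <- allocate_sparse(design, n_subjects, derive_seed(seed, 1))
  set.seed(derive_seed(seed, 2))
  a <- plan$assignment
  true <- vapply(seq_len(nrow(a)), function(i) {
    p <- onecomp_params(cohort$ka[a$subject_idx[i]], cohort$ke[a$subject_idx[i]],
                        cohort$v_over_f[a$subject_idx[i]],
                        model$typical$dose_mg_per_kg)
    predict_concentration(p, a$time[i])
  }, numeric(1))
  eps_p <- stats::rnorm(nrow(a)); eps_a <- stats::rnorm(nrow(a))
  obs <- pmax(0, true * (1 + model$residual[["prop"]] * eps_p) +
                 model$residual[["add"]] * eps_a)
  below <- obs < model$lloq
  grid <- expand.grid(subject_idx = seq_len(n_subjects),
                      time = c(0, design$scheduled_times))
  key <- paste(a$subject_idx, a$time)
  gkey <- paste(grid$subject_idx, grid$time)
  conc <- rep(NA_real_, nrow(grid))
  conc[grid$time == 0] <- 0
  hit <- match(gkey, key)
  sampled <- !is.na(hit)
  conc[sampled] <- obs[hit[sampled]]
  if (blq == "censor") conc[sampled][below[hit[sampled]]] <- NA_real_
  else conc[sampled][below[hit[sampled]]] <- 0
  concentration_records(cohort$subject[grid$subject_idx], grid$time, conc)
}

#' Write a dataset with its manifest
#'
#' Emits the dataset CSV (long or wide) and a JSON manifest recording the
#' generating model, design and seed, so a run is reproducible from its
#' artifacts alone.
#'
#' @param records a [concentration_records()] table.
#' @param dir output directory (created if needed).
#' @param model,design,seed provenance recorded in the manifest.
#' @param format CSV dialect.
#' @return the dataset path, invisibly.
#' @export
write_dataset <- function(records, dir, model, design, seed,
                          format = c("long", "wide")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0("dataset_", format, ".csv"))
  write_concentration_table(records, path, format)
  manifest <- list(
    model = list(typical = unclass(model$typical), iiv_cv = as.list(model$iiv_cv),
                 residual = as.list(model$residual), lloq = model$lloq),
    design = unclass(design), n_subjects = length(unique(records$subject)),
    seed = seed, format = format)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Parameter-recovery harness
#'
#' Repeats generate -> pool -> NCA -> one-compartment fit over replicate
#' synthetic studies and reports median relative bias and relative RMSE of
#' the recovered quantities against the generating truth (lambda-z, AUC0-inf,
#' Cmax, t1/2 from NCA; ka, ke, V/F from the fit). NCA quantities on a
#' sparse grid carry discretization bias relative to the continuous truth;
#' they are reported separately from the fit parameters, which are directly
#' comparable.
#'
#' @param model a [pop_pk_model()].
#' @param design a [study_design()].
#' @param n_subjects cohort size per replicate.
#' @param n_replicates number of replicate studies (0 gives an empty report).
#' @param seed RNG seed governing all replicates.
#' @return object of class `recovery_report`: data.frame with columns
#'   `parameter`, `estimator`, `truth`, `median_rel_bias`, `rel_rmse`,
#'   `n_ok`, plus attribute `n_replicates`.
#' @export
end_to_end_recovery <- function(model, design, n_subjects = 14,
                                n_replicates = 200, seed = 1L) {
  truth_sec <- secondary_parameters(model$typical)
  truth <- c(lambda_z = model$typical$ke, auc_0_inf = truth_sec$auc_0_inf,
             cmax = truth_sec$cmax, t_half = truth_sec$t_half,
             ka = model$typical$ka, ke = model$typical$ke,
             v_over_f = model$typical$v_over_f)
  est_names <- c(rep("nca", 4), rep("fit", 3))
  if (n_replicates == 0) {
    out <- data.frame(parameter = character(), estimator = character(),
                      truth = numeric(), median_rel_bias = numeric(),
                      rel_rmse = numeric(), n_ok = integer())
    attr(out, "n_replicates") <- 0L
    class(out) <- c("recovery_report", "data.frame")
    return(out)
  }
  set.seed(seed)
  rep_seeds <- sample.int(2147480000L, n_replicates)
  rel <- matrix(NA_real_, n_replicates, length(truth),
                dimnames = list(NULL, names(truth)))
  for (r in seq_len(n_replicates)) {
    recs <- generate_dataset(model, design, n_subjects, rep_seeds[r])
    prof <- tryCatch(pool(recs), pooledPK_error = function(e) NULL)
    if (is.null(prof)) next
    nca <- tryCatch(run_nca(prof), pooledPK_error = function(e) NULL)
    if (!is.null(nca)) {
      rel[r, "lambda_z"] <- nca$lambda_fit$lambda_z / truth["lambda_z"] - 1
      rel[r, "auc_0_inf"] <- nca$auc_0_inf / truth["auc_0_inf"] - 1
      rel[r, "cmax"] <- nca$cmax / truth["cmax"] - 1
      rel[r, "t_half"] <- nca$lambda_fit$t_half / truth["t_half"] - 1
    }
    fit <- tryCatch(fit_onecomp(prof, model$typical$dose_mg_per_kg),
                    pooledPK_error = function(e) NULL)
    if (!is.null(fit)) {
      rel[r, "ka"] <- fit$params$ka / truth["ka"] - 1
      rel[r, "ke"] <- fit$params$ke / truth["ke"] - 1
      rel[r, "v_over_f"] <- fit$params$v_over_f / truth["v_over_f"] - 1
    }
  }
  out <- data.frame(
    parameter = names(truth), estimator = est_names, truth = unname(truth),
    median_rel_bias = apply(rel, 2, stats::median, na.rm = TRUE),
    rel_rmse = apply(rel, 2, function(x) sqrt(mean(x^2, na.rm = TRUE))),
    n_ok = apply(rel, 2, function(x) sum(!is.na(x))), row.names = NULL)
  attr(out, "n_replicates") <- n_replicates
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicate synthetic studies\n",
              attr(x, "n_replicates") %||% nrow(x)))
  df <- as.data.frame(x)
  df$median_rel_bias <- signif(df$median_rel_bias, 3)
  df$rel_rmse <- signif(df$rel_rmse, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
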