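decision_features <- c("nihss", "age_80plus", "onset_precise",
                       "anticoagulant", "prestroke_mrs", "t_oa", "t_as",
                       "arrival_by_ambulance", "ischemic")

# Sentinel arrival-to-scan value for never-scanned patients; far beyond any
# plausible scan time, so tree splits treat "not scanned" as its own region.
SCAN_MISSING_SENTINEL <- 10000

#' Patients eligible for decision modelling
#'
#' The modelling population is restricted to out-of-hospital-onset strokes
#' arriving within 4 hours of a known onset time.  No feature that directly
#' encodes whether thrombolysis was given enters the feature set.
#'
#' @param patients patient table.
#' @param arrival_window minutes from onset to arrival (default 240).
#' @return the eligible subset, with missing arrival-to-scan times replaced
#'   by a large sentinel.
#' @export
ml_eligible <- function(patients, arrival_window = 240) {
  out <- patients[patients$out_of_hospital_onset == 1 &
                    patients$onset_known == 1 &
                    !is.na(patients$t_oa) &
                    patients$t_oa <= arrival_window, ]
  out$t_as[is.na(out$t_as)] <- SCAN_MISSING_SENTINEL
  out
}

#' Train one hospital's thrombolysis decision model
#'
#' A probability random forest (100 trees, unrestricted depth, fixed seed)
#' over the eligible patients of one hospital, predicting whether
#' thrombolysis was given from `nihss`, `age_80plus`, `onset_precise`,
#' `anticoagulant`, `prestroke_mrs`, `t_oa`, `t_as`,
#' `arrival_by_ambulance` and stroke type (`ischemic`).  Hospitals whose eligible patients are all
#' treated or all untreated get a degenerate constant model.  Refitting
#' with the same seed reproduces identical predictions.
#'
#' @param patients patient table (whole system or one hospital).
#' @param hospital_id hospital to train.
#' @param exclude_ids patient ids to withhold from training (e.g. the
#'   held-out cohort pool).
#' @param seed integer seed for the forest.
#' @param num_trees number of trees.
#' @param min_patients refuse to fit below this many eligible patients.
#' @return an object of class `decision_model`.
#' @export
train_hospital_model <- function(patients, hospital_id, exclude_ids = NULL,
                                 seed = 1L, num_trees = 100L,
                                 min_patients = 25L) {
  pts <- ml_eligible(patients)
  pts <- pts[pts$hospital_id == hospital_id, ]
  if (!is.null(exclude_ids)) pts <- pts[!pts$patient_id %in% exclude_ids, ]
  if (nrow(pts) < min_patients) {
    stop(sprintf("hospital '%s': only %d eligible training patients (< %d)",
                 hospital_id, nrow(pts), min_patients), call. = FALSE)
  }
  y <- factor(ifelse(pts$thrombolysis == 1, "yes", "no"),
              levels = c("no", "yes"))
  if (length(unique(y)) == 1) {
    fit <- NULL
    constant <- as.character(unique(y))
  } else {
    fit <- ranger::ranger(
      x = as.data.frame(pts[decision_features]), y = y,
      num.trees = num_trees, probability = TRUE,
      seed = seed, num.threads = 1
    )
    constant <- NULL
  }
  structure(list(
    hospital_id = hospital_id,
    fit = fit,
    constant = constant,
    features = decision_features,
    training_size = nrow(pts),
    seed = seed,
    num_trees = num_trees
  ), class = "decision_model")
}

#' @export
print.decision_model <- function(x, ...) {
  cat(sprintf("<decision_model> %s: %s, trained on %d patients\n",
              x$hospital_id,
              if (is.null(x$fit)) paste0("constant '", x$constant, "'")
              else sprintf("random forest (%d trees)", x$num_trees),
              x$training_size))
  invisible(x)
}

#' Predicted probability of treatment under a hospital's model
#'
#' @param model a `decision_model`.
#' @param patients patient feature rows (missing arrival-to-scan times are
#'   sentinel-coded as in training).
#' @return numeric vector of treatment probabilities.
#' @export
predict_treatment_prob <- function(model, patients) {
  stopifnot(inherits(model, "decision_model"))
  missing_f <- setdiff(model$features, names(patients))
  if (length(missing_f)) {
    stop("missing feature(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(patients[model$features])
  x$t_as[is.na(x$t_as)] <- SCAN_MISSING_SENTINEL
  if (anyNA(x)) stop("feature values must be complete", call. = FALSE)
  if (is.null(model$fit)) {
    return(rep(if (model$constant == "yes") 1 else 0, nrow(x)))
  }
  p <- predict(model$fit, data = x, num.threads = 1)$predictions
  unname(p[, "yes"])
}

#' @rdname predict_treatment_prob
#' @param threshold classification threshold on the treatment probability.
#' @return `predict_treatment()` returns a 0/1 vector.
#' @export
predict_treatment <- function(model, patients, threshold = 0.5) {
  as.integer(predict_treatment_prob(model, patients) >= threshold)
}

#' Sensitivity/specificity crossing point
#'
#' As the classification threshold sweeps from 0 to 1, sensitivity falls
#' and specificity rises; the crossing is the largest value the two can
#' attain together.  Both curves are evaluated at every distinct predicted
#' probability and interpolated linearly between the adjacent thresholds
#' that bracket the crossing.
#'
#' @param probs predicted probabilities of the positive class.
#' @param labels 0/1 observed labels.
#' @return the common sensitivity = specificity value.
#' @export
sens_spec_crossing <- function(probs, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to locate the crossing",
         call. = FALSE)
  }
  thr <- sort(unique(c(0, probs, 1)))
  sens <- vapply(thr, function(t) mean(probs[labels == 1] >= t), 0)
  spec <- vapply(thr, function(t) mean(probs[labels == 0] < t), 0)
  d <- sens - spec
  if (d[1] <= 0) return(sens[1])
  if (d[length(d)] > 0) return(sens[length(d)])
  i <- max(which(d > 0)) # d[i] > 0 >= d[i + 1]
  a <- d[i] / (d[i] - d[i + 1])
  sens[i] + a * (sens[i + 1] - sens[i])
}

rank_auc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated accuracy of a hospital decision model
#'
#' Stratified k-fold cross-validation over one hospital's eligible
#' patients, refitting the forest with the model's own hyperparameters on
#' each training split.  Reports fold-averaged accuracy (0.5 threshold),
#' ROC area under the curve (rank statistic), and the
#' sensitivity-equals-specificity crossing value.
#'
#' @param model a `decision_model` (supplies hospital and hyperparameters).
#' @param patients patient table containing the hospital's patients.
#' @param k number of folds (>= 2).
#' @return a list with `accuracy`, `roc_auc`, `sens_eq_spec`, `n`.
#' @export
evaluate_model <- function(model, patients, k = 5) {
  stopifnot(inherits(model, "decision_model"), k >= 2)
  pts <- ml_eligible(patients)
  pts <- pts[pts$hospital_id == model$hospital_id, ]
  y <- as.integer(pts$thrombolysis)
  if (length(unique(y)) < 2) {
    stop("cross-validated metrics are undefined with a single class",
         call. = FALSE)
  }
  if (min(table(y)) < k) {
    stop(sprintf("minority class has %d cases; cannot stratify %d folds",
                 min(table(y)), k), call. = FALSE)
  }
  fold <- stratified_folds(y, k, model$seed)
  metrics <- lapply(seq_len(k), function(f) {
    tr <- pts[fold != f, ]
    te <- pts[fold == f, ]
    fit <- ranger::ranger(
      x = as.data.frame(tr[model$features]),
      y = factor(ifelse(tr$thrombolysis == 1, "yes", "no"),
                 levels = c("no", "yes")),
      num.trees = model$num_trees, probability = TRUE,
      seed = model$seed + f, num.threads = 1
    )
    p <- predict(fit, data = as.data.frame(te[model$features]),
                 num.threads = 1)$predictions[, "yes"]
    yt <- as.integer(te$thrombolysis)
    c(accuracy = mean((p >= 0.5) == (yt == 1)),
      roc_auc = rank_auc(p, yt),
      sens_eq_spec = sens_spec_crossing(p, yt))
  })
  m <- colMeans(do.call(rbind, metrics))
  list(accuracy = m[["accuracy"]], roc_auc = m[["roc_auc"]],
       sens_eq_spec = m[["sens_eq_spec"]], n = nrow(pts))
}

#' Hospital-stratified holdout split
#'
#' Marks a fixed-seed fraction of each hospital's eligible patients as held
#' out.  Models are trained with these patients excluded, which guarantees
#' that a cohort drawn from the holdout pool was never seen in training.
#'
#' @param patients patient table.
#' @param prop held-out fraction per hospital.
#' @param seed integer seed.
#' @return character vector of held-out `patient_id`s.
#' @export
holdout_split <- function(patients, prop = 0.2, seed = 1L) {
  assert_proportion(prop, "prop")
  pts <- ml_eligible(patients)
  set.seed(seed)
  unlist(lapply(split(pts$patient_id, pts$hospital_id), function(ids) {
    sample(ids, size = round(prop * length(ids)))
  }), use.names = FALSE)
}

#' Draw the shared evaluation cohort
#'
#' A fixed-seed sample (without replacement) of eligible patients from the
#' held-out pool across all hospitals.  Every hospital model scores this
#' same cohort, and by construction none of its rows were used in training.
#'
#' @param patients patient table.
#' @param size cohort size.
#' @param holdout_ids patient ids from [holdout_split()].
#' @param seed integer seed.
#' @return tibble of cohort patients.
#' @export
build_cohort <- function(patients, size, holdout_ids, seed = 1L) {
  pts <- ml_eligible(patients)
  pool <- pts[pts$patient_id %in% holdout_ids, ]
  if (size > nrow(pool)) {
    stop(sprintf("cohort of %d requested but only %d held-out patients",
                 size, nrow(pool)), call. = FALSE)
  }
  if (size == 0) return(pool[0, ])
  set.seed(seed)
  pool[sample(nrow(pool), size), ]
}

#' Select the benchmark hospitals
#'
#' Scores the shared cohort with every hospital model and ranks hospitals
#' by the fraction of the cohort predicted to be treated; the top
#' `n_benchmark` form the benchmark set whose majority vote defines the
#' benchmark decision.  Rate ties are broken by hospital id (ascending), so
#' membership does not depend on the order of the model list.
#'
#' @param models list of `decision_model`s.
#' @param cohort cohort table ([build_cohort()]).
#' @param n_benchmark number of benchmark hospitals (default 30).
#' @return an object of class `benchmark_set`: members, their models and
#'   the predicted cohort rates of all hospitals.
#' @export
select_benchmark <- function(models, cohort, n_benchmark = 30) {
  if (length(models) < n_benchmark) {
    stop(sprintf("%d models supplied but %d benchmark hospitals requested",
                 length(models), n_benchmark), call. = FALSE)
  }
  rates <- tibble::tibble(
    hospital_id = vapply(models, function(m) m$hospital_id, ""),
    cohort_rate = vapply(models, function(m) {
      mean(predict_treatment(m, cohort))
    }, 0)
  )
  ord <- order(-rates$cohort_rate, rates$hospital_id)
  members <- rates$hospital_id[ord][seq_len(n_benchmark)]
  names(models) <- rates$hospital_id
  structure(list(
    members = members,
    models = models[members],
    cohort_rates = rates[ord, ]
  ), class = "benchmark_set")
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat(sprintf("<benchmark_set> %d hospitals, cohort rates %.1f%%-%.1f%%\n",
              length(x$members),
              100 * min(x$cohort_rates$cohort_rate[seq_along(x$members)]),
              100 * max(x$cohort_rates$cohort_rate[seq_along(x$members)])))
  invisible(x)
}

#' Benchmark majority-vote decision
#'
#' A patient "would receive thrombolysis" when strictly more than half of
#' the benchmark hospitals' models predict treatment; an exact tie counts
#' as no (the conservative reading of a majority).
#'
#' @param bench a `benchmark_set`.
#' @param patients patient feature rows.
#' @return 0/1 vector of benchmark decisions.
#' @export
benchmark_decide <- function(bench, patients) {
  stopifnot(inherits(bench, "benchmark_set"))
  votes <- vapply(bench$models, function(m) predict_treatment(m, patients),
                  integer(nrow(patients)))
  votes <- matrix(votes, nrow = nrow(patients))
  as.integer(rowSums(votes) > length(bench$models) / 2)
}

#' Benchmark thrombolysis rate for one hospital's patients
#'
#' The fraction of the hospital's treatment-eligible patients
#' (out-of-hospital onset, onset known, scanned within `eligibility_window`
#' minutes of onset) that the benchmark majority vote would treat.  The
#' denominator deliberately matches the one behind `p_treat_eligible`, so
#' the result can replace it directly in the Benchmark scenario.
#'
#' @param bench a `benchmark_set`.
#' @param patients the hospital's patients (any rows; the eligibility
#'   filter is applied internally).
#' @param eligibility_window minutes from onset within which the scan must
#'   have completed.
#' @return a proportion in `[0, 1]`.
#' @export
benchmark_rate <- function(bench, patients, eligibility_window = 240) {
  pts <- patients[patients$out_of_hospital_onset == 1 &
                    patients$onset_known == 1 &
                    !is.na(patients$t_oa) & !is.na(patients$t_as) &
                    (patients$t_oa + patients$t_as) <= eligibility_window, ]
  if (nrow(pts) == 0) {
    stop("no eligible patients to score against the benchmark",
         call. = FALSE)
  }
  mean(benchmark_decide(bench, pts))
}

#' Benchmark rates for every hospital
#'
#' @param bench a `benchmark_set`.
#' @param patients whole-system patient table.
#' @param eligibility_window minutes from onset within which the scan must
#'   have completed.
#' @return tibble with `hospital_id`, `benchmark_rate`.
#' @export
benchmark_rates_all <- function(bench, patients, eligibility_window = 240) {
  ids <- sort(unique(patients$hospital_id))
  tibble::tibble(
    hospital_id = ids,
    benchmark_rate = vapply(ids, function(id) {
      benchmark_rate(bench, patients[patients$hospital_id == id, ],
                     eligibility_window)
    }, 0)
  )
}

#' Between-hospital agreement profile
#'
#' For each cohort patient, every model casts a vote; the agreement share
#' is the fraction of models siding with the per-patient majority.  The
#' profile reports the fraction of patients whose agreement share reaches
#' `quorum`, overall and split by whether the patient actually received
#' thrombolysis.
#'
#' @param models list of `decision_model`s (>= 2).
#' @param cohort cohort table with observed `thrombolysis`.
#' @param quorum required agreement share (default 0.8).
#' @return a list with `overall`, `among_treated`, `among_untreated`.
#' @export
agreement_profile <- function(models, cohort, quorum = 0.8) {
  if (length(models) < 2) stop("need at least 2 models", call. = FALSE)
  votes <- vapply(models, function(m) predict_treatment(m, cohort),
                  integer(nrow(cohort)))
  votes <- matrix(votes, nrow = nrow(cohort))
  share_yes <- rowMeans(votes)
  agree <- pmax(share_yes, 1 - share_yes)
  ok <- agree >= quorum
  treated <- cohort$thrombolysis == 1
  list(
    overall = mean(ok),
    among_treated = if (any(treated)) mean(ok[treated]) else NA_real_,
    among_untreated = if (any(!treated)) mean(ok[!treated]) else NA_real_
  )
}
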