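#' Keep only subjects with a complete set of speed trials
#'
#' @param sig_set a `signature_set` (or any object with `vectors` and `meta`).
#' @param required_trials exact number of trials a subject must have.
#' @return the filtered `signature_set`.
#' @export
filter_complete_subjects <- function(sig_set, required_trials = 9) {
  counts <- table(sig_set$meta$subject_id)
  keep_subj <- names(counts)[counts == required_trials]
  if (!length(keep_subj)) stop("no subject has the required number of trials")
  idx <- which(sig_set$meta$subject_id %in% keep_subj)
  subset_signatures(sig_set, idx)
}

subset_signatures <- function(sig_set, idx) {
  out <- sig_set
  out$vectors <- sig_set$vectors[idx, , drop = FALSE]
  out$loops <- sig_set$loops[idx]
  out$meta <- sig_set$meta[idx, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Seeded per-subject train/test split
#'
#' Per subject, `k_train` trials are drawn uniformly without replacement into
#' the training set; the remainder go to test. Deterministic given the seed
#' (the experiment sets the seed to the run number).
#'
#' @param sig_set a `signature_set`.
#' @param k_train training trials per subject (1 to trials-per-subject - 1).
#' @param seed integer seed.
#' @return list of integer row indices `train` and `test`.
#' @export
split_trials <- function(sig_set, k_train, seed) {
  subj <- sig_set$meta$subject_id
  per <- table(subj)
  if (k_train < 1 || any(k_train > per - 1))
    stop("k_train must be between 1 and trials_per_subject - 1")
  with_seed(seed, {
    train <- integer(0)
    for (s in unique(subj)) {
      rows <- which(subj == s)
      train <- c(train, sample(rows, k_train))
    }
    list(train = sort(train), test = setdiff(seq_along(subj), train))
  })
}

#' Train a linear SVM to identify subjects
#'
#' Features are z-scored with training-set statistics (applied unchanged at
#' test time; zero-variance columns are left unscaled) and fed to a
#' linear-kernel multiclass SVM (one-vs-one, cost 1).
#'
#' @param x training feature matrix (rows = trials).
#' @param labels subject labels.
#' @return object of class `identify_svm`.
#' @export
train_identify_svm <- function(x, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 subjects")
  if (any(table(labels) == 0)) stop("a class has no training samples")
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  fit <- e1071::svm(xs, labels, kernel = "linear", cost = 1, scale = FALSE)
  out <- list(fit = fit, center = center, scale = scale_,
              levels = levels(labels))
  class(out) <- "identify_svm"
  out
}

#' @param object an `identify_svm`.
#' @param newx feature matrix of test trials.
#' @param ... unused.
#' @rdname train_identify_svm
#' @export
predict.identify_svm <- function(object, newx, ...) {
  xs <- sweep(sweep(newx, 2, object$center), 2, object$scale, "/")
  predict(object$fit, xs)
}

# Shared protocol: for each k, n_runs seeded splits, accuracy pooled over all
# test trials; used for both signature vectors and discrete-variable tables.
run_identification <- function(x, subjects, k_range, n_runs, label,
                               permute_labels = FALSE, seed_offset = 0) {
  sig <- list(vectors = x, meta = data.frame(subject_id = subjects))
  res <- list(); conf <- list()
  for (k in k_range) {
    for (run in seq_len(n_runs)) {
      sp <- split_trials(sig, k, run + seed_offset)
      lab_train <- subjects[sp$train]
      if (permute_labels)
        lab_train <- with_seed(derive_seed(run + seed_offset, 17),
                               sample(lab_train))
      cls <- train_identify_svm(x[sp$train, , drop = FALSE], lab_train)
      pred <- predict(cls, x[sp$test, , drop = FALSE])
      truth <- factor(subjects[sp$test], levels = cls$levels)
      acc <- mean(as.character(pred) == as.character(truth))
      res[[length(res) + 1]] <- data.frame(label = label, k = k, run = run,
                                           accuracy = acc)
      conf[[paste0("k", k, "_run", run)]] <- table(truth = truth, pred = pred)
    }
  }
  results <- do.call(rbind, res)
  summary <- do.call(rbind, lapply(split(results, results$k), function(d) {
    data.frame(label = label, k = d$k[1], mean_accuracy = mean(d$accuracy),
               ci_lo = unname(quantile(d$accuracy, 0.025)),
               ci_hi = unname(quantile(d$accuracy, 0.975)),
               n_runs = nrow(d))
  }))
  rownames(summary) <- NULL
  out <- list(results = results, summary = summary, confusions = conf,
              label = label)
  class(out) <- "classification_result"
  out
}

#' Speed-generalization identification experiment
#'
#' For each training-set size `k`, `n_runs` seeded splits (seed = run number)
#' are drawn, a linear SVM is trained on `k` trials per subject, and accuracy
#' is pooled over all test trials. Mean accuracy and the 2.5/97.5 percentile
#' interval across runs are reported per `k`.
#'
#' @param sig_set a complete-subject `signature_set`.
#' @param k_range training-set sizes to sweep.
#' @param n_runs runs (seeded splits) per `k`.
#' @param label tag recorded in the result tables (e.g. the data type).
#' @param permute_labels permute training labels within each run (chance-level
#'   control).
#' @return object of class `classification_result` with `results`
#'   (label, k, run, accuracy), `summary` and per-run confusion matrices.
#' @export
speed_generalization_experiment <- function(sig_set, k_range = 1:8,
                                            n_runs = 140,
                                            label = "signatures",
                                            permute_labels = FALSE) {
  run_identification(sig_set$vectors, sig_set$meta$subject_id, k_range,
                     n_runs, label, permute_labels)
}

#' Identification baseline from discrete-variable tables
#'
#' Applies the same seeded SVM protocol as
#' [speed_generalization_experiment()] to a discrete-variable table.
#'
#' @param table data.frame from [cohort_discrete_table()] (metadata columns
#'   `trial_id`, `subject_id`, `speed` plus feature columns) or a plain
#'   feature matrix.
#' @param subjects subject labels (taken from the table when omitted).
#' @param k_range,n_runs protocol parameters.
#' @param label tag for the result tables.
#' @return a `classification_result`.
#' @export
baseline_discrete_experiment <- function(table, subjects = NULL,
                                         k_range = 1:8, n_runs = 140,
                                         label = "discrete") {
  if (is.data.frame(table)) {
    if (is.null(subjects)) subjects <- table$subject_id
    feat <- as.matrix(table[, setdiff(names(table),
                                      c("trial_id", "subject_id", "speed")),
                            drop = FALSE])
  } else {
    feat <- as.matrix(table)
    if (is.null(subjects)) stop("subjects must be supplied with a matrix")
  }
  run_identification(feat, subjects, k_range, n_runs, label)
}

#' Compare two accuracy distributions (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test with effect size r, defined as
#' `Z / sqrt(n_a + n_b)`;
#' Z is the tie-corrected normal approximation, signed by the direction of
#' `a` relative to `b`. The reported U counts pairs where `a > b` (plus half
#' the ties), i.e. the `wilcox.test` W convention.
#'
#' @param acc_a,acc_b accuracy samples.
#' @return list with `U`, `p`, `effect_r`, `n_a`, `n_b`.
#' @export
compare_accuracy_distributions <- function(acc_a, acc_b) {
  if (!length(acc_a) || !length(acc_b)) stop("empty accuracy sample")
  wt <- suppressWarnings(wilcox.test(acc_a, acc_b, exact = FALSE, correct = FALSE))
  n1 <- length(acc_a); n2 <- length(acc_b); n <- n1 + n2
  U <- unname(wt$statistic)
  mu <- n1 * n2 / 2
  ties <- table(c(acc_a, acc_b))
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sig2 > 0) (U - mu) / sqrt(sig2) else 0
  list(U = U, p = wt$p.value, effect_r = z / sqrt(n), n_a = n1, n_b = n2)
}
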