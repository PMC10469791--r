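#' Evaluation scenario splits
#'
#' Realizes the four session-based evaluation protocols:
#'
#' * `within_session`: stratified k-fold cross-validation on one session; in
#'   each fold one fold is the test set, one of the remaining folds (rotating)
#'   is the validation set and the rest train.
#' * `cross_session_case1`: train on all of session 1; session 2 is split in
#'   recorded order into two equal phases, the first for validation and the
#'   second for test.
#' * `cross_session_case2`: train and validate (stratified 20% held out) on
#'   session 1 only; ALL of session 2 is the test set.
#' * `two_session`: stratified k-fold over both sessions pooled.
#'
#' Session-2 trials never appear in any training set of the cross-session
#' scenarios.
#'
#' @param dataset an `lgct_epochs` carrying session ids.
#' @param scenario one of `"within_session"`, `"cross_session_case1"`,
#'   `"cross_session_case2"`, `"two_session"`.
#' @param k_folds number of CV folds (k-fold scenarios).
#' @param seed seed for the stratified shuffles.
#' @param session which session a `within_session` split uses.
#' @return An object of class `lgct_split`: list with `scenario` and `folds`,
#'   each fold a list of disjoint integer index vectors `train`, `val`,
#'   `test` into the trials of `dataset`.
#' @export
make_splits <- function(dataset, scenario = c("within_session",
                                              "cross_session_case1",
                                              "cross_session_case2",
                                              "two_session"),
                        k_folds = 10L, seed = 1L, session = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(dataset, "lgct_epochs"))
  sessions <- dataset$sessions
  labels <- dataset$labels
  need_two <- scenario %in% c("cross_session_case1", "cross_session_case2")
  if (need_two && length(unique(sessions)) < 2L)
    stop("scenario ", scenario, " requires two sessions; dataset has ",
         length(unique(sessions)))
  set.seed(seed)
  folds <- switch(scenario,
    within_session = {
      pool <- which(sessions == session)
      if (length(pool) == 0L) stop("no trials in session ", session)
      kfold_rotating(pool, labels[pool], k_folds)
    },
    two_session = kfold_rotating(seq_along(labels), labels, k_folds),
    cross_session_case1 = {
      s1 <- which(sessions == 1L)
      s2 <- which(sessions == 2L)
      half <- floor(length(s2) / 2)
      list(list(train = s1, val = s2[seq_len(half)],
                test = s2[(half + 1L):length(s2)]))
    },
    cross_session_case2 = {
      s1 <- which(sessions == 1L)
      s2 <- which(sessions == 2L)
      val <- stratified_sample(labels[s1], frac = 0.2)
      list(list(train = s1[-val], val = s1[val], test = s2))
    })
  structure(list(scenario = scenario, folds = folds,
                 n_trials = n_trials(dataset)), class = "lgct_split")
}

# stratified k folds over `pool`; fold i tests on fold i, validates on fold
# (i %% k) + 1 and trains on the rest
kfold_rotating <- function(pool, labels, k) {
  assign_fold <- integer(length(pool))
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    if (length(members) < k)
      stop("class ", cl, " has fewer trials (", length(members),
           ") than folds (", k, ")")
    members <- sample(members)
    assign_fold[members] <- rep_len(seq_len(k), length(members))
  }
  lapply(seq_len(k), function(i) {
    v <- (i %% k) + 1L
    list(train = pool[!assign_fold %in% c(i, v)],
         val = pool[assign_fold == v],
         test = pool[assign_fold == i])
  })
}

stratified_sample <- function(labels, frac) {
  unlist(lapply(unique(labels), function(cl) {
    members <- which(labels == cl)
    sample(members, max(1L, round(frac * length(members))))
  }), use.names = FALSE)
}

#' Check a split for leakage
#'
#' Asserts that within every fold train/val/test are pairwise disjoint, and
#' that cross-session scenarios place no session-2 trial in any training set.
#'
#' @param split an [make_splits()] result.
#' @param dataset the `lgct_epochs` the split was made from.
#' @return `TRUE` invisibly; stops on violation.
#' @export
check_no_leakage <- function(split, dataset) {
  for (f in split$folds) {
    if (length(intersect(f$train, f$test)) ||
        length(intersect(f$train, f$val)) ||
        length(intersect(f$val, f$test)))
      stop("leakage: overlapping train/val/test sets in scenario ",
           split$scenario)
    if (split$scenario %in% c("cross_session_case1", "cross_session_case2") &&
        any(dataset$sessions[f$train] == 2L))
      stop("leakage: session-2 trial in a cross-session training set")
  }
  invisible(TRUE)
}

#' Run an evaluation scenario end to end
#'
#' For each fold: build a freshly initialized model (fold-specific seed
#' derived from `seed`), train with early stopping, predict the test fold and
#' record accuracy. Aggregates the per-fold accuracies into mean and sample
#' (n-1) standard deviation.
#'
#' @param mb an `lgct_multiband` over the full dataset.
#' @param dataset the matching `lgct_epochs` (labels and sessions).
#' @param scenario scenario name, see [make_splits()].
#' @param model_cfg an [model_config()].
#' @param train_cfg a [train_config()].
#' @param k_folds folds for the CV scenarios.
#' @param seed root seed: split seed and per-fold model/train seeds derive
#'   from it.
#' @param folds_to_run optional subset of fold indices (compute control).
#' @param montage montage for [build_model()]; defaults to the dataset's.
#' @param keep_last_model if `TRUE`, the trained model of the last fold run
#'   is returned as `last_model` (for checkpointing).
#' @return An object of class `lgct_result`: list with `scenario`,
#'   `fold_accuracy` (%), `mean_accuracy`, `sd_accuracy`, `histories`.
#' @export
run_scenario <- function(mb, dataset, scenario, model_cfg, train_cfg,
                         k_folds = 10L, seed = 1L, folds_to_run = NULL,
                         montage = NULL, keep_last_model = FALSE) {
  split <- make_splits(dataset, scenario, k_folds = k_folds, seed = seed)
  check_no_leakage(split, dataset)
  if (is.null(montage)) montage <- dataset$montage
  run_idx <- if (is.null(folds_to_run)) seq_along(split$folds)
             else as.integer(folds_to_run)
  accs <- numeric(0)
  histories <- list()
  last_model <- NULL
  for (i in run_idx) {
    f <- split$folds[[i]]
    fold_seed <- (as.numeric(seed) * 1009 + i * 9973) %% 2147483647
    mcfg <- model_cfg
    mcfg$seed <- as.integer(fold_seed)
    model <- build_model(mcfg, montage = montage)
    tcfg <- train_cfg
    tcfg$seed <- as.integer((fold_seed + 1L) %% 2147483647L)
    fit <- train_model(model,
                       list(data = subset_multiband(mb, f$train),
                            labels = dataset$labels[f$train]),
                       list(data = subset_multiband(mb, f$val),
                            labels = dataset$labels[f$val]),
                       tcfg)
    pred <- predict_model(fit$model, subset_multiband(mb, f$test))
    accs <- c(accs, accuracy(pred$labels, dataset$labels[f$test]))
    histories[[length(histories) + 1L]] <- fit$history
    if (keep_last_model) last_model <- fit$model
  }
  structure(list(scenario = scenario, fold_accuracy = accs,
                 mean_accuracy = mean(accs),
                 sd_accuracy = if (length(accs) > 1L) stats::sd(accs) else 0,
                 folds_run = run_idx, histories = histories,
                 last_model = last_model),
            class = "lgct_result")
}

#' @export
print.lgct_result <- function(x, ...) {
  cat(sprintf("<lgct_result> %s: mean accuracy %.2f%% (SD %.2f) over %d fold(s)\n",
              x$scenario, x$mean_accuracy, x$sd_accuracy,
              length(x$fold_accuracy)))
  invisible(x)
}

#' Paired t-test between two per-subject accuracy vectors
#'
#' Two-sided paired t-test on the differences, reported together with the
#' Pearson correlation of the pair.
#'
#' @param acc_a,acc_b equal-length (>= 2) numeric vectors paired by subject.
#' @return List with `t`, `df`, `p`, `correlation`.
#' @export
paired_ttest <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b), length(acc_a) >= 2L)
  d <- acc_a - acc_b
  if (stats::sd(d) == 0) {
    if (mean(d) != 0)
      stop("degenerate paired t-test: constant nonzero differences")
    return(list(t = 0, df = length(d) - 1L, p = 1,
                correlation = stats::cor(acc_a, acc_b)))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, correlation = stats::cor(acc_a, acc_b))
}
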