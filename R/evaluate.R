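#' Cross-validation and classification metrics
#'
#' The evaluation harness treats the ranker as an ordinary classifier: the
#' highest-belief candidate is the prediction, an empty ranking (no
#' applicable rule, or a total-conflict fold) counts as an incorrect
#' prediction and is never excluded from the denominator, so accuracies are
#' comparable with baselines that always predict. Folds are stratified by
#' diagnosis so every fold sees a fair share of each disorder's cases.
#'
#' Metrics follow the standard definitions over the pooled test predictions:
#' accuracy = 100 L / N with L the number of correct top-1 predictions and N
#' the number of evaluated cases; per-class precision = correct_i /
#' (predictions of class i), per-class recall = correct_i / N_i; macro
#' precision/recall are unweighted means over the classes present in the
#' test data, with precision 0 by convention for a class that is never
#' predicted.
#'
#' @name evaluation
NULL

#' Stratified k-fold split
#'
#' Cases are grouped by diagnosis, each group is shuffled with the given
#' seed and dealt round-robin into folds, so per-fold class counts differ by
#' at most one from perfect stratification and the whole split is a pure
#' function of (collection, k, seed). A round-robin pointer carries over
#' between classes to balance overall fold sizes.
#'
#' @param collection a \code{case_collection}.
#' @param k number of folds (default 5).
#' @param seed integer RNG seed.
#' @return list of k elements, each a list with integer case indices
#'   \code{train} and \code{test}; test folds are disjoint and their union
#'   covers the collection.
#' @export
kfold_split <- function(collection, k = 5L, seed = 1L) {
  stopifnot(inherits(collection, "case_collection"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  diag <- vapply(collection$cases, `[[`, "", "diagnosis")
  diag[is.na(diag)] <- "<undiagnosed>"
  tab <- table(diag)
  if (any(tab < k)) {
    warning(sprintf("%d class(es) have fewer than k = %d cases; their cases cannot appear in every fold",
                    sum(tab < k), k), call. = FALSE)
  }
  fold_of <- integer(collection$N)
  ptr <- 0L
  with_seed(seed, {
    for (cls in sort(unique(diag))) {
      idx <- which(diag == cls)
      idx <- idx[sample.int(length(idx))]
      for (i in idx) {
        fold_of[[i]] <- (ptr %% k) + 1L
        ptr <- ptr + 1L
      }
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

# evaluate an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Classification metrics from truth/prediction pairs
#'
#' @param truth character vector of true disorder symbols.
#' @param predicted character vector of predicted symbols; \code{NA} marks a
#'   case where the model made no prediction (counted as incorrect).
#' @return a list with \code{accuracy}, \code{macro_precision},
#'   \code{macro_recall} (percentages) and a \code{per_class} data.frame
#'   (class, n_cases, correct, incorrect_predictions, precision, recall).
#' @export
classification_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  N <- length(truth)
  classes <- sort(unique(truth))
  per <- lapply(classes, function(cl) {
    n_i <- sum(truth == cl)
    correct <- sum(!is.na(predicted) & predicted == cl & truth == cl)
    wrong_pred <- sum(!is.na(predicted) & predicted == cl & truth != cl)
    denom <- correct + wrong_pred
    data.frame(class = cl, n_cases = n_i, correct = correct,
               incorrect_predictions = wrong_pred,
               precision = if (denom > 0) 100 * correct / denom else 0,
               recall = 100 * correct / n_i,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(accuracy = 100 * sum(!is.na(predicted) & predicted == truth) / N,
       macro_precision = mean(per$precision),
       macro_recall = mean(per$recall),
       per_class = per)
}

#' Cross-validated evaluation of a diagnosis model
#'
#' Runs stratified k-fold cross-validation: for each fold the model is
#' trained on the train split only and issues a top-1 prediction for every
#' test case. Reports per-fold metrics, their mean, and pooled metrics over
#' the union of test predictions.
#'
#' @param collection a \code{case_collection} with diagnosed cases.
#' @param method \code{"dst"} (rule mining + evidential ranking),
#'   \code{"naive_bayes"} (Laplace-smoothed Bernoulli baseline) or
#'   \code{"majority"} (most frequent training class).
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold split.
#' @param folds optionally, a precomputed split from \code{\link{kfold_split}}
#'   (overrides \code{k}/\code{seed}).
#' @param min_support_count,max_itemset_size mining parameters for
#'   \code{method = "dst"}.
#' @return an \code{evaluation_report}: list with \code{accuracy},
#'   \code{macro_precision}, \code{macro_recall}, \code{per_class} (pooled),
#'   \code{fold_reports} (data.frame, one row per fold), \code{mean_fold}
#'   (means of the per-fold metrics), \code{method}, \code{n_evaluated}.
#' @export
evaluate_model <- function(collection, method = c("dst", "naive_bayes", "majority"),
                           k = 5L, seed = 1L, folds = NULL,
                           min_support_count = 2L, max_itemset_size = 10L) {
  method <- match.arg(method)
  stopifnot(inherits(collection, "case_collection"))
  if (is.null(folds)) folds <- kfold_split(collection, k = k, seed = seed)
  truth_all <- character(0)
  pred_all <- character(0)
  fold_rows <- list()
  for (f in seq_along(folds)) {
    train <- subset_cases(collection, folds[[f]]$train)
    test <- subset_cases(collection, folds[[f]]$test)
    truth <- vapply(test$cases, `[[`, "", "diagnosis")
    pred <- switch(method,
      dst = {
        fit <- evidence_model(train, min_support_count = min_support_count,
                              max_itemset_size = max_itemset_size)
        predict(fit, newdata = test, type = "class")
      },
      naive_bayes = {
        fit <- naive_bayes_fit(train)
        vapply(test$cases, function(cs) naive_bayes_predict(fit, cs$phenotypes), "")
      },
      majority = {
        cls <- majority_class(train)
        rep(cls, test$N)
      })
    m <- classification_metrics(truth, pred)
    fold_rows[[f]] <- data.frame(fold = f, n = test$N,
                                 accuracy = m$accuracy,
                                 macro_precision = m$macro_precision,
                                 macro_recall = m$macro_recall)
    truth_all <- c(truth_all, truth)
    pred_all <- c(pred_all, pred)
  }
  pooled <- classification_metrics(truth_all, pred_all)
  fold_reports <- do.call(rbind, fold_rows)
  structure(list(
    method = method,
    k = length(folds),
    n_evaluated = length(truth_all),
    accuracy = pooled$accuracy,
    macro_precision = pooled$macro_precision,
    macro_recall = pooled$macro_recall,
    per_class = pooled$per_class,
    fold_reports = fold_reports,
    mean_fold = colMeans(fold_reports[, c("accuracy", "macro_precision",
                                          "macro_recall")])
  ), class = "evaluation_report")
}

#' Most frequent training class (baseline)
#'
#' @param collection a \code{case_collection}.
#' @return the disorder symbol of the largest class; ties broken by symbol
#'   order.
#' @export
majority_class <- function(collection) {
  diag <- vapply(collection$cases, `[[`, "", "diagnosis")
  diag <- diag[!is.na(diag)]
  if (length(diag) == 0L) stop("no diagnosed cases", call. = FALSE)
  tab <- table(diag)
  names(tab)[order(-as.numeric(tab), names(tab))][[1]]
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, method = %s (%d cases)\n",
              x$k, x$method, x$n_evaluated))
  print(x$fold_reports, row.names = FALSE, digits = 4)
  cat(sprintf("pooled:  accuracy %.2f | macro precision %.2f | macro recall %.2f\n",
              x$accuracy, x$macro_precision, x$macro_recall))
  invisible(x)
}
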