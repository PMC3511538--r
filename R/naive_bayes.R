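#' Bernoulli naive Bayes baseline with Laplace smoothing
#'
#' The comparison baseline: a presence/absence naive Bayes classifier over
#' the phenotype vocabulary. Class priors are proportional to class counts.
#' Feature likelihoods get add-one (Laplace) smoothing,
#' \eqn{P(f | c) = (n_{fc} + 1) / (n_c + 2)}, so a phenotype never seen with
#' a class still receives non-zero probability — the standard fix for
#' zero counts in sparse data, and the contrast case for the evidential
#' approach, which needs no such estimator because ignorance has its own
#' representation there.
#'
#' @param train a \code{case_collection} with diagnosed cases.
#' @return an object of class \code{nb_model}.
#' @export
naive_bayes_fit <- function(train) {
  stopifnot(inherits(train, "case_collection"))
  diag <- vapply(train$cases, `[[`, "", "diagnosis")
  keep <- which(!is.na(diag))
  if (length(keep) == 0L) stop("no diagnosed cases to train on", call. = FALSE)
  diag <- diag[keep]
  cases <- train$cases[keep]
  classes <- sort(unique(diag))
  vocab <- sort(unique(unlist(lapply(cases, `[[`, "phenotypes"))))
  n_c <- vapply(classes, function(cl) sum(diag == cl), 0L)
  # n_fc: features x classes presence counts
  counts <- matrix(0L, nrow = length(vocab), ncol = length(classes),
                   dimnames = list(vocab, classes))
  for (i in seq_along(cases)) {
    counts[cases[[i]]$phenotypes, diag[[i]]] <-
      counts[cases[[i]]$phenotypes, diag[[i]]] + 1L
  }
  lik <- sweep(counts + 1, 2L, n_c + 2, "/")  # Laplace: (n_fc + 1)/(n_c + 2)
  structure(list(classes = classes,
                 vocab = vocab,
                 log_prior = log(n_c / sum(n_c)),
                 log_lik_present = log(lik),
                 log_lik_absent = log(1 - lik)),
            class = "nb_model")
}

#' Predict the most probable disorder for a query
#'
#' Scores each class by the log posterior over the full training vocabulary
#' (present and absent features both contribute, as in a Bernoulli event
#' model). Query phenotypes outside the vocabulary carry no information and
#' are ignored. Ties are broken by class symbol order, and a query with only
#' unseen phenotypes falls back to the prior argmax.
#'
#' @param model an \code{nb_model}.
#' @param query character vector of phenotype symbols.
#' @return the predicted disorder symbol.
#' @export
naive_bayes_predict <- function(model, query) {
  stopifnot(inherits(model, "nb_model"))
  present <- model$vocab %in% query
  scores <- model$log_prior +
    colSums(model$log_lik_present[present, , drop = FALSE]) +
    colSums(model$log_lik_absent[!present, , drop = FALSE])
  model$classes[[which.max(scores)]]  # which.max: first index, classes sorted
}

#' @export
print.nb_model <- function(x, ...) {
  cat("Bernoulli naive Bayes (Laplace-smoothed):",
      length(x$classes), "classes,", length(x$vocab), "features\n")
  invisible(x)
}
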