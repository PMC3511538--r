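#' Fit an evidential diagnosis model
#'
#' The canonical front door of the package: mines the rule base from an
#' encoded case collection and wraps it, with its dictionary and mining
#' parameters, into a model object that supports \code{predict} (candidate
#' ranking or top-1 class), \code{coef} (the rule table — the rules are the
#' model's coefficients), \code{print} and \code{summary}.
#'
#' @param collection a \code{case_collection} with diagnosed cases (see
#'   \code{\link{encode_cases}} / \code{\link{read_cases}}).
#' @param min_support_count absolute minimum support for itemset mining
#'   (default 2, i.e. relative support 2/N).
#' @param max_itemset_size maximum itemset size (default 10).
#' @param prune focal-set pruning threshold used at prediction time.
#' @return an object of class \code{evidence_model}.
#' @examples
#' cc <- encode_cases(data.frame(
#'   case_id = c("a", "b", "c"),
#'   diagnosis = c("Achondroplasia", "Achondroplasia", "Hypochondroplasia"),
#'   phenotypes = c("Dwarfism|Macrocephaly", "Dwarfism", "Short stature")))
#' fit <- evidence_model(cc)
#' predict(fit, newdata = list(c("Dwarfism")))
#' @export
evidence_model <- function(collection, min_support_count = 2L,
                           max_itemset_size = 10L, prune = 1e-12) {
  stopifnot(inherits(collection, "case_collection"))
  diag <- vapply(collection$cases, `[[`, "", "diagnosis")
  if (all(is.na(diag))) {
    stop("cannot fit a model: no case carries a diagnosis", call. = FALSE)
  }
  itemsets <- find_frequent_itemsets(collection,
                                     min_support_count = min_support_count,
                                     max_size = max_itemset_size)
  rules <- derive_rules(itemsets)
  structure(
    list(rules = rules,
         dictionary = collection$dictionary,
         n_itemsets = length(itemsets),
         n_train = collection$N,
         params = list(min_support_count = as.integer(min_support_count),
                       max_itemset_size = as.integer(max_itemset_size),
                       prune = prune),
         call = match.call()),
    class = "evidence_model")
}

#' @export
print.evidence_model <- function(x, ...) {
  cat("Evidential diagnosis model\n")
  cat("  trained on", x$n_train, "cases;", x$n_itemsets, "frequent itemsets,",
      length(x$rules), "evidence rules\n")
  cat("  min support", x$params$min_support_count,
      "| max itemset size", x$params$max_itemset_size, "\n")
  invisible(x)
}

#' @export
summary.evidence_model <- function(object, ...) {
  df <- as.data.frame(object$rules)
  out <- list(
    n_rules = nrow(df),
    n_train = object$n_train,
    params = object$params,
    confidence = if (nrow(df)) summary(df$confidence) else NULL,
    antecedent_size = if (nrow(df))
      table(lengths(strsplit(df$antecedent, "|", fixed = TRUE))) else NULL,
    rules_per_disorder = if (nrow(df)) table(df$consequent) else NULL
  )
  class(out) <- "summary.evidence_model"
  out
}

#' @export
print.summary.evidence_model <- function(x, ...) {
  cat("Evidential diagnosis model:", x$n_rules, "rules from", x$n_train,
      "cases\n")
  if (!is.null(x$confidence)) {
    cat("Rule confidence:\n"); print(x$confidence)
    cat("Antecedent sizes:\n"); print(x$antecedent_size)
  }
  invisible(x)
}

#' Extract the mined rule base
#'
#' @param object an \code{evidence_model}.
#' @param decode if \code{TRUE}, antecedent/consequent are returned as term
#'   strings instead of symbols.
#' @param ... unused.
#' @return a data.frame of rules with their support counts and confidences.
#' @export
coef.evidence_model <- function(object, decode = FALSE, ...) {
  df <- as.data.frame(object$rules)
  if (decode && nrow(df)) {
    dict <- object$dictionary
    df$antecedent <- vapply(strsplit(df$antecedent, "|", fixed = TRUE),
                            function(s) paste(decode_symbol(dict, s),
                                              collapse = "|"), "")
    df$consequent <- decode_symbol(dict, df$consequent)
  }
  df
}

#' Predict candidate disorders for new phenotype sets
#'
#' @param object an \code{evidence_model}.
#' @param newdata one of: a \code{case_collection}, a list of character
#'   vectors of phenotype symbols or terms, or a single character vector.
#'   Terms are resolved against the model dictionary; unknown terms simply
#'   match no rule.
#' @param type \code{"ranking"} (a \code{candidate_ranking} per query) or
#'   \code{"class"} (the top-1 disorder symbol per query, \code{NA} when
#'   there is no evidence or no decision).
#' @param ... unused.
#' @return a list of \code{candidate_ranking}s, or a character vector of
#'   disorder symbols, one element per query.
#' @export
predict.evidence_model <- function(object, newdata,
                                   type = c("ranking", "class"), ...) {
  type <- match.arg(type)
  queries <- .as_queries(object, newdata)
  rankings <- lapply(queries, function(q) {
    if (length(q) == 0L) {
      structure(list(query = q,
                     entries = data.frame(disorder = character(0),
                                          belief = numeric(0),
                                          plausibility = numeric(0),
                                          n_rules = integer(0)),
                     conflict_K = 0, status = "no_evidence"),
                class = "candidate_ranking")
    } else {
      rank_candidates(q, object$rules, prune = object$params$prune)
    }
  })
  if (type == "ranking") return(rankings)
  vapply(rankings, function(r) {
    if (r$status != "ok" || nrow(r$entries) == 0L) NA_character_
    else r$entries$disorder[[1]]
  }, "")
}

.as_queries <- function(object, newdata) {
  dict <- object$dictionary
  to_symbols <- function(x) {
    known <- x %in% names(dict$display)
    out <- character(0)
    for (i in seq_along(x)) {
      if (known[[i]]) out <- c(out, x[[i]])
      else {
        s <- encode_term(dict, x[[i]], "phenotype")
        if (!is.na(s)) out <- c(out, s)
      }
    }
    unique(out)
  }
  if (inherits(newdata, "case_collection")) {
    lapply(newdata$cases, function(cs) cs$phenotypes)
  } else if (is.list(newdata)) {
    lapply(newdata, to_symbols)
  } else if (is.character(newdata)) {
    list(to_symbols(newdata))
  } else {
    stop("newdata must be a case_collection, a list of phenotype vectors, ",
         "or a character vector", call. = FALSE)
  }
}
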