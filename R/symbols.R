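#' Symbolic encoding of patient cases
#'
#' Clinical decision support over sparse phenotype data works on an encoded
#' representation: every phenotype term (e.g. "Short stature") is mapped to a
#' phenotype symbol \code{S1, S2, ...} and every disorder term (e.g.
#' "Achondroplasia") to a disorder symbol \code{D1, D2, ...}. The two symbol
#' namespaces are disjoint, so any symbol decodes to exactly one term. Terms
#' are opaque string keys: matching is exact after whitespace trimming and
#' case folding, and no ontology structure is consulted.
#'
#' @name symbols
#' @keywords internal
NULL

.term_key <- function(x) tolower(trimws(x))

new_symbol_dictionary <- function() {
  structure(
    list(
      phenotype = character(0),  # named: term key -> symbol
      disorder  = character(0),
      display   = character(0)   # named: symbol -> original term string
    ),
    class = "symbol_dictionary"
  )
}

dict_add <- function(dict, term, kind) {
  key <- .term_key(term)
  if (!nzchar(key)) stop("empty term string", call. = FALSE)
  map <- dict[[kind]]
  if (key %in% names(map)) return(dict)
  sym <- paste0(if (kind == "phenotype") "S" else "D", length(map) + 1L)
  map[[key]] <- sym
  dict[[kind]] <- map
  dict$display[[sym]] <- trimws(term)
  dict
}

#' Encode a term as its symbol
#'
#' @param dict a \code{symbol_dictionary}.
#' @param term a term string.
#' @param kind \code{"phenotype"} or \code{"disorder"}.
#' @return the symbol, or \code{NA_character_} if the term is unknown.
#' @export
encode_term <- function(dict, term, kind = c("phenotype", "disorder")) {
  kind <- match.arg(kind)
  sym <- unname(dict[[kind]][.term_key(term)])
  if (is.null(sym)) NA_character_ else sym
}

#' Decode a symbol back to its term
#'
#' @param dict a \code{symbol_dictionary}.
#' @param symbol a symbol string (or vector of them).
#' @return the original term string(s); unknown symbols decode to \code{NA}.
#' @export
decode_symbol <- function(dict, symbol) {
  out <- unname(dict$display[symbol])
  out[!(symbol %in% names(dict$display))] <- NA_character_
  out
}

is_disorder_symbol <- function(x) startsWith(x, "D")
is_phenotype_symbol <- function(x) startsWith(x, "S")

#' @export
print.symbol_dictionary <- function(x, ...) {
  cat("Symbol dictionary:", length(x$phenotype), "phenotype terms,",
      length(x$disorder), "disorder terms\n")
  invisible(x)
}

#' Encode raw patient cases into a case collection
#'
#' Builds the symbol dictionary in first-occurrence order while translating
#' each case's phenotype terms and (optional) diagnosis term into symbols.
#' Duplicate phenotype terms within a case collapse to a single symbol;
#' cases sharing a term share its symbol.
#'
#' @param raw_cases either a data.frame with columns \code{case_id},
#'   \code{diagnosis} (may be \code{NA} for query-only cases) and
#'   \code{phenotypes} (a pipe-separated string or a list column of character
#'   vectors), or a list whose elements are lists with fields \code{case_id},
#'   \code{diagnosis} and \code{phenotypes}.
#' @param dictionary optionally, an existing \code{symbol_dictionary} to
#'   extend (used when encoding test cases against a training vocabulary).
#' @return a \code{case_collection}: list with elements \code{cases} (each a
#'   list with \code{case_id}, \code{phenotypes} — sorted phenotype symbols —
#'   and \code{diagnosis}, a disorder symbol or \code{NA}), \code{dictionary}
#'   and \code{N}.
#' @examples
#' raw <- data.frame(case_id = "p1", diagnosis = "Achondroplasia",
#'                   phenotypes = "Short stature|Cleft palate")
#' cc <- encode_cases(raw)
#' cc$cases[[1]]$phenotypes   # "S1" "S2"
#' cc$cases[[1]]$diagnosis    # "D1"
#' @export
encode_cases <- function(raw_cases, dictionary = NULL) {
  raw <- .normalize_raw_cases(raw_cases)
  if (length(raw) == 0L) stop("no cases to encode", call. = FALSE)
  dict <- if (is.null(dictionary)) new_symbol_dictionary() else dictionary

  cases <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    rc <- raw[[i]]
    terms <- trimws(as.character(rc$phenotypes))
    terms <- terms[nzchar(terms)]
    if (length(terms) == 0L) {
      stop(sprintf("case '%s' has no phenotype terms", rc$case_id),
           call. = FALSE)
    }
    for (t in terms) dict <- dict_add(dict, t, "phenotype")
    syms <- unique(unname(vapply(terms, function(t) encode_term(dict, t), "")))
    diag <- NA_character_
    dterm <- rc$diagnosis
    if (!is.null(dterm) && !is.na(dterm) && nzchar(trimws(dterm))) {
      dict <- dict_add(dict, dterm, "disorder")
      diag <- encode_term(dict, dterm, "disorder")
    }
    cases[[i]] <- list(case_id = as.character(rc$case_id),
                       phenotypes = sort(syms),
                       diagnosis = diag)
  }
  structure(list(cases = cases, dictionary = dict, N = length(cases)),
            class = "case_collection")
}

.normalize_raw_cases <- function(raw_cases) {
  if (is.data.frame(raw_cases)) {
    need <- c("case_id", "diagnosis", "phenotypes")
    miss <- setdiff(need, names(raw_cases))
    if (length(miss)) {
      stop("raw case table is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    lapply(seq_len(nrow(raw_cases)), function(i) {
      ph <- raw_cases$phenotypes[[i]]
      if (is.character(ph) && length(ph) == 1L && grepl("|", ph, fixed = TRUE)) {
        ph <- strsplit(ph, "|", fixed = TRUE)[[1]]
      }
      list(case_id = raw_cases$case_id[[i]],
           diagnosis = raw_cases$diagnosis[[i]],
           phenotypes = ph)
    })
  } else if (is.list(raw_cases)) {
    raw_cases
  } else {
    stop("raw_cases must be a data.frame or a list", call. = FALSE)
  }
}

#' @export
print.case_collection <- function(x, ...) {
  nd <- length(unique(stats::na.omit(vapply(x$cases, `[[`, "", "diagnosis"))))
  cat("Case collection:", x$N, "cases,",
      length(x$dictionary$phenotype), "phenotype terms,",
      nd, "diagnosed disorders\n")
  invisible(x)
}

#' @export
summary.case_collection <- function(object, ...) {
  sizes <- vapply(object$cases, function(cs) length(cs$phenotypes), 0L)
  diag <- vapply(object$cases, `[[`, "", "diagnosis")
  out <- list(
    n_cases = object$N,
    n_phenotype_terms = length(object$dictionary$phenotype),
    n_disorders = length(unique(stats::na.omit(diag))),
    features_per_case = summary(sizes),
    class_sizes = if (any(!is.na(diag))) table(diag[!is.na(diag)]) else table(character(0))
  )
  class(out) <- "summary.case_collection"
  out
}

#' @export
print.summary.case_collection <- function(x, ...) {
  cat("Cases:", x$n_cases, " Phenotype vocabulary:", x$n_phenotype_terms,
      " Disorders:", x$n_disorders, "\nFeatures per case:\n")
  print(x$features_per_case)
  invisible(x)
}

#' Subset a case collection by case index
#'
#' The dictionary is shared (not re-encoded), so symbols stay comparable
#' between the subset and the parent collection.
#'
#' @param collection a \code{case_collection}.
#' @param idx integer indices of the cases to keep.
#' @return a \code{case_collection} over the same dictionary.
#' @export
subset_cases <- function(collection, idx) {
  stopifnot(inherits(collection, "case_collection"))
  structure(list(cases = collection$cases[idx],
                 dictionary = collection$dictionary,
                 N = length(idx)),
            class = "case_collection")
}

#' Per-feature coverage of a disorder
#'
#' Coverage of a clinical feature for a disorder is the percentage of cases
#' diagnosed with that disorder in which the feature is present: a feature
#' seen in 2 of the 4 cases of a disorder has coverage 50; one seen in 1 of
#' 101 cases has coverage ~0.99. It is the working measure of sparseness in
#' a case collection.
#'
#' @param feature a phenotype symbol (or a phenotype term known to the
#'   collection's dictionary).
#' @param disorder a disorder symbol (or disorder term); must have at least
#'   one case in the collection.
#' @param collection a \code{case_collection}.
#' @return coverage as a percentage in [0, 100], full precision.
#' @export
coverage <- function(feature, disorder, collection) {
  stopifnot(inherits(collection, "case_collection"))
  dict <- collection$dictionary
  fsym <- if (feature %in% names(dict$display)) feature else
    encode_term(dict, feature, "phenotype")
  dsym <- if (disorder %in% names(dict$display)) disorder else
    encode_term(dict, disorder, "disorder")
  if (is.na(dsym)) stop("unknown disorder: ", disorder, call. = FALSE)
  diag <- vapply(collection$cases, `[[`, "", "diagnosis")
  of_disorder <- which(!is.na(diag) & diag == dsym)
  if (length(of_disorder) == 0L) {
    stop("disorder has no cases in the collection: ", disorder, call. = FALSE)
  }
  if (is.na(fsym)) return(0)  # never-seen feature: 0% of the cases carry it
  with_feature <- sum(vapply(collection$cases[of_disorder],
                             function(cs) fsym %in% cs$phenotypes, TRUE))
  100 * with_feature / length(of_disorder)
}

#' Mean observed coverage of a collection
#'
#' Averages \code{\link{coverage}} over every (disorder, feature) pair in
#' which the feature occurs in at least one case of the disorder. Pairs where
#' the disorder has a single case are excluded, mirroring how sparseness is
#' summarised for registry data (a lone case would contribute only degenerate
#' 100% coverages).
#'
#' @param collection a \code{case_collection}.
#' @return a list with \code{mean}, \code{median}, \code{values} (the per-pair
#'   coverage percentages).
#' @export
coverage_summary <- function(collection) {
  stopifnot(inherits(collection, "case_collection"))
  diag <- vapply(collection$cases, `[[`, "", "diagnosis")
  vals <- numeric(0)
  for (dsym in unique(stats::na.omit(diag))) {
    idx <- which(!is.na(diag) & diag == dsym)
    if (length(idx) < 2L) next
    feats <- table(unlist(lapply(collection$cases[idx], `[[`, "phenotypes")))
    vals <- c(vals, 100 * as.numeric(feats) / length(idx))
  }
  list(mean = if (length(vals)) mean(vals) else NA_real_,
       median = if (length(vals)) stats::median(vals) else NA_real_,
       values = vals)
}
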