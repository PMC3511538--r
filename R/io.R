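#' File formats
#'
#' Case tables travel as UTF-8 TSV with a header row and columns
#' \code{case_id}, \code{diagnosis}, \code{phenotypes} (pipe-separated terms).
#' Rule bases are JSON with an explicit \code{schema_version}; confidences
#' round-trip at full double precision. Rankings are written as TSV with one
#' candidate per row.
#'
#' @name beliefmine-io
#' @keywords internal
NULL

RULEBASE_SCHEMA_VERSION <- "1.0"

#' Read a case table
#'
#' @param path path to a TSV file with header \code{case_id}, \code{diagnosis},
#'   \code{phenotypes}; the phenotypes field holds pipe-separated term strings.
#'   An empty diagnosis field marks a query-only (undiagnosed) case.
#' @return a raw-case data.frame suitable for \code{\link{encode_cases}}
#'   (phenotypes as a list column).
#' @export
read_cases <- function(path) {
  if (!file.exists(path)) stop("case file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty case file: ", path, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  need <- c("case_id", "diagnosis", "phenotypes")
  if (!identical(header[seq_along(need)], need)) {
    stop("case file must start with header: case_id\tdiagnosis\tphenotypes",
         call. = FALSE)
  }
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("malformed case row at line %d: expected 3 fields, got %d",
                   i, length(f)), call. = FALSE)
    }
    ph <- strsplit(f[[3]], "|", fixed = TRUE)[[1]]
    ph <- trimws(ph)
    ph <- ph[nzchar(ph)]
    if (length(ph) == 0L) {
      stop(sprintf("empty phenotype field at line %d (case '%s')", i, f[[1]]),
           call. = FALSE)
    }
    list(case_id = f[[1]],
         diagnosis = if (nzchar(trimws(f[[2]]))) f[[2]] else NA_character_,
         phenotypes = ph)
  })
  data.frame(
    case_id = vapply(rows, `[[`, "", "case_id"),
    diagnosis = vapply(rows, `[[`, "", "diagnosis"),
    phenotypes = I(lapply(rows, `[[`, "phenotypes")),
    stringsAsFactors = FALSE
  )
}

#' Write a case collection (or raw-case data.frame) as a TSV case table
#'
#' @param x a \code{case_collection} or a raw-case data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_cases <- function(x, path) {
  if (inherits(x, "case_collection")) {
    dict <- x$dictionary
    rows <- vapply(x$cases, function(cs) {
      terms <- decode_symbol(dict, cs$phenotypes)
      dterm <- if (is.na(cs$diagnosis)) "" else decode_symbol(dict, cs$diagnosis)
      paste(cs$case_id, dterm, paste(terms, collapse = "|"), sep = "\t")
    }, "")
  } else {
    rows <- vapply(seq_len(nrow(x)), function(i) {
      ph <- x$phenotypes[[i]]
      if (length(ph) == 1L && grepl("|", ph, fixed = TRUE)) ph <- strsplit(ph, "|", fixed = TRUE)[[1]]
      d <- x$diagnosis[[i]]
      paste(x$case_id[[i]], if (is.na(d)) "" else d,
            paste(ph, collapse = "|"), sep = "\t")
    }, "")
  }
  writeLines(c("case_id\tdiagnosis\tphenotypes", rows), path, useBytes = TRUE)
  invisible(path)
}

#' Save a rule base to JSON
#'
#' Rules are stored by term (not symbol) so a rule base is self-contained
#' and can be applied against queries encoded with any dictionary that knows
#' the same terms. Confidences are written at full double precision so that
#' \code{load_rulebase(save_rulebase(x))} is the identity.
#'
#' @param rules an \code{evidence_rules} object (see \code{\link{derive_rules}}).
#' @param path output path for the JSON file.
#' @param dictionary the \code{symbol_dictionary} used to decode symbols.
#' @return \code{path}, invisibly.
#' @export
save_rulebase <- function(rules, path, dictionary) {
  stopifnot(inherits(rules, "evidence_rules"))
  payload <- list(
    schema_version = RULEBASE_SCHEMA_VERSION,
    n_rules = length(rules),
    rules = lapply(unclass(rules), function(r) {
      list(antecedent = as.list(decode_symbol(dictionary, r$antecedent)),
           consequent = decode_symbol(dictionary, r$consequent),
           support_count = r$support_count,
           confidence = r$confidence)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a rule base from JSON
#'
#' @param path path to a JSON rule base written by \code{\link{save_rulebase}}.
#' @param dictionary a \code{symbol_dictionary}; terms unknown to it are added
#'   (phenotype and disorder namespaces respectively), so loading against a
#'   fresh dictionary reconstructs a consistent encoding.
#' @return a list with \code{rules} (an \code{evidence_rules} object in symbol
#'   space) and the possibly extended \code{dictionary}.
#' @export
load_rulebase <- function(path, dictionary = NULL) {
  if (!file.exists(path)) stop("rule base not found: ", path, call. = FALSE)
  payload <- jsonlite::read_json(path)
  if (!identical(payload$schema_version, RULEBASE_SCHEMA_VERSION)) {
    stop("unknown rule base schema version: ",
         if (is.null(payload$schema_version)) "<missing>" else payload$schema_version,
         call. = FALSE)
  }
  dict <- if (is.null(dictionary)) new_symbol_dictionary() else dictionary
  rules <- vector("list", length(payload$rules))
  for (i in seq_along(payload$rules)) {
    pr <- payload$rules[[i]]
    ants <- unlist(pr$antecedent, use.names = FALSE)
    for (t in ants) dict <- dict_add(dict, t, "phenotype")
    dict <- dict_add(dict, pr$consequent, "disorder")
    rules[[i]] <- list(
      antecedent = sort(unname(vapply(ants, function(t) encode_term(dict, t), ""))),
      consequent = encode_term(dict, pr$consequent, "disorder"),
      support_count = as.integer(pr$support_count),
      confidence = as.numeric(pr$confidence)
    )
  }
  list(rules = structure(rules, class = "evidence_rules"), dictionary = dict)
}

#' Write a candidate ranking as TSV
#'
#' Columns: disorder term, belief, plausibility, supporting-rule count.
#'
#' @param ranking a \code{candidate_ranking} (see \code{\link{rank_candidates}}).
#' @param path output path; \code{""} writes to stdout.
#' @param dictionary the \code{symbol_dictionary} used to decode disorder
#'   symbols back to terms.
#' @return \code{path}, invisibly.
#' @export
write_ranking <- function(ranking, path, dictionary) {
  stopifnot(inherits(ranking, "candidate_ranking"))
  e <- ranking$entries
  header <- "disorder\tbelief\tplausibility\tn_rules"
  if (nrow(e) == 0L) {
    lines <- header
  } else {
    terms <- decode_symbol(dictionary, e$disorder)
    lines <- c(header, vapply(seq_len(nrow(e)), function(i) {
      paste(terms[[i]],
            format(e$belief[[i]], digits = 15),
            format(e$plausibility[[i]], digits = 15),
            e$n_rules[[i]], sep = "\t")
    }, ""))
  }
  if (identical(path, "")) cat(lines, sep = "\n") else writeLines(lines, path)
  invisible(path)
}
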