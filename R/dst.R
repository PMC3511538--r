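#' Dempster-Shafer machinery
#'
#' A basic belief assignment (mass function) allocates unit belief over
#' focal item sets — here sets of phenotype symbols plus at most one disorder
#' symbol — with any residual belief on the frame of discernment Theta
#' (total ignorance). The mass of the empty set is 0 and all masses sum to 1.
#' Each evidence rule becomes a simple support function: its confidence is
#' the mass of the proposition antecedent-union-consequent, the remainder
#' sits on Theta. Independent evidences over the same frame are fused with
#' Dempster's rule of combination: product masses accrue to the intersection
#' of their focal sets, products with empty intersection accrue to the
#' conflict K, and the non-empty part is renormalized by 1 - K. K = 1 (total
#' conflict) is an error condition, never a silent division by zero.
#'
#' Decision support then reads the combined mass through constrained belief
#' and plausibility: for a query phenotype set A and candidate disorder c,
#' Bel_c sums the masses of focal sets whose phenotype part is contained in
#' A and whose disorder element is c (the evidence that must hold), while
#' Pl_c also admits focal sets merely intersecting A plus the ignorance mass
#' (the evidence that may hold). Candidates are ranked by belief alone;
#' plausibility is reported for transparency.
#'
#' @name dst
NULL

.MASS_TOL <- 1e-9

#' Construct a mass function
#'
#' @param focal named numeric vector: names are focal-set keys (symbols
#'   joined by \code{"\r"} in sorted order) or a list mapping is built via
#'   \code{focal_sets}/\code{masses}; use \code{\link{make_focal_key}} to
#'   build keys from symbol vectors.
#' @param theta_mass mass on the frame of discernment.
#' @return a \code{mass_function}.
#' @export
mass_function <- function(focal = numeric(0), theta_mass = 0) {
  if (length(focal) && is.null(names(focal))) {
    stop("focal masses must be named by focal-set key", call. = FALSE)
  }
  if (any(!nzchar(names(focal)))) {
    stop("the empty set cannot carry mass", call. = FALSE)
  }
  if (any(focal < -.MASS_TOL) || theta_mass < -.MASS_TOL) {
    stop("masses must be non-negative", call. = FALSE)
  }
  tot <- sum(focal) + theta_mass
  if (abs(tot - 1) > .MASS_TOL) {
    stop(sprintf("masses must sum to 1 (got %.12f)", tot), call. = FALSE)
  }
  structure(list(focal = focal, theta = theta_mass), class = "mass_function")
}

#' Build a focal-set key from a symbol vector
#' @param items character vector of symbols.
#' @return the canonical (sorted) key string.
#' @export
make_focal_key <- function(items) paste(sort(items), collapse = "\r")

#' Split a focal-set key back into symbols
#' @param key a key produced by \code{\link{make_focal_key}}.
#' @return character vector of symbols.
#' @export
split_focal_key <- function(key) strsplit(key, "\r", fixed = TRUE)[[1]]

#' The vacuous mass function (total ignorance)
#' @return a \code{mass_function} with all mass on Theta.
#' @export
vacuous_mass <- function() mass_function(theta_mass = 1)

#' @export
print.mass_function <- function(x, ...) {
  cat("Mass function:", length(x$focal), "focal sets, m(Theta) =",
      format(x$theta, digits = 6), "\n")
  for (k in names(x$focal)) {
    cat(sprintf("  m({%s}) = %.6f\n", paste(split_focal_key(k), collapse = ","),
                x$focal[[k]]))
  }
  invisible(x)
}

#' Convert an evidence rule to a simple support function
#'
#' @param rule a single evidence rule (list with \code{antecedent},
#'   \code{consequent}, \code{confidence}).
#' @return a \code{mass_function} with
#'   \code{m(antecedent + consequent) = confidence} and the residual
#'   \code{1 - confidence} on Theta.
#' @export
rule_to_mass <- function(rule) {
  conf <- rule$confidence
  if (!is.numeric(conf) || is.na(conf) || conf <= 0 || conf > 1) {
    stop("rule confidence must lie in (0, 1]", call. = FALSE)
  }
  key <- make_focal_key(c(rule$antecedent, rule$consequent))
  focal <- stats::setNames(conf, key)
  mass_function(focal = focal, theta_mass = 1 - conf)
}

.total_conflict_error <- function(detail = NULL) {
  msg <- "total conflict (K = 1): the evidences are fully contradictory"
  if (!is.null(detail)) msg <- paste0(msg, " [", detail, "]")
  stop(errorCondition(msg, class = "beliefmine_total_conflict"))
}

#' Combine two mass functions with Dempster's rule
#'
#' For every pair of focal sets B (from \code{m1}) and C (from \code{m2}),
#' with Theta acting as the universal set, the product mass
#' \code{m1(B) m2(C)} accrues to the intersection of B and C; products whose
#' intersection is empty accrue to the conflict K, and every non-empty
#' result is divided by \code{1 - K}. The realized conflict is attached as
#' attribute \code{"conflict"}.
#'
#' @param m1,m2 \code{mass_function} objects.
#' @return the joint \code{mass_function}; \code{attr(, "conflict")} holds K.
#' @export
combine <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  items1 <- lapply(names(m1$focal), split_focal_key)
  items2 <- lapply(names(m2$focal), split_focal_key)

  acc <- new.env(parent = emptyenv(), hash = TRUE)
  theta_acc <- m1$theta * m2$theta
  K <- 0
  add <- function(key, p) {
    prev <- if (exists(key, envir = acc, inherits = FALSE))
      get(key, envir = acc) else 0
    assign(key, prev + p, envir = acc)
  }
  # Theta x focal and focal x Theta keep the focal set intact
  for (i in seq_along(items1)) add(names(m1$focal)[[i]], m1$focal[[i]] * m2$theta)
  for (j in seq_along(items2)) add(names(m2$focal)[[j]], m2$focal[[j]] * m1$theta)
  for (i in seq_along(items1)) {
    for (j in seq_along(items2)) {
      p <- m1$focal[[i]] * m2$focal[[j]]
      if (p == 0) next
      inter <- intersect(items1[[i]], items2[[j]])
      if (length(inter) == 0L) K <- K + p
      else add(make_focal_key(inter), p)
    }
  }
  if (K >= 1 - .MASS_TOL) .total_conflict_error()
  keys <- ls(acc, sorted = TRUE)
  focal <- vapply(keys, function(k) get(k, envir = acc), 0) / (1 - K)
  names(focal) <- keys
  out <- mass_function(focal = focal, theta_mass = theta_acc / (1 - K))
  attr(out, "conflict") <- K
  out
}

#' Combine a list of mass functions
#'
#' Left fold of \code{\link{combine}}; Dempster's rule is commutative and
#' associative, so the result is invariant (to numerical tolerance) under
#' permutation of the inputs. After each pairwise combination, focal sets
#' whose mass falls below \code{prune} are dropped and the remaining masses
#' renormalized, which bounds the growth of the focal family when many
#' evidences apply while perturbing the result by less than the tolerance
#' used anywhere in the package.
#'
#' @param masses non-empty list of \code{mass_function} objects.
#' @param prune pruning threshold for focal masses (default \code{1e-12}).
#' @return the joint \code{mass_function}; \code{attr(, "conflict")} holds
#'   the aggregate conflict \code{1 - prod(1 - K_i)} over the pairwise steps.
#' @export
combine_all <- function(masses, prune = 1e-12) {
  if (!is.list(masses) || length(masses) == 0L) {
    stop("combine_all needs a non-empty list of mass functions", call. = FALSE)
  }
  out <- masses[[1]]
  keep_frac <- 1
  if (length(masses) >= 2L) {
    for (i in seq(2L, length(masses))) {
      out <- withCallingHandlers(
        combine(out, masses[[i]]),
        beliefmine_total_conflict = function(e) {
          stop(errorCondition(
            sprintf("total conflict while combining evidence %d into the fold of evidences 1..%d",
                    i, i - 1L),
            class = "beliefmine_total_conflict"))
        }
      )
      keep_frac <- keep_frac * (1 - attr(out, "conflict"))
      out <- .prune_mass(out, prune)
    }
  }
  attr(out, "conflict") <- 1 - keep_frac
  out
}

.prune_mass <- function(m, prune) {
  if (prune <= 0 || length(m$focal) == 0L) return(m)
  keep <- m$focal >= prune
  if (all(keep)) return(m)
  focal <- m$focal[keep]
  tot <- sum(focal) + m$theta
  mass_function(focal = focal / tot, theta_mass = m$theta / tot)
}

.focal_parts <- function(key) {
  items <- split_focal_key(key)
  list(phe = items[is_phenotype_symbol(items)],
       dis = items[is_disorder_symbol(items)])
}

#' Constrained belief of a disorder given observed phenotypes
#'
#' Sums the masses of the focal sets whose phenotype part is fully included
#' in the observation set \code{A} and whose disorder element equals
#' \code{c_s}: the lower bound on the total degree of belief in the disorder
#' given exactly those observations.
#'
#' @param m a \code{mass_function} (typically the combined evidence).
#' @param A non-empty set of phenotype symbols (the observations).
#' @param c_s a disorder symbol (the candidate conclusion).
#' @return belief value in [0, 1].
#' @export
constrained_belief <- function(m, A, c_s) {
  .check_bel_args(m, A, c_s)
  bel <- 0
  for (k in names(m$focal)) {
    p <- .focal_parts(k)
    if (length(p$dis) == 1L && p$dis == c_s && all(p$phe %in% A)) {
      bel <- bel + m$focal[[k]]
    }
  }
  bel
}

#' Constrained plausibility of a disorder given observed phenotypes
#'
#' Upper-bound counterpart of \code{\link{constrained_belief}}: sums the
#' masses of focal sets with conclusion \code{c_s} whose phenotype part
#' intersects \code{A} (or is empty), plus the ignorance mass on Theta.
#' Combined focal sets that lost their conclusion element contribute only
#' through Theta, since the plausibility of a conclusion requires the
#' conclusion to be part of the proposition.
#'
#' @inheritParams constrained_belief
#' @return plausibility value in [0, 1]; always \code{>= constrained_belief}.
#' @export
constrained_plausibility <- function(m, A, c_s) {
  .check_bel_args(m, A, c_s)
  pl <- m$theta
  for (k in names(m$focal)) {
    p <- .focal_parts(k)
    if (length(p$dis) == 1L && p$dis == c_s &&
        (length(p$phe) == 0L || any(p$phe %in% A))) {
      pl <- pl + m$focal[[k]]
    }
  }
  min(pl, 1)
}

.check_bel_args <- function(m, A, c_s) {
  stopifnot(inherits(m, "mass_function"))
  if (length(A) == 0L) stop("observation set A must be non-empty", call. = FALSE)
  if (length(c_s) != 1L || !is_disorder_symbol(c_s)) {
    stop("c_s must be a single disorder symbol", call. = FALSE)
  }
  invisible(TRUE)
}

#' Select the rules applicable to a query
#'
#' A rule applies when its whole antecedent is present in the query
#' phenotype set.
#'
#' @param query character vector of phenotype symbols.
#' @param rules an \code{evidence_rules} object.
#' @return an \code{evidence_rules} object with the applicable subset.
#' @export
select_applicable_rules <- function(query, rules) {
  stopifnot(inherits(rules, "evidence_rules"))
  keep <- vapply(unclass(rules), function(r) all(r$antecedent %in% query), TRUE)
  structure(unclass(rules)[keep], class = "evidence_rules")
}

#' Rank candidate disorders for a query phenotype set
#'
#' Selects the applicable rules, converts each into a simple support
#' function, combines them all with Dempster's rule, and scores every
#' disorder appearing in an applicable rule's consequent by its constrained
#' belief (and plausibility). The ranking is ordered by belief descending;
#' ties fall back to plausibility descending, then disorder symbol
#' ascending. Belief is the sole decision criterion: plausibility counts
#' evidence that merely may apply and is reported only for transparency.
#' Evidences are folded in a fixed order (antecedent size, then symbols) so
#' repeated calls are bit-reproducible; order invariance of the combination
#' itself is a separate mathematical property.
#'
#' @param query non-empty character vector of phenotype symbols.
#' @param rules an \code{evidence_rules} object (the rule base).
#' @param prune focal-set pruning threshold passed to \code{\link{combine_all}}.
#' @return a \code{candidate_ranking}: list with \code{query}, \code{entries}
#'   (data.frame: disorder, belief, plausibility, n_rules, sorted), \code{conflict_K},
#'   and \code{status} — \code{"ok"}, \code{"no_evidence"} (no applicable
#'   rule) or \code{"total_conflict"} (combination impossible; no decision).
#' @export
rank_candidates <- function(query, rules, prune = 1e-12) {
  if (length(query) == 0L) stop("query must be non-empty", call. = FALSE)
  app <- select_applicable_rules(query, rules)
  empty <- data.frame(disorder = character(0), belief = numeric(0),
                      plausibility = numeric(0), n_rules = integer(0),
                      stringsAsFactors = FALSE)
  if (length(app) == 0L) {
    return(structure(list(query = query, entries = empty, conflict_K = 0,
                          status = "no_evidence"),
                     class = "candidate_ranking"))
  }
  ord <- order(vapply(unclass(app), function(r) length(r$antecedent), 0L),
               vapply(unclass(app), function(r)
                 paste(c(r$antecedent, r$consequent), collapse = "\r"), ""))
  app_sorted <- unclass(app)[ord]
  masses <- lapply(app_sorted, rule_to_mass)
  joint <- tryCatch(
    combine_all(masses, prune = prune),
    beliefmine_total_conflict = function(e) e
  )
  if (inherits(joint, "beliefmine_total_conflict")) {
    return(structure(list(query = query, entries = empty, conflict_K = 1,
                          status = "total_conflict"),
                     class = "candidate_ranking"))
  }
  cons <- vapply(app_sorted, `[[`, "", "consequent")
  disorders <- sort(unique(cons))
  bel <- vapply(disorders, function(d) constrained_belief(joint, query, d), 0)
  pl <- vapply(disorders, function(d) constrained_plausibility(joint, query, d), 0)
  nr <- vapply(disorders, function(d) sum(cons == d), 0L)
  o <- order(-bel, -pl, disorders)
  entries <- data.frame(disorder = disorders[o], belief = unname(bel[o]),
                        plausibility = unname(pl[o]), n_rules = unname(nr[o]),
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(query = query, entries = entries,
                 conflict_K = attr(joint, "conflict"), status = "ok"),
            class = "candidate_ranking")
}

#' @export
print.candidate_ranking <- function(x, ..., n = 10L) {
  cat("Candidate ranking for query {", paste(x$query, collapse = ","), "}\n",
      sep = "")
  if (x$status == "no_evidence") {
    cat("  no evidence: no rule applies to this query\n")
  } else if (x$status == "total_conflict") {
    cat("  no decision: total conflict among applicable evidences\n")
  } else {
    cat(sprintf("  conflict K = %.4f\n", x$conflict_K))
    print(utils::head(x$entries, n), row.names = FALSE)
  }
  invisible(x)
}
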