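#' Association-rule extraction from encoded cases
#'
#' Each patient case contributes one transaction: its phenotype symbols plus
#' its diagnosis symbol. Frequent itemsets are discovered by a level-wise
#' (Apriori) search: size-k candidates are generated only by joining frequent
#' size-(k-1) itemsets that share a lexicographic prefix, and any candidate
#' with an infrequent subset is pruned before counting (downward closure).
#' Support is an absolute transaction count. The defaults encode the mining
#' regime for sparse rare-disorder data: an absolute minimum support of 2
#' (i.e. relative support 2/N), chosen to keep rare but repeated
#' associations, and a maximum itemset size of 10 to bound the exponential
#' search. Itemsets containing exactly one disorder symbol yield evidence
#' rules phenotype-set -> disorder whose confidence
#' \eqn{conf = supp(antecedent \cup \{disorder\}) / supp(antecedent)}
#' is later used directly as a basic belief assignment; deliberately, no
#' minimum-confidence filter is applied, because dropping low-confidence
#' rules would bias the combined belief values.
#'
#' @name rule-mining
NULL

.itemset_key <- function(items) paste(items, collapse = "\r")

#' Find frequent itemsets by level-wise search
#'
#' @param collection a \code{case_collection}.
#' @param min_support_count absolute minimum support (default 2: an itemset
#'   must appear in at least two cases).
#' @param max_size maximum itemset size (default 10).
#' @return a \code{frequent_itemsets} object: a list of itemsets, each a list
#'   with \code{items} (sorted symbol vector) and \code{support_count}.
#' @examples
#' cc <- encode_cases(data.frame(
#'   case_id = c("a", "b", "c"),
#'   diagnosis = "Achondroplasia",
#'   phenotypes = c("Dwarfism", "Dwarfism", "Dwarfism|Cleft palate")))
#' fi <- find_frequent_itemsets(cc)
#' @export
find_frequent_itemsets <- function(collection, min_support_count = 2L,
                                   max_size = 10L) {
  stopifnot(inherits(collection, "case_collection"))
  if (collection$N == 0L) stop("empty case collection", call. = FALSE)
  min_support_count <- as.integer(min_support_count)
  max_size <- as.integer(max_size)
  if (min_support_count < 1L) stop("min_support_count must be >= 1", call. = FALSE)
  if (max_size < 2L) stop("max_size must be >= 2", call. = FALSE)

  txns <- lapply(collection$cases, function(cs) {
    t <- cs$phenotypes
    if (!is.na(cs$diagnosis)) t <- c(t, cs$diagnosis)
    unique(t)
  })
  universe <- sort(unique(unlist(txns)))
  if (length(universe) == 0L) stop("empty case collection", call. = FALSE)

  # vertical layout: per item, the ids of the transactions containing it
  tid_of_item <- vector("list", length(universe))
  for (ti in seq_along(txns)) {
    ids <- match(txns[[ti]], universe)
    for (it in ids) tid_of_item[[it]] <- c(tid_of_item[[it]], ti)
  }

  out_items <- list()
  out_supp <- integer(0)
  freq_keys <- new.env(parent = emptyenv(), hash = TRUE)

  keep1 <- which(lengths(tid_of_item) >= min_support_count)
  if (length(keep1) == 0L) {
    return(structure(list(), class = "frequent_itemsets"))
  }
  level_items <- matrix(keep1, ncol = 1L)
  level_tids <- tid_of_item[keep1]
  level_supp <- lengths(level_tids)
  for (r in seq_along(keep1)) {
    out_items[[length(out_items) + 1L]] <- keep1[r]
    assign(.itemset_key(keep1[r]), level_supp[[r]], envir = freq_keys)
  }
  out_supp <- c(out_supp, level_supp)

  k <- 2L
  while (k <= max_size && nrow(level_items) >= 2L) {
    cand <- .apriori_join(level_items, level_tids, freq_keys,
                          min_support_count)
    if (length(cand$supp) == 0L) break
    level_items <- cand$items
    level_tids <- cand$tids
    level_supp <- cand$supp
    for (r in seq_len(nrow(level_items))) {
      out_items[[length(out_items) + 1L]] <- level_items[r, ]
      assign(.itemset_key(level_items[r, ]), level_supp[[r]], envir = freq_keys)
    }
    out_supp <- c(out_supp, level_supp)
    k <- k + 1L
  }

  res <- lapply(seq_along(out_items), function(i) {
    list(items = universe[out_items[[i]]], support_count = out_supp[[i]])
  })
  structure(res, class = "frequent_itemsets")
}

# join frequent (k-1)-itemsets sharing a (k-2)-prefix, prune by downward
# closure, count support via tidset intersection of the two parents
.apriori_join <- function(items, tids, freq_keys, min_support_count) {
  n <- nrow(items)
  k1 <- ncol(items)
  prefix <- if (k1 == 1L) rep("", n) else
    apply(items[, -k1, drop = FALSE], 1L, paste, collapse = "\r")
  ord <- order(prefix, items[, k1])
  items <- items[ord, , drop = FALSE]
  tids <- tids[ord]
  prefix <- prefix[ord]

  cand_items <- list()
  cand_tids <- list()
  cand_supp <- integer(0)
  grp <- split(seq_len(n), prefix)
  for (g in grp) {
    if (length(g) < 2L) next
    for (a in seq_len(length(g) - 1L)) {
      for (b in seq(a + 1L, length(g))) {
        i <- g[[a]]; j <- g[[b]]
        cand <- c(items[i, ], items[j, k1])
        # downward closure: every (k-1)-subset must already be frequent
        ok <- TRUE
        if (k1 >= 2L) {
          for (drop_pos in seq_len(k1)) {  # dropping the last element gives parent i
            sub <- cand[-drop_pos]
            if (!exists(.itemset_key(sub), envir = freq_keys, inherits = FALSE)) {
              ok <- FALSE
              break
            }
          }
        }
        if (!ok) next
        tt <- intersect(tids[[i]], tids[[j]])
        if (length(tt) >= min_support_count) {
          cand_items[[length(cand_items) + 1L]] <- cand
          cand_tids[[length(cand_tids) + 1L]] <- tt
          cand_supp <- c(cand_supp, length(tt))
        }
      }
    }
  }
  list(items = if (length(cand_items)) do.call(rbind, cand_items) else
         matrix(integer(0), 0L, k1 + 1L),
       tids = cand_tids, supp = cand_supp)
}

#' @export
print.frequent_itemsets <- function(x, ...) {
  sizes <- vapply(unclass(x), function(s) length(s$items), 0L)
  cat("Frequent itemsets:", length(x), "itemsets, sizes",
      if (length(sizes)) paste(range(sizes), collapse = "-") else "-", "\n")
  invisible(x)
}

#' Derive evidence rules from frequent itemsets
#'
#' Each frequent itemset containing exactly one disorder symbol and at least
#' one phenotype symbol is partitioned into its phenotype part (antecedent)
#' and its disorder (consequent). Confidence is the ratio of the itemset's
#' support to its antecedent's support; by downward closure the antecedent is
#' itself frequent, so its support is available from the same search. No
#' minimum-confidence threshold is applied. Itemsets without a disorder, or
#' with no phenotype part, yield no rule; itemsets with two or more disorder
#' symbols are discarded (they cannot arise from one-diagnosis cases unless
#' support counting is degenerate).
#'
#' @param itemsets a \code{frequent_itemsets} object produced by
#'   \code{\link{find_frequent_itemsets}}.
#' @return an \code{evidence_rules} object: list of rules, each with
#'   \code{antecedent} (sorted phenotype symbols), \code{consequent} (one
#'   disorder symbol), \code{support_count}, \code{confidence}.
#' @export
derive_rules <- function(itemsets) {
  stopifnot(inherits(itemsets, "frequent_itemsets"))
  supp_of <- new.env(parent = emptyenv(), hash = TRUE)
  for (s in unclass(itemsets)) {
    assign(.itemset_key(sort(s$items)), s$support_count, envir = supp_of)
  }
  rules <- list()
  for (s in unclass(itemsets)) {
    dis <- s$items[is_disorder_symbol(s$items)]
    phe <- s$items[is_phenotype_symbol(s$items)]
    if (length(dis) != 1L || length(phe) < 1L) next
    akey <- .itemset_key(sort(phe))
    if (!exists(akey, envir = supp_of, inherits = FALSE)) {
      stop("internal consistency error: antecedent {",
           paste(phe, collapse = ","),
           "} missing from the frequent set (downward closure violated)",
           call. = FALSE)
    }
    asupp <- get(akey, envir = supp_of)
    rules[[length(rules) + 1L]] <- list(
      antecedent = sort(phe),
      consequent = dis,
      support_count = s$support_count,
      confidence = s$support_count / asupp
    )
  }
  structure(rules, class = "evidence_rules")
}

#' @export
print.evidence_rules <- function(x, ..., n = 10L) {
  cat("Evidence rules:", length(x), "rules\n")
  show <- utils::head(seq_along(x), n)
  for (i in show) {
    r <- x[[i]]
    cat(sprintf("  {%s} -> %s  (supp %d, conf %.4f)\n",
                paste(r$antecedent, collapse = ","), r$consequent,
                r$support_count, r$confidence))
  }
  if (length(x) > length(show)) cat("  ...\n")
  invisible(x)
}

#' Evidence rules as a data.frame
#'
#' @param x an \code{evidence_rules} object.
#' @param ... unused.
#' @return a data.frame with columns \code{antecedent} (pipe-separated
#'   symbols), \code{consequent}, \code{support_count}, \code{confidence}.
#' @export
as.data.frame.evidence_rules <- function(x, ...) {
  data.frame(
    antecedent = vapply(unclass(x), function(r) paste(r$antecedent, collapse = "|"), ""),
    consequent = vapply(unclass(x), `[[`, "", "consequent"),
    support_count = vapply(unclass(x), `[[`, 0L, "support_count"),
    confidence = vapply(unclass(x), `[[`, 0, "confidence"),
    stringsAsFactors = FALSE
  )
}
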