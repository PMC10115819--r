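#' Build market-basket transactions from a study
#'
#' Each sample becomes one transaction: an item per present taxon (binarized
#' value 1), an item per discretized phenotype (`"name=high"` when at or
#' above the per-variable median, `"name=low"` below — ties go to high,
#' deterministically), an age-bin item (`"day=3"` etc.), and the treatment
#' flag `"CTC"` for samples of the treated (`CON`) group.
#'
#' @param binary Samples x taxa binary matrix.
#' @param phenotypes Optional samples x variables numeric matrix of
#'   continuous phenotypes.
#' @param metadata Optional data frame with `group` and/or `day` columns
#'   aligned with the samples.
#' @param treatment_item Label of the treatment item (default `"CTC"`).
#' @return An object of class `transaction_set`: a list of character item
#'   vectors, one per sample.
#' @export
build_transactions <- function(binary, phenotypes = NULL, metadata = NULL,
                               treatment_item = "CTC") {
  binary <- as.matrix(binary)
  n <- nrow(binary)
  tr <- lapply(seq_len(n), function(k) colnames(binary)[binary[k, ] == 1])
  if (!is.null(phenotypes)) {
    phenotypes <- as.matrix(phenotypes)
    stopifnot(nrow(phenotypes) == n)
    med <- apply(phenotypes, 2, stats::median)
    lab <- t(ifelse(t(phenotypes) >= med,
                    paste0(colnames(phenotypes), "=high"),
                    paste0(colnames(phenotypes), "=low")))
    tr <- lapply(seq_len(n), function(k) c(tr[[k]], lab[k, ]))
  }
  if (!is.null(metadata)) {
    stopifnot(nrow(metadata) == n)
    if ("day" %in% names(metadata)) {
      tr <- lapply(seq_len(n), function(k) {
        c(tr[[k]], paste0("day=", metadata$day[k]))
      })
    }
    if ("group" %in% names(metadata)) {
      tr <- lapply(seq_len(n), function(k) {
        if (metadata$group[k] == "CON") c(tr[[k]], treatment_item)
        else tr[[k]]
      })
    }
  }
  structure(lapply(tr, unique), class = "transaction_set")
}

#' Mine association rules with the a-priori algorithm
#'
#' Level-wise frequent-itemset search (every subset of a frequent itemset is
#' itself frequent, so candidates at level k are joins of frequent sets at
#' level k-1), followed by rule generation over all antecedent/consequent
#' splits of each frequent itemset.  Support, confidence and lift are exact
#' counts over the transactions, not estimates.
#'
#' @param transactions A [build_transactions] result (or any list of
#'   character vectors).
#' @param min_support Minimum itemset support in `(0, 1]` (default 0.2).
#' @param min_confidence Minimum rule confidence in `(0, 1]` (default 0.8).
#' @param max_len Maximum itemset size searched (default unlimited).
#' @return An object of class `rule_set`: a data frame with `antecedent`
#'   and `consequent` (comma-joined sorted item labels), `support`,
#'   `confidence`, `lift`.  Thresholds that nothing survives give an empty
#'   rule set, not an error.
#' @export
mine_rules <- function(transactions, min_support = 0.2,
                       min_confidence = 0.8, max_len = Inf) {
  if (min_support <= 0 || min_support > 1 ||
      min_confidence <= 0 || min_confidence > 1) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  tr <- lapply(transactions, unique)
  n <- length(tr)
  items <- sort(unique(unlist(tr)))
  empty <- data.frame(antecedent = character(), consequent = character(),
                      support = numeric(), confidence = numeric(),
                      lift = numeric())
  if (length(items) == 0) return(structure(empty, class = c("rule_set", "data.frame")))

  inc <- vapply(items,
                function(it) vapply(tr, function(t) it %in% t, logical(1)),
                logical(n))
  inc <- matrix(inc, nrow = n, dimnames = list(NULL, items))

  support_of <- function(ids) {
    mean(rowSums(inc[, ids, drop = FALSE]) == length(ids))
  }

  sup <- new.env(parent = emptyenv())
  key_of <- function(ids) paste(ids, collapse = ",")

  # level 1
  s1 <- colMeans(inc)
  frequent <- lapply(which(s1 >= min_support), function(i) i)
  for (f in frequent) assign(key_of(f), s1[[f]], envir = sup)
  all_frequent <- frequent

  level <- frequent
  k <- 1L
  while (length(level) > 1 && k < max_len) {
    k <- k + 1L
    # join step: pairs sharing their first k-2 items
    cand <- list()
    for (a in seq_along(level)) {
      for (b in seq_along(level)) {
        if (b <= a) next
        ia <- level[[a]]
        ib <- level[[b]]
        if (k == 2L || identical(ia[-(k - 1L)], ib[-(k - 1L)])) {
          if (ia[k - 1L] < ib[k - 1L]) {
            cand[[length(cand) + 1L]] <- c(ia[-(k - 1L)],
                                           sort(c(ia[k - 1L], ib[k - 1L])))
          }
        }
      }
    }
    # prune + count
    nxt <- list()
    for (cs in cand) {
      subs_ok <- all(vapply(seq_along(cs), function(d) {
        exists(key_of(cs[-d]), envir = sup)
      }, logical(1)))
      if (!subs_ok) next
      s <- support_of(cs)
      if (s >= min_support) {
        assign(key_of(cs), s, envir = sup)
        nxt[[length(nxt) + 1L]] <- cs
      }
    }
    all_frequent <- c(all_frequent, nxt)
    level <- nxt
  }

  # rule generation
  rows <- list()
  for (fs in all_frequent) {
    m <- length(fs)
    if (m < 2) next
    s_full <- get(key_of(fs), envir = sup)
    for (mask in seq_len(2^m - 2)) {
      sel <- bitwAnd(mask %/% 2^(seq_len(m) - 1), 1L) == 1L
      ante <- fs[sel]
      cons <- fs[!sel]
      conf <- s_full / get(key_of(ante), envir = sup)
      if (conf >= min_confidence) {
        lift <- conf / get(key_of(cons), envir = sup)
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = paste(items[ante], collapse = ","),
          consequent = paste(items[cons], collapse = ","),
          support = s_full, confidence = conf, lift = lift
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(-out$lift, -out$support, out$antecedent, out$consequent), ]
  rownames(out) <- NULL
  structure(out, class = c("rule_set", "data.frame"))
}

#' Filter rules mentioning an item
#'
#' Keeps rules whose antecedent or consequent contains `item`, sorted by
#' lift (descending), then support (descending), then lexically.  Filtering
#' is idempotent.
#'
#' @param rules A [mine_rules] result.
#' @param item Item label (e.g. `"CTC"`).
#' @return A `rule_set` with the matching rules.
#' @export
rules_about <- function(rules, item) {
  has <- function(s) {
    vapply(strsplit(s, ",", fixed = TRUE), function(x) item %in% x,
           logical(1))
  }
  out <- rules[has(rules$antecedent) | has(rules$consequent), , drop = FALSE]
  out <- out[order(-out$lift, -out$support, out$antecedent, out$consequent), ]
  rownames(out) <- NULL
  structure(out, class = c("rule_set", "data.frame"))
}
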