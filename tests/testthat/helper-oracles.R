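# Independent oracles and small fixture builders used across the suite.

# map binary state rows to 1-based state indices (component 1 fastest)
state_index <- function(states) {
  1 + as.integer(states %*% 2^(seq_len(ncol(states)) - 1))
}

# brute-force association-rule miner: enumerate every itemset and every
# antecedent/consequent split, counting supports directly.  Kept deliberately
# naive and independent of mine_rules().
brute_force_rules <- function(transactions, min_support, min_confidence) {
  tr <- lapply(transactions, unique)
  n <- length(tr)
  items <- sort(unique(unlist(tr)))
  p <- length(items)
  supp <- function(set) {
    mean(vapply(tr, function(t) all(set %in% t), logical(1)))
  }
  rows <- list()
  for (code in seq_len(2^p - 1)) {
    sel <- bitwAnd(code %/% 2^(seq_len(p) - 1), 1L) == 1L
    fs <- items[sel]
    if (length(fs) < 2) next
    s_full <- supp(fs)
    if (s_full < min_support) next
    m <- length(fs)
    for (mask in seq_len(2^m - 2)) {
      asel <- bitwAnd(mask %/% 2^(seq_len(m) - 1), 1L) == 1L
      ante <- fs[asel]
      cons <- fs[!asel]
      conf <- s_full / supp(ante)
      if (conf >= min_confidence) {
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = paste(sort(ante), collapse = ","),
          consequent = paste(sort(cons), collapse = ","),
          support = s_full, confidence = conf,
          lift = conf / supp(cons))
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(antecedent = character(), consequent = character(),
                      support = numeric(), confidence = numeric(),
                      lift = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$antecedent, out$consequent), ]
}

# random transaction set over <= 6 items
random_transactions <- function(seed, n_items = 6, n_tr = 20) {
  set.seed(seed)
  items <- LETTERS[seq_len(n_items)]
  tr <- lapply(seq_len(sample(5:n_tr, 1)), function(i) {
    sample(items, sample.int(n_items, 1))
  })
  structure(tr, class = "transaction_set")
}

# sort a rule set into a canonical order for comparison
canonical_rules <- function(r) {
  r <- as.data.frame(r)
  r$antecedent <- vapply(strsplit(r$antecedent, ","), function(x)
    paste(sort(x), collapse = ","), character(1))
  r$consequent <- vapply(strsplit(r$consequent, ","), function(x)
    paste(sort(x), collapse = ","), character(1))
  r <- r[order(r$antecedent, r$consequent), ]
  rownames(r) <- NULL
  r
}

# the trial-scale environment grid: both treatments x three growth stages
study_environments <- function() {
  list(c(0, 0), c(0, 0.53), c(0, 1), c(1, 0), c(1, 0.53), c(1, 1))
}
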