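#' Per-animal change from the baseline day
#'
#' Subtracts each animal's day-3 (baseline) value from every later record,
#' per variable, and keeps all days — so the baseline rows are exactly zero.
#' Working on changes removes stable between-animal differences before
#' causal analysis.
#'
#' @param data Data frame with `animal_id` and `day` columns plus numeric
#'   variable columns.
#' @param baseline_day The reference day (default 3).
#' @param keep_baseline Keep the all-zero baseline rows (default `TRUE`).
#' @return A data frame of the same shape (minus baseline rows when
#'   `keep_baseline = FALSE`) with variables replaced by changes.
#' @export
delta_transform <- function(data, baseline_day = 3, keep_baseline = TRUE) {
  if (!all(c("animal_id", "day") %in% names(data))) {
    stop("`data` needs `animal_id` and `day` columns", call. = FALSE)
  }
  vars <- setdiff(names(data), c("animal_id", "day", "sample_id", "group"))
  base <- data[data$day == baseline_day, , drop = FALSE]
  missing <- setdiff(unique(data$animal_id), base$animal_id)
  if (length(missing)) {
    stop("no day-", baseline_day, " record for animal(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(base$animal_id)) {
    stop("multiple baseline records per animal", call. = FALSE)
  }
  idx <- match(data$animal_id, base$animal_id)
  out <- data
  for (v in vars) out[[v]] <- data[[v]] - base[[v]][idx]
  if (!keep_baseline) out <- out[out$day != baseline_day, , drop = FALSE]
  out
}

# Hyvarinen's maximum-entropy approximation to the differential entropy of a
# standardized variable
approx_entropy <- function(u) {
  k1 <- 79.047
  k2 <- 7.4129
  gamma <- 0.37457
  0.5 * (1 + log(2 * pi)) -
    k1 * (mean(log(cosh(u))) - gamma)^2 -
    k2 * mean(u * exp(-u^2 / 2))^2
}

# residual of xi regressed on xj (both centered)
ls_residual <- function(xi, xj) {
  xi - (sum(xi * xj) / sum(xj * xj)) * xj
}

standardize <- function(x) (x - mean(x)) / stats::sd(x)

# likelihood-ratio measure for direction j -> i: positive when the model
# "j causes i" explains the pair better than "i causes j"
pair_direction_measure <- function(xj, xi) {
  xj_s <- standardize(xj)
  xi_s <- standardize(xi)
  r_i <- ls_residual(xi_s, xj_s)
  r_j <- ls_residual(xj_s, xi_s)
  (approx_entropy(xi_s) + approx_entropy(standardize(r_j))) -
    (approx_entropy(xj_s) + approx_entropy(standardize(r_i)))
}

#' Estimate a linear non-Gaussian acyclic causal model
#'
#' Direct estimation of a LiNGAM: repeatedly pick the most plausibly
#' exogenous remaining variable — the one whose pairwise
#' non-Gaussianity-based likelihood-ratio scores least contradict it being
#' upstream of all others — regress it out of the remaining variables, and
#' recurse.  The recovered causal order is then filled in by ordinary least
#' squares: each variable is regressed on all of its predecessors, giving an
#' unpruned strictly lower-triangular strengths matrix `B` (in causal
#' order).  The procedure is deterministic given the data.
#'
#' @param data Numeric matrix or data frame (rows = observations); needs
#'   more rows than columns.
#' @return An object of class `causal_model`: `causal_order` (variable
#'   names, exogenous first), `B` (p x p matrix in the original variable
#'   order; `B[i, j]` is the direct strength of variable j on variable i,
#'   structurally zero unless j precedes i), and `diagnostics` (per-variable
#'   residual negentropy; values near zero mean near-Gaussian residuals and
#'   weak identifiability, flagged with a warning).
#' @export
direct_lingam <- function(data) {
  X <- as.matrix(data)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  nm <- colnames(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) {
    stop("need more observations (", n, ") than variables (", p, ")",
         call. = FALSE)
  }
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("constant column(s): ",
         paste(nm[apply(X, 2, stats::sd) == 0], collapse = ", "),
         call. = FALSE)
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  work <- X
  U <- seq_len(p)
  order_idx <- integer(0)
  while (length(U) > 1) {
    viol <- vapply(U, function(j) {
      sum(vapply(setdiff(U, j), function(i) {
        min(0, pair_direction_measure(work[, j], work[, i]))^2
      }, numeric(1)))
    }, numeric(1))
    root <- U[which.min(viol)]
    order_idx <- c(order_idx, root)
    U <- setdiff(U, root)
    for (i in U) work[, i] <- ls_residual(work[, i], work[, root])
  }
  order_idx <- c(order_idx, U)

  B <- matrix(0, p, p, dimnames = list(nm, nm))
  for (m in seq_len(p)[-1]) {
    y <- X[, order_idx[m]]
    Z <- X[, order_idx[seq_len(m - 1)], drop = FALSE]
    B[order_idx[m], order_idx[seq_len(m - 1)]] <- stats::lsfit(
      Z, y, intercept = FALSE)$coefficients
  }

  # residual non-Gaussianity: negentropy of each variable's residual given
  # its predecessors (exogenous variables use their own negentropy)
  gauss_h <- 0.5 * (1 + log(2 * pi))
  resid <- X - X %*% t(B)[, , drop = FALSE]
  diag_neg <- apply(resid, 2, function(r) {
    gauss_h - approx_entropy(standardize(r))
  })
  if (max(diag_neg) < 1e-3) {
    warning("all residuals are near-Gaussian; the causal order is weakly ",
            "identified", call. = FALSE)
  }
  structure(
    list(causal_order = nm[order_idx], B = B,
         diagnostics = list(residual_negentropy = diag_neg)),
    class = "causal_model"
  )
}

#' @export
print.causal_model <- function(x, ...) {
  cat("<causal_model> causal order: ",
      paste(x$causal_order, collapse = " -> "), "\n", sep = "")
  nz <- sum(x$B != 0)
  cat("  ", nz, " nonzero direct strength(s); largest |B| = ",
      signif(max(abs(x$B)), 4), "\n", sep = "")
  invisible(x)
}

#' Internal-standard validation of a causal model
#'
#' A taxonomically nested pair — a family and its dominant genus — is an
#' internal standard: almost all of the family's signal is the genus, so the
#' direct causal strength between the two should be close to 1 whichever
#' way the recovered order connects them (the reverse regression of a
#' near-deterministic pair has essentially the same coefficient).  A
#' coefficient within `[1 - tol, 1 + tol]` passes; a disconnected pair is
#' reported as coefficient 0 and fails.
#'
#' @param model A [direct_lingam] result.
#' @param pairs List of `c(parent, child)` label pairs (or a 2-column
#'   matrix/data frame).
#' @param tol Tolerance around 1 (default 0.1).
#' @return A data frame: `parent`, `child`, `coefficient`, `pass`.
#' @export
internal_standard_check <- function(model, pairs, tol = 0.1) {
  if (is.matrix(pairs) || is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(k) unlist(pairs[k, 1:2]))
  }
  rows <- lapply(pairs, function(pr) {
    parent <- pr[[1]]
    child <- pr[[2]]
    if (!all(c(parent, child) %in% rownames(model$B))) {
      stop("variable(s) not in the model: ",
           paste(setdiff(c(parent, child), rownames(model$B)),
                 collapse = ", "), call. = FALSE)
    }
    coef <- model$B[child, parent]
    if (coef == 0) coef <- model$B[parent, child]
    data.frame(parent = parent, child = child, coefficient = coef,
               pass = coef >= 1 - tol & coef <= 1 + tol)
  })
  do.call(rbind, rows)
}

#' Export a causal model as a weighted DAG
#'
#' Writes the edges with `|B| > threshold` (default 0: all nonzero edges,
#' matching an unpruned strengths matrix) with their signed weights.  The
#' graph is acyclic by construction of the strengths matrix.
#'
#' @param model A [direct_lingam] result.
#' @param file Output path.
#' @param threshold Absolute-strength cutoff (default 0).
#' @param format `"graphml"`, `"dot"` or `"tsv"`.
#' @return The edge data frame (`from`, `to`, `weight`), invisibly.
#' @export
export_dag <- function(model, file, threshold = 0,
                       format = c("graphml", "dot", "tsv")) {
  format <- match.arg(format)
  idx <- which(abs(model$B) > threshold, arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(model$B)[idx[, 2]],
    to = rownames(model$B)[idx[, 1]],
    weight = model$B[idx]
  )
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  nodes <- rownames(model$B)
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = nodes))
    igraph::write_graph(g, file, format = "graphml")
  } else if (format == "dot") {
    con <- file(file, "w")
    writeLines("digraph causal_model {", con)
    for (v in nodes) writeLines(sprintf("  \"%s\";", v), con)
    apply(edges, 1, function(e) {
      writeLines(sprintf("  \"%s\" -> \"%s\" [weight=%s];",
                         e[["from"]], e[["to"]], e[["weight"]]), con)
    })
    writeLines("}", con)
    close(con)
  } else {
    utils::write.table(edges, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(edges)
}

#' Read back an exported DAG
#'
#' @param file Path written by [export_dag].
#' @param format `"graphml"` or `"tsv"`.
#' @return A data frame `from`, `to`, `weight`.
#' @export
read_dag <- function(file, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(file, format = "graphml")
    e <- igraph::as_data_frame(g, what = "edges")
    out <- data.frame(from = e$from, to = e$to, weight = e$weight)
  } else {
    out <- utils::read.delim(file, stringsAsFactors = FALSE)
  }
  out <- out[order(out$from, out$to), ]
  rownames(out) <- NULL
  out
}
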