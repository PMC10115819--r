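#' Parameters of the extended pairwise maximum-entropy model
#'
#' Bundles the four parameter blocks of the community model: per-component
#' biases `h`, symmetric pairwise couplings `J` (zero diagonal), and the two
#' environmental response vectors `g_a` (antibiotic treatment) and `g_s`
#' (growth stage).  A positive `J[i, j]` favours co-occurrence of components
#' `i` and `j`; a positive `g_a[i]` means treatment raises the occurrence
#' probability of component `i`; a positive `g_s[i]` means component `i`
#' favours the later growth stage.
#'
#' @param h Numeric vector of length N, per-component bias.
#' @param J N x N symmetric numeric matrix with zero diagonal; the pair term
#'   of the energy counts each unordered pair once (`i < j` convention), so
#'   couplings are stored symmetrically but never double-counted.
#' @param g_a,g_s Numeric vectors of length N; treatment and stage couplings.
#'   Default to zero vectors (plain pairwise maximum-entropy model).
#' @param names Optional character vector of component names.
#'
#' @return An object of class `maxent_params`.
#' @export
#' @examples
#' p <- maxent_params(h = c(-0.1, -0.1), J = matrix(c(0, 1, 1, 0), 2))
#' energy(c(1, 1), c(0, 0), p)
maxent_params <- function(h, J, g_a = NULL, g_s = NULL, names = NULL) {
  h <- as.numeric(h)
  n <- length(h)
  J <- as.matrix(J)
  if (!all(dim(J) == n)) {
    stop("`J` must be ", n, " x ", n, " to match `h`", call. = FALSE)
  }
  if (is.null(g_a)) g_a <- numeric(n)
  if (is.null(g_s)) g_s <- numeric(n)
  g_a <- as.numeric(g_a)
  g_s <- as.numeric(g_s)
  if (length(g_a) != n || length(g_s) != n) {
    stop("`g_a` and `g_s` must have the same length as `h`", call. = FALSE)
  }
  if (!all(is.finite(h), is.finite(J), is.finite(g_a), is.finite(g_s))) {
    stop("all parameters must be finite", call. = FALSE)
  }
  if (max(abs(J - t(J))) > 1e-8) {
    stop("`J` must be symmetric", call. = FALSE)
  }
  if (any(diag(J) != 0)) {
    stop("`J` must have a zero diagonal (no self-coupling)", call. = FALSE)
  }
  J <- (J + t(J)) / 2
  if (is.null(names)) names <- names(h)
  if (is.null(names)) names <- paste0("c", seq_len(n))
  names(h) <- names(g_a) <- names(g_s) <- names
  dimnames(J) <- list(names, names)
  structure(
    list(h = h, J = J, g_a = g_a, g_s = g_s),
    class = "maxent_params"
  )
}

#' @export
print.maxent_params <- function(x, ...) {
  n <- length(x$h)
  cat("<maxent_params> ", n, " components\n", sep = "")
  cat("  h   in [", round(min(x$h), 3), ", ", round(max(x$h), 3), "]\n", sep = "")
  od <- x$J[upper.tri(x$J)]
  if (length(od)) {
    cat("  J   in [", round(min(od), 3), ", ", round(max(od), 3), "]\n", sep = "")
  }
  cat("  g_a in [", round(min(x$g_a), 3), ", ", round(max(x$g_a), 3), "]\n", sep = "")
  cat("  g_s in [", round(min(x$g_s), 3), ", ", round(max(x$g_s), 3), "]\n", sep = "")
  invisible(x)
}

#' Draw random model parameters
#'
#' Convenience generator for simulation studies: every free parameter
#' (`h`, the upper triangle of `J`, `g_a`, `g_s`) is drawn independently and
#' uniformly from `[-limit, limit]` using the current RNG state.
#'
#' @param n_components Number of components N.
#' @param limit Half-width of the uniform range (default 1).
#' @param names Optional component names.
#' @return A [maxent_params] object.
#' @export
random_maxent_params <- function(n_components, limit = 1, names = NULL) {
  n <- n_components
  J <- matrix(0, n, n)
  if (n > 1) {
    J[upper.tri(J)] <- stats::runif(n * (n - 1) / 2, -limit, limit)
    J <- J + t(J)
  }
  maxent_params(
    h = stats::runif(n, -limit, limit), J = J,
    g_a = stats::runif(n, -limit, limit),
    g_s = stats::runif(n, -limit, limit),
    names = names
  )
}

#' Per-sample component state matrix
#'
#' The observation unit of the model: one row per sample, one column per
#' component.  Taxon components are binary presence/absence states; chemical
#' components are concentrations scaled to `[0, 1]`.  Taxa always come first,
#' so the component vector is `(taxa[1..n_m], chemicals[1..n_c])`.
#'
#' @param values Numeric samples x N matrix with values in `[0, 1]`.
#' @param kinds Character vector of length N, each `"binary"` or
#'   `"continuous"`.  Defaults to all binary.
#' @param n_m,n_c Counts of taxon and chemical components; derived from
#'   `kinds` when omitted.
#' @return An object of class `component_matrix`.
#' @export
component_matrix <- function(values, kinds = NULL, n_m = NULL, n_c = NULL) {
  values <- as.matrix(values)
  N <- ncol(values)
  if (is.null(kinds)) kinds <- rep("binary", N)
  if (length(kinds) != N || !all(kinds %in% c("binary", "continuous"))) {
    stop("`kinds` must give 'binary' or 'continuous' for each of the ",
         N, " components", call. = FALSE)
  }
  if (anyNA(values) || min(values) < 0 || max(values) > 1) {
    stop("component values must lie in [0, 1] with no missing entries",
         call. = FALSE)
  }
  bin <- values[, kinds == "binary", drop = FALSE]
  if (length(bin) && !all(bin %in% c(0, 1))) {
    stop("binary components must be exactly 0 or 1", call. = FALSE)
  }
  if (is.null(n_m)) n_m <- sum(kinds == "binary")
  if (is.null(n_c)) n_c <- N - n_m
  if (n_m + n_c != N) stop("n_m + n_c must equal ncol(values)", call. = FALSE)
  if (is.null(colnames(values))) colnames(values) <- paste0("c", seq_len(N))
  if (is.null(rownames(values))) rownames(values) <- paste0("s", seq_len(nrow(values)))
  structure(
    list(values = values, kinds = kinds, n_m = n_m, n_c = n_c),
    class = "component_matrix"
  )
}

#' @export
print.component_matrix <- function(x, ...) {
  cat("<component_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " components (", x$n_m, " taxa + ", x$n_c, " chemicals)\n", sep = "")
  invisible(x)
}

#' Per-sample environmental conditions
#'
#' One row per sample, aligned with the [component_matrix]: `ea` is the
#' antibiotic-treatment indicator (1 = treated, 0 = untreated) and `es` the
#' growth stage scaled to `[0, 1]`.
#'
#' @param ea Numeric vector in `{0, 1}`.
#' @param es Numeric vector in `[0, 1]`.
#' @param sample_ids Optional sample identifiers.
#' @return An object of class `environment_matrix` (a data frame with columns
#'   `ea` and `es`).
#' @export
environment_matrix <- function(ea, es, sample_ids = NULL) {
  ea <- as.numeric(ea)
  es <- as.numeric(es)
  if (length(ea) != length(es)) {
    stop("`ea` and `es` must have equal length", call. = FALSE)
  }
  if (!all(ea %in% c(0, 1))) stop("`ea` must be 0 or 1", call. = FALSE)
  if (anyNA(es) || min(es) < 0 || max(es) > 1) {
    stop("`es` must lie in [0, 1]", call. = FALSE)
  }
  out <- data.frame(ea = ea, es = es)
  if (!is.null(sample_ids)) rownames(out) <- sample_ids
  class(out) <- c("environment_matrix", "data.frame")
  out
}

# internal: check a component matrix and environment matrix describe the same
# samples in the same order
check_alignment <- function(components, env) {
  if (nrow(components$values) != nrow(env)) {
    stop("component and environment matrices describe different numbers ",
         "of samples", call. = FALSE)
  }
  rs <- rownames(components$values)
  re <- rownames(env)
  if (!is.null(rs) && !is.null(re) && !all(rs == re) &&
      !all(re == as.character(seq_len(nrow(env))))) {
    stop("sample identifiers of components and environment do not match",
         call. = FALSE)
  }
  invisible(TRUE)
}
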