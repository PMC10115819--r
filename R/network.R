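#' Signed interaction network from a fitted model
#'
#' Keeps every coupling `J[i, j]` whose p-value is at or below `alpha` and
#' annotates it with its sign: positive couplings favour co-occurrence
#' (drawn blue in the usual rendering), negative couplings disfavour it
#' (red).  The diagonal never contributes an edge.
#'
#' @param fit A [maxent_significance] result (a fit carrying p-values).
#' @param alpha Significance level for edge inclusion (default 0.05).
#' @return An object of class `signed_network`: `nodes` (component names)
#'   and `edges` (data frame `from`, `to`, `J`, `sign`, `p`), `alpha`.
#' @export
build_network <- function(fit, alpha = 0.05) {
  if (is.null(fit$p_values)) {
    stop("`fit` carries no p-values; run maxent_significance()",
         call. = FALSE)
  }
  J <- fit$params$J
  p <- fit$p_values$J
  nm <- names(fit$params$h)
  ut <- which(upper.tri(J) & p <= alpha, arr.ind = TRUE)
  edges <- data.frame(
    from = nm[ut[, 1]], to = nm[ut[, 2]],
    J = J[ut], sign = ifelse(J[ut] >= 0, "positive", "negative"),
    p = p[ut]
  )
  edges <- edges[order(edges$p, -abs(edges$J)), ]
  rownames(edges) <- NULL
  structure(list(nodes = nm, edges = edges, alpha = alpha),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat("<signed_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges at alpha = ", x$alpha, " (",
      sum(x$edges$sign == "positive"), " positive, ",
      sum(x$edges$sign == "negative"), " negative)\n", sep = "")
  invisible(x)
}

#' Classify components by their treatment and stage responses
#'
#' Places every component in one of four quadrants of the
#' (growth-stage coupling `g_s`, treatment coupling `g_a`) plane:
#' \describe{
#'   \item{Group I}{`g_s < 0`, `g_a > 0` — early-stage components boosted by
#'     the antibiotic.}
#'   \item{Group II}{`g_s > 0`, `g_a > 0` — late-stage components boosted by
#'     the antibiotic.}
#'   \item{Group III}{`g_s < 0`, `g_a < 0` — early-stage components
#'     suppressed by the antibiotic.}
#'   \item{Group IV}{`g_s > 0`, `g_a < 0` — late-stage components suppressed
#'     by the antibiotic.}
#' }
#' Components with `|g_a| <= delta` or `|g_s| <= delta` fall in no quadrant
#' and are reported as `"unclassified"`; the default dead zone is
#' `delta = 0`, i.e. pure sign quadrants with only exact zeros unclassified.
#'
#' @param params A [maxent_params] object (or a `maxent_fit`).
#' @param delta Dead-zone half width (default 0).
#' @return A data frame: `component`, `g_a`, `g_s`, `group` (factor with
#'   levels I-IV and unclassified).
#' @export
classify_response <- function(params, delta = 0) {
  if (inherits(params, "maxent_fit")) params <- params$params
  g_a <- params$g_a
  g_s <- params$g_s
  group <- rep("unclassified", length(g_a))
  group[g_s < -delta & g_a > delta] <- "I"
  group[g_s > delta & g_a > delta] <- "II"
  group[g_s < -delta & g_a < -delta] <- "III"
  group[g_s > delta & g_a < -delta] <- "IV"
  data.frame(
    component = names(g_a),
    g_a = unname(g_a), g_s = unname(g_s),
    group = factor(group, levels = c("I", "II", "III", "IV", "unclassified"))
  )
}
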