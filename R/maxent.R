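#' Energy of a community state
#'
#' The energy of state `sigma` under environment `env = (ea, es)` is
#' \deqn{E(\sigma | \epsilon) = -\Big(\sum_{i<j} J_{ij}\sigma_i\sigma_j
#'   + \epsilon_a \sum_i g_i^a \sigma_i + \epsilon_s \sum_i g_i^s \sigma_i
#'   + \sum_i h_i \sigma_i\Big),}
#' with the pair term counted once per unordered pair.  Low energy means high
#' occurrence probability.
#'
#' @param sigma Numeric state vector of length N with entries in `[0, 1]`.
#' @param env Length-2 numeric `(ea, es)`.
#' @param params A [maxent_params] object.
#' @return A single numeric energy value.
#' @export
#' @examples
#' p <- maxent_params(h = c(-0.1, -0.1), J = matrix(c(0, 1, 1, 0), 2))
#' energy(c(1, 1), c(0, 0), p) # -0.8
energy <- function(sigma, env, params) {
  sigma <- as.numeric(sigma)
  if (length(sigma) != length(params$h)) {
    stop("state has ", length(sigma), " components but the model has ",
         length(params$h), call. = FALSE)
  }
  if (anyNA(sigma) || min(sigma) < 0 || max(sigma) > 1) {
    stop("state components must lie in [0, 1]", call. = FALSE)
  }
  ea <- env[[1]]
  es <- env[[2]]
  field <- params$h + ea * params$g_a + es * params$g_s
  -(0.5 * sum(sigma * (params$J %*% sigma)) + sum(field * sigma))
}

#' Exact state distribution for small all-binary models
#'
#' Enumerates all `2^N` binary states and returns their probabilities
#' `P(sigma | env) = exp(-E) / sum(exp(-E))`.  Only feasible for
#' `N <= 20`; chemical (continuous) components are not supported here.
#'
#' @inheritParams energy
#' @param kinds Optional component kinds; if any are `"continuous"` the call
#'   is refused.
#' @return A data frame with one row per state: the state columns, `energy`
#'   and `prob`, plus attribute `"states"` holding the raw state matrix.
#' @export
exact_distribution <- function(params, env, kinds = NULL) {
  n <- length(params$h)
  if (!is.null(kinds) && any(kinds == "continuous")) {
    stop("exact enumeration supports binary components only; ",
         "continuous components require Gibbs sampling", call. = FALSE)
  }
  if (n > 20) {
    stop("exact enumeration is limited to N <= 20 components", call. = FALSE)
  }
  states <- enumerate_states(n)
  colnames(states) <- names(params$h)
  e <- state_energies(states, params, env)
  logp <- -e - max(-e)
  p <- exp(logp)
  p <- p / sum(p)
  out <- as.data.frame(states)
  out$energy <- e
  out$prob <- p
  attr(out, "states") <- states
  out
}

# all 2^n binary states; component 1 varies fastest, so the row index of
# state sigma is 1 + sum(sigma_i * 2^(i-1))
enumerate_states <- function(n) {
  idx <- 0:(2^n - 1)
  vapply(seq_len(n), function(i) bitwAnd(idx %/% 2^(i - 1), 1L),
         integer(length(idx)))
}

# energies of many states at once (rows of `states`)
state_energies <- function(states, params, env) {
  field <- params$h + env[[1]] * params$g_a + env[[2]] * params$g_s
  pair <- 0.5 * rowSums((states %*% params$J) * states)
  -(pair + as.numeric(states %*% field))
}

#' Gibbs sampling from the community model
#'
#' Systematic-scan Gibbs sampler.  Binary components are resampled from their
#' conditional Bernoulli distribution; continuous components from the
#' closed-form truncated-exponential conditional on `[0, 1]`.  Components
#' listed in `clamped` keep their initial value throughout.
#'
#' @inheritParams energy
#' @param params A [maxent_params] object.
#' @param env Length-2 `(ea, es)` environment.
#' @param n_sweeps Number of recorded sweeps (one sample per sweep after
#'   burn-in).
#' @param seed Integer seed; the sampler is a pure function of its arguments
#'   and this seed.
#' @param kinds Component kinds (`"binary"`/`"continuous"`); default all
#'   binary.
#' @param clamped Logical mask (length N) of components that are never
#'   updated.
#' @param init Optional initial state; random when omitted.
#' @param burn_in Discarded initial sweeps (default 1000).
#' @param thin Keep every `thin`-th sweep (default 1).
#' @return Numeric `n_sweeps` x N matrix of sampled states.
#' @export
gibbs_sample <- function(params, env, n_sweeps, seed,
                         kinds = NULL, clamped = NULL, init = NULL,
                         burn_in = 1000, thin = 1) {
  n <- length(params$h)
  if (is.null(kinds)) kinds <- rep("binary", n)
  if (is.null(clamped)) clamped <- rep(FALSE, n)
  set.seed(seed)
  if (is.null(init)) {
    init <- ifelse(kinds == "binary",
                   as.numeric(stats::runif(n) < 0.5), stats::runif(n))
  }
  out <- .cs_gibbs(params$h, params$J, params$g_a, params$g_s,
                   env[[1]], env[[2]], matrix(init, nrow = 1),
                   kinds == "binary", as.logical(clamped),
                   as.integer(n_sweeps), as.integer(burn_in),
                   as.integer(thin))
  colnames(out) <- names(params$h)
  out
}

#' Control settings for stochastic-approximation fitting
#'
#' Tunables of the Robbins-Monro fit.  The learning rate follows
#' `a_t = a0 / (1 + t / tau)`; `n_chains` persistent Gibbs chains are kept per
#' distinct environment and advanced `sweeps_per_iter` sweeps between
#' parameter updates.  Returned parameters are averaged over the final
#' `avg_frac` fraction of iterations.  Biases of degenerate (always present /
#' always absent) components are capped at `h_max`.
#'
#' @param n_iter Number of Robbins-Monro iterations (default 5000).
#' @param a0 Initial learning rate (default 0.2).
#' @param tau Learning-rate decay time constant in iterations (default 1000).
#' @param n_chains Persistent chains per distinct environment (default 100).
#' @param sweeps_per_iter Gibbs sweeps per iteration (default 1).
#' @param h_max Cap on `|h|` for degenerate components (default 10).
#' @param avg_frac Tail fraction used for Polyak averaging (default 0.2).
#' @return A list of class `maxent_control`.
#' @export
maxent_control <- function(n_iter = 5000, a0 = 0.2, tau = 1000,
                           n_chains = 100, sweeps_per_iter = 1,
                           h_max = 10, avg_frac = 0.2) {
  structure(
    list(n_iter = as.integer(n_iter), a0 = a0, tau = tau,
         n_chains = as.integer(n_chains),
         sweeps_per_iter = as.integer(sweeps_per_iter),
         h_max = h_max, avg_frac = avg_frac),
    class = "maxent_control"
  )
}

# observed sufficient statistics of a dataset:
# means of sigma_i, sigma_i*sigma_j, ea*sigma_i, es*sigma_i
observed_moments <- function(values, ea, es) {
  S <- nrow(values)
  list(
    h = colMeans(values),
    J = crossprod(values) / S,
    ga = colMeans(values * ea),
    gs = colMeans(values * es)
  )
}

# lean fitting core shared by fit_maxent() and the repeated-estimation loop
# of maxent_significance(): no class validation, no object construction
fit_core <- function(values, kinds, ea, es, control, seed) {
  obs <- observed_moments(values, ea, es)
  key <- paste(ea, es)
  envs <- !duplicated(key)
  env_w <- as.numeric(table(factor(key, levels = key[envs]))) / length(key)
  h0 <- ifelse(kinds == "binary",
               stats::qlogis(pmin(pmax(obs$h, 0.02), 0.98)), 0)
  set.seed(seed)
  res <- .cs_sa_fit(obs$h, obs$J, obs$ga, obs$gs,
                    ea[envs], es[envs], env_w,
                    kinds == "binary",
                    h0, matrix(0, ncol(values), ncol(values)),
                    numeric(ncol(values)), numeric(ncol(values)),
                    control$n_iter, control$a0, control$tau,
                    control$n_chains, control$sweeps_per_iter,
                    control$h_max, control$avg_frac,
                    length(unique(ea)) > 1, length(unique(es)) > 1)
  res$obs <- obs
  res
}

#' Fit the extended pairwise maximum-entropy model
#'
#' Maximum-likelihood estimation by stochastic approximation: parameters are
#' nudged toward matching the observed sufficient statistics (component
#' means, pairwise co-occurrence means and environment-weighted means)
#' against statistics simulated from persistent Gibbs chains, one block of
#' chains per distinct environment present in the data.
#'
#' The treatment couplings `g_a` are estimated only when the treatment
#' indicator actually varies across samples, and likewise `g_s` for the
#' growth stage; otherwise they are fixed at zero and the model reduces to
#' the plain pairwise maximum-entropy model.
#'
#' @param components A [component_matrix].
#' @param env An [environment_matrix] aligned with `components`.
#' @param control A [maxent_control] list of optimizer settings.
#' @param seed Integer seed for the simulation chains.
#' @return An object of class `maxent_fit` with elements `params`
#'   ([maxent_params]), `trace` (per-iteration worst moment mismatch),
#'   `moments` (observed and final simulated), `control`, `seed` and
#'   `estimated` (which parameter blocks were free).
#' @export
fit_maxent <- function(components, env, control = maxent_control(), seed = 1) {
  check_alignment(components, env)
  values <- components$values
  kinds <- components$kinds
  ea <- env$ea
  es <- env$es
  obs <- observed_moments(values, ea, es)

  degenerate <- kinds == "binary" & (obs$h == 0 | obs$h == 1)
  if (any(degenerate)) {
    warning("component(s) ", paste(names(obs$h)[degenerate], collapse = ", "),
            " are always absent or always present; their h is capped at ",
            "+/-", control$h_max, call. = FALSE)
  }

  res <- fit_core(values, kinds, ea, es, control, seed)
  nm <- colnames(values)
  params <- maxent_params(res$h, res$J, res$g_a, res$g_s, names = nm)
  sim <- list(h = stats::setNames(res$sim_h, nm), J = res$sim_J,
              ga = stats::setNames(res$sim_ga, nm),
              gs = stats::setNames(res$sim_gs, nm))
  structure(
    list(params = params, trace = res$trace,
         moments = list(observed = obs, simulated = sim),
         kinds = kinds, control = control, seed = seed,
         estimated = c(g_a = length(unique(ea)) > 1,
                       g_s = length(unique(es)) > 1)),
    class = "maxent_fit"
  )
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat("<maxent_fit> ", length(x$params$h), " components, ",
      x$control$n_iter, " iterations\n", sep = "")
  cat("  final moment mismatch (max |obs - sim|): ",
      signif(utils::tail(x$trace, 1), 3), "\n", sep = "")
  print(x$params)
  invisible(x)
}

# flatten a parameter set to one named vector (h, upper-tri J, g_a, g_s)
flatten_params <- function(p) {
  n <- length(p$h)
  ut <- upper.tri(p$J)
  jn <- outer(names(p$h), names(p$h), paste, sep = ":")[ut]
  c(stats::setNames(p$h, paste0("h.", names(p$h))),
    stats::setNames(p$J[ut], paste0("J.", jn)),
    stats::setNames(p$g_a, paste0("g_a.", names(p$h))),
    stats::setNames(p$g_s, paste0("g_s.", names(p$h))))
}

#' Per-parameter significance by repeated estimation
#'
#' Repeats the stochastic-approximation fit `n_reps` times and derives a
#' two-sided sign-stability p-value for every parameter:
#' `p = 2 * min(frac(theta <= 0), frac(theta >= 0))`, floored at
#' `1 / (n_reps + 1)` (no parameter can appear "infinitely significant" from
#' a finite number of repeats).
#'
#' Two resampling schemes are available.  `"bootstrap"` (the default)
#' resamples the samples with replacement before each repeat, so the spread
#' of the repeated estimates reflects sampling variability and the p-values
#' are approximately calibrated under a null parameter.  `"rerun"` repeats
#' the fit on the fixed data with fresh RNG streams only, so the spread
#' reflects Monte Carlo noise of the estimator alone; it measures the
#' stability of a reported sign, not sampling uncertainty (see the package
#' vignette for why this distinction matters).
#'
#' @inheritParams fit_maxent
#' @param n_reps Number of repeated fits (default 2000).
#' @param seed Integer seed controlling all repeats.
#' @param method `"bootstrap"` or `"rerun"` (see Details).
#' @param rep_control Optional [maxent_control] used for the repeated fits;
#'   defaults to `control`.  Lighter settings here trade p-value precision
#'   for speed.
#' @return An object of class `maxent_significance`: the point `fit` plus
#'   `p_values` (list with the shapes of the parameter blocks), `estimates`
#'   (reps x parameters matrix), `n_reps` and `method`.
#' @export
maxent_significance <- function(components, env, control = maxent_control(),
                                n_reps = 2000, seed = 1,
                                method = c("bootstrap", "rerun"),
                                rep_control = NULL) {
  method <- match.arg(method)
  if (n_reps < 100) {
    warning("n_reps < 100 gives unstable p-values", call. = FALSE)
  }
  if (is.null(rep_control)) rep_control <- control
  fit <- fit_maxent(components, env, control, seed = seed)

  S <- nrow(components$values)
  values <- components$values
  kinds <- components$kinds
  ut <- upper.tri(fit$params$J)
  est <- matrix(NA_real_, n_reps, length(flatten_params(fit$params)))
  set.seed(seed + 1L)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  for (r in seq_len(n_reps)) {
    if (method == "bootstrap") {
      set.seed(rep_seeds[r])
      idx <- sample.int(S, S, replace = TRUE)
      res <- fit_core(values[idx, , drop = FALSE], kinds,
                      env$ea[idx], env$es[idx], rep_control, rep_seeds[r])
    } else {
      res <- fit_core(values, kinds, env$ea, env$es, rep_control,
                      rep_seeds[r])
    }
    est[r, ] <- c(res$h, res$J[ut], res$g_a, res$g_s)
  }
  colnames(est) <- names(flatten_params(fit$params))

  p_flat <- apply(est, 2, function(v) {
    p <- 2 * min(mean(v <= 0), mean(v >= 0))
    min(max(p, 1 / (n_reps + 1)), 1)
  })
  n <- length(fit$params$h)
  nm <- names(fit$params$h)
  p_J <- matrix(1, n, n, dimnames = list(nm, nm))
  ut <- upper.tri(p_J)
  p_J[ut] <- p_flat[grep("^J\\.", names(p_flat))]
  p_J <- pmin(p_J, t(p_J))
  p_values <- list(
    h = stats::setNames(p_flat[grep("^h\\.", names(p_flat))], nm),
    J = p_J,
    g_a = stats::setNames(p_flat[grep("^g_a\\.", names(p_flat))], nm),
    g_s = stats::setNames(p_flat[grep("^g_s\\.", names(p_flat))], nm)
  )
  structure(
    c(fit, list(p_values = p_values, estimates = est,
                n_reps = n_reps, method = method)),
    class = c("maxent_significance", "maxent_fit")
  )
}

#' @export
print.maxent_significance <- function(x, ...) {
  cat("<maxent_significance> ", x$n_reps, " repeats, method = ",
      x$method, "\n", sep = "")
  sig <- sum(x$p_values$J[upper.tri(x$p_values$J)] <= 0.05)
  cat("  couplings with p <= 0.05: ", sig, "\n", sep = "")
  NextMethod()
}
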