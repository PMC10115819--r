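#' Stable states of the fitted energy landscape
#'
#' Enumerates all binary community states and reports the local minima of the
#' energy: states whose energy is strictly lower than that of every
#' single-flip neighbour.  These are the model's stable community
#' compositions at the given environment.  Chemical (continuous) components
#' cannot be flipped, so they are clamped at fixed levels and contribute an
#' effective field to the binary taxa plus a constant energy offset.
#'
#' @param params A [maxent_params] object.
#' @param env Length-2 `(ea, es)` environment.
#' @param kinds Component kinds; default all binary.
#' @param clamp Named (or positional) numeric values at which continuous
#'   components are held; default 0.5 for each.  Typically the dataset means.
#' @param basins If `TRUE` (default), assign every enumerated state to its
#'   minimum by steepest descent and report basin sizes.
#' @return An object of class `landscape_summary`: `minima` (data frame with
#'   `state` bitstring over the binary components, `energy`, `basin_size`),
#'   `basin_of` (integer vector over all `2^n` enumerated states), `flat`
#'   flag, `env`, and the binary component names.  A landscape with no strict
#'   minimum (all parameters zero) yields an empty `minima` table and
#'   `flat = TRUE`.
#' @export
#' @examples
#' p <- maxent_params(h = c(-0.1, -0.1), J = matrix(c(0, 1, 1, 0), 2))
#' find_minima(p, c(0, 0))$minima # (0,0) at E = 0 and (1,1) at E = -0.8
find_minima <- function(params, env, kinds = NULL, clamp = NULL,
                        basins = TRUE) {
  eff <- clamp_continuous(params, env, kinds, clamp)
  n <- length(eff$field)
  if (n == 0) stop("no binary components to enumerate", call. = FALSE)
  if (n > 20) {
    stop("exact landscape enumeration is limited to 20 binary components; ",
         "use descend() from multiple random starts instead", call. = FALSE)
  }
  states <- enumerate_states(n)
  # dE[k, i] = energy change of flipping component i in state k
  F <- states %*% eff$J + matrix(eff$field, nrow(states), n, byrow = TRUE)
  dE <- (2 * states - 1) * F
  e <- -(0.5 * rowSums((states %*% eff$J) * states) +
           as.numeric(states %*% eff$field)) + eff$offset
  is_min <- rowSums(dE > 0) == n

  flat <- !any(is_min)
  nm <- eff$names
  minima_idx <- which(is_min)
  basin_of <- NULL
  basin_size <- rep(NA_integer_, length(minima_idx))
  if (!flat && basins) {
    # successor map: flip the lowest-energy-improving component
    # (max.col on -dE with ties.method = "first" breaks ties toward the
    # lowest component index)
    best <- max.col(-dE, ties.method = "first")
    improves <- dE[cbind(seq_len(nrow(dE)), best)] < 0
    succ <- seq_len(nrow(states))
    succ[improves] <- bitwXor(succ[improves] - 1L,
                              as.integer(2^(best[improves] - 1))) + 1L
    basin_of <- succ
    repeat {
      nxt <- basin_of[basin_of]
      if (all(nxt == basin_of)) break
      basin_of <- nxt
    }
    basin_of <- match(basin_of, minima_idx)
    basin_size <- tabulate(basin_of, nbins = length(minima_idx))
  }

  ord <- order(e[minima_idx])
  minima_idx <- minima_idx[ord]
  if (!is.null(basin_of)) basin_of <- order(ord)[basin_of]
  minima <- data.frame(
    state = apply(states[minima_idx, , drop = FALSE], 1, paste, collapse = ""),
    energy = e[minima_idx],
    basin_size = if (!flat && basins) basin_size[ord]
                 else rep(NA_integer_, length(minima_idx))
  )
  structure(
    list(minima = minima, basin_of = basin_of, flat = flat,
         env = c(ea = env[[1]], es = env[[2]]), components = nm,
         clamped = eff$clamp),
    class = "landscape_summary"
  )
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat("<landscape_summary> env (ea, es) = (", x$env[1], ", ", x$env[2],
      ")\n", sep = "")
  if (x$flat) {
    cat("  flat landscape: no strict local minimum\n")
  } else {
    cat("  ", nrow(x$minima), " stable state(s):\n", sep = "")
    print(x$minima, ...)
  }
  invisible(x)
}

# reduce a mixed model to an effective all-binary one by clamping continuous
# components: their couplings shift the binary fields, their own terms give a
# constant energy offset
clamp_continuous <- function(params, env, kinds, clamp) {
  n <- length(params$h)
  if (is.null(kinds)) kinds <- rep("binary", n)
  bin <- which(kinds == "binary")
  con <- which(kinds == "continuous")
  field <- params$h + env[[1]] * params$g_a + env[[2]] * params$g_s
  offset <- 0
  cvals <- NULL
  if (length(con)) {
    if (is.null(clamp)) clamp <- rep(0.5, length(con))
    if (!is.null(names(clamp))) {
      clamp <- clamp[names(params$h)[con]]
    }
    if (length(clamp) != length(con) || anyNA(clamp)) {
      stop("`clamp` must give one value per continuous component",
           call. = FALSE)
    }
    cvals <- as.numeric(clamp)
    field_b <- field[bin] +
      as.numeric(params$J[bin, con, drop = FALSE] %*% cvals)
    offset <- -(0.5 * sum(cvals * (params$J[con, con, drop = FALSE] %*% cvals)) +
                  sum(field[con] * cvals))
  } else {
    field_b <- field[bin]
  }
  list(field = field_b, J = params$J[bin, bin, drop = FALSE],
       offset = offset, names = names(params$h)[bin],
       clamp = if (length(con)) stats::setNames(cvals, names(params$h)[con]))
}

#' Steepest descent to a stable state
#'
#' From a binary start state, repeatedly move to the lowest-energy
#' single-flip neighbour while that neighbour is strictly lower in energy;
#' ties are broken toward the lowest component index.  The energy sequence is
#' strictly decreasing, so the walk terminates — at a strict local minimum,
#' or immediately if no neighbour improves (a flat start is flagged rather
#' than walked).
#'
#' @inheritParams find_minima
#' @param state Binary start state over the binary components.
#' @return A list: final `state`, its `energy`, number of `steps`, and
#'   `flat` (`TRUE` when the start had no strictly lower neighbour and is not
#'   a strict minimum itself).
#' @export
descend <- function(state, params, env, kinds = NULL, clamp = NULL) {
  eff <- clamp_continuous(params, env, kinds, clamp)
  sigma <- as.numeric(state)
  if (length(sigma) != length(eff$field) || !all(sigma %in% c(0, 1))) {
    stop("`state` must be a binary vector over the ",
         length(eff$field), " binary components", call. = FALSE)
  }
  e_of <- function(s) {
    -(0.5 * sum(s * (eff$J %*% s)) + sum(eff$field * s)) + eff$offset
  }
  steps <- 0L
  repeat {
    F <- as.numeric(eff$J %*% sigma) + eff$field
    dE <- (2 * sigma - 1) * F
    if (min(dE) >= 0) break
    i <- which.min(dE)
    sigma[i] <- 1 - sigma[i]
    steps <- steps + 1L
  }
  F <- as.numeric(eff$J %*% sigma) + eff$field
  dE <- (2 * sigma - 1) * F
  list(state = sigma, energy = e_of(sigma), steps = steps,
       flat = steps == 0L && min(dE) >= 0 && any(dE == 0))
}

#' Landscape across the treatment and growth-stage gradient
#'
#' Recomputes the stable states over a grid of environments — both treatment
#' levels crossed with a grid of growth stages — so the appearance,
#' disappearance and deepening of stable community states along calf
#' development can be tabulated (and surface-plotted downstream).  Minima are
#' ordered by energy at each grid point.
#'
#' @inheritParams find_minima
#' @param ea_values Treatment levels to scan (default `c(0, 1)`).
#' @param es_grid Growth-stage grid on `[0, 1]`; at least 2 points unless a
#'   single point is explicitly requested.
#' @return A data frame with one row per (gridpoint, minimum): `ea`, `es`,
#'   `state`, `energy`, `basin_size`, `flat`.
#' @export
landscape_over_gradient <- function(params, ea_values = c(0, 1),
                                    es_grid = seq(0, 1, length.out = 11),
                                    kinds = NULL, clamp = NULL) {
  rows <- list()
  for (ea in ea_values) {
    for (es in es_grid) {
      ls <- find_minima(params, c(ea, es), kinds = kinds, clamp = clamp)
      if (ls$flat) {
        rows[[length(rows) + 1L]] <- data.frame(
          ea = ea, es = es, state = NA_character_,
          energy = NA_real_, basin_size = NA_integer_, flat = TRUE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          ea = ea, es = es, state = ls$minima$state,
          energy = ls$minima$energy, basin_size = ls$minima$basin_size,
          flat = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
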