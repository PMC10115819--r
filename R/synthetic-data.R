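#' Ground-truth model for simulation studies
#'
#' Couples a known parameter set with component kinds and a list of
#' environments, so communities can be sampled from it and the sampler /
#' estimator pair can be validated against the truth.
#'
#' @param params A [maxent_params] object.
#' @param component_kinds Character vector (`"binary"`/`"continuous"`), one
#'   per component; default all binary.
#' @param environments A list of length-2 `(ea, es)` vectors with
#'   `ea` in `{0, 1}` and `es` in `[0, 1]`.
#' @return An object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(params, component_kinds = NULL,
                               environments = list(c(0, 0))) {
  n <- length(params$h)
  if (is.null(component_kinds)) component_kinds <- rep("binary", n)
  stopifnot(length(component_kinds) == n,
            all(component_kinds %in% c("binary", "continuous")))
  for (e in environments) {
    stopifnot(length(e) == 2, e[[1]] %in% c(0, 1),
              e[[2]] >= 0, e[[2]] <= 1)
  }
  structure(
    list(params = params, n_components = n,
         component_kinds = component_kinds, environments = environments),
    class = "ground_truth_model"
  )
}

#' Sample communities from a known model
#'
#' Draws `n_samples_per_env` community states from `P(sigma | env)` for each
#' environment of the ground-truth model.  All-binary models with up to 20
#' components are sampled exactly (full enumeration of the state
#' distribution); models with continuous components fall back to Gibbs
#' sampling.  The output is reproducible: it is a pure function of the model,
#' the sample size and the seed.
#'
#' @param model A [ground_truth_model].
#' @param n_samples_per_env Samples to draw per environment.
#' @param seed Integer seed.
#' @param method `"auto"` (default), `"exact"` or `"gibbs"`.  Requesting
#'   `"exact"` with continuous components is an error.
#' @param burn_in,thin Gibbs settings (used only on the Gibbs path).
#' @return A list with `components` (a [component_matrix]) and `env`
#'   (an [environment_matrix]).
#' @export
generate_community <- function(model, n_samples_per_env, seed,
                               method = c("auto", "exact", "gibbs"),
                               burn_in = 1000, thin = 5) {
  method <- match.arg(method)
  has_cont <- any(model$component_kinds == "continuous")
  if (method == "exact" && has_cont) {
    stop("exact enumeration sampling is unsupported with continuous ",
         "components; use method = 'gibbs'", call. = FALSE)
  }
  if (method == "auto") method <- if (has_cont) "gibbs" else "exact"
  if (method == "exact" && model$n_components > 20) {
    stop("exact sampling is limited to 20 components", call. = FALSE)
  }

  set.seed(seed)
  vals <- list()
  ea <- es <- numeric(0)
  for (e in model$environments) {
    if (method == "exact") {
      dist <- exact_distribution(model$params, e)
      states <- attr(dist, "states")
      idx <- sample.int(nrow(states), n_samples_per_env,
                        replace = TRUE, prob = dist$prob)
      draw <- states[idx, , drop = FALSE]
    } else {
      draw <- .cs_gibbs(
        model$params$h, model$params$J, model$params$g_a, model$params$g_s,
        e[[1]], e[[2]],
        matrix(ifelse(model$component_kinds == "binary",
                      as.numeric(stats::runif(model$n_components) < 0.5),
                      stats::runif(model$n_components)), nrow = 1),
        model$component_kinds == "binary",
        rep(FALSE, model$n_components),
        as.integer(n_samples_per_env), as.integer(burn_in), as.integer(thin))
    }
    vals[[length(vals) + 1L]] <- draw
    ea <- c(ea, rep(e[[1]], n_samples_per_env))
    es <- c(es, rep(e[[2]], n_samples_per_env))
  }
  values <- do.call(rbind, vals)
  colnames(values) <- names(model$params$h)
  rownames(values) <- sprintf("s%04d", seq_len(nrow(values)))
  list(
    components = component_matrix(values, model$component_kinds),
    env = environment_matrix(ea, es, rownames(values))
  )
}

# genus -> taxonomy-string table for the mock study; families chosen so that
# family-level internal standards (e.g. Enterobacteriaceae/Escherichia) exist
study_taxa <- function() {
  g <- c("Prevotella", "Bacteroides", "Parabacteroides", "Alistipes",
         "Faecalibacterium", "Oscillospira", "Ruminococcus",
         "Dorea", "Blautia", "Coprococcus", "Roseburia", "Clostridium",
         "Butyrivibrio", "Anaerostipes",
         "Lactobacillus", "Streptococcus", "Enterococcus",
         "Megasphaera", "Selenomonas", "Mitsuokella", "Dialister",
         "Phascolarctobacterium", "Succinivibrio", "Escherichia",
         "Sutterella", "Desulfovibrio", "Campylobacter", "Fibrobacter",
         "Treponema", "Akkermansia", "Bifidobacterium", "Eubacterium",
         "Turicibacter", "Sarcina", "Methanobrevibacter", "Methanosphaera")
  f <- c("Prevotellaceae", "Bacteroidaceae", "Porphyromonadaceae",
         "Rikenellaceae", "Ruminococcaceae", "Ruminococcaceae",
         "Ruminococcaceae", "Lachnospiraceae", "Lachnospiraceae",
         "Lachnospiraceae", "Lachnospiraceae", "Lachnospiraceae",
         "Lachnospiraceae", "Lachnospiraceae", "Lactobacillaceae",
         "Streptococcaceae", "Enterococcaceae", "Veillonellaceae",
         "Veillonellaceae", "Veillonellaceae", "Veillonellaceae",
         "Veillonellaceae", "Succinivibrionaceae", "Enterobacteriaceae",
         "Alcaligenaceae", "Desulfovibrionaceae", "Campylobacteraceae",
         "Fibrobacteraceae", "Spirochaetaceae", "Verrucomicrobiaceae",
         "Bifidobacteriaceae", "Eubacteriaceae", "Turicibacteraceae",
         "Clostridiaceae", "Methanobacteriaceae", "Methanobacteriaceae")
  k <- ifelse(g %in% c("Methanobrevibacter", "Methanosphaera"),
              "Archaea", "Bacteria")
  data.frame(genus = g, family = f, kingdom = k,
             taxonomy = paste0("k__", k, ";f__", f, ";g__", g))
}

# per-genus generator settings for the mock study: baseline log intensity,
# stage trend and treatment (CTC) shift on the log scale
study_effects <- function(effect_size = 1) {
  tx <- study_taxa()
  n <- nrow(tx)
  base <- seq(2.5, -6.5, length.out = n)
  names(base) <- tx$genus
  # commoner taxa get the higher baselines; keep the two designated
  # responders at intermediate prevalence so treatment can move them across
  # the detection threshold
  base["Methanobrevibacter"] <- -4.2
  base["Dorea"] <- -1
  stage <- stats::setNames(rep(0, n), tx$genus)
  stage[c("Prevotella", "Ruminococcus", "Oscillospira", "Fibrobacter",
          "Treponema", "Megasphaera")] <- c(1.5, 1.2, 1.0, 1.4, 1.0, 0.8)
  stage[c("Lactobacillus", "Escherichia", "Streptococcus",
          "Bifidobacterium", "Enterococcus")] <- c(-1.5, -1.8, -1.0, -1.2, -0.8)
  treat <- stats::setNames(rep(0, n), tx$genus)
  # strong designated responders: the methanogen rises under CTC, the
  # butyrate producer falls
  treat["Methanobrevibacter"] <- 5
  treat["Dorea"] <- -4
  # milder responders so that roughly a third of the genera react
  treat[c("Methanosphaera", "Sarcina", "Turicibacter", "Streptococcus",
          "Escherichia")] <- 1.2
  treat[c("Butyrivibrio", "Roseburia", "Coprococcus", "Anaerostipes",
          "Lactobacillus")] <- -1.2
  list(taxa = tx, base = base, stage = stage, treat = treat * effect_size)
}

#' Simulate a mock two-group calf study
#'
#' Generates a complete study the shape of a 12-animal antibiotic trial: two
#' balanced groups (`CON`, fed the antibiotic; `EXP`, antibiotic-free), three
#' sampling days (3, 30, 60), one sample per animal per day.  Genus-level
#' relative abundances arise from log-normal intensities (baseline x stage
#' trend x group effect x animal effect x noise) normalized to sum to one,
#' which produces the realistic sparsity the presence/absence threshold
#' needs.  Eight fecal chemicals and four serum analytes are generated on a
#' log-normal scale.
#'
#' Under the `"trial"` profile the treatment raises a methanogen-like
#' genus (*Methanobrevibacter*), suppresses a butyrate-producing genus
#' (*Dorea*, family Lachnospiraceae) together with fecal butyrate and serum
#' IgA, and nudges about a third of the remaining genera; `"null"` removes
#' every group effect.
#'
#' @param n_animals Total number of animals (even; >= 4); default 12.
#' @param seed Integer seed; the study is a pure function of the arguments
#'   and the seed.
#' @param effect_profile `"trial"` (default) or `"null"`.
#' @param effect_size Multiplier on all treatment effects (default 1).
#' @return An object of class `mock_study`: `metadata` (sample_id,
#'   animal_id, group, day), `abundance` (samples x genera relative
#'   abundances, taxonomy strings as column names), `chemicals` (samples x 8),
#'   `physiology` (samples x 4), and `taxa` (the genus/family/taxonomy
#'   table).
#' @export
generate_study <- function(n_animals = 12, seed = 1,
                           effect_profile = c("trial", "null"),
                           effect_size = 1) {
  effect_profile <- match.arg(effect_profile)
  if (n_animals < 4) {
    stop("the design needs at least 4 animals (2 per group)", call. = FALSE)
  }
  if (n_animals %% 2 != 0) {
    stop("`n_animals` must be even for balanced groups", call. = FALSE)
  }
  if (effect_profile == "null") effect_size <- 0
  eff <- study_effects(effect_size)
  days <- c(3, 30, 60)
  stage <- c(`3` = 0, `30` = 0.53, `60` = 1)

  set.seed(seed)
  animals <- sprintf("A%02d", seq_len(n_animals))
  group <- rep(c("CON", "EXP"), each = n_animals / 2)
  meta <- data.frame(
    sample_id = as.vector(outer(animals, days,
                                function(a, d) paste0(a, "_d", d))),
    animal_id = rep(animals, times = length(days)),
    group = rep(group, times = length(days)),
    day = rep(days, each = n_animals)
  )
  meta <- meta[order(meta$animal_id, meta$day), ]
  rownames(meta) <- meta$sample_id

  n_g <- nrow(eff$taxa)
  animal_re <- matrix(stats::rnorm(n_animals * n_g, 0, 0.6), n_animals,
                      dimnames = list(animals, eff$taxa$genus))
  ctc <- as.numeric(meta$group == "CON")
  st <- stage[as.character(meta$day)]
  logint <- matrix(eff$base, nrow(meta), n_g, byrow = TRUE) +
    outer(st, eff$stage) +
    outer(ctc * st, eff$treat) + # treatment effects build up with exposure
    animal_re[meta$animal_id, ] +
    matrix(stats::rnorm(nrow(meta) * n_g, 0, 1.1), nrow(meta))
  inten <- exp(logint)
  abundance <- inten / rowSums(inten)
  dimnames(abundance) <- list(meta$sample_id, eff$taxa$taxonomy)

  chem_names <- c("acetate", "propionate", "butyrate", "isobutyrate",
                  "valerate", "isovalerate", "lactate", "phosphate")
  chem_base <- c(3.8, 3.0, 2.3, 1.0, 0.8, 0.7, 1.5, 2.0)
  chem_stage <- c(0.6, 0.8, 0.9, 0.3, 0.3, 0.3, -1.0, 0.2)
  chem_treat <- c(0, -0.15, -0.9, 0, 0, 0, 0.3, 0) * effect_size
  chem_animal <- matrix(stats::rnorm(n_animals * 8, 0, 0.15), n_animals,
                        dimnames = list(animals, chem_names))
  chemicals <- exp(
    matrix(chem_base, nrow(meta), 8, byrow = TRUE) +
      outer(st, chem_stage) +
      outer(ctc * st, chem_treat) +
      chem_animal[meta$animal_id, ] +
      matrix(stats::rnorm(nrow(meta) * 8, 0, 0.25), nrow(meta))
  )
  dimnames(chemicals) <- list(meta$sample_id, chem_names)

  phys_names <- c("glucose", "T_Cho", "NEFA", "IgA")
  phys_base <- c(4.6, 4.4, 5.0, 3.0)
  phys_stage <- c(-0.2, 0.3, -0.4, 0.5)
  phys_treat <- c(0, 0, 0, -0.5) * effect_size
  phys_animal <- matrix(stats::rnorm(n_animals * 4, 0, 0.1), n_animals,
                        dimnames = list(animals, phys_names))
  physiology <- exp(
    matrix(phys_base, nrow(meta), 4, byrow = TRUE) +
      outer(st, phys_stage) +
      outer(ctc * st, phys_treat) +
      phys_animal[meta$animal_id, ] +
      matrix(stats::rnorm(nrow(meta) * 4, 0, 0.2), nrow(meta))
  )
  dimnames(physiology) <- list(meta$sample_id, phys_names)

  structure(
    list(metadata = meta, abundance = abundance, chemicals = chemicals,
         physiology = physiology, taxa = eff$taxa,
         effect_profile = effect_profile, effect_size = effect_size,
         seed = seed),
    class = "mock_study"
  )
}

#' @export
print.mock_study <- function(x, ...) {
  cat("<mock_study> ", nrow(x$metadata), " samples (",
      length(unique(x$metadata$animal_id)), " animals x ",
      length(unique(x$metadata$day)), " days), profile = ",
      x$effect_profile, "\n", sep = "")
  invisible(x)
}

#' Simulate a linear non-Gaussian structural equation model
#'
#' Draws `x = B x + e` in the true causal order (`b_matrix` must be strictly
#' lower triangular, so the model is acyclic by construction), then shuffles
#' the column order and records the permutation — exactly the situation a
#' causal-discovery method must undo.
#'
#' @param b_matrix Strictly lower-triangular numeric matrix of connection
#'   strengths (`b[i, j]` = effect of variable j on variable i, in the true
#'   order).
#' @param noise Character vector of per-variable noise distributions, each
#'   `"uniform"`, `"laplace"` or `"gaussian"`; recycled.  Gaussian noise
#'   makes the causal direction unidentifiable and triggers a warning unless
#'   `allow_gaussian = TRUE`.
#' @param n Number of observations.
#' @param seed Integer seed.
#' @param scale Per-variable noise standard deviations (recycled, default 1).
#' @param allow_gaussian Silence the Gaussian-identifiability warning.
#' @return An `n` x p numeric matrix of the observed (shuffled) variables,
#'   with attributes `permutation` (observed column -> true variable index),
#'   `b_true` and `true_names`.
#' @export
generate_sem <- function(b_matrix, noise = "uniform", n, seed,
                         scale = 1, allow_gaussian = FALSE) {
  B <- as.matrix(b_matrix)
  p <- nrow(B)
  stopifnot(ncol(B) == p)
  if (any(B[upper.tri(B, diag = TRUE)] != 0)) {
    stop("`b_matrix` must be strictly lower triangular ",
         "(acyclic in the true order)", call. = FALSE)
  }
  noise <- rep_len(noise, p)
  scale <- rep_len(scale, p)
  if (!all(noise %in% c("uniform", "laplace", "gaussian"))) {
    stop("noise distributions must be uniform, laplace or gaussian",
         call. = FALSE)
  }
  if (any(noise == "gaussian") && !allow_gaussian) {
    warning("Gaussian noise makes the causal direction unidentifiable",
            call. = FALSE)
  }
  set.seed(seed)
  X <- matrix(0, n, p)
  for (j in seq_len(p)) {
    e <- switch(noise[j],
      uniform = stats::runif(n, -sqrt(3), sqrt(3)) * scale[j],
      laplace = {
        u <- stats::runif(n, -0.5, 0.5)
        -sign(u) * log(1 - 2 * abs(u)) / sqrt(2) * scale[j]
      },
      gaussian = stats::rnorm(n, 0, scale[j])
    )
    X[, j] <- if (j > 1) {
      as.numeric(X[, seq_len(j - 1), drop = FALSE] %*% B[j, seq_len(j - 1)]) + e
    } else e
  }
  true_names <- paste0("x", seq_len(p))
  perm <- sample.int(p)
  out <- X[, perm, drop = FALSE]
  colnames(out) <- true_names[perm]
  attr(out, "permutation") <- perm
  attr(out, "b_true") <- B
  attr(out, "true_names") <- true_names
  out
}
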