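#' Run the whole analysis pipeline on a study
#'
#' Chains the stages end to end, the way the analysis is meant to be used on
#' a real dataset: preprocessing (binarize, prevalence-filter, scale,
#' encode), maximum-entropy fitting with repeated-estimation significance,
#' the signed interaction network and treatment/stage response
#' classification, association-rule screening for treatment-linked items,
#' and DirectLiNGAM causal discovery on per-animal log-scale changes from
#' the baseline day.
#'
#' For the causal stage the selected variables (treatment flag plus focal
#' chemicals/taxa) are log-transformed before the baseline-day subtraction —
#' concentrations and abundances act multiplicatively, so fold changes are
#' the scale on which a linear causal model is well specified — and the
#' all-zero baseline rows are dropped before estimation, since they carry no
#' information about treatment response.
#'
#' @param study A [generate_study] result (or compatible list).
#' @param focal_taxa Genus names carried into the causal stage (default the
#'   methanogen and butyrate-producer read-outs).
#' @param focal_chemicals Chemical names carried into the causal stage.
#' @param control [maxent_control] settings for the fit.
#' @param n_reps Repeats for the significance stage (default 200).
#' @param alpha Edge-inclusion level for the network (default 0.05).
#' @param min_support,min_confidence Association-rule thresholds.
#' @param seed Integer seed for the stochastic stages.
#' @param significance Set `FALSE` to skip the repeated-estimation stage
#'   (no p-values, no network; faster).
#' @return A list with `preprocessed`, `fit`, `classification`, `network`
#'   (unless `significance = FALSE`), `rules` (rules mentioning the
#'   treatment item), `causal` (the [direct_lingam] model) and
#'   `causal_data` (the table it was fitted to).
#' @export
run_pipeline <- function(study,
                         focal_taxa = c("Methanobrevibacter", "Dorea"),
                         focal_chemicals = "butyrate",
                         control = maxent_control(n_iter = 1500,
                                                  n_chains = 30),
                         n_reps = 200, alpha = 0.05,
                         min_support = 0.2, min_confidence = 0.8,
                         seed = 1, significance = TRUE) {
  pp <- preprocess_study(study)

  if (significance) {
    fit <- suppressWarnings(maxent_significance(
      pp$components, pp$env, control, n_reps = n_reps, seed = seed,
      rep_control = maxent_control(n_iter = 300, n_chains = 10, tau = 150)))
    network <- build_network(fit, alpha = alpha)
  } else {
    fit <- suppressWarnings(fit_maxent(pp$components, pp$env, control,
                                       seed = seed))
    network <- NULL
  }
  classification <- classify_response(fit$params)

  tr <- build_transactions(pp$binary, study$physiology, study$metadata)
  rules <- mine_rules(tr, min_support = min_support,
                      min_confidence = min_confidence, max_len = 2)
  ctc_rules <- rules_about(rules, "CTC")

  # causal stage on log-scale changes from the baseline day
  meta <- study$metadata
  genus <- genus_from_taxonomy(colnames(study$abundance))
  cd <- data.frame(animal_id = meta$animal_id, day = meta$day)
  for (g in focal_taxa) {
    cd[[g]] <- log(study$abundance[, which(genus == g)[1]] + 1e-6)
  }
  for (ch in focal_chemicals) {
    cd[[ch]] <- log(study$chemicals[, ch])
  }
  dl <- delta_transform(cd, keep_baseline = FALSE)
  dl$CTC <- as.numeric(meta$group[match(dl$animal_id, meta$animal_id)] == "CON")
  causal_data <- dl[, c("CTC", focal_chemicals, focal_taxa)]
  causal <- suppressWarnings(direct_lingam(causal_data))

  list(preprocessed = pp, fit = fit, classification = classification,
       network = network, rules = ctc_rules, causal = causal,
       causal_data = causal_data)
}
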