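#' Binarize relative abundances into presence/absence
#'
#' A genus is scored present (1) in a sample when its relative abundance is
#' strictly greater than the detection threshold, and absent (0) otherwise —
#' the threshold itself counts as absent, the usual detection-limit reading.
#'
#' @param abundance Samples x taxa numeric matrix of relative abundances in
#'   `[0, 1]`.
#' @param threshold Detection threshold (default 0.001).
#' @return Binary matrix of the same shape and dimnames.
#' @export
binarize_abundance <- function(abundance, threshold = 0.001) {
  abundance <- as.matrix(abundance)
  if (anyNA(abundance) || min(abundance) < 0) {
    stop("abundances must be nonnegative with no missing values",
         call. = FALSE)
  }
  out <- (abundance > threshold) * 1
  dimnames(out) <- dimnames(abundance)
  out
}

#' Prevalence filter for taxa
#'
#' Retains taxa that appear in more than `min_exclusive` and fewer than
#' `max_exclusive` samples (both bounds exclusive): ubiquitous and
#' near-absent taxa carry no co-occurrence information for the model.
#' With the defaults and a 36-sample study, a taxon present in 3 to 34
#' samples is kept.
#'
#' @param binary Samples x taxa binary matrix (see [binarize_abundance]).
#' @param min_exclusive,max_exclusive Exclusive presence-count bounds
#'   (defaults 2 and 35).
#' @return Character vector of retained taxon names, in their original
#'   column order.
#' @export
filter_prevalence <- function(binary, min_exclusive = 2, max_exclusive = 35) {
  binary <- as.matrix(binary)
  counts <- colSums(binary)
  keep <- counts > min_exclusive & counts < max_exclusive
  if (!any(keep)) {
    stop("no taxon passes the prevalence filter (",
         min_exclusive, ", ", max_exclusive, "); presence counts ranged ",
         min(counts), "-", max(counts), " over ", nrow(binary), " samples",
         call. = FALSE)
  }
  colnames(binary)[keep]
}

#' Scale chemical concentrations to the unit interval
#'
#' Per-analyte min-max scaling `(x - min) / (max - min)`, so the smallest
#' observed concentration maps to 0 and the largest to 1.  A constant
#' analyte is mapped to all zeros (with a warning) rather than NaN, to keep
#' the downstream model runnable.
#'
#' @param chemicals Samples x analytes numeric matrix.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
scale_chemicals <- function(chemicals) {
  chemicals <- as.matrix(chemicals)
  if (anyNA(chemicals) || any(!is.finite(chemicals))) {
    stop("chemical values must be finite", call. = FALSE)
  }
  rng <- apply(chemicals, 2, range)
  span <- rng[2, ] - rng[1, ]
  const <- span == 0
  if (any(const)) {
    warning("constant analyte(s) ",
            paste(colnames(chemicals)[const], collapse = ", "),
            " scaled to 0", call. = FALSE)
    span[const] <- 1
  }
  out <- sweep(sweep(chemicals, 2, rng[1, ]), 2, span, "/")
  out[, const] <- 0
  out
}

#' Encode treatment and growth stage as model environments
#'
#' The treated group (`CON`, fed the antibiotic) maps to `ea = 1` and the
#' antibiotic-free group (`EXP`) to `ea = 0`.  Sampling days map onto the
#' unit interval by the fixed dictionary `3 -> 0`, `30 -> 0.53`, `60 -> 1`;
#' any other day is an error (no interpolation).
#'
#' @param metadata Data frame with columns `group` (`"CON"`/`"EXP"`) and
#'   `day` (3, 30 or 60); row names or a `sample_id` column name the
#'   samples.
#' @return An [environment_matrix] with one row per metadata row.
#' @export
encode_environment <- function(metadata) {
  if (!all(c("group", "day") %in% names(metadata))) {
    stop("metadata needs `group` and `day` columns", call. = FALSE)
  }
  if (!all(metadata$group %in% c("CON", "EXP"))) {
    stop("group must be 'CON' or 'EXP'", call. = FALSE)
  }
  stage <- c(`3` = 0, `30` = 0.53, `60` = 1)
  key <- as.character(metadata$day)
  if (!all(key %in% names(stage))) {
    stop("unknown day(s): ", paste(unique(key[!key %in% names(stage)]),
                                   collapse = ", "),
         "; expected 3, 30 or 60", call. = FALSE)
  }
  ids <- if ("sample_id" %in% names(metadata)) metadata$sample_id
         else rownames(metadata)
  environment_matrix(
    ea = as.numeric(metadata$group == "CON"),
    es = unname(stage[key]),
    sample_ids = ids
  )
}

#' Assemble taxa and chemicals into one component matrix
#'
#' Concatenates binarized taxa (first) and scaled chemicals (after) into the
#' state vector the model observes, recording `n_m` and `n_c`.  Sample sets
#' must match exactly and in order.
#'
#' @param binary Samples x taxa binary matrix.
#' @param chemicals Optional samples x analytes matrix scaled to `[0, 1]`.
#' @return A [component_matrix] with `n_m = ncol(binary)` and
#'   `n_c = ncol(chemicals)`.
#' @export
assemble_components <- function(binary, chemicals = NULL) {
  binary <- as.matrix(binary)
  if (is.null(chemicals)) {
    return(component_matrix(binary, rep("binary", ncol(binary))))
  }
  chemicals <- as.matrix(chemicals)
  if (nrow(binary) != nrow(chemicals) ||
      (!is.null(rownames(binary)) && !is.null(rownames(chemicals)) &&
       !all(rownames(binary) == rownames(chemicals)))) {
    stop("taxa and chemical tables describe different samples ",
         "(or a different sample order)", call. = FALSE)
  }
  component_matrix(
    cbind(binary, chemicals),
    c(rep("binary", ncol(binary)), rep("continuous", ncol(chemicals))),
    n_m = ncol(binary), n_c = ncol(chemicals)
  )
}

#' Per-group Pearson correlations between analytes and taxa
#'
#' Computes the Pearson correlation of every (analyte, taxon) pair within
#' each treatment group separately, by default using only the 30- and 60-day
#' samples (the early, day-3 communities are still assembling and are
#' excluded).  A zero-variance column yields `NA` — undefined, not zero.
#'
#' @param acids Samples x analytes numeric matrix.
#' @param genera Samples x taxa numeric matrix (same samples, same order).
#' @param group Character/factor vector of group labels per sample.
#' @param day Optional numeric vector of sampling days per sample; required
#'   when `days` filtering is wanted.
#' @param days Days to keep (default `c(30, 60)`); `NULL` keeps all.
#' @return A long data frame: `group`, `analyte`, `taxon`, `r`.
#' @export
correlation_matrix <- function(acids, genera, group, day = NULL,
                               days = c(30, 60)) {
  acids <- as.matrix(acids)
  genera <- as.matrix(genera)
  if (is.null(colnames(acids))) {
    colnames(acids) <- paste0("analyte", seq_len(ncol(acids)))
  }
  if (is.null(colnames(genera))) {
    colnames(genera) <- paste0("taxon", seq_len(ncol(genera)))
  }
  stopifnot(nrow(acids) == nrow(genera), length(group) == nrow(acids))
  keep <- rep(TRUE, nrow(acids))
  if (!is.null(day) && !is.null(days)) keep <- day %in% days
  out <- list()
  for (g in unique(group)) {
    m <- keep & group == g
    if (sum(m) < 3) {
      stop("group ", g, " has fewer than 3 samples after day filtering",
           call. = FALSE)
    }
    r <- suppressWarnings(stats::cor(acids[m, , drop = FALSE],
                                     genera[m, , drop = FALSE]))
    out[[g]] <- data.frame(
      group = g,
      analyte = rep(rownames(r), times = ncol(r)),
      taxon = rep(colnames(r), each = nrow(r)),
      r = as.vector(r)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parse QIIME-classic taxonomy strings down to genus
#'
#' Extracts the `g__` field from strings like
#' `"k__Bacteria;...;f__Lachnospiraceae;g__Dorea"`.  Unassigned or empty
#' genus fields give `NA` (such columns are typically dropped before
#' modelling).
#'
#' @param taxonomy Character vector of taxonomy strings.
#' @return Character vector of genus names (`NA` where unassigned).
#' @export
genus_from_taxonomy <- function(taxonomy) {
  m <- regmatches(taxonomy, regexpr("g__[^;]*", taxonomy))
  out <- rep(NA_character_, length(taxonomy))
  hit <- grepl("g__[^;]*", taxonomy)
  g <- sub("^g__", "", m)
  g[g == ""] <- NA_character_
  out[hit] <- g
  out
}

#' Run the full preprocessing chain on a mock or real study
#'
#' Convenience wrapper: binarize abundances, apply the prevalence filter,
#' min-max scale the chemicals, encode the environments and assemble the
#' component matrix.  Column names of the abundance table may be taxonomy
#' strings; they are collapsed to genus names.
#'
#' @param study A `mock_study` (see [generate_study]) or a list with the
#'   same `abundance`, `chemicals`, `metadata` elements.
#' @param threshold Binarization threshold (default 0.001).
#' @param min_exclusive,max_exclusive Prevalence bounds (defaults 2, 35).
#' @return A list with `components` ([component_matrix]), `env`
#'   ([environment_matrix]), `binary` (full binary matrix) and
#'   `retained` (taxa kept by the prevalence filter).
#' @export
preprocess_study <- function(study, threshold = 0.001,
                             min_exclusive = 2, max_exclusive = 35) {
  ab <- study$abundance
  has_tax <- grepl("g__", colnames(ab))
  genus <- ifelse(has_tax, genus_from_taxonomy(colnames(ab)), colnames(ab))
  keep_named <- !is.na(genus)
  ab <- ab[, keep_named, drop = FALSE]
  colnames(ab) <- genus[keep_named]
  binary <- binarize_abundance(ab, threshold)
  retained <- filter_prevalence(binary, min_exclusive, max_exclusive)
  chems <- scale_chemicals(study$chemicals)
  components <- assemble_components(binary[, retained, drop = FALSE], chems)
  env <- encode_environment(study$metadata)
  list(components = components, env = env,
       binary = binary, retained = retained)
}
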