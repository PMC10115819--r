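#' Write a mock study to plain-text tables
#'
#' Emits `abundance.tsv` (samples x taxa, taxonomy strings in the header),
#' `chemicals.tsv`, `physiology.tsv` and `metadata.tsv` into `dir`.  Output
#' is deterministic: the same study object always produces byte-identical
#' files.
#'
#' @param study A [generate_study] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, f, label = "sample_id") {
    df <- data.frame(rownames(x), as.data.frame(x), check.names = FALSE)
    names(df)[1] <- label
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(study$abundance, "abundance.tsv")
  wt(study$chemicals, "chemicals.tsv")
  wt(study$physiology, "physiology.tsv")
  utils::write.table(study$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a study back from a directory of tables
#'
#' Counterpart of [write_study]; returns a list usable by
#' [preprocess_study].
#'
#' @param dir Directory holding `abundance.tsv`, `chemicals.tsv`,
#'   `physiology.tsv` (optional) and `metadata.tsv`.
#' @return A list with `abundance`, `chemicals`, `physiology`, `metadata`.
#' @export
read_study <- function(dir) {
  rd <- function(f) {
    df <- utils::read.delim(file.path(dir, f), check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"),
                            stringsAsFactors = FALSE)
  rownames(meta) <- meta$sample_id
  out <- list(abundance = rd("abundance.tsv"),
              chemicals = rd("chemicals.tsv"),
              metadata = meta)
  if (file.exists(file.path(dir, "physiology.tsv"))) {
    out$physiology <- rd("physiology.tsv")
  }
  out
}

#' Serialize fitted model parameters
#'
#' Writes `h.tsv` (h, g_a, g_s per component), `J.tsv` (full symmetric
#' coupling matrix) and `meta.json` (pair-sum convention, settings, seed)
#' into `dir`.
#'
#' @param fit A `maxent_fit` (or bare [maxent_params]).
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_maxent_params <- function(fit, dir) {
  params <- if (inherits(fit, "maxent_fit")) fit$params else fit
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdf <- data.frame(component = names(params$h), h = unname(params$h),
                    g_a = unname(params$g_a), g_s = unname(params$g_s))
  utils::write.table(hdf, file.path(dir, "h.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jdf <- data.frame(component = rownames(params$J),
                    as.data.frame(params$J), check.names = FALSE)
  utils::write.table(jdf, file.path(dir, "J.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(pair_sum_convention = "i<j (each unordered pair counted once)",
               n_components = length(params$h))
  if (inherits(fit, "maxent_fit")) {
    meta$settings <- unclass(fit$control)
    meta$seed <- fit$seed
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read serialized model parameters
#'
#' @param dir Directory written by [write_maxent_params].
#' @return A [maxent_params] object.
#' @export
read_maxent_params <- function(dir) {
  hdf <- utils::read.delim(file.path(dir, "h.tsv"), stringsAsFactors = FALSE)
  jdf <- utils::read.delim(file.path(dir, "J.tsv"), check.names = FALSE,
                           stringsAsFactors = FALSE)
  J <- as.matrix(jdf[, -1, drop = FALSE])
  rownames(J) <- jdf[[1]]
  maxent_params(hdf$h, J, hdf$g_a, hdf$g_s, names = hdf$component)
}

#' Export a signed interaction network
#'
#' Writes the significant-coupling network as an edge-list TSV
#' (`source`, `target`, `J`, `sign`, `p`) or as GraphML with the same edge
#' attributes.
#'
#' @param network A [build_network] result.
#' @param file Output path.
#' @param format `"tsv"` or `"graphml"`.
#' @return The file path, invisibly.
#' @export
export_network <- function(network, file, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  edges <- network$edges
  if (format == "tsv") {
    names(edges)[1:2] <- c("source", "target")
    utils::write.table(edges, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = network$nodes))
    igraph::write_graph(g, file, format = "graphml")
  }
  invisible(file)
}
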