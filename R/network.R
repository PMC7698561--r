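#' Correlation network of selected features
#'
#' Pearson correlations between features over the study samples (QCs
#' excluded), on the post-glog scale; edges connect pairs with
#' `|r| >= cutoff`. Constant features have undefined correlation and are
#' excluded with a warning.
#'
#' @param x numeric matrix, features x samples (post-glog study
#'   samples), rownames = feature ids.
#' @param nodes feature ids to include (typically the significant
#'   features annotated with at least one primary ion).
#' @param cutoff absolute-correlation threshold (the study uses 0.8).
#' @return an object of class `correlation_network`: `nodes`, `edges`
#'   (data.frame `from`, `to`, `r`) and `cutoff`.
#' @export
correlation_network <- function(x, nodes = rownames(x), cutoff = 0.8) {
  if (length(nodes) < 2) stop("need at least 2 nodes", call. = FALSE)
  miss <- setdiff(nodes, rownames(x))
  if (length(miss)) stop("feature not in matrix: ", miss[1L], call. = FALSE)
  sub <- x[nodes, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant feature(s): ",
            paste(nodes[sds == 0], collapse = ", "))
    sub <- sub[sds > 0, , drop = FALSE]
    nodes <- rownames(sub)
  }
  r <- stats::cor(t(sub))
  idx <- which(upper.tri(r) & abs(r) >= cutoff, arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1L]], to = nodes[idx[, 2L]],
                      r = r[idx], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff),
            class = "correlation_network")
}

#' Connected components of a correlation network
#'
#' Standard graph components over the network's nodes, ordered by size
#' (largest first), ties broken lexicographically by their first member.
#' In the study, one highly connected component collected the treatment-
#' responsive metabolites together with their correlated partners.
#'
#' @param network a [correlation_network()].
#' @return list of character vectors of feature ids (each sorted).
#' @export
connected_components <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = network$nodes))
  comp <- igraph::components(g)
  out <- lapply(split(names(comp$membership), comp$membership), sort)
  names(out) <- NULL
  first <- vapply(out, `[`, character(1), 1L)
  out[order(-lengths(out), first)]
}

#' Per-feature significance comparison table
#'
#' The data behind a multivariate-vs-univariate significance plot:
#' -log10 of the univariate p-value against the sMC F-value, with flags
#' marking which method selected each feature. No graphics are produced
#' here; the table is plot-ready.
#'
#' @param wilcoxon_p per-feature univariate p-values.
#' @param smc_f per-feature sMC F-values (same order).
#' @param selections named list of character vectors of selected feature
#'   ids (one entry per method); may be empty.
#' @param feature_ids feature ids aligning the two vectors.
#' @return a data.frame with `feature_id`, `neg_log10_p`, `smc_f` and
#'   one logical `selected_<method>` column per selection.
#' @export
significance_scatter <- function(wilcoxon_p, smc_f, selections = list(),
                                 feature_ids = names(wilcoxon_p)) {
  if (length(wilcoxon_p) != length(smc_f)) {
    stop("p-value and F-value vectors differ in length", call. = FALSE)
  }
  if (is.null(feature_ids)) feature_ids <- as.character(seq_along(wilcoxon_p))
  out <- data.frame(feature_id = feature_ids,
                    neg_log10_p = -log10(wilcoxon_p),
                    smc_f = smc_f, stringsAsFactors = FALSE)
  for (m in names(selections)) {
    out[[paste0("selected_", m)]] <- feature_ids %in% selections[[m]]
  }
  out
}
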