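#' Pathway enrichment by Fisher's exact and EASE tests
#'
#' For each pathway, a 2x2 table over the annotated metabolite background
#' (inside/outside the pathway x significant/not) is scored with the
#' right-tail Fisher exact test. The EASE variant (Expression Analysis
#' Systematic Explorer) is the conservative version with the overlap count
#' reduced by one (floored at zero), so EASE p >= Fisher p always.
#'
#' @param significant character vector of significant metabolite ids
#'   (must be a subset of `background`).
#' @param background character vector of all annotated metabolite ids.
#' @param pathways named list mapping pathway id to metabolite ids, e.g.
#'   from [reference_pathways()].
#' @param use_ease if `TRUE` (default) the significance call at `alpha`
#'   uses the EASE p-value, otherwise the Fisher p-value.
#' @param alpha significance level for the `significant` flag.
#' @return a data.frame with one row per pathway that has at least one
#'   annotated member: `pathway_id`, `n_members`, `n_significant`,
#'   `background_size`, `background_significant`, `fisher_p`, `ease_p`,
#'   `significant`. Pathways with no annotated member are skipped with a
#'   message.
#' @export
pathway_enrichment <- function(significant, background, pathways,
                               use_ease = TRUE, alpha = 0.05) {
  background <- unique(background)
  significant <- unique(significant)
  extra <- setdiff(significant, background)
  if (length(extra)) {
    stop("significant metabolites not in background: ", extra[1L], call. = FALSE)
  }
  N <- length(background)
  S <- length(significant)
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(pathways[[pw]], background)
    K <- length(members)
    if (K == 0L) {
      message("pathway '", pw, "' has no annotated member; skipped")
      return(NULL)
    }
    a <- length(intersect(members, significant))
    # right tail of the hypergeometric: P(overlap >= a)
    fisher_p <- stats::phyper(a - 1L, K, N - K, S, lower.tail = FALSE)
    a_ease <- max(a - 1L, 0L)
    ease_p <- stats::phyper(a_ease - 1L, K, N - K, S, lower.tail = FALSE)
    data.frame(pathway_id = pw, n_members = K, n_significant = a,
               background_size = N, background_significant = S,
               fisher_p = fisher_p, ease_p = ease_p,
               significant = (if (use_ease) ease_p else fisher_p) < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no pathway has any annotated member", call. = FALSE)
  rownames(out) <- NULL
  out[order(out$fisher_p, out$pathway_id), , drop = FALSE]
}

# Shared machinery: map features to valid metabolites once, then compute
# per-pathway enrichment for a given per-feature p-value vector.
annotation_map <- function(input, reference, tolerance_ppm,
                           adducts = adduct_rules()) {
  hits <- annotate_features(input, reference, tolerance_ppm, adducts)
  enforced <- enforce_primary_ions(hits)
  fid <- if ("feature_id" %in% names(input)) input$feature_id else rownames(input)
  if (is.null(fid)) fid <- as.character(seq_len(nrow(input)))
  list(hits = enforced$hits,
       metabolites = enforced$metabolites,
       feature_ids = fid,
       # feature -> metabolite links of retained metabolites
       links = unique(enforced$hits[, c("feature_id", "metabolite_id")]))
}

enrich_from_map <- function(map, pvalues, p_cutoff, pathways,
                            use_ease = TRUE, alpha = 0.05) {
  sig_features <- map$feature_ids[pvalues <= p_cutoff]
  sig_metabolites <- unique(map$links$metabolite_id[
    map$links$feature_id %in% sig_features])
  pathway_enrichment(sig_metabolites, map$metabolites, pathways,
                     use_ease = use_ease, alpha = alpha)
}

#' Permutation validation of pathway significance
#'
#' Guards against false-positive pathways: the per-feature p-value vector
#' is permuted across features `n_perm` times (the m/z structure, and
#' hence the annotation, stays fixed), the pathway significance level is
#' recomputed each time, and the permutation value is the fraction of
#' permutations in which the pathway reaches a lower (more significant)
#' level than the actual data. A truly enriched pathway yields 0; a
#' spurious one drifts toward large values.
#'
#' @param input 4-column annotation input (`mz`, `rt`, `p_value`, `mode`).
#' @param reference metabolite reference from
#'   [load_metabolite_reference()].
#' @param pathways named list of pathway memberships.
#' @param tolerance_ppm annotation tolerance in ppm.
#' @param p_cutoff feature significance cutoff applied to `p_value` (e.g.
#'   0.01, 3e-7, or a realized BH cutoff).
#' @param n_perm number of permutations (the study uses 100).
#' @param seed integer seed for the permutations.
#' @param use_ease use the EASE p-value as the significance level
#'   (default), else Fisher.
#' @return a data.frame: `pathway_id`, `observed_p`, `n_perm`,
#'   `permutation_value`, plus the observed enrichment columns.
#' @export
permutation_validate <- function(input, reference, pathways, tolerance_ppm = 1,
                                 p_cutoff = 0.01, n_perm = 100, seed = 1,
                                 use_ease = TRUE) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  map <- annotation_map(input, reference, tolerance_ppm)
  observed <- enrich_from_map(map, input$p_value, p_cutoff, pathways,
                              use_ease = use_ease)
  obs_p <- if (use_ease) observed$ease_p else observed$fisher_p
  names(obs_p) <- observed$pathway_id
  beats <- stats::setNames(integer(length(obs_p)), names(obs_p))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- sample(input$p_value)
    pe <- enrich_from_map(map, perm, p_cutoff, pathways, use_ease = use_ease)
    pp <- if (use_ease) pe$ease_p else pe$fisher_p
    names(pp) <- pe$pathway_id
    common <- intersect(names(beats), names(pp))
    beats[common] <- beats[common] + (pp[common] < obs_p[common])
  }
  observed$observed_p <- obs_p
  observed$n_perm <- n_perm
  observed$permutation_value <- as.numeric(beats[observed$pathway_id]) / n_perm
  observed
}
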