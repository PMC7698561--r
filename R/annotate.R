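# Monoisotopic atomic masses (Da). Carbon-12 is exact by definition.
ELEMENT_MASSES <- c(
  C  = 12,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  P  = 30.97376151,
  Na = 22.98976928,
  K  = 38.96370649,
  Cl = 34.96885271
)

# Mass of a proton (H minus one electron), used for protonation/deprotonation.
PROTON_MASS <- 1.00727646

#' Monoisotopic mass of an elemental formula
#'
#' Parses a Hill-style elemental formula over the alphabet
#' C, H, N, O, S, P, Na, K, Cl and sums monoisotopic atomic masses.
#'
#' @param formula character vector of formulas, e.g. `"C7H8N2O2"`.
#' @return numeric vector of monoisotopic masses (Da).
#' @export
#' @examples
#' monoisotopic_mass("C6H6N2O") # nicotinamide, 122.0480
monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (!nzchar(paste(toks, collapse = "")) ||
        nchar(paste(toks, collapse = "")) != nchar(f)) {
      stop("cannot parse formula: ", f, call. = FALSE)
    }
    total <- 0
    for (tok in toks) {
      el <- sub("[0-9]*$", "", tok)
      cnt <- sub("^[A-Za-z]+", "", tok)
      cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
      if (!el %in% names(ELEMENT_MASSES)) {
        stop("unknown element '", el, "' in formula ", f, call. = FALSE)
      }
      total <- total + ELEMENT_MASSES[[el]] * cnt
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Adduct rules for m/z annotation
#'
#' The ten adduct forms used for matching features to metabolites, with the
#' group gain/loss constants of the Mummichog convention (water 18.0106,
#' ammonia 17.0265, Na-H 21.9820, K-H 37.9559, Cl 34.9689, acetate 59.0133)
#' and proton mass 1.00727646. `delta` is the total mass shift applied to
#' the neutral monoisotopic mass M; the observed m/z of an adduct is
#' `(M + delta) / charge`. The six primary ions are M+H, M+Na, M-H2O+H
#' (positive mode) and M-H, M-2H, M-H2O-H (negative mode).
#'
#' @return a data.frame with columns `name`, `delta`, `charge`, `polarity`,
#'   `is_primary`.
#' @export
adduct_rules <- function() {
  data.frame(
    name = c("M+H[1+]", "M+Na[1+]", "M-H2O+H[1+]", "M-NH3+H[1+]", "M+K[1+]",
             "M-H[1-]", "M-2H[2-]", "M-H2O-H[1-]", "M+Cl[-]", "M+CH3COO[-]"),
    delta = c(PROTON_MASS,
              21.9820 + PROTON_MASS,
              -18.0106 + PROTON_MASS,
              -17.0265 + PROTON_MASS,
              37.9559 + PROTON_MASS,
              -PROTON_MASS,
              -2 * PROTON_MASS,
              -18.0106 - PROTON_MASS,
              34.9689,
              59.0133),
    charge = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L),
    polarity = c(rep("positive", 5L), rep("negative", 5L)),
    is_primary = c(TRUE, TRUE, TRUE, FALSE, FALSE,
                   TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Theoretical m/z of a metabolite under an adduct rule
#'
#' @param mass neutral monoisotopic mass (Da), or an elemental formula
#'   (character), in which case the mass is derived via
#'   [monoisotopic_mass()].
#' @param adduct an adduct name from [adduct_rules()], or a single-row
#'   subset of that data.frame.
#' @return theoretical m/z (Thomson).
#' @export
#' @examples
#' theoretical_mz("C7H8N2O2", "M+H[1+]")      # 153.0659
#' theoretical_mz("C7H8N2O2", "M-NH3+H[1+]")  # 136.0394
theoretical_mz <- function(mass, adduct) {
  if (is.character(mass)) mass <- monoisotopic_mass(mass)
  if (is.character(adduct)) {
    rules <- adduct_rules()
    i <- match(adduct, rules$name)
    if (anyNA(i)) stop("unknown adduct rule: ", adduct[which(is.na(i))[1L]],
                       call. = FALSE)
    adduct <- rules[i, , drop = FALSE]
  }
  if (any(mass <= 0)) stop("neutral mass must be positive", call. = FALSE)
  (mass + adduct$delta) / adduct$charge
}

#' Load a metabolite pathway reference from TSV
#'
#' The reference schema is `metabolite_id, name, formula,
#' monoisotopic_mass, pathway_ids` (pathway ids separated by `;`). Either
#' the formula or the mass may be omitted; when both are present they must
#' agree within 1e-4 Da. The package ships a miniature curated reference of
#' ~50 human metabolites over four pathways (vitamin B3, arachidonic acid,
#' methionine-cysteine, purine) under
#' `system.file("extdata", "mini_metabolite_reference.tsv", package = "metaboselect")`.
#'
#' @param path path to the reference TSV; defaults to the packaged
#'   miniature reference.
#' @return a data.frame with a numeric `monoisotopic_mass` column and a
#'   list-column `pathways`.
#' @export
load_metabolite_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mini_metabolite_reference.tsv",
                        package = "metaboselect")
  }
  ref <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  need <- c("metabolite_id", "name", "formula", "monoisotopic_mass", "pathway_ids")
  miss <- setdiff(need, names(ref))
  if (length(miss)) stop("reference missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  dup <- ref$metabolite_id[duplicated(ref$metabolite_id)]
  if (length(dup)) stop("duplicated metabolite_id: ", dup[1L], call. = FALSE)
  stored <- suppressWarnings(as.numeric(ref$monoisotopic_mass))
  has_formula <- !is.na(ref$formula) & nzchar(ref$formula)
  derived <- rep(NA_real_, nrow(ref))
  derived[has_formula] <- monoisotopic_mass(ref$formula[has_formula])
  both <- has_formula & !is.na(stored)
  off <- both & abs(stored - derived) > 1e-4
  if (any(off)) {
    stop(sprintf("stored mass of '%s' (%.4f) disagrees with formula-derived %.4f",
                 ref$metabolite_id[which(off)[1L]], stored[which(off)[1L]],
                 derived[which(off)[1L]]), call. = FALSE)
  }
  mass <- ifelse(is.na(stored), derived, stored)
  if (anyNA(mass)) {
    stop("metabolite '", ref$metabolite_id[which(is.na(mass))[1L]],
         "' has neither formula nor mass", call. = FALSE)
  }
  if (any(mass <= 0)) stop("monoisotopic mass must be positive", call. = FALSE)
  ref$monoisotopic_mass <- mass
  ref$pathways <- strsplit(ref$pathway_ids, ";", fixed = TRUE)
  ref
}

#' Pathway membership map of a reference
#'
#' @param reference a reference data.frame from
#'   [load_metabolite_reference()].
#' @return named list: pathway id to character vector of metabolite ids.
#' @export
reference_pathways <- function(reference) {
  pw <- unique(unlist(reference$pathways))
  stats::setNames(lapply(pw, function(p) {
    reference$metabolite_id[vapply(reference$pathways,
                                   function(x) p %in% x, logical(1))]
  }), pw)
}

#' Annotate features to metabolites by adduct m/z matching
#'
#' Mummichog-style matching: every (metabolite, adduct) pair whose
#' theoretical m/z lies within the ppm tolerance of an observed feature m/z
#' of the same ionization mode yields a hit. One feature may hit several
#' metabolites (isomers/isobars) and one metabolite several features.
#'
#' @param input a data.frame with columns `mz`, `rt`, `p_value`, `mode`
#'   (rownames taken as feature ids, or a `feature_id` column).
#' @param reference a reference data.frame from
#'   [load_metabolite_reference()].
#' @param tolerance_ppm mass tolerance in ppm (the study uses 1, 3 and 5).
#' @param adducts adduct rule set, by default [adduct_rules()].
#' @return a data.frame of hits: `feature_id`, `metabolite_id`, `adduct`,
#'   `theoretical_mz`, `observed_mz`, `ppm_error`, `is_primary`, `p_value`.
#' @export
annotate_features <- function(input, reference, tolerance_ppm = 1,
                              adducts = adduct_rules()) {
  if (!nrow(reference)) stop("empty metabolite reference", call. = FALSE)
  fid <- if ("feature_id" %in% names(input)) input$feature_id else rownames(input)
  if (is.null(fid)) fid <- as.character(seq_len(nrow(input)))
  hits <- vector("list", nrow(adducts))
  for (a in seq_len(nrow(adducts))) {
    rule <- adducts[a, ]
    in_mode <- which(input$mode == rule$polarity)
    if (!length(in_mode)) next
    theo <- (reference$monoisotopic_mass + rule$delta) / rule$charge
    # |obs - theo| / theo * 1e6 <= tol, via interval lookup on sorted theo
    obs <- input$mz[in_mode]
    dm <- abs(outer(obs, theo, "-")) / rep(theo, each = length(obs)) * 1e6
    idx <- which(dm <= tolerance_ppm, arr.ind = TRUE)
    if (!nrow(idx)) next
    hits[[a]] <- data.frame(
      feature_id = fid[in_mode[idx[, 1L]]],
      metabolite_id = reference$metabolite_id[idx[, 2L]],
      adduct = rule$name,
      theoretical_mz = theo[idx[, 2L]],
      observed_mz = obs[idx[, 1L]],
      ppm_error = (obs[idx[, 1L]] - theo[idx[, 2L]]) / theo[idx[, 2L]] * 1e6,
      is_primary = rule$is_primary,
      p_value = input$p_value[in_mode[idx[, 1L]]],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(feature_id = character(), metabolite_id = character(),
                      adduct = character(), theoretical_mz = numeric(),
                      observed_mz = numeric(), ppm_error = numeric(),
                      is_primary = logical(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$feature_id, out$metabolite_id, out$adduct), , drop = FALSE]
}

#' Enforce primary ions on an annotation hit list
#'
#' A metabolite assignment is valid only if at least one of its hits is a
#' primary ion (M+H, M+Na, M-H2O+H, M-H, M-2H, M-H2O-H). Non-primary hits
#' of retained metabolites are kept as corroboration; metabolites matched
#' only through non-primary adducts (e.g. M+K alone) are dropped.
#'
#' @param hits a hit data.frame from [annotate_features()].
#' @return a list with `metabolites` (retained metabolite ids) and `hits`
#'   (hits of retained metabolites).
#' @export
enforce_primary_ions <- function(hits) {
  if (!nrow(hits)) return(list(metabolites = character(), hits = hits))
  valid <- unique(hits$metabolite_id[hits$is_primary])
  list(metabolites = sort(valid),
       hits = hits[hits$metabolite_id %in% valid, , drop = FALSE])
}

#' Percentage of features annotated to at least one metabolite
#'
#' @param n_annotated number of features with at least one valid assignment.
#' @param n_total total number of features in the table.
#' @return percentage (0-100).
#' @export
annotation_coverage <- function(n_annotated, n_total) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  100 * n_annotated / n_total
}
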