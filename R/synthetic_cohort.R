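#' Configuration for the synthetic paired cohort
#'
#' Defines the study design the generator emulates: a paired cohort
#' (each patient sampled before and during treatment), duplicate
#' injections, a pooled QC sample injected after every 9th or 10th study
#' injection (alternating), a few thousand features, intra-batch intensity
#' drift, zero-inflated missingness in the low-intensity tail, a block of
#' treatment-responsive features with large fold changes and high mutual
#' correlation, and highly correlated "proxy" features outside the block
#' that carry a scaled copy of the block's treatment signal.
#'
#' @param n_patients number of patients (default 14).
#' @param n_replicates duplicate injections per (patient, condition)
#'   (default 2).
#' @param qc_interval integer vector cycled to space QC injections
#'   (default `c(9, 10)`: a QC after every 9th, then 10th, study sample).
#' @param n_features total number of features (default 2000).
#' @param block_specs list of blocks; each block is a list with `size`,
#'   `cor` (target within-block correlation), `fold_change` (per-feature
#'   fold, recycled to `size`) and `direction` (+1 increase, -1 decrease).
#'   The default is one 10-feature block with fold changes spanning
#'   roughly 2x-10x.
#' @param n_proxy_features number of proxy features baiting sparse
#'   selectors (default 15).
#' @param proxy_gain_range range of the multiplier applied to the block's
#'   treatment signal in proxy features (default `c(0.6, 2.4)`; the upper
#'   end yields proxies that out-discriminate the block itself).
#' @param drift_amplitude relative amplitude of the smooth intra-batch
#'   intensity drift over injection order (default 0.15).
#' @param missing_rate target fraction of intensities zeroed in the
#'   low-intensity tail (default 0.10).
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal measurement noise (default 0.15).
#' @param patient_sd standard deviation of the per-(feature, patient)
#'   random effect on the log scale (default 0.15).
#' @param baseline_log_mean,baseline_log_sd mean and sd of per-feature
#'   baseline log intensity.
#' @param annotation_rate fraction of null features whose m/z is placed on
#'   an adduct of a (non-spiked) reference metabolite, so that the
#'   annotation stage has a realistic background (default 0.30).
#' @param spiked_pathway pathway id of the packaged reference whose
#'   metabolites carry the causal block (default `"vitamin_b3"`).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 14L,
                          n_replicates = 2L,
                          qc_interval = c(9L, 10L),
                          n_features = 2000L,
                          block_specs = list(list(
                            size = 10L,
                            cor = 0.7,
                            fold_change = c(7.00, 2.02, 2.76, 1.94, 9.50,
                                            6.77, 7.75, 6.98, 7.20, 4.52),
                            direction = 1
                          )),
                          n_proxy_features = 15L,
                          proxy_gain_range = c(0.6, 2.4),
                          drift_amplitude = 0.15,
                          missing_rate = 0.10,
                          noise_cv = 0.15,
                          patient_sd = 0.15,
                          baseline_log_mean = log(5e4),
                          baseline_log_sd = 1.0,
                          annotation_rate = 0.30,
                          spiked_pathway = "vitamin_b3",
                          seed = 1L) {
  cfg <- structure(as.list(environment()), class = "cohort_config")
  sizes <- vapply(cfg$block_specs, function(b) as.integer(b$size), integer(1))
  if (sum(sizes) + cfg$n_proxy_features > cfg$n_features) {
    stop("block sizes plus proxies exceed n_features", call. = FALSE)
  }
  for (b in cfg$block_specs) {
    if (any(b$fold_change <= 0)) stop("fold changes must be > 0", call. = FALSE)
    if (b$cor <= 0 || b$cor >= 1) stop("block correlation must be in (0,1)", call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (cfg$noise_cv < 0 || cfg$drift_amplitude < 0) {
    stop("noise_cv and drift_amplitude must be non-negative", call. = FALSE)
  }
  cfg
}

# smooth low-order drift shape over scaled injection order, max|s| = 1
drift_shape <- function(a1, a2, tt) {
  s <- a1 * tt + a2 * (tt^2 - 1 / 3)
  m <- max(abs(s))
  if (m < 1e-12) rep(0, length(tt)) else s / m
}

#' Generate a synthetic paired cohort with known ground truth
#'
#' Generative model (log scale): per-feature baseline ~ Normal; a
#' per-(feature, patient) random effect; a condition effect equal to the
#' log fold change on responsive features; block correlation induced by a
#' shared patient-level latent factor; multiplicative log-normal
#' measurement noise; a smooth per-feature multiplicative drift over
#' injection order; zeros drawn with a logistic probability that decreases
#' with underlying intensity. QC samples are the noise-free population
#' mean profile plus technical noise and drift, mimicking a pooled QC.
#' Causal-block features are placed at adduct m/z values of the spiked
#' pathway's metabolites; proxy features are kept unannotatable.
#'
#' @param config a [cohort_config()].
#' @param reference metabolite reference (default: the packaged miniature
#'   reference).
#' @return a list with `table` (a [feature_table]), `meta` (sample
#'   metadata) and `truth` (responsive ids with fold changes, block
#'   memberships, proxy ids, drift curves, the seeded annotation map and
#'   the spiked pathway id).
#' @export
generate_cohort <- function(config = cohort_config(), reference = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(reference)) reference <- load_metabolite_reference()
  set.seed(config$seed)
  np <- config$n_patients
  nr <- config$n_replicates
  patients <- sprintf("P%02d", seq_len(np))

  study <- expand.grid(replicate_index = seq_len(nr),
                       condition = c("before", "during"),
                       patient_id = patients,
                       stringsAsFactors = FALSE)[, 3:1]
  study$sample_id <- sprintf("%s_%s_r%d", study$patient_id, study$condition,
                             study$replicate_index)
  ns <- nrow(study)

  # injection sequence: random study order, QC after every 9th/10th (alternating)
  seq_study <- sample.int(ns)
  gaps <- rep_len(config$qc_interval, ns)
  inj <- list(); qc_count <- 0L; pos <- 0L; g <- 1L
  while (pos < ns) {
    take <- min(gaps[g], ns - pos)
    inj[[length(inj) + 1L]] <- study$sample_id[seq_study[(pos + 1L):(pos + take)]]
    pos <- pos + take; g <- g + 1L
    qc_count <- qc_count + 1L
    inj[[length(inj) + 1L]] <- sprintf("QC%d", qc_count)
  }
  inj_ids <- unlist(inj)
  n_all <- length(inj_ids)
  is_qc <- grepl("^QC", inj_ids)

  meta <- data.frame(
    sample_id = inj_ids,
    patient_id = ifelse(is_qc, NA_character_,
                        study$patient_id[match(inj_ids, study$sample_id)]),
    condition = ifelse(is_qc, "QC",
                       study$condition[match(inj_ids, study$sample_id)]),
    replicate_index = ifelse(is_qc, 1L,
                             study$replicate_index[match(inj_ids, study$sample_id)]),
    injection_order = seq_len(n_all),
    is_qc = is_qc,
    stringsAsFactors = FALSE
  )

  p <- config$n_features
  feature_ids <- sprintf("F%04d", seq_len(p))
  blocks <- config$block_specs
  sizes <- vapply(blocks, function(b) as.integer(b$size), integer(1))
  block_idx <- split(seq_len(sum(sizes)), rep(seq_along(blocks), sizes))
  n_proxy <- config$n_proxy_features
  proxy_idx <- if (n_proxy > 0) sum(sizes) + seq_len(n_proxy) else integer()
  null_idx <- setdiff(seq_len(p), c(unlist(block_idx), proxy_idx))

  # baselines: block and proxy features sit in the upper intensity range so
  # they survive the missingness filters, as the study's confirmed features did
  mu <- stats::rnorm(p, config$baseline_log_mean, config$baseline_log_sd)
  hi <- c(unlist(block_idx), proxy_idx)
  mu[hi] <- config$baseline_log_mean + 1.0 + stats::rnorm(length(hi), 0, 0.3)

  sdlog <- sqrt(log(1 + config$noise_cv^2))
  s2 <- config$patient_sd^2 + sdlog^2

  # Block covariance: feature j of a block carries its treatment shift c_j
  # plus two patient-level latent factors — one aligned with the effect
  # sizes (loading kappa * c_j) and one shared equally (loading beta0).
  # beta0 is solved so the weakest pair's population correlation sits a
  # small finite-sample margin above the configured target.
  kappa <- 0.1
  cond_eff <- numeric(p)           # log fold change per feature
  beta0 <- numeric(p)              # loading on the shared latent factor
  latent_block <- integer(p)       # which block's latents a feature uses
  solve_beta0 <- function(cs, r_target, s2) {
    if (length(cs) < 2 || s2 <= 0) {
      return(if (s2 > 0) sqrt(r_target / (1 - r_target) * s2) else 0)
    }
    r_pop <- min(r_target + 0.05, 0.97)
    cs <- sort(abs(cs))[1:2]
    v <- 1 / 4 + kappa^2
    fn <- function(b2) {
      num <- cs[1] * cs[2] * v + b2
      den <- sqrt(prod(cs^2 * v + b2 + s2))
      num / den - r_pop
    }
    if (fn(0) >= 0) return(0)
    sqrt(stats::uniroot(fn, c(0, 1e3))$root)
  }
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    idx <- block_idx[[k]]
    dir <- if (is.null(b$direction)) 1 else b$direction
    cond_eff[idx] <- dir * log(rep_len(b$fold_change, length(idx)))
    beta0[idx] <- solve_beta0(cond_eff[idx], b$cor, s2)
    latent_block[idx] <- k
  }
  gain <- stats::runif(n_proxy, config$proxy_gain_range[1L],
                       config$proxy_gain_range[2L])

  pat_eff <- matrix(stats::rnorm(p * np, 0, config$patient_sd), p, np,
                    dimnames = list(NULL, patients))
  nb <- length(blocks)
  g0 <- matrix(stats::rnorm(nb * np), nb, np)  # shared latent, per block
  g1 <- matrix(stats::rnorm(nb * np), nb, np)  # effect-aligned latent

  # noise-free study log intensities (drift and noise excluded)
  logx0 <- matrix(mu, p, ns)
  pidx <- match(study$patient_id, patients)
  during <- study$condition == "during"
  logx0 <- logx0 + pat_eff[, pidx, drop = FALSE]
  logx0 <- logx0 + outer(cond_eff, as.numeric(during))
  has_lat <- latent_block > 0L
  if (any(has_lat)) {
    lb <- latent_block[has_lat]
    logx0[has_lat, ] <- logx0[has_lat, ] +
      beta0[has_lat] * g0[lb, pidx, drop = FALSE] +
      (kappa * cond_eff[has_lat]) * g1[lb, pidx, drop = FALSE]
  }
  # proxies: a scaled copy of block 1's mean structured signal + own noise
  if (n_proxy > 0) {
    b1 <- block_idx[[1L]]
    c_bar <- mean(cond_eff[b1])
    sig <- c_bar * (as.numeric(during) + kappa * g1[1L, pidx]) +
      mean(beta0[b1]) * g0[1L, pidx]
    logx0[proxy_idx, ] <- logx0[proxy_idx, ] + outer(gain, rep(1, ns)) *
      matrix(sig, n_proxy, ns, byrow = TRUE)
    cond_eff[proxy_idx] <- gain * c_bar
  }

  # pooled-QC profile: population mean of the noise-free linear intensities
  qc_base <- rowMeans(exp(logx0))

  # per-feature smooth drift over injection order
  tt <- 2 * (seq_len(n_all) - 1) / max(n_all - 1, 1L) - 1
  a1 <- stats::rnorm(p); a2 <- stats::rnorm(p)
  drift <- matrix(1, p, n_all)
  if (config$drift_amplitude > 0) {
    for (j in seq_len(p)) {
      drift[j, ] <- 1 + config$drift_amplitude * drift_shape(a1[j], a2[j], tt)
    }
  }

  intens <- matrix(0, p, n_all, dimnames = list(feature_ids, inj_ids))
  study_cols <- match(study$sample_id, inj_ids)
  noise_s <- if (sdlog > 0) matrix(stats::rnorm(p * ns, 0, sdlog), p, ns) else 0
  intens[, study_cols] <- exp(logx0 + noise_s)
  qc_cols <- which(is_qc)
  noise_q <- if (sdlog > 0) matrix(stats::rnorm(p * length(qc_cols), 0, sdlog),
                                   p, length(qc_cols)) else 0
  intens[, qc_cols] <- qc_base * exp(noise_q)
  intens <- intens * drift[, meta$injection_order[match(colnames(intens), meta$sample_id)], drop = FALSE]

  # zero-inflation: logistic probability decreasing in underlying intensity
  if (config$missing_rate > 0) {
    lx <- log(intens)
    t0 <- stats::quantile(lx, config$missing_rate, names = FALSE)
    pz <- stats::plogis((t0 - lx) / 0.3)
    intens[stats::runif(length(pz)) < pz] <- 0
  }

  # m/z placement: block features on spiked-pathway adducts, a fraction of
  # null features on other reference metabolites, the rest (and all proxies)
  # away from any reference adduct
  rules <- adduct_rules()
  spiked <- config$spiked_pathway
  ref_spiked <- reference[vapply(reference$pathways, function(x) spiked %in% x,
                                 logical(1)), , drop = FALSE]
  if (!nrow(ref_spiked)) stop("spiked pathway not in reference: ", spiked,
                              call. = FALSE)
  all_theo <- unlist(lapply(seq_len(nrow(rules)), function(a)
    (reference$monoisotopic_mass + rules$delta[a]) / rules$charge[a]))

  rand_mz <- function(n) {
    out <- numeric(n); got <- 0L
    while (got < n) {
      cand <- stats::runif(n, 70.5, 699.5)
      ok <- vapply(cand, function(m)
        all(abs(m - all_theo) / all_theo * 1e6 > 20), logical(1))
      take <- min(sum(ok), n - got)
      if (take > 0) out[(got + 1L):(got + take)] <- cand[ok][seq_len(take)]
      got <- got + take
    }
    out
  }

  mz <- rand_mz(p)
  rt <- stats::runif(p, 0.5, 15.9)
  mode <- sample(c("positive", "negative"), p, replace = TRUE)
  ann <- data.frame(feature_id = character(), metabolite_id = character(),
                    adduct = character(), stringsAsFactors = FALSE)

  place_on <- function(idx, met_rows, adduct_names) {
    combos <- expand.grid(a = adduct_names, m = seq_len(nrow(met_rows)),
                          stringsAsFactors = FALSE)[, c("m", "a")]
    combos <- combos[order(combos$m), ]
    theo <- theoretical_mz(met_rows$monoisotopic_mass[combos$m], combos$a)
    keep <- theo >= 70 & theo <= 700
    combos <- combos[keep, ]; theo <- theo[keep]
    take <- seq_len(min(length(idx), nrow(combos)))
    rule_pol <- rules$polarity[match(combos$a, rules$name)]
    mz[idx[take]] <<- theo[take] *
      (1 + stats::runif(length(take), -0.3, 0.3) * 1e-6)
    mode[idx[take]] <<- rule_pol[take]
    rt[idx[take]] <<- stats::runif(length(take), 1.0, 3.5)
    ann <<- rbind(ann, data.frame(
      feature_id = feature_ids[idx[take]],
      metabolite_id = met_rows$metabolite_id[combos$m[take]],
      adduct = combos$a[take], stringsAsFactors = FALSE))
  }

  place_on(block_idx[[1L]], ref_spiked, c("M+H[1+]", "M-H[1-]", "M+Na[1+]"))

  n_ann <- round(config$annotation_rate * length(null_idx))
  if (n_ann > 0) {
    ref_other <- reference[!reference$metabolite_id %in% ref_spiked$metabolite_id, ,
                           drop = FALSE]
    pick_m <- sample.int(nrow(ref_other), n_ann, replace = TRUE)
    pick_a <- sample(rules$name, n_ann, replace = TRUE)
    theo <- theoretical_mz(ref_other$monoisotopic_mass[pick_m], pick_a)
    ok <- which(theo >= 70 & theo <= 700)
    tgt <- sample(null_idx, length(ok))
    # wider mass errors than the spiked block, so the annotated feature
    # count grows with the ppm tolerance as in real data
    mz[tgt] <- theo[ok] * (1 + stats::runif(length(ok), -4, 4) * 1e-6)
    mode[tgt] <- rules$polarity[match(pick_a[ok], rules$name)]
    ann <- rbind(ann, data.frame(
      feature_id = feature_ids[tgt],
      metabolite_id = ref_other$metabolite_id[pick_m[ok]],
      adduct = pick_a[ok], stringsAsFactors = FALSE))
  }

  table <- feature_table(feature_ids, mz, rt, mode, intens, inj_ids)
  truth <- list(
    responsive = data.frame(
      feature_id = feature_ids[unlist(block_idx)],
      fold_change = exp(abs(cond_eff[unlist(block_idx)])),
      log_fold_change = cond_eff[unlist(block_idx)],
      block = rep(seq_along(blocks), sizes),
      stringsAsFactors = FALSE),
    blocks = lapply(block_idx, function(i) feature_ids[i]),
    proxy_ids = feature_ids[proxy_idx],
    proxy_gain = stats::setNames(gain, feature_ids[proxy_idx]),
    drift = drift,
    annotation = ann,
    spiked_pathway = spiked,
    feature_ids = feature_ids,
    config = config
  )
  list(table = table, meta = meta, truth = truth)
}

#' Recovery metrics of a selection against the cohort ground truth
#'
#' @param selected character vector of selected feature ids.
#' @param truth the `truth` element of [generate_cohort()].
#' @return a list with `sensitivity` (fraction of responsive features
#'   selected), `n_proxy` (count of proxy features selected) and `fdp`
#'   (fraction of the selection outside the responsive set).
#' @export
evaluate_recovery <- function(selected, truth) {
  unknown <- setdiff(selected, truth$feature_ids)
  if (length(unknown)) stop("unknown feature id: ", unknown[1L], call. = FALSE)
  responsive <- truth$responsive$feature_id
  sens <- if (length(responsive)) {
    length(intersect(selected, responsive)) / length(responsive)
  } else NA_real_
  fdp <- if (length(selected)) {
    length(setdiff(selected, responsive)) / length(selected)
  } else 0
  list(sensitivity = sens,
       n_proxy = length(intersect(selected, truth$proxy_ids)),
       fdp = fdp)
}
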