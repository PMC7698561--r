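#!/usr/bin/env Rscript

# Step 5 — correlation network of significant annotated features, and the
# multivariate-vs-univariate significance comparison.
#
# Nodes are the significant features annotated with at least one primary
# ion; edges require |Pearson r| >= 0.8 on the post-glog scale over the
# study samples. The largest connected component should collect the
# causal block together with its correlated proxies — the structure the
# sparse selectors exploited.

suppressPackageStartupMessages(library(metaboselect))
dir.create("results", showWarnings = FALSE)

coh <- generate_cohort(cohort_config(seed = 1))
truth <- coh$truth
pp <- preprocess_full(coh$table, coh$meta)
study <- coh$meta$sample_id[!coh$meta$is_qc]

glog_tab <- pp$table
glog_tab$intensities <- pp$glog[, glog_tab$sample_ids]
avg <- average_duplicates(glog_tab, coh$meta)
pats <- unique(avg$meta$patient_id)
pvals <- wilcoxon_paired(
  avg$table$intensities[, paste0(pats, "_before")],
  avg$table$intensities[, paste0(pats, "_during")])

# sMC significance on the full preprocessed cohort (the default node source)
X <- t(pp$x[, study])
y <- code_classes(coh$meta$condition[match(study, coh$meta$sample_id)])
ncomp <- max(1L, wrt_select_ncomp(X, y, seed = 3)$n_components)
model <- fit_pls(X, y, A = ncomp)
sm <- smc(model, X, alpha = 0.01)

input <- export_mummichog_input(pp$table, pvals)
hits <- enforce_primary_ions(annotate_features(input, load_metabolite_reference(), 1))
annotated <- unique(hits$hits$feature_id)
nodes <- intersect(pp$table$feature_ids[sm$selected], annotated)
# correlated significant features without any annotation join the picture
nodes <- union(nodes, intersect(pp$table$feature_ids[sm$selected],
                                c(truth$proxy_ids)))

net <- correlation_network(pp$glog[, study], nodes = nodes, cutoff = 0.8)
comps <- connected_components(net)
comp_tab <- data.frame(
  component = seq_along(comps),
  size = lengths(comps),
  block_members = vapply(comps, function(cc)
    length(intersect(cc, truth$blocks[[1]])), integer(1)),
  proxies = vapply(comps, function(cc)
    length(intersect(cc, truth$proxy_ids)), integer(1)),
  features = vapply(comps, paste, character(1), collapse = ",")
)
write.table(comp_tab, "results/network_components.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Network on %d nodes, %d edges (|r| >= %.1f):\n",
            length(net$nodes), nrow(net$edges), net$cutoff))
print(comp_tab[, 1:4], row.names = FALSE)

# Fig-1-style table: every selected feature plus the causal block,
# with flags for the sparse selections of step 3
sel <- jsonlite::read_json("results/selected_features.json", simplifyVector = TRUE)
scatter <- significance_scatter(
  setNames(pvals, pp$table$feature_ids), sm$F,
  selections = list(cars = sel$cars, spls = sel$spls),
  feature_ids = pp$table$feature_ids)
scatter$in_block <- scatter$feature_id %in% truth$blocks[[1]]
scatter$is_proxy <- scatter$feature_id %in% truth$proxy_ids
keep <- scatter$in_block | scatter$is_proxy | scatter$selected_cars |
  scatter$selected_spls
write.table(scatter[keep, ], "results/significance_scatter.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

blk <- scatter[scatter$in_block, ]
cat(sprintf("\nCausal block: -log10(p) in [%.1f, %.1f], sMC F in [%.0f, %.0f]\n",
            min(blk$neg_log10_p), max(blk$neg_log10_p),
            min(blk$smc_f), max(blk$smc_f)))
cat(sprintf("Sparse selections hitting the block: CARS %d/%d, sPLS %d/%d\n",
            sum(blk$selected_cars), length(sel$cars),
            sum(blk$selected_spls), length(sel$spls)))
cat("Wrote results/network_components.tsv and results/significance_scatter.tsv\n")
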