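#!/usr/bin/env Rscript
# Community structure: Jensen-Shannon beta diversity within and across
# patients, alpha diversity per site, and PERMANOVA of site on the distance
# matrix. Mirrors the across-people vs within-people contrasts of the
# aerodigestive study design on the synthetic cohort from 01_simulate.R.

library(aerodx)

tab <- read_abundance_table("results/cohort_counts.tsv")
md <- read_sample_metadata("results/cohort_metadata.tsv")
rel <- to_relative_abundance(tab)

dm <- pairwise_distances(rel, metric = "jsd")
write_distance_matrix(dm, "results/jsd_matrix.tsv")

pairs <- list(c("lung", "oropharynx"), c("lung", "gastric"),
              c("oropharynx", "gastric"))

cat("Within-patient median JSD per site pair:\n")
within_rows <- lapply(pairs, function(pr) {
  wp <- within_patient_distances(dm, md, pr)
  data.frame(site_pair = paste(pr, collapse = "-"),
             median_jsd = median(wp$distance), n_patients = nrow(wp))
})
within_tab <- do.call(rbind, within_rows)
print(within_tab)

cat("\nAcross-patient median JSD per site (same-batch pairs):\n")
across_tab <- do.call(rbind, lapply(c("lung", "oropharynx", "gastric"),
  function(s) {
    d <- across_patient_distances(dm, md, s)
    data.frame(site = s, median_jsd = median(d), n_pairs = length(d))
  }))
print(across_tab)

cat("\nWithin vs across patients (signed-rank):\n")
wa_tab <- do.call(rbind, lapply(pairs, function(pr) {
  wa <- within_vs_across(dm, md, pr)
  data.frame(site_pair = paste(pr, collapse = "-"),
             frac_within_lower = mean(wa$records$within <
                                        wa$records$across_mean_a),
             p_vs_site_a = wa$p_a, p_vs_site_b = wa$p_b)
}))
print(wa_tab)

aero <- md[md$site %in% c("lung", "oropharynx", "gastric"), ]
perm <- permanova(dm[aero$sample_id, aero$sample_id], aero$site,
                  n_permutations = 999, seed = 2)
cat(sprintf("\nPERMANOVA of site: pseudo-F = %.2f, p = %.3g\n",
            perm$pseudo_F, perm$p_value))

alpha_tab <- do.call(rbind, lapply(c("lung", "oropharynx", "gastric"),
  function(s) {
    ids <- md$sample_id[md$site == s]
    sub <- align_samples(tab, md[md$site == s, ])$table
    data.frame(site = s,
               median_shannon = median(alpha_diversity_table(sub, "shannon")),
               median_chao1 = median(alpha_diversity_table(sub, "chao1")))
  }))
cat("\nAlpha diversity by site:\n")
print(alpha_tab)

write.table(within_tab, "results/within_patient_jsd.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(across_tab, "results/across_patient_jsd.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(wa_tab, "results/within_vs_across.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(alpha_tab, "results/alpha_diversity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nWrote JSD matrix and summary tables under results/\n")
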