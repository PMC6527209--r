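#!/usr/bin/env Rscript
# Aspirator vs non-aspirator contrasts: within-patient JSD by group for each
# site pair, alpha-diversity comparisons, co-occurrence prevalence of the
# planted lung-oropharynx exchanged OTUs with the paired log10 t-test, and
# Kruskal-Wallis differential abundance with per-site BH correction.

library(aerodx)

tab <- read_abundance_table("results/cohort_counts.tsv")
md <- read_sample_metadata("results/cohort_metadata.tsv")
rel <- to_relative_abundance(tab)
truth <- read.delim("results/planted_exchanged_otus.tsv",
                    stringsAsFactors = FALSE)
dm <- read_distance_matrix("results/jsd_matrix.tsv")

pairs <- list(c("lung", "oropharynx"), c("lung", "gastric"),
              c("oropharynx", "gastric"))

cat("Within-patient JSD by aspiration status (rank-sum test):\n")
jsd_tab <- do.call(rbind, lapply(pairs, function(pr) {
  cmp <- compare_within_patient_jsd(dm, md, pr)
  meds <- setNames(cmp$group_summaries$median, cmp$group_summaries$group)
  data.frame(site_pair = paste(pr, collapse = "-"),
             median_aspirator = meds[["aspirator"]],
             median_non_aspirator = meds[["non_aspirator"]],
             p_value = cmp$p_value)
}))
print(jsd_tab)

cat("\nAlpha diversity by aspiration status (Shannon, rank-sum):\n")
alpha_tab <- do.call(rbind, lapply(c("lung", "oropharynx", "gastric"),
  function(s) {
    cmp <- compare_alpha(tab, md, s, metric = "shannon")
    data.frame(site = s, p_value = cmp$p_value)
  }))
print(alpha_tab)

planted <- truth$otu_id[truth$site_pair == "lung-oropharynx"]
pa <- cooccurrence_prevalence(rel, md, planted, c("lung", "oropharynx"),
                              "aspirator")
pn <- cooccurrence_prevalence(rel, md, planted, c("lung", "oropharynx"),
                              "non_aspirator")
dp <- differential_prevalence(pn, pa)
cat(sprintf("\nCo-occurrence of planted lung-oropharynx OTUs: aspirator median %.1f%%, non-aspirator median %.1f%%, paired-t p = %.2g\n",
            median(pa), median(pn), dp$p_value))
prev_tab <- data.frame(otu_id = planted, non_aspirator = unname(pn),
                       aspirator = unname(pa),
                       difference = unname(dp$difference))
prev_tab <- prev_tab[order(-prev_tab$difference), ]
write.table(prev_tab, "results/cooccurrence_prevalence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\nDifferential abundance (Kruskal-Wallis, BH per site):\n")
for (s in c("lung", "oropharynx", "gastric")) {
  res <- differential_abundance(rel, md, s)
  cat(sprintf("  %-11s %3d taxa tested, %d with q < 0.1\n", s, nrow(res),
              sum(res$q_value < 0.1)))
  write.table(res, sprintf("results/diff_abundance_%s.tsv", s), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

write.table(jsd_tab, "results/aspiration_jsd.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nWrote aspiration contrast tables under results/\n")
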