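#!/usr/bin/env Rscript
# Random-forest classification surfaces: site discrimination with
# patient-grouped 5-fold cross-validation, and leave-one-out aspiration
# classifiers on exchanged-OTU presence, concordance coding, and whole
# communities — the layout of the study's classifier tables.

library(aerodx)

tab <- read_abundance_table("results/cohort_counts.tsv")
md <- read_sample_metadata("results/cohort_metadata.tsv")
rel <- to_relative_abundance(tab)
truth <- read.delim("results/planted_exchanged_otus.tsv",
                    stringsAsFactors = FALSE)

cat("Site classifiers (patient-grouped 5-fold CV, 1000 trees):\n")
site_tab <- do.call(rbind, lapply(
  list(c("lung", "oropharynx"), c("lung", "gastric"),
       c("oropharynx", "gastric")),
  function(pr) {
    rep <- site_classifier_cv(rel, md, pr, n_trees = 1000, seed = 21)
    data.frame(sites = paste(pr, collapse = " vs "), auc = round(rep$auc, 3))
  }))
print(site_tab)

loo_row <- function(label, feats, seed) {
  rep <- aspiration_classifier_loo(feats, n_trees = 1000, seed = seed)
  data.frame(classifier = label, auc = round(rep$auc, 2),
             fisher_p = signif(rep$fisher_p, 2),
             n_non_asp = rep$n_negative, n_asp = rep$n_positive)
}

planted <- truth$otu_id[truth$site_pair == "lung-oropharynx"]
cat("\nAspiration classifiers from lung-oropharynx exchanged OTUs (LOO):\n")
exch_tab <- rbind(
  loo_row("presence in lung",
          build_features(rel, md, "exchanged_presence", "lung",
                         exchanged_otus = planted), 31),
  loo_row("presence in oropharynx",
          build_features(rel, md, "exchanged_presence", "oropharynx",
                         exchanged_otus = planted), 32),
  loo_row("concordance",
          build_features(rel, md, "exchanged_concordance",
                         c("lung", "oropharynx"),
                         exchanged_otus = planted), 33))
print(exch_tab)

cat("\nAspiration classifiers from whole communities (LOO):\n")
comm_tab <- rbind(
  loo_row("lung", build_features(rel, md, "community", "lung"), 41),
  loo_row("oropharynx", build_features(rel, md, "community", "oropharynx"),
          42),
  loo_row("lung + oropharynx",
          build_features(rel, md, "community", c("lung", "oropharynx")), 43),
  loo_row("all three sites",
          build_features(rel, md, "community",
                         c("lung", "oropharynx", "gastric")), 44))
print(comm_tab)

write.table(site_tab, "results/site_classifiers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rbind(exch_tab, comm_tab), "results/aspiration_classifiers.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nWrote classifier tables under results/\n")
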