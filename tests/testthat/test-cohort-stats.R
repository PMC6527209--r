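test_that("aspirators show more similar lung-oropharynx communities", {
  coh <- cached_cohort(1)
  rel <- to_relative_abundance(coh$table)
  dm <- pairwise_distances(rel, "jsd")
  res <- compare_within_patient_jsd(dm, coh$metadata, c("lung", "oropharynx"))
  meds <- stats::setNames(res$group_summaries$median,
                          res$group_summaries$group)
  expect_lt(meds[["aspirator"]], meds[["non_aspirator"]])
  expect_lt(res$p_value, 0.05)
  expect_equal(sort(res$group_summaries$n), c(23L, 25L))

  only_unt <- coh$metadata[coh$metadata$aspiration_status == "untested", ]
  expect_error(compare_within_patient_jsd(dm, only_unt,
                                          c("lung", "oropharynx")),
               "at least 2")
})

test_that("alpha-diversity contrasts detect a planted richness deficit", {
  withr::with_seed(41, {
    rich <- matrix(rpois(120 * 12, 8), nrow = 120)
    poor <- matrix(0, nrow = 120, ncol = 12)
    poor[1:12, ] <- matrix(rpois(12 * 12, 80), nrow = 12)  # 10% of the taxa
    tab <- abundance_table(cbind(rich, poor))
  })
  md <- data.frame(sample_id = colnames(tab),
                   patient_id = paste0("p", 1:24),
                   site = "lung", batch = "B1",
                   aspiration_status = rep(c("non_aspirator", "aspirator"),
                                           each = 12),
                   stringsAsFactors = FALSE)
  res <- compare_alpha(tab, md, "lung", metric = "chao1")
  expect_lt(res$p_value, 0.05)
  meds <- stats::setNames(res$group_summaries$median,
                          res$group_summaries$group)
  expect_lt(meds[["aspirator"]], meds[["non_aspirator"]])
  expect_error(compare_alpha(tab, md, "stool"), "no labeled samples")
})

test_that("alpha contrasts do not reject when groups share a composition", {
  withr::with_seed(43, {
    tab <- abundance_table(matrix(rpois(80 * 30, 10), nrow = 80))
    pv <- replicate(40, {
      md <- data.frame(sample_id = colnames(tab),
                       patient_id = paste0("p", 1:30), site = "lung",
                       batch = "B1",
                       aspiration_status = sample(rep(c("aspirator",
                                                        "non_aspirator"), 15)),
                       stringsAsFactors = FALSE)
      compare_alpha(tab, md, "lung", metric = "shannon")$p_value
    })
  })
  expect_lt(mean(pv < 0.05), 0.2)
})

test_that("differential abundance flags a planted shift with the smallest q", {
  withr::with_seed(47, {
    counts <- matrix(rpois(60 * 30, 20), nrow = 60)
    counts[7, 16:30] <- rpois(15, 200)  # 10-fold group shift in taxon 7
    tab <- to_relative_abundance(abundance_table(counts))
  })
  md <- data.frame(sample_id = colnames(tab), patient_id = paste0("p", 1:30),
                   site = "gastric", batch = "B1",
                   aspiration_status = rep(c("non_aspirator", "aspirator"),
                                           each = 15),
                   stringsAsFactors = FALSE)
  res <- differential_abundance(tab, md, "gastric")
  expect_identical(res$taxon[which.min(res$q_value)], "OTU_7")
  expect_lt(min(res$q_value), 0.1)
  # two-group Kruskal-Wallis is invariant to monotone transforms of each
  # taxon's abundances; cube every taxon and pad with a filler taxon so the
  # columns still close to 1
  cubed <- unclass(tab)^3
  filler <- 1 - colSums(cubed)
  res_cube <- differential_abundance(
    abundance_table(rbind(cubed, filler = filler), mode = "relative"),
    md, "gastric")
  expect_equal(res$statistic[match("OTU_7", res$taxon)],
               res_cube$statistic[match("OTU_7", res_cube$taxon)],
               tolerance = 1e-12)
})

test_that("constant taxa are excluded and reported", {
  counts <- matrix(5, nrow = 3, ncol = 8)
  counts[1, ] <- c(1, 9, 2, 8, 3, 7, 4, 6)
  counts[2, ] <- 10 - counts[1, ]  # constant column totals keep OTU_3 flat
  tab <- to_relative_abundance(abundance_table(counts))
  md <- data.frame(sample_id = colnames(tab), patient_id = paste0("p", 1:8),
                   site = "lung", batch = "B1",
                   aspiration_status = rep(c("aspirator", "non_aspirator"), 4),
                   stringsAsFactors = FALSE)
  res <- differential_abundance(tab, md, "lung")
  expect_false("OTU_3" %in% res$taxon)
  expect_true("OTU_3" %in% attr(res, "dropped"))
})

test_that("reflux correlations recover exact monotone relationships", {
  coh <- cached_cohort(1)
  rel <- to_relative_abundance(coh$table)
  dm <- pairwise_distances(rel, "jsd")
  wp <- within_patient_distances(dm, coh$metadata, c("lung", "gastric"))
  md <- coh$metadata
  md$reflux_total <- wp$distance[match(md$patient_id, wp$patient_id)]
  res <- reflux_correlation(dm, md, "reflux_total")
  expect_equal(res$statistic_value, 1)
  md$reflux_neg <- -2 * md$reflux_total + 5
  res_neg <- reflux_correlation(dm, md, "reflux_neg")
  expect_equal(res_neg$statistic_value, -1)
  md$sparse <- NA_real_
  md$sparse[1:4] <- 1:4
  expect_error(reflux_correlation(dm, md, "sparse"), "at least 5")
  expect_error(reflux_correlation(dm, md, "nope"), "no column")
})

test_that("independent covariates give near-zero correlation", {
  coh <- cached_cohort(1)
  rel <- to_relative_abundance(coh$table)
  dm <- pairwise_distances(rel, "jsd")
  md <- coh$metadata
  withr::with_seed(53, {
    pats <- unique(md$patient_id)
    cov_vals <- stats::setNames(rnorm(length(pats)), pats)
  })
  md$noise <- cov_vals[md$patient_id]
  res <- reflux_correlation(dm, md, "noise")
  expect_lt(abs(res$statistic_value), 0.35)
  expect_gt(res$p_value, 0.005)
})
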