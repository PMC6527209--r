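test_that("partial Spearman handles perfect, degenerate and tied cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_partial(x, x, c(3, 1, 4, 5, 2)), 1)
  # constant z reduces to plain Spearman
  y <- c(2, 1, 3, 5, 4)
  expect_equal(spearman_partial(x, y, rep(0, 5)),
               stats::cor(x, y, method = "spearman"))
  # constant x or y -> not computable
  expect_true(is.na(spearman_partial(rep(1, 5), y, x)))
  # |r_xz| = 1 -> undefined denominator
  expect_true(is.na(spearman_partial(x, y, x)))
  expect_error(spearman_partial(1:2, 1:2, 1:2), "at least 3")
  expect_error(spearman_partial(1:5, 1:4, 1:5), "same length")
})

test_that("partial Spearman equals the residual-correlation oracle", {
  expect_equal(spearman_partial(c(1, 2, 3, 4, 5, 6), c(2, 1, 3, 5, 4, 6),
                                c(3, 6, 1, 5, 2, 4)),
               partial_oracle(c(1, 2, 3, 4, 5, 6), c(2, 1, 3, 5, 4, 6),
                              c(3, 6, 1, 5, 2, 4)),
               tolerance = 1e-12)
  withr::with_seed(13, {
    for (i in 1:200) {
      n <- sample(5:40, 1)
      x <- sample(0:8, n, replace = TRUE)  # heavy ties, like zero-inflated
      y <- rnorm(n)                        # abundances
      z <- sample(0:3, n, replace = TRUE)
      if (sd(x) == 0 || sd(z) == 0) next
      expect_equal(spearman_partial(x, y, z), partial_oracle(x, y, z),
                   tolerance = 1e-12)
    }
  })
})

test_that("partial converges to plain Spearman when z is independent", {
  withr::with_seed(17, {
    diffs <- replicate(100, {
      x <- rnorm(200)
      y <- x + rnorm(200)
      z <- rnorm(200)
      abs(spearman_partial(x, y, z) - cor(x, y, method = "spearman"))
    })
  })
  expect_lt(mean(diffs), 0.05)
})

test_that("permutation p-values are deterministic and tail-correct", {
  x <- c(0.1, 0.4, 0.2, 0.9, 0.7, 0.3, 0.8)
  z <- c(0.2, 0.1, 0.5, 0.3, 0.9, 0.4, 0.6)
  r1 <- permutation_p(x, x, z, n_permutations = 500, seed = 99)
  r2 <- permutation_p(x, x, z, n_permutations = 500, seed = 99)
  expect_identical(r1, r2)
  expect_equal(r1$partial_rho, 1)
  # rho = 1 can only be matched, never exceeded -> p = 0 under strict >
  expect_equal(r1$perm_p, 0)
  expect_error(permutation_p(rep(1, 5), x[1:5], z[1:5]), "not computable")
})

test_that("permutation test is invariant to joint reordering of the triple", {
  withr::with_seed(23, {
    x <- rnorm(30)
    y <- x + rnorm(30)
    z <- rnorm(30)
    ord <- sample(30)
  })
  a <- permutation_p(x, y, z, n_permutations = 300, seed = 5)
  b <- permutation_p(x[ord], y[ord], z[ord], n_permutations = 300, seed = 5)
  expect_equal(a$partial_rho, b$partial_rho, tolerance = 1e-12)
  expect_lt(abs(a$perm_p - b$perm_p), 0.05)
})

test_that("exchange detection recovers planted OTUs and is reproducible", {
  coh <- cached_cohort(2, aspiration_mixing = 0)
  rel <- to_relative_abundance(coh$table)
  res <- detect_exchanged(rel, coh$metadata, c("lung", "oropharynx"),
                          n_permutations = 500, seed = 77)
  planted <- coh$truth$exchanged[["lung-oropharynx"]]
  hits <- res$otu_id[res$exchanged]
  expect_gt(mean(planted %in% hits), 0.6)
  expect_true(all(res$n_patients >= 10))
  expect_true(all(res$q_value >= res$perm_p - 1e-15))
  expect_true(all(res$exchanged == (res$q_value < 0.1)))
  res2 <- detect_exchanged(rel, coh$metadata, c("lung", "oropharynx"),
                           n_permutations = 500, seed = 77)
  expect_identical(res, res2)
})

test_that("detection degenerates gracefully when nothing passes the filter", {
  # 12 triple-site patients, but each OTU co-occurs in at most 5 of them
  withr::with_seed(67, {
    counts <- matrix(rpois(4 * 36, 30) + 1, nrow = 4)
  })
  md <- expand.grid(site = c("lung", "oropharynx", "gastric"),
                    patient_id = sprintf("q%02d", 1:12),
                    stringsAsFactors = FALSE)
  md$sample_id <- paste(md$patient_id, md$site, sep = "_")
  md$batch <- "B1"
  md$aspiration_status <- "untested"
  colnames(counts) <- md$sample_id
  lung_cols <- md$sample_id[md$site == "lung"]
  counts[, lung_cols[6:12]] <- 0          # OTUs absent from most lungs
  for (j in 6:12) {                       # keep columns non-zero, rotating
    counts[(j %% 4) + 1, lung_cols[j]] <- 5   # so no OTU reaches 10 lungs
  }
  rel <- to_relative_abundance(abundance_table(counts))
  res <- detect_exchanged(rel, md, c("lung", "oropharynx"),
                          n_permutations = 100, seed = 1)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "n_candidates"), 4L)

  coh <- cached_cohort(2, aspiration_mixing = 0)
  big_rel <- to_relative_abundance(coh$table)
  small <- align_samples(big_rel,
                         coh$metadata[coh$metadata$patient_id %in%
                                        sprintf("P%03d", 1:5), ])
  expect_error(detect_exchanged(small$table, small$metadata,
                                c("lung", "oropharynx")),
               "all three aerodigestive sites")
})

test_that("shuffling patient IDs destroys the planted exchange signal", {
  coh <- cached_cohort(2, aspiration_mixing = 0)
  rel <- to_relative_abundance(coh$table)
  cal <- null_calibration(rel, coh$metadata, c("lung", "oropharynx"),
                          n_rounds = 3, n_permutations = 500, seed = 19)
  expect_length(cal$counts, 3L)
  expect_lte(stats::median(cal$counts), 2)
  expect_equal(cal$max_count, max(cal$counts))
  cal2 <- null_calibration(rel, coh$metadata, c("lung", "oropharynx"),
                           n_rounds = 3, n_permutations = 500, seed = 19)
  expect_identical(cal, cal2)
  expect_error(null_calibration(rel, coh$metadata, c("lung", "oropharynx"),
                                n_rounds = 0), "at least 1")
})

test_that("co-occurrence prevalence counts dual-site carriage per group", {
  coh <- cached_cohort(1)
  rel <- to_relative_abundance(coh$table)
  ids <- rownames(rel)[1:5]
  prev <- cooccurrence_prevalence(rel, coh$metadata, ids,
                                  c("lung", "oropharynx"), "aspirator")
  expect_length(prev, 5L)
  expect_true(all(prev >= 0 & prev <= 100))
  expect_equal(attr(prev, "n_patients"), 25L)
  # direct recount for one OTU
  md <- coh$metadata
  asp <- unique(md$patient_id[md$aspiration_status == "aspirator"])
  lungs <- md$sample_id[md$site == "lung" & md$patient_id %in% asp]
  oros <- md$sample_id[md$site == "oropharynx" & md$patient_id %in% asp]
  manual <- 100 * mean(rel[ids[1], lungs] > 0 & rel[ids[1], oros] > 0)
  expect_equal(unname(prev[1]), manual)
  expect_error(cooccurrence_prevalence(rel, coh$metadata, "no_such_otu",
                                       c("lung", "oropharynx"), "aspirator"),
               "not in table")
})

test_that("differential prevalence reports differences and a paired test", {
  p1 <- c(a = 10, b = 20, c = 0)
  p2 <- c(a = 50, b = 25, c = 40)
  res <- differential_prevalence(p1, p2, n_group1 = 23, n_group2 = 25)
  expect_equal(unname(res$difference), c(40, 5, 40))
  expect_false(res$degenerate)
  expect_lt(res$p_value, 0.2)
  same <- differential_prevalence(p1, p1, n_group1 = 23, n_group2 = 23)
  expect_true(all(same$difference == 0))
  expect_true(same$degenerate)
  expect_error(differential_prevalence(p1, p2[c(2, 1, 3)]), "same OTUs")
})
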