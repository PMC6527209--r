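test_that("reading and writing an OTU table is the identity", {
  tab <- make_tiny_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, path)
  back <- read_abundance_table(path)
  expect_equal(dim(back), c(3L, 3L))
  expect_identical(rownames(back), rownames(tab))
  expect_identical(colnames(back), colnames(tab))
  expect_identical(otu_taxonomy(back), otu_taxonomy(tab))
  expect_equal(unclass(back), unclass(tab), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(table_mode(back), "counts")
})

test_that("reader tolerates the QIIME classic dialect and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# Constructed from biom file",
               "#OTU ID\ts1\ts2\ttaxonomy",
               "OTU_1\t3\t4\tBacteria;Firmicutes",
               "OTU_2\t0\t1\t"), path)
  tab <- read_abundance_table(path)
  expect_equal(dim(tab), c(2L, 2L))
  expect_identical(otu_taxonomy(tab), c("Bacteria;Firmicutes", ""))

  writeLines(c("#OTU ID\ts1\ts1", "OTU_1\t1\t2"), path)
  expect_error(read_abundance_table(path), "duplicate sample ID.*s1")
  writeLines(c("#OTU ID\ts1\ts2", "OTU_1\t1\t-2"), path)
  expect_error(read_abundance_table(path), "negative")
  writeLines(c("#OTU ID\ts1\ts2", "OTU_1\t1\t2", "OTU_1\t3\t4"), path)
  expect_error(read_abundance_table(path), "duplicate OTU ID.*OTU_1")
})

test_that("an empty table round-trips as a header-only file", {
  tab <- abundance_table(matrix(numeric(), 0, 2,
                                dimnames = list(NULL, c("s1", "s2"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, path)
  back <- read_abundance_table(path)
  expect_equal(nrow(back), 0L)
  expect_identical(colnames(back), c("s1", "s2"))
})

test_that("relative normalization divides by column totals and is idempotent", {
  tab <- make_tiny_table()
  rel <- to_relative_abundance(tab)
  expect_identical(table_mode(rel), "relative")
  expect_equal(unname(rel[, "s1"]), c(0.2, 0.5, 0.3))
  expect_equal(unname(rel[, "s2"]), c(0.2, 0.0, 0.8))
  expect_identical(to_relative_abundance(rel), rel)
  withr::with_seed(1, {
    big <- abundance_table(matrix(rpois(600, 20), nrow = 30))
  })
  sums <- colSums(to_relative_abundance(big))
  expect_true(all(abs(sums - 1) <= 1e-9))

  zero <- abundance_table(matrix(c(1, 2, 0, 0), 2,
                                 dimnames = list(NULL, c("ok", "empty"))))
  expect_error(to_relative_abundance(zero), "empty")
})

test_that("relative tables still sum to 1 after a file round trip", {
  rel <- to_relative_abundance(make_tiny_table())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(rel, path)
  back <- read_abundance_table(path)
  expect_true(all(abs(colSums(back) - 1) <= 1e-9))
})

test_that("taxonomic collapsing pools lineages and conserves totals", {
  tab <- to_relative_abundance(make_tiny_table())
  gen <- collapse_to_rank(tab, "genus")
  # the two Streptococcus OTUs merge; the unannotated one gets a sentinel
  expect_equal(nrow(gen), 2L)
  strep <- grep("Streptococcus$", rownames(gen))
  expect_equal(unname(gen[strep, "s1"]), 0.2 + 0.5)
  expect_true(any(grepl("unclassified at genus", rownames(gen))))
  expect_equal(colSums(gen), colSums(tab))

  fam <- collapse_to_rank(tab, "family")
  expect_equal(sort(unname(colSums(fam))), sort(unname(colSums(tab))))
  expect_error(collapse_to_rank(tab, "species"), "unknown rank")

  # conservation on a larger random table with synthetic lineages
  coh <- cached_cohort(1)
  rel <- to_relative_abundance(coh$table)
  collapsed <- collapse_to_rank(rel, "genus")
  expect_equal(colSums(collapsed), colSums(rel), tolerance = 1e-12)
  expect_true(nrow(collapsed) < nrow(rel))
})

test_that("metadata parsing normalizes site aliases and validates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpatient_id\tsite\tbatch\taspiration_status\tppi",
               "s1\tp1\tBAL\tB1\taspirator\t1",
               "s2\tp1\tOropharyngeal swab\tB1\taspirator\t1",
               "s3\tp2\tGastric fluid\tB2\tuntested\t0"), path)
  md <- read_sample_metadata(path)
  expect_identical(md$site, c("lung", "oropharynx", "gastric"))
  expect_identical(md$ppi, c(1L, 1L, 0L))

  writeLines(c("sample_id\tpatient_id\tsite\tbatch\taspiration_status",
               "s1\tp1\tnares\tB1\taspirator"), path)
  expect_error(read_sample_metadata(path), "unrecognized site")
  writeLines(c("sample_id\tpatient_id\tsite\tbatch\taspiration_status",
               "s1\tp1\tBAL\tB1\taspirator",
               "s2\tp1\tlung\tB1\taspirator"), path)
  expect_error(read_sample_metadata(path), "more than one")
})

test_that("sample alignment intersects IDs and reports drops", {
  tab <- make_tiny_table()
  md <- make_tiny_metadata()
  full <- align_samples(tab, md)
  expect_identical(colnames(full$table), colnames(tab))
  expect_identical(full$dropped, character())

  md_extra <- rbind(md, data.frame(sample_id = "s9", patient_id = "p9",
                                   site = "stool", batch = "B1",
                                   aspiration_status = "untested"))
  sup <- align_samples(tab, md_extra)
  expect_identical(colnames(sup$table), colnames(tab))
  expect_identical(sup$dropped, "s9")

  part <- align_samples(tab, md[md$sample_id %in% c("s1", "s2"), ])
  expect_identical(colnames(part$table), c("s1", "s2"))
  expect_equal(nrow(part$metadata), 2L)

  md_disjoint <- md
  md_disjoint$sample_id <- c("x1", "x2", "x3")
  expect_error(align_samples(tab, md_disjoint), "no sample IDs shared")
})
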