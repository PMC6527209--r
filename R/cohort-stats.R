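# group labels per patient for aspiration contrasts; "untested" is dropped
aspiration_groups <- function(metadata) {
  md <- unique(metadata[, c("patient_id", "aspiration_status")])
  md[md$aspiration_status %in% c("aspirator", "non_aspirator"), , drop = FALSE]
}

group_comparison <- function(statistic_name, statistic_value, p_value,
                             group_summaries, q_value = NA_real_) {
  structure(list(statistic_name = statistic_name,
                 statistic_value = statistic_value,
                 p_value = p_value, q_value = q_value,
                 group_summaries = group_summaries),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s = %.4g, p = %.3g\n",
              x$statistic_name, x$statistic_value, x$p_value))
  print(x$group_summaries)
  invisible(x)
}

#' Compare within-patient beta diversity between aspirators and non-aspirators
#'
#' Within-patient distances for a site pair are split by the patients'
#' aspiration status and compared with a Wilcoxon rank-sum test. A lower
#' aspirator median for the lung-oropharynx pair is the signature of
#' oropharyngeal material reaching the airway.
#'
#' @inheritParams within_patient_distances
#' @return A `group_comparison`: rank-sum statistic, p-value, and per-group
#'   median and n.
#' @export
compare_within_patient_jsd <- function(dm, metadata, site_pair) {
  wp <- within_patient_distances(dm, metadata, site_pair)
  grp <- aspiration_groups(metadata)
  wp$group <- grp$aspiration_status[match(wp$patient_id, grp$patient_id)]
  wp <- wp[!is.na(wp$group), , drop = FALSE]
  split_d <- split(wp$distance, wp$group)
  if (length(split_d) < 2L || min(lengths(split_d)) < 2L)
    stop("need at least 2 aspirators and 2 non-aspirators with both sites")
  wt <- stats::wilcox.test(split_d$aspirator, split_d$non_aspirator,
                           exact = FALSE)
  summ <- data.frame(group = names(split_d),
                     median = vapply(split_d, stats::median, numeric(1)),
                     n = lengths(split_d), row.names = NULL)
  group_comparison("wilcoxon_ranksum", unname(wt$statistic), wt$p.value, summ)
}

#' Compare alpha diversity between patient groups at one site
#'
#' @param table counts-mode [abundance_table].
#' @param metadata metadata `data.frame`.
#' @param site site whose samples are compared.
#' @param metric alpha-diversity metric (see [alpha_diversity()]).
#' @return A `group_comparison` with per-group median and n.
#' @export
compare_alpha <- function(table, metadata, site, metric = "shannon") {
  stopifnot(is_abundance_table(table))
  md <- metadata[metadata$sample_id %in% colnames(table) &
                   metadata$site == site &
                   metadata$aspiration_status %in%
                     c("aspirator", "non_aspirator"), , drop = FALSE]
  if (!nrow(md)) stop("no labeled samples at site '", site, "'")
  sub <- unclass_matrix(table)[, md$sample_id, drop = FALSE]
  vals <- apply(sub, 2L, alpha_diversity, metric = metric)
  split_v <- split(vals, md$aspiration_status)
  if (length(split_v) < 2L || min(lengths(split_v)) < 2L)
    stop("need at least 2 samples per aspiration group at site '", site, "'")
  wt <- stats::wilcox.test(split_v$aspirator, split_v$non_aspirator,
                           exact = FALSE)
  summ <- data.frame(group = names(split_v),
                     median = vapply(split_v, stats::median, numeric(1)),
                     n = lengths(split_v), row.names = NULL)
  group_comparison("wilcoxon_ranksum", unname(wt$statistic), wt$p.value, summ)
}

#' Differential abundance between aspirators and non-aspirators
#'
#' Per-taxon Kruskal-Wallis tests (tie-corrected) on relative abundances at
#' one site, optionally after collapsing to a taxonomic rank, with
#' Benjamini-Hochberg q-values computed within this one (site, rank) family.
#' Taxa absent from every sample of the site are dropped before testing.
#'
#' @param table relative-mode [abundance_table].
#' @param metadata metadata `data.frame`.
#' @param site site whose samples are tested.
#' @param rank optional rank passed to [collapse_to_rank()]; `NULL` tests
#'   OTUs directly.
#' @return A `data.frame`: `taxon`, `statistic`, `p_value`, `q_value`,
#'   per-group medians and n; attribute `dropped` lists zero-variance taxa.
#' @export
differential_abundance <- function(table, metadata, site, rank = NULL) {
  stopifnot(is_abundance_table(table))
  if (table_mode(table) != "relative")
    stop("differential abundance is computed on relative abundances")
  if (!is.null(rank)) table <- collapse_to_rank(table, rank)
  md <- metadata[metadata$sample_id %in% colnames(table) &
                   metadata$site == site &
                   metadata$aspiration_status %in%
                     c("aspirator", "non_aspirator"), , drop = FALSE]
  groups <- factor(md$aspiration_status)
  if (nlevels(groups) < 2L)
    stop("need both aspirator groups at site '", site, "'")
  v <- unclass_matrix(table)[, md$sample_id, drop = FALSE]
  keep <- apply(v, 1L, function(r) length(unique(r)) > 1L)
  dropped <- rownames(v)[!keep]
  v <- v[keep, , drop = FALSE]
  res <- lapply(seq_len(nrow(v)), function(i) {
    kw <- stats::kruskal.test(v[i, ], groups)
    med <- tapply(v[i, ], groups, stats::median)
    data.frame(taxon = rownames(v)[i], statistic = unname(kw$statistic),
               p_value = kw$p.value,
               median_aspirator = unname(med["aspirator"]),
               median_non_aspirator = unname(med["non_aspirator"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(taxon = character(), statistic = numeric(),
                      p_value = numeric(), median_aspirator = numeric(),
                      median_non_aspirator = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE)
  } else {
    out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  }
  attr(out, "dropped") <- dropped
  attr(out, "n_per_group") <- table(groups)
  out
}

#' Correlation between a reflux covariate and within-patient distance
#'
#' Spearman correlation (average ranks on ties) between a per-patient
#' clinical covariate (e.g. number of reflux episodes, percent full-column
#' reflux) and the within-patient beta diversity for a site pair — by
#' default the lung-gastric distance, asking whether more severe reflux
#' makes the two communities more alike.
#'
#' @inheritParams within_patient_distances
#' @param covariate name of a numeric metadata column.
#' @param site_pair site pair, default `c("lung", "gastric")`.
#' @return A `group_comparison` with `statistic_name = "spearman"`; the
#'   summary reports the number of patients used.
#' @export
reflux_correlation <- function(dm, metadata, covariate,
                               site_pair = c("lung", "gastric")) {
  if (!covariate %in% names(metadata))
    stop("metadata has no column '", covariate, "'")
  wp <- within_patient_distances(dm, metadata, site_pair)
  cov_by_patient <- tapply(metadata[[covariate]], metadata$patient_id,
                           function(v) {
                             v <- v[!is.na(v)]
                             if (length(v)) v[1L] else NA_real_
                           })
  wp$cov <- as.numeric(cov_by_patient[wp$patient_id])
  wp <- wp[!is.na(wp$cov), , drop = FALSE]
  if (nrow(wp) < 5L)
    stop("need at least 5 patients with both sites and a '", covariate,
         "' value (have ", nrow(wp), ")")
  ct <- suppressWarnings(
    stats::cor.test(wp$cov, wp$distance, method = "spearman"))
  summ <- data.frame(group = "all", median = stats::median(wp$distance),
                     n = nrow(wp), row.names = NULL)
  group_comparison("spearman", unname(ct$estimate), ct$p.value, summ)
}
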