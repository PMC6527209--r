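#' Within-patient distances for a pair of body sites
#'
#' For every patient sampled at both sites of the pair, the beta-diversity
#' distance between that patient's two samples. Patients missing either site
#' are skipped.
#'
#' @param dm symmetric distance matrix with sample-ID dimnames.
#' @param metadata metadata `data.frame` (`sample_id`, `patient_id`, `site`,
#'   `batch`, ...).
#' @param site_pair character vector of two distinct sites.
#' @return A `data.frame` with columns `patient_id`, `distance`.
#' @export
within_patient_distances <- function(dm, metadata, site_pair) {
  site_pair <- check_site_pair(site_pair)
  md <- metadata[metadata$sample_id %in% rownames(dm), , drop = FALSE]
  a <- md[md$site == site_pair[1L], c("patient_id", "sample_id")]
  b <- md[md$site == site_pair[2L], c("patient_id", "sample_id")]
  both <- merge(a, b, by = "patient_id", suffixes = c("_a", "_b"))
  if (!nrow(both))
    return(data.frame(patient_id = character(), distance = numeric()))
  d <- dm[cbind(both$sample_id_a, both$sample_id_b)]
  out <- data.frame(patient_id = both$patient_id, distance = as.numeric(d),
                    stringsAsFactors = FALSE)
  out[order(out$patient_id), , drop = FALSE]
}

#' Across-patient distances for a single body site
#'
#' Distances between all unordered pairs of distinct patients' samples of one
#' site. Only pairs sequenced in the same batch are compared, so batch
#' effects do not inflate the across-patient dissimilarity.
#'
#' @inheritParams within_patient_distances
#' @param site a single site.
#' @return Numeric vector of distances (possibly empty).
#' @export
across_patient_distances <- function(dm, metadata, site) {
  md <- metadata[metadata$sample_id %in% rownames(dm) &
                   metadata$site == site, , drop = FALSE]
  n <- nrow(md)
  if (n < 2L) return(numeric())
  out <- numeric()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (md$patient_id[i] != md$patient_id[j] &&
          md$batch[i] == md$batch[j]) {
        out <- c(out, dm[md$sample_id[i], md$sample_id[j]])
      }
    }
  }
  out
}

# mean distance from one sample to all other patients' same-site samples in
# the same batch; NA when no comparator exists
across_mean_for_sample <- function(dm, md_site, sample_id) {
  row <- md_site[md_site$sample_id == sample_id, , drop = FALSE]
  others <- md_site[md_site$patient_id != row$patient_id &
                      md_site$batch == row$batch, , drop = FALSE]
  if (!nrow(others)) return(NA_real_)
  mean(dm[sample_id, others$sample_id])
}

#' Within-patient vs across-patient distance comparison
#'
#' For each patient with both sites of the pair, compares the within-patient
#' distance between the two sites with (a) the mean distance from the
#' patient's site-a sample to all other patients' site-a samples and (b) the
#' same for site b (same-batch comparators only). Paired Wilcoxon
#' signed-rank tests ask whether within-patient communities are closer than
#' the across-patient baseline for each site.
#'
#' @inheritParams within_patient_distances
#' @return A list with `records` (a `data.frame`: `patient_id`, `within`,
#'   `across_mean_a`, `across_mean_b`), `p_a`, `p_b` (signed-rank p-values;
#'   `NA` with `degenerate = TRUE` when all paired differences are zero) and
#'   `degenerate`.
#' @export
within_vs_across <- function(dm, metadata, site_pair) {
  site_pair <- check_site_pair(site_pair)
  wp <- within_patient_distances(dm, metadata, site_pair)
  if (nrow(wp) < 6L)
    stop("need at least 6 patients with both sites (have ", nrow(wp), ")")
  md <- metadata[metadata$sample_id %in% rownames(dm), , drop = FALSE]
  md_a <- md[md$site == site_pair[1L], , drop = FALSE]
  md_b <- md[md$site == site_pair[2L], , drop = FALSE]
  sa <- md_a$sample_id[match(wp$patient_id, md_a$patient_id)]
  sb <- md_b$sample_id[match(wp$patient_id, md_b$patient_id)]
  across_a <- vapply(sa, function(s) across_mean_for_sample(dm, md_a, s),
                     numeric(1))
  across_b <- vapply(sb, function(s) across_mean_for_sample(dm, md_b, s),
                     numeric(1))
  records <- data.frame(patient_id = wp$patient_id, within = wp$distance,
                        across_mean_a = unname(across_a),
                        across_mean_b = unname(across_b),
                        stringsAsFactors = FALSE)
  signed_rank_p <- function(within, across) {
    ok <- !is.na(across)
    diffs <- within[ok] - across[ok]
    if (all(diffs == 0)) return(NA_real_)
    stats::wilcox.test(within[ok], across[ok], paired = TRUE,
                       exact = FALSE)$p.value
  }
  p_a <- signed_rank_p(records$within, records$across_mean_a)
  p_b <- signed_rank_p(records$within, records$across_mean_b)
  list(records = records, p_a = p_a, p_b = p_b,
       degenerate = is.na(p_a) && is.na(p_b))
}

check_site_pair <- function(site_pair) {
  site_pair <- as.character(site_pair)
  if (length(site_pair) != 2L || site_pair[1L] == site_pair[2L])
    stop("site_pair must be two distinct sites")
  bad <- setdiff(site_pair, SITES)
  if (length(bad)) stop("unknown site: ", bad[1L])
  site_pair
}

# the third aerodigestive site, used for partialling in exchange detection
partial_site_for <- function(site_pair) {
  if (!all(site_pair %in% AERODIGESTIVE_SITES))
    stop("partialling is defined only for aerodigestive site pairs")
  setdiff(AERODIGESTIVE_SITES, site_pair)
}
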