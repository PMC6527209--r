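#' First-order partial Spearman correlation
#'
#' The partial correlation of `x` and `y` given `z` on the rank scale:
#' `(r_xy - r_xz * r_zy) / sqrt((1 - r_xz^2) * (1 - r_zy^2))`, where each
#' `r` is a Spearman correlation (Pearson correlation of average ranks, so
#' ties are handled). This asks whether an OTU's abundances in two body
#' sites co-vary across patients beyond what the third site explains.
#'
#' A constant `z` contributes `r_xz = r_zy = 0`, so the partial reduces to
#' the plain Spearman correlation of `x` and `y`. A constant `x` or `y`, or
#' a degenerate denominator (`|r_xz| = 1` or `|r_zy| = 1`), makes the
#' statistic not computable and returns `NA`.
#'
#' @param x,y,z numeric vectors of equal length `>= 3`, paired over patients.
#' @return The partial correlation in \[-1, 1\], or `NA` when not computable.
#' @export
spearman_partial <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y, z must have the same length")
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y) || anyNA(z)) stop("inputs must not contain NA")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  rx <- rank(x)
  ry <- rank(y)
  r_xy <- stats::cor(rx, ry)
  if (stats::sd(z) == 0) {
    r_xz <- 0
    r_zy <- 0
  } else {
    rz <- rank(z)
    r_xz <- stats::cor(rx, rz)
    r_zy <- stats::cor(rz, ry)
  }
  # rank-collinear z (|r| = 1 up to rounding) leaves nothing to partial on
  if (1 - r_xz^2 <= 1e-12 || 1 - r_zy^2 <= 1e-12) return(NA_real_)
  den2 <- (1 - r_xz^2) * (1 - r_zy^2)
  rho <- (r_xy - r_xz * r_zy) / sqrt(den2)
  min(max(rho, -1), 1)
}

# standardized ranks: mean 0, unit sd (NULL if constant)
std_ranks <- function(v) {
  r <- rank(v)
  s <- stats::sd(r)
  if (s == 0) return(NULL)
  (r - mean(r)) / s
}

# null distribution of the partial statistic under permutation of y,
# vectorized over permutations: x and z stay paired, y is shuffled, and all
# Spearman terms are Pearson products of standardized ranks
null_partials <- function(x, y, z, n_permutations) {
  n <- length(x)
  xs <- std_ranks(x)
  ys <- std_ranks(y)
  zs <- std_ranks(z)  # NULL when z constant -> r_xz = r_zy = 0
  perm <- vapply(seq_len(n_permutations),
                 function(i) ys[sample.int(n)], numeric(n))
  r_xy <- as.numeric(crossprod(xs, perm)) / (n - 1)
  if (is.null(zs)) return(pmin(pmax(r_xy, -1), 1))
  r_xz <- sum(xs * zs) / (n - 1)
  r_zy <- as.numeric(crossprod(zs, perm)) / (n - 1)
  den2 <- (1 - r_xz^2) * (1 - r_zy^2)
  out <- (r_xy - r_xz * r_zy) / sqrt(den2)
  out[den2 <= 0] <- NA_real_
  pmin(pmax(out, -1), 1)
}

#' Permutation p-value for the partial Spearman statistic
#'
#' Shuffles `y` uniformly at random (keeping `x` and `z` paired) and reports
#' the fraction of null partial correlations strictly larger than the
#' observed one — a one-sided upper-tail test of positive association, the
#' alternative under which an OTU is being exchanged between sites.
#'
#' @inheritParams spearman_partial
#' @param n_permutations number of shuffles (2000 by default).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (so a caller can seed once for a whole scan).
#' @return List with `partial_rho`, `perm_p`, `n_permutations`.
#' @export
permutation_p <- function(x, y, z, n_permutations = 2000, seed = NULL) {
  obs <- spearman_partial(x, y, z)
  if (is.na(obs))
    stop("observed partial correlation is not computable for this triple")
  run <- function() {
    nulls <- null_partials(x, y, z, n_permutations)
    sum(nulls > obs, na.rm = TRUE) / n_permutations
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(partial_rho = obs, perm_p = p, n_permutations = n_permutations)
}

# patient-by-site sample map restricted to patients with all three
# aerodigestive sites present in both table and metadata
triple_site_patients <- function(table, metadata) {
  md <- metadata[metadata$sample_id %in% colnames(table) &
                   metadata$site %in% AERODIGESTIVE_SITES, , drop = FALSE]
  wide <- list()
  for (s in AERODIGESTIVE_SITES) {
    sub <- md[md$site == s, c("patient_id", "sample_id")]
    names(sub)[2L] <- s
    wide[[s]] <- sub
  }
  m <- Reduce(function(a, b) merge(a, b, by = "patient_id"), wide)
  m[order(m$patient_id), , drop = FALSE]
}

#' Detect OTUs exchanged between two aerodigestive sites
#'
#' For each OTU, takes the patients (among those with all three
#' aerodigestive sites sequenced) whose relative abundance is non-zero in
#' both sites of the pair, computes the partial Spearman correlation of the
#' two sites' abundances given the third site's abundances in the same
#' patients (third-site zeros retained), and a one-sided permutation
#' p-value. Only OTUs co-occurring in at least `min_patients` patients are
#' tested; Benjamini-Hochberg correction is applied across the tested OTUs
#' of this site pair, and OTUs with `q < q_threshold` are flagged exchanged.
#'
#' @param table relative-mode [abundance_table].
#' @param metadata metadata `data.frame`.
#' @param site_pair two aerodigestive sites, e.g. `c("lung", "oropharynx")`.
#' @param min_patients minimum co-occurrence count for an OTU to be tested.
#' @param n_permutations permutations per OTU.
#' @param q_threshold FDR threshold defining "exchanged".
#' @param seed integer seed governing all permutations of the scan.
#' @return A `data.frame` (one row per tested OTU): `otu_id`, `site_a`,
#'   `site_b`, `n_patients`, `partial_rho`, `perm_p`, `q_value`, `exchanged`.
#'   Attribute `n_candidates` counts all OTUs in the table; an empty result
#'   means no OTU met the prevalence filter.
#' @export
detect_exchanged <- function(table, metadata, site_pair, min_patients = 10,
                             n_permutations = 2000, q_threshold = 0.1,
                             seed = NULL) {
  stopifnot(is_abundance_table(table))
  if (table_mode(table) != "relative")
    stop("detect_exchanged needs a relative-mode table")
  site_pair <- check_site_pair(site_pair)
  third <- partial_site_for(site_pair)
  pts <- triple_site_patients(table, metadata)
  if (nrow(pts) < min_patients)
    stop("only ", nrow(pts), " patients have all three aerodigestive sites; ",
         "need at least ", min_patients)
  v <- unclass_matrix(table)
  A <- v[, pts[[site_pair[1L]]], drop = FALSE]
  B <- v[, pts[[site_pair[2L]]], drop = FALSE]
  Z <- v[, pts[[third]], drop = FALSE]
  scan <- function() {
    rows <- vector("list", nrow(v))
    for (i in seq_len(nrow(v))) {
      idx <- A[i, ] > 0 & B[i, ] > 0
      n_pat <- sum(idx)
      if (n_pat < min_patients) next
      x <- A[i, idx]
      y <- B[i, idx]
      z <- Z[i, idx]
      rho <- spearman_partial(x, y, z)
      if (is.na(rho)) next  # not computable; excluded from the BH family
      p <- sum(null_partials(x, y, z, n_permutations) > rho, na.rm = TRUE) /
        n_permutations
      rows[[i]] <- data.frame(otu_id = rownames(v)[i],
                              site_a = site_pair[1L], site_b = site_pair[2L],
                              n_patients = n_pat, partial_rho = rho,
                              perm_p = p, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  res <- if (is.null(seed)) scan() else withr::with_seed(seed, scan())
  if (is.null(res)) {
    res <- data.frame(otu_id = character(), site_a = character(),
                      site_b = character(), n_patients = integer(),
                      partial_rho = numeric(), perm_p = numeric(),
                      q_value = numeric(), exchanged = logical(),
                      stringsAsFactors = FALSE)
  } else {
    res$q_value <- stats::p.adjust(res$perm_p, method = "BH")
    res$exchanged <- res$q_value < q_threshold
    rownames(res) <- NULL
  }
  attr(res, "n_candidates") <- nrow(v)
  attr(res, "site_pair") <- site_pair
  res
}

# shuffle patient identities independently for each OTU within each site's
# triple-site columns; returns a table with the same dimnames. The shuffled
# columns are no longer compositions (each OTU moved independently), so the
# object is assembled without the column-sum validation — the detector only
# uses within-OTU ranks, which the shuffle is meant to decouple.
shuffle_patients_per_otu <- function(table, pts) {
  v <- unclass_matrix(table)
  for (s in AERODIGESTIVE_SITES) {
    cols <- match(pts[[s]], colnames(v))
    k <- length(cols)
    for (i in seq_len(nrow(v))) {
      v[i, cols] <- v[i, cols][sample.int(k)]
    }
  }
  structure(v, taxonomy = otu_taxonomy(table), mode = table_mode(table),
            class = class(table))
}

#' Null calibration of the exchanged-OTU count
#'
#' Destroys any within-patient pairing by shuffling patient IDs for each OTU
#' in each site, then re-runs the full exchange detection; repeated over
#' `n_rounds` shuffles. The count of "exchanged" OTUs found in shuffled data
#' measures how many detections the pipeline produces by chance alone.
#'
#' @inheritParams detect_exchanged
#' @param n_rounds number of shuffle rounds.
#' @return A list with `n_rounds`, `counts` (exchanged OTUs per round) and
#'   `max_count`.
#' @export
null_calibration <- function(table, metadata, site_pair, n_rounds = 10,
                             min_patients = 10, n_permutations = 2000,
                             q_threshold = 0.1, seed = NULL) {
  if (n_rounds < 1L) stop("n_rounds must be at least 1")
  pts <- triple_site_patients(table, metadata)
  run <- function() {
    counts <- integer(n_rounds)
    for (r in seq_len(n_rounds)) {
      shuffled <- shuffle_patients_per_otu(table, pts)
      res <- detect_exchanged(shuffled, metadata, site_pair,
                              min_patients = min_patients,
                              n_permutations = n_permutations,
                              q_threshold = q_threshold, seed = NULL)
      counts[r] <- sum(res$exchanged)
    }
    counts
  }
  counts <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(n_rounds = n_rounds, counts = counts, max_count = max(counts))
}

#' Co-occurrence prevalence of exchanged OTUs in a patient group
#'
#' For each OTU, the percentage of the group's patients that carry it
#' (abundance > 0) in both sites of the pair, among group patients with both
#' sites sampled.
#'
#' @inheritParams detect_exchanged
#' @param exchanged_otus character vector of OTU IDs.
#' @param group aspiration status defining the patient group
#'   (`"aspirator"` or `"non_aspirator"`).
#' @return Named numeric vector of prevalences (percent) with attribute
#'   `n_patients`, the group denominator.
#' @export
cooccurrence_prevalence <- function(table, metadata, exchanged_otus,
                                    site_pair, group) {
  stopifnot(is_abundance_table(table))
  site_pair <- check_site_pair(site_pair)
  md <- metadata[metadata$sample_id %in% colnames(table), , drop = FALSE]
  grp_patients <- unique(md$patient_id[md$aspiration_status == group])
  a <- md[md$site == site_pair[1L] & md$patient_id %in% grp_patients, ]
  b <- md[md$site == site_pair[2L] & md$patient_id %in% grp_patients, ]
  both <- merge(a[, c("patient_id", "sample_id")],
                b[, c("patient_id", "sample_id")],
                by = "patient_id", suffixes = c("_a", "_b"))
  if (!nrow(both))
    stop("no '", group, "' patients with both ", site_pair[1L], " and ",
         site_pair[2L], " sampled")
  missing <- setdiff(exchanged_otus, rownames(table))
  if (length(missing)) stop("OTU not in table: ", missing[1L])
  va <- unclass_matrix(table)[exchanged_otus, both$sample_id_a, drop = FALSE]
  vb <- unclass_matrix(table)[exchanged_otus, both$sample_id_b, drop = FALSE]
  prev <- 100 * rowMeans(va > 0 & vb > 0)
  names(prev) <- exchanged_otus
  attr(prev, "n_patients") <- nrow(both)
  prev
}

#' Differential co-occurrence prevalence between two patient groups
#'
#' Per-OTU prevalence difference (group 2 minus group 1, percentage points)
#' and a paired t-test on the log10 prevalences across OTUs. Zero
#' prevalences are replaced by the half-patient pseudo-prevalence
#' `100 * 0.5 / n_group` before taking logs.
#'
#' @param prev_group1,prev_group2 named prevalence vectors over the same OTU
#'   set (as returned by [cooccurrence_prevalence()]).
#' @param n_group1,n_group2 group denominators; taken from the `n_patients`
#'   attribute when present.
#' @return List with `difference` (named vector), `statistic`, `p_value`
#'   (`NA` with `degenerate = TRUE` when the paired log differences are all
#'   zero) and `degenerate`.
#' @export
differential_prevalence <- function(prev_group1, prev_group2,
                                    n_group1 = attr(prev_group1, "n_patients"),
                                    n_group2 = attr(prev_group2, "n_patients")) {
  if (length(prev_group1) != length(prev_group2) ||
      (!is.null(names(prev_group1)) && !is.null(names(prev_group2)) &&
       !identical(names(prev_group1), names(prev_group2))))
    stop("prevalence vectors must cover the same OTUs in the same order")
  diff <- as.numeric(prev_group2) - as.numeric(prev_group1)
  names(diff) <- names(prev_group1)
  floor_log <- function(p, n) {
    if (any(p == 0) && is.null(n))
      stop("zero prevalence present; supply the group size for the ",
           "half-patient pseudo-prevalence")
    p[p == 0] <- 100 * 0.5 / n
    log10(p)
  }
  l1 <- floor_log(as.numeric(prev_group1), n_group1)
  l2 <- floor_log(as.numeric(prev_group2), n_group2)
  if (all(l2 - l1 == 0))
    return(list(difference = diff, statistic = NA_real_, p_value = NA_real_,
                degenerate = TRUE))
  tt <- stats::t.test(l2, l1, paired = TRUE)
  list(difference = diff, statistic = unname(tt$statistic),
       p_value = tt$p.value, degenerate = FALSE)
}

#' Write exchange results with taxonomy columns
#'
#' @param results `data.frame` from [detect_exchanged()].
#' @param table the [abundance_table] carrying taxonomy (optional).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_exchange_results <- function(results, path, table = NULL) {
  out <- results
  if (!is.null(table) && !is.null(otu_taxonomy(table))) {
    lm <- lineage_matrix(otu_taxonomy(table))
    idx <- match(out$otu_id, rownames(table))
    out$family <- lm[idx, 5L]
    out$genus <- lm[idx, 6L]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
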