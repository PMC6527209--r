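#' Jensen-Shannon distance between two relative-abundance profiles
#'
#' The square root of the Jensen-Shannon divergence with base-2 logarithms:
#' `sqrt(0.5 * KL(p || m) + 0.5 * KL(q || m))` with `m = (p + q)/2` and the
#' convention `0 * log 0 = 0`. With base-2 logs the distance lies in
#' \[0, 1\]: 0 for identical communities, 1 for communities with disjoint
#' support. It is a proper metric on the simplex, symmetric and bounded,
#' which makes it well suited to compositional microbiome profiles.
#'
#' @param p,q non-negative numeric vectors of equal length, each summing to 1
#'   (within 1e-6).
#' @return The Jensen-Shannon distance, a scalar in \[0, 1\].
#' @export
jensen_shannon_distance <- function(p, q) {
  if (length(p) != length(q))
    stop("p and q must have the same length (", length(p), " vs ",
         length(q), ")")
  if (anyNA(p) || anyNA(q)) stop("p and q must not contain NA")
  if (min(p) < 0 || min(q) < 0) stop("p and q must be non-negative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("p and q must each sum to 1 (use to_relative_abundance first)")
  sqrt(js_divergence(p, q))
}

# base-2 Jensen-Shannon divergence; 0 log 0 := 0 via subsetting to support
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  ip <- p > 0
  iq <- q > 0
  kl_pm <- sum(p[ip] * log2(p[ip] / m[ip]))
  kl_qm <- sum(q[iq] * log2(q[iq] / m[iq]))
  d2 <- 0.5 * kl_pm + 0.5 * kl_qm
  min(max(d2, 0), 1)  # clip floating-point spill just outside [0, 1]
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|p_i - q_i|) / sum(p_i + q_i)`, in \[0, 1\].
#'
#' @param p,q non-negative numeric vectors of equal length, not both all-zero.
#' @return The Bray-Curtis dissimilarity.
#' @export
bray_curtis <- function(p, q) {
  if (length(p) != length(q))
    stop("p and q must have the same length")
  if (min(p) < 0 || min(q) < 0) stop("p and q must be non-negative")
  if (sum(p) == 0 && sum(q) == 0)
    stop("Bray-Curtis undefined when both vectors are all zero")
  as.numeric(vegan::vegdist(rbind(p, q), method = "bray"))
}

#' Pairwise beta-diversity matrix
#'
#' Computes all unordered sample-pair distances for a relative-abundance
#' table under the chosen metric.
#'
#' @param table a relative-mode [abundance_table].
#' @param metric `"jsd"` (Jensen-Shannon distance) or `"braycurtis"`.
#' @return A symmetric numeric matrix with zero diagonal, sample IDs as
#'   dimnames.
#' @export
pairwise_distances <- function(table, metric = c("jsd", "braycurtis")) {
  metric <- match.arg(metric)
  stopifnot(is_abundance_table(table))
  if (table_mode(table) != "relative")
    stop("pairwise_distances needs a relative-mode table; ",
         "call to_relative_abundance first")
  v <- unclass_matrix(table)
  n <- ncol(v)
  if (metric == "braycurtis") {
    dm <- as.matrix(vegan::vegdist(t(v), method = "bray"))
  } else {
    dm <- matrix(0, n, n)
    if (n > 1) {
      for (i in seq_len(n - 1L)) {
        pi_ <- v[, i]
        for (j in (i + 1L):n) {
          dm[i, j] <- dm[j, i] <- sqrt(js_divergence(pi_, v[, j]))
        }
      }
    }
  }
  dimnames(dm) <- list(colnames(v), colnames(v))
  dm
}

#' Write / read a distance matrix in the tab-delimited square dialect
#'
#' @param dm symmetric matrix with sample-ID dimnames.
#' @param path file path.
#' @return `read_distance_matrix` returns the matrix; `write_distance_matrix`
#'   returns `path` invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  utils::write.table(cbind(sample_id = rownames(dm), as.data.frame(dm)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Alpha diversity of a single sample
#'
#' Computed on raw OTU counts. `shannon` is base-2 Shannon entropy of the
#' count frequencies; `simpson` is the Gini-Simpson index `1 - sum(f_i^2)`;
#' `chao1` is the classic richness estimator `S_obs + F1^2 / (2 F2)` where
#' `F1`/`F2` are the singleton/doubleton counts, with the usual
#' `F1 (F1 - 1) / 2` correction when there are no doubletons.
#'
#' @param counts non-negative integer vector with positive total.
#' @param metric `"shannon"`, `"chao1"` or `"simpson"`.
#' @return The diversity value.
#' @export
alpha_diversity <- function(counts, metric = c("shannon", "chao1", "simpson")) {
  metric <- match.arg(metric)
  if (anyNA(counts) || min(counts) < 0)
    stop("counts must be non-negative and NA-free")
  total <- sum(counts)
  if (total <= 0) stop("counts must have a positive total")
  switch(metric,
    shannon = as.numeric(vegan::diversity(counts, index = "shannon", base = 2)),
    simpson = as.numeric(vegan::diversity(counts, index = "simpson")),
    chao1 = {
      s_obs <- sum(counts > 0)
      f1 <- sum(counts == 1)
      f2 <- sum(counts == 2)
      if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
    }
  )
}

#' Per-sample alpha diversity for a table
#'
#' @param table counts-mode [abundance_table].
#' @inheritParams alpha_diversity
#' @return Named numeric vector, one value per sample.
#' @export
alpha_diversity_table <- function(table, metric = "shannon") {
  stopifnot(is_abundance_table(table))
  if (table_mode(table) != "counts")
    stop("alpha diversity is computed on raw counts")
  apply(unclass_matrix(table), 2L, alpha_diversity, metric = metric)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance of a grouping factor on a
#' pairwise distance matrix (via [vegan::adonis2()]). The p-value uses the
#' add-one convention `p = (1 + #{F* >= F}) / (1 + n_permutations)`.
#'
#' @param dm symmetric distance matrix with sample-ID dimnames.
#' @param grouping vector of group labels, one per sample (in `dm` order).
#' @param n_permutations number of label permutations.
#' @param seed optional integer seed for the permutations.
#' @return A list with `pseudo_F` and `p_value`.
#' @export
permanova <- function(dm, grouping, n_permutations = 999, seed = NULL) {
  grouping <- as.character(grouping)
  if (length(grouping) != nrow(dm))
    stop("grouping length must match the distance matrix")
  tab <- table(grouping)
  if (length(tab) < 2L)
    stop("PERMANOVA needs at least 2 groups")
  if (min(tab) < 2L)
    stop("every group needs at least 2 samples (singleton group: '",
         names(tab)[which.min(tab)], "')")
  run <- function() {
    fit <- vegan::adonis2(stats::as.dist(dm) ~ g,
                          data = data.frame(g = factor(grouping)),
                          permutations = n_permutations)
    list(pseudo_F = fit$F[1L], p_value = fit$`Pr(>F)`[1L])
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
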