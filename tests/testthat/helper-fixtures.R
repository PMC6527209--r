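# small deterministic fixtures and independent oracles used across tests

make_tiny_table <- function() {
  abundance_table(
    matrix(c(2, 2, 0,
             5, 0, 5,
             3, 8, 5), nrow = 3, byrow = TRUE,
           dimnames = list(c("OTU_A", "OTU_B", "OTU_C"), c("s1", "s2", "s3"))),
    taxonomy = c("Bacteria;Firmicutes;c;o;Streptococcaceae;Streptococcus",
                 "Bacteria;Firmicutes;c;o;Streptococcaceae;Streptococcus",
                 "Bacteria;Bacteroidetes;c;o;Prevotellaceae;"),
    mode = "counts")
}

make_tiny_metadata <- function() {
  data.frame(
    sample_id = c("s1", "s2", "s3"),
    patient_id = c("p1", "p1", "p2"),
    site = c("lung", "oropharynx", "lung"),
    batch = "B1",
    aspiration_status = c("aspirator", "aspirator", "non_aspirator"),
    stringsAsFactors = FALSE)
}

# random relative-abundance vector on the simplex
random_simplex <- function(k) {
  v <- stats::rexp(k)
  v / sum(v)
}

# independent JSD oracle: entropy identity JS(p,q) = H(m) - (H(p) + H(q))/2
jsd_oracle <- function(p, q) {
  h <- function(v) {
    v <- v[v > 0]
    -sum(v * log2(v))
  }
  m <- (p + q) / 2
  d2 <- h(m) - (h(p) + h(q)) / 2
  sqrt(max(d2, 0))
}

# independent partial-Spearman oracle: correlation of the residuals of
# rank(x) and rank(y) each regressed on rank(z)
partial_oracle <- function(x, y, z) {
  rx <- rank(x)
  ry <- rank(y)
  rz <- rank(z)
  ex <- stats::resid(stats::lm(rx ~ rz))
  ey <- stats::resid(stats::lm(ry ~ rz))
  stats::cor(ex, ey)
}

# direct Benjamini-Hochberg step-up q-values
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# cached default cohorts so several test files can share one generation
cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(seed, null = FALSE, ...) {
  key <- paste0(if (null) "null" else "alt", seed, "_",
                paste(unlist(list(...)), collapse = "_"))
  if (is.null(cohort_cache[[key]])) {
    spec <- cohort_spec(seed = seed, ...)
    cohort_cache[[key]] <- if (null) null_cohort(spec) else
      generate_cohort(spec)
  }
  cohort_cache[[key]]
}
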