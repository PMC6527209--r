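#' Synthetic aerodigestive cohort specification
#'
#' Parameters of the Dirichlet-multinomial cohort generator. The defaults
#' mirror the study design the analysis assumes: 66 patients with all three
#' aerodigestive sites sampled (25 aspirators, 23 non-aspirators, 18
#' untested), a conserved "core" oropharyngeal community, sparse highly
#' person-specific lung and gastric communities sharing a patient base,
#' 20 exchanged OTUs planted per site pair with within-patient rank
#' correlation `exchange_strength`, an aspiration effect mixing a fraction
#' `aspiration_mixing` of the patient's oropharyngeal community into the
#' lung, 10,000 reads per sample in 2 sequencing batches.
#'
#' @param n_patients number of patients (each gets all three sites).
#' @param fraction_aspirators,fraction_untested fractions of patients labeled
#'   aspirator / untested; the rest are non-aspirators.
#' @param n_otus number of OTUs in the community pool.
#' @param n_exchanged exchanged OTUs planted per aerodigestive site pair.
#' @param core_concentration Dirichlet concentration of patient oropharyngeal
#'   communities around the shared core (high = conserved).
#' @param person_concentration concentration of patient-specific lung/gastric
#'   bases around the global pool (low = sparse, person-specific).
#' @param site_concentration concentration of a patient's lung and gastric
#'   communities around that patient's base.
#' @param exchange_strength target within-patient Spearman correlation of
#'   planted exchanged OTUs between their two sites, in \[0, 1\].
#' @param aspiration_mixing fraction of an aspirator's lung community drawn
#'   from that patient's oropharynx, in \[0, 1\].
#' @param sequencing_depth multinomial reads per sample.
#' @param dropout probability that an OTU present in the latent composition
#'   yields zero reads beyond multinomial sampling.
#' @param n_batches sequencing batches, assigned round-robin over patients.
#' @param seed integer seed; all generator randomness flows from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 66, fraction_aspirators = 25 / 66,
                        fraction_untested = 18 / 66, n_otus = 200,
                        n_exchanged = 20, core_concentration = 75,
                        person_concentration = 40, site_concentration = 50,
                        exchange_strength = 0.8, aspiration_mixing = 0.6,
                        sequencing_depth = 10000, dropout = 0.05,
                        n_batches = 2, seed = 1) {
  spec <- list(n_patients = n_patients,
               fraction_aspirators = fraction_aspirators,
               fraction_untested = fraction_untested, n_otus = n_otus,
               n_exchanged = n_exchanged,
               core_concentration = core_concentration,
               person_concentration = person_concentration,
               site_concentration = site_concentration,
               exchange_strength = exchange_strength,
               aspiration_mixing = aspiration_mixing,
               sequencing_depth = sequencing_depth, dropout = dropout,
               n_batches = n_batches, seed = seed)
  for (f in c("fraction_aspirators", "fraction_untested",
              "exchange_strength", "aspiration_mixing", "dropout")) {
    if (spec[[f]] < 0 || spec[[f]] > 1)
      stop("spec field '", f, "' must lie in [0, 1]")
  }
  if (spec$fraction_aspirators + spec$fraction_untested > 1)
    stop("spec fields 'fraction_aspirators' + 'fraction_untested' exceed 1")
  if (spec$n_exchanged * 3 > spec$n_otus)
    stop("spec field 'n_exchanged' too large for 'n_otus'")
  for (f in c("n_patients", "n_otus", "sequencing_depth", "n_batches")) {
    if (spec[[f]] < 1) stop("spec field '", f, "' must be positive")
  }
  for (f in c("core_concentration", "person_concentration",
              "site_concentration")) {
    if (spec[[f]] <= 0) stop("spec field '", f, "' must be positive")
  }
  structure(spec, class = "cohort_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  s <- sum(g)
  if (s == 0) {  # pathological all-underflow draw; fall back to the mean
    g <- alpha
    s <- sum(g)
  }
  g / s
}

# deterministic synthetic lineages: consecutive OTU pairs share a full
# lineage down to genus (so genus collapsing merges them), every sixth OTU
# is unannotated at genus level (blank final rank)
synthetic_taxonomy <- function(n_otus) {
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria", "Fusobacteria")
  vapply(seq_len(n_otus), function(i) {
    g <- (i + 1L) %/% 2L
    p <- phyla[(g - 1L) %% length(phyla) + 1L]
    fam <- sprintf("Family%02d", (g - 1L) %/% 5L + 1L)
    gen <- if (i %% 6L == 0L) "" else sprintf("Genus%03d", g)
    paste("Bacteria", p, paste0(p, "_class"), paste0(p, "_order"), fam, gen,
          sep = ";")
  }, character(1))
}

# the three aerodigestive pairs with their donor site listed first
EXCHANGE_PAIRS <- list(c("lung", "oropharynx"),
                       c("lung", "gastric"),
                       c("oropharynx", "gastric"))

pair_key <- function(pair) paste(pair, collapse = "-")

# Gaussian-copula rank remap: permute the recipient's existing latent values
# for one OTU so their ranks follow a noisy copy of the donor's ranks,
# hitting a target Spearman correlation while preserving the recipient
# marginal exactly. Pearson latent r = 2 sin(pi * rho_s / 6). The link is
# applied among patients where the donor carries the OTU — exchange is only
# defined where there is something to exchange; recipient values of
# donor-free patients are left untouched.
plant_link <- function(donor_vals, recipient_vals, rho_s) {
  idx <- which(donor_vals > 0)
  n <- length(idx)
  if (n < 3L) return(recipient_vals)
  r_latent <- 2 * sin(pi * rho_s / 6)
  za <- stats::qnorm((rank(donor_vals[idx]) - 0.5) / n)
  zb <- r_latent * za + sqrt(1 - r_latent^2) * stats::rnorm(n)
  out <- recipient_vals
  out[idx] <- sort(recipient_vals[idx])[rank(zb, ties.method = "first")]
  out
}

generate_cohort_impl <- function(spec, shared_person_base) {
  P <- spec$n_patients
  K <- spec$n_otus
  otu_ids <- sprintf("OTU_%04d", seq_len(K))
  taxonomy <- synthetic_taxonomy(K)
  patient_ids <- sprintf("P%03d", seq_len(P))

  # log-normal rank-abundance pools; the lung/gastric pool and the
  # oropharyngeal core share most of their log-scale variance so the sites
  # share predominant members, as aerodigestive communities do
  shared_field <- stats::rnorm(K)
  base_global <- exp(1.5 * (sqrt(0.7) * shared_field +
                              sqrt(0.3) * stats::rnorm(K)))
  base_global <- base_global / sum(base_global)
  core_oro <- exp(1.5 * (sqrt(0.7) * shared_field +
                           sqrt(0.3) * stats::rnorm(K)))
  core_oro <- core_oro / sum(core_oro)

  # exchanged OTUs: prevalent members of both community pools (the study's
  # exchanged taxa are common aerodigestive genera), interleaved over the
  # abundance ranking, disjoint across the three site pairs
  need <- 3L * spec$n_exchanged
  r_glob <- rank(-base_global)
  r_core <- rank(-core_oro)
  pool_depth <- need
  repeat {  # smallest both-site rank cutoff holding enough candidates
    pool <- which(r_glob <= pool_depth & r_core <= pool_depth)
    if (length(pool) >= need || pool_depth >= K) break
    pool_depth <- pool_depth + 5L
  }
  if (length(pool) < need)
    stop("cannot place ", need, " exchanged OTUs among ", K, " OTUs")
  score <- r_glob + r_core
  top <- pool[order(score[pool])][seq_len(need)]
  exchanged <- list()
  for (k in seq_along(EXCHANGE_PAIRS)) {
    idx <- if (spec$n_exchanged > 0)
      top[seq(k, length(top), by = 3L)] else integer()
    exchanged[[pair_key(EXCHANGE_PAIRS[[k]])]] <- otu_ids[idx]
  }

  latent <- list(lung = matrix(0, K, P), oropharynx = matrix(0, K, P),
                 gastric = matrix(0, K, P))
  for (p in seq_len(P)) {
    if (shared_person_base) {
      b <- rdirichlet1(spec$person_concentration * base_global)
      b_lung <- b_gast <- b
    } else {
      b_lung <- rdirichlet1(spec$person_concentration * base_global)
      b_gast <- rdirichlet1(spec$person_concentration * base_global)
    }
    latent$lung[, p] <- rdirichlet1(spec$site_concentration * b_lung)
    latent$gastric[, p] <- rdirichlet1(spec$site_concentration * b_gast)
    latent$oropharynx[, p] <- rdirichlet1(spec$core_concentration * core_oro)
  }

  if (spec$exchange_strength > 0) {
    for (k in seq_along(EXCHANGE_PAIRS)) {
      pair <- EXCHANGE_PAIRS[[k]]
      rows <- match(exchanged[[pair_key(pair)]], otu_ids)
      if (!length(rows)) next
      rec <- latent[[pair[2L]]]
      for (i in rows) {
        rec[i, ] <- plant_link(latent[[pair[1L]]][i, ], rec[i, ],
                               spec$exchange_strength)
      }
      latent[[pair[2L]]] <- rec
    }
    for (s in names(latent))
      latent[[s]] <- sweep(latent[[s]], 2L, colSums(latent[[s]]), "/")
  }

  n_asp <- round(spec$fraction_aspirators * P)
  n_unt <- round(spec$fraction_untested * P)
  status <- sample(rep(c("aspirator", "untested", "non_aspirator"),
                       c(n_asp, n_unt, P - n_asp - n_unt)))
  mixing <- ifelse(status == "aspirator", spec$aspiration_mixing, 0)
  names(mixing) <- patient_ids
  for (p in seq_len(P)) {
    if (mixing[p] > 0) {
      latent$lung[, p] <- (1 - mixing[p]) * latent$lung[, p] +
        mixing[p] * latent$oropharynx[, p]
    }
  }

  sites <- names(latent)
  counts <- matrix(0L, K, P * length(sites))
  sample_ids <- character(P * length(sites))
  md_rows <- vector("list", P * length(sites))
  batch <- paste0("B", (seq_len(P) - 1L) %% spec$n_batches + 1L)
  col <- 0L
  for (p in seq_len(P)) {
    for (s in sites) {
      col <- col + 1L
      comp <- latent[[s]][, p]
      y <- stats::rmultinom(1L, spec$sequencing_depth, comp)[, 1L]
      if (spec$dropout > 0) {
        drop <- stats::runif(K) < spec$dropout & comp > 0
        y[drop] <- 0L
      }
      counts[, col] <- y
      sample_ids[col] <- paste(patient_ids[p], s, sep = "_")
      md_rows[[col]] <- data.frame(sample_id = sample_ids[col],
                                   patient_id = patient_ids[p], site = s,
                                   batch = batch[p],
                                   aspiration_status = status[p],
                                   stringsAsFactors = FALSE)
    }
  }
  table <- abundance_table(counts, otu_ids = otu_ids,
                           sample_ids = sample_ids, taxonomy = taxonomy,
                           mode = "counts")
  metadata <- validate_metadata(do.call(rbind, md_rows))
  truth <- list(exchanged = exchanged, mixing = mixing, latent = latent,
                base_global = base_global, core_oropharynx = core_oro,
                spec = spec)
  list(table = table, metadata = metadata, truth = truth)
}

#' Generate a synthetic multi-site cohort with planted ground truth
#'
#' Draws, per patient: an oropharyngeal community around a single shared
#' core; a sparse patient-specific base shared by the lung and gastric
#' communities (so those sites are person-driven); exchanged OTUs whose
#' latent abundances in their two sites are rank-correlated within patients
#' at `exchange_strength` (a Gaussian-copula remap that preserves each
#' site's marginal abundances); and an aspiration effect replacing a
#' fraction `aspiration_mixing` of aspirator lungs with the patient's own
#' oropharyngeal community. Counts are multinomial at `sequencing_depth`
#' with independent dropout.
#'
#' @param spec a [cohort_spec()].
#' @return A list: `table` (counts-mode [abundance_table]), `metadata`
#'   (`data.frame`), `truth` (planted exchanged OTU IDs per site pair,
#'   per-patient mixing coefficients, latent compositions, base
#'   compositions, and the spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed,
                   generate_cohort_impl(spec, shared_person_base = TRUE))
}

#' Generate a fully null cohort
#'
#' Same generator with `exchange_strength = 0`, `aspiration_mixing = 0`, and
#' independent patient bases for lung and gastric, so all sites are
#' independent given their per-site base compositions — the testbed for
#' null calibration and type-I-error suites.
#'
#' @inheritParams generate_cohort
#' @return As [generate_cohort()]; `truth$exchanged` still names the OTU
#'   slots that would have been planted, but no link is present.
#' @export
null_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  spec$exchange_strength <- 0
  spec$aspiration_mixing <- 0
  withr::with_seed(spec$seed,
                   generate_cohort_impl(spec, shared_person_base = FALSE))
}

#' Summarize a cohort by site combination and aspiration status
#'
#' @param table an [abundance_table] (used to restrict to analyzed samples);
#'   may be `NULL` to summarize the metadata alone.
#' @param metadata metadata `data.frame`.
#' @return A `data.frame` with `site_combination`, `aspiration_status`, `n`
#'   (patients).
#' @export
summarize_cohort <- function(table, metadata) {
  md <- metadata
  if (!is.null(table))
    md <- md[md$sample_id %in% colnames(table), , drop = FALSE]
  if (!nrow(md))
    return(data.frame(site_combination = character(),
                      aspiration_status = character(), n = integer()))
  combo <- tapply(md$site, md$patient_id,
                  function(s) paste(sort(unique(s)), collapse = "+"))
  status <- tapply(md$aspiration_status, md$patient_id, function(a) a[1L])
  df <- data.frame(site_combination = as.character(combo),
                   aspiration_status = as.character(status),
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(n = seq_len(nrow(df))),
                          by = df[, c("site_combination",
                                      "aspiration_status")], FUN = length)
  agg[order(agg$site_combination, agg$aspiration_status), , drop = FALSE]
}
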