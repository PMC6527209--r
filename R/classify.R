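#' Concordance encoding of presence across two sites
#'
#' Codes each OTU 1 when it is present in both sites or absent in both, and
#' 0 when present in exactly one — capturing whether the two sites agree
#' about the OTU regardless of abundance.
#'
#' @param presence_a,presence_b binary (0/1 or logical) vectors of equal
#'   length, one element per OTU.
#' @return Integer 0/1 vector.
#' @export
concordance_encoding <- function(presence_a, presence_b) {
  if (length(presence_a) != length(presence_b))
    stop("presence vectors must have the same length")
  a <- as.integer(as.logical(presence_a))
  b <- as.integer(as.logical(presence_b))
  if (anyNA(a) || anyNA(b)) stop("presence vectors must be binary, no NA")
  as.integer(a == b)
}

#' Area under the ROC curve via the Mann-Whitney normalization
#'
#' @param scores numeric predicted probabilities / scores.
#' @param labels binary truth (logical, or coercible; `TRUE` = positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute an AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise.
#' @return The two-sided hypergeometric exact p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}

# report assembled from pooled out-of-fold predictions; positive class is
# "aspirator" for aspiration tasks, the second site for site tasks
classifier_report <- function(predictions, positive) {
  truth <- predictions$truth == positive
  hard <- predictions$probability > 0.5
  auc <- roc_auc(predictions$probability, truth)
  cm <- matrix(c(sum(hard & truth), sum(hard & !truth),
                 sum(!hard & truth), sum(!hard & !truth)),
               nrow = 2, byrow = TRUE,
               dimnames = list(predicted = c("positive", "negative"),
                               truth = c("positive", "negative")))
  fisher_p <- fisher_exact_2x2(cm[1, 1], cm[1, 2], cm[2, 1], cm[2, 2])
  list(auc = auc, fisher_p = fisher_p, predictions = predictions,
       confusion = cm, n_positive = sum(truth), n_negative = sum(!truth),
       positive_class = positive)
}

#' Random-forest site classifier with patient-grouped cross-validation
#'
#' Distinguishes samples of two body sites with a random forest evaluated by
#' k-fold cross-validation in which the folds partition *patients*, so the
#' two samples of one patient can never straddle the train/test split and
#' leak patient identity.
#'
#' @param table relative-mode [abundance_table].
#' @param metadata metadata `data.frame`.
#' @param sites two sites to discriminate.
#' @param n_folds number of patient folds.
#' @param n_trees trees per forest.
#' @param seed integer seed for fold assignment and forests.
#' @return A classifier report: `auc`, `fisher_p`, pooled out-of-fold
#'   `predictions` (sample, truth, probability, fold), `confusion`, class
#'   sizes. The positive class is `sites[2]`.
#' @export
site_classifier_cv <- function(table, metadata, sites, n_folds = 5,
                               n_trees = 1000, seed = NULL) {
  stopifnot(is_abundance_table(table))
  sites <- check_site_pair(sites)
  md <- metadata[metadata$sample_id %in% colnames(table) &
                   metadata$site %in% sites, , drop = FALSE]
  patients <- unique(md$patient_id)
  if (length(patients) < n_folds)
    stop("need at least ", n_folds, " patients (have ", length(patients), ")")
  x <- t(unclass_matrix(table)[, md$sample_id, drop = FALSE])
  y <- factor(md$site, levels = sites)
  run <- function() {
    fold_of <- sample(rep_len(seq_len(n_folds), length(patients)))
    names(fold_of) <- patients
    sample_fold <- fold_of[md$patient_id]
    preds <- data.frame(unit = md$sample_id, truth = as.character(y),
                        probability = NA_real_, fold = as.integer(sample_fold),
                        stringsAsFactors = FALSE)
    for (f in seq_len(n_folds)) {
      test <- sample_fold == f
      if (!any(test)) next
      if (nlevels(droplevels(y[!test])) < 2L)
        stop("fold ", f, " leaves a single-class training set")
      fit <- randomForest::randomForest(x[!test, , drop = FALSE], y[!test],
                                        ntree = n_trees)
      pr <- stats::predict(fit, x[test, , drop = FALSE], type = "prob")
      preds$probability[test] <- pr[, sites[2L]]
    }
    preds
  }
  preds <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  classifier_report(preds, positive = sites[2L])
}

#' Build feature matrices for aspiration classifiers
#'
#' Units are patients having all requested sites sampled and a determined
#' aspiration label. Three encodings:
#' * `community`: site-tagged relative abundances of every OTU (each site's
#'   abundances are separate features);
#' * `exchanged_presence`: 0/1 presence of each exchanged OTU in a single
#'   site;
#' * `exchanged_concordance`: the [concordance_encoding()] of each exchanged
#'   OTU across the two sites of the pair.
#'
#' @param table relative-mode [abundance_table].
#' @param metadata metadata `data.frame`.
#' @param mode one of `"community"`, `"exchanged_presence"`,
#'   `"exchanged_concordance"`.
#' @param sites character vector of sites (one for `exchanged_presence`, two
#'   for `exchanged_concordance`, any number for `community`).
#' @param exchanged_otus OTU IDs (required for the exchanged modes).
#' @return A list: `x` (units x features matrix), `y` (factor with levels
#'   `non_aspirator`, `aspirator`), `unit_ids` (patient IDs), `excluded`
#'   (patients dropped for missing sites or untested status).
#' @export
build_features <- function(table, metadata,
                           mode = c("community", "exchanged_presence",
                                    "exchanged_concordance"),
                           sites, exchanged_otus = NULL) {
  mode <- match.arg(mode)
  stopifnot(is_abundance_table(table))
  sites <- unique(as.character(sites))
  if (length(bad <- setdiff(sites, SITES))) stop("unknown site: ", bad[1L])
  if (mode == "exchanged_presence" && length(sites) != 1L)
    stop("exchanged_presence uses exactly one site")
  if (mode == "exchanged_concordance" && length(sites) != 2L)
    stop("exchanged_concordance uses exactly two sites")
  if (mode != "community") {
    if (is.null(exchanged_otus))
      stop("exchanged modes need an exchanged-OTU list")
    if (length(missing <- setdiff(exchanged_otus, rownames(table))))
      stop("OTU not in table: ", missing[1L])
  }
  md <- metadata[metadata$sample_id %in% colnames(table), , drop = FALSE]
  labeled <- unique(md[md$aspiration_status %in%
                         c("aspirator", "non_aspirator"),
                       c("patient_id", "aspiration_status")])
  sample_of <- lapply(sites, function(s) {
    sub <- md[md$site == s, ]
    stats::setNames(sub$sample_id, sub$patient_id)
  })
  names(sample_of) <- sites
  has_all <- labeled$patient_id[vapply(labeled$patient_id, function(p)
    all(vapply(sample_of, function(m) p %in% names(m), logical(1))),
    logical(1))]
  excluded <- setdiff(unique(md$patient_id), has_all)
  if (length(has_all) < 2L)
    stop("fewer than 2 eligible patients for sites ",
         paste(sites, collapse = "+"))
  v <- unclass_matrix(table)
  blocks <- lapply(sites, function(s) {
    m <- t(v[, sample_of[[s]][has_all], drop = FALSE])
    rownames(m) <- has_all
    if (mode == "community") {
      colnames(m) <- paste(s, colnames(m), sep = "|")
      m
    } else {
      pm <- (m[, exchanged_otus, drop = FALSE] > 0) * 1L
      colnames(pm) <- paste(s, exchanged_otus, sep = "|")
      pm
    }
  })
  x <- switch(mode,
    community = do.call(cbind, blocks),
    exchanged_presence = {
      m <- blocks[[1L]]
      colnames(m) <- exchanged_otus
      m
    },
    exchanged_concordance = {
      m <- (blocks[[1L]] == blocks[[2L]]) * 1L
      colnames(m) <- exchanged_otus
      m
    })
  y <- factor(labeled$aspiration_status[match(has_all, labeled$patient_id)],
              levels = c("non_aspirator", "aspirator"))
  list(x = x, y = y, unit_ids = has_all, excluded = excluded)
}

#' Leave-one-out random-forest aspiration classifier
#'
#' For each unit, trains a forest on all other units and predicts the
#' left-out unit's aspiration probability; the pooled leave-one-out
#' predictions give the ROC AUC and a Fisher exact p-value on the 2x2
#' confusion matrix of hard calls at probability 0.5.
#'
#' @param features a feature set from [build_features()].
#' @param n_trees trees per forest.
#' @param seed integer seed.
#' @return A classifier report (see [site_classifier_cv()]); positive class
#'   `"aspirator"`.
#' @export
aspiration_classifier_loo <- function(features, n_trees = 1000, seed = NULL) {
  x <- features$x
  y <- features$y
  if (nlevels(droplevels(y)) < 2L || min(table(y)) < 2L)
    stop("need at least 2 units in each aspiration class")
  n <- nrow(x)
  run <- function() {
    prob <- numeric(n)
    for (i in seq_len(n)) {
      fit <- randomForest::randomForest(x[-i, , drop = FALSE], y[-i],
                                        ntree = n_trees)
      prob[i] <- stats::predict(fit, x[i, , drop = FALSE],
                                type = "prob")[, "aspirator"]
    }
    prob
  }
  prob <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  preds <- data.frame(unit = features$unit_ids, truth = as.character(y),
                      probability = prob, fold = seq_len(n),
                      stringsAsFactors = FALSE)
  classifier_report(preds, positive = "aspirator")
}
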