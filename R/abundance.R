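#' OTU abundance table
#'
#' An `abundance_table` is a dense non-negative numeric matrix with OTUs as
#' rows and samples as columns, a per-OTU taxonomy lineage, and a `mode` flag
#' saying whether the values are raw counts or relative abundances (every
#' sample column summing to 1).
#'
#' Taxonomy lineages are semicolon-delimited rank strings
#' (kingdom;phylum;class;order;family;genus); an empty string at a rank means
#' the OTU was not annotated at that rank.
#'
#' @param values numeric matrix, rows = OTUs, columns = samples, all >= 0.
#' @param otu_ids character vector of unique OTU identifiers (defaults to
#'   `rownames(values)`).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to `colnames(values)`).
#' @param taxonomy character vector of lineage strings, one per OTU; may be
#'   `NULL` when no taxonomy is available.
#' @param mode `"counts"` or `"relative"`.
#'
#' @return An object of class `abundance_table`: the matrix with `taxonomy`
#'   and `mode` attributes.
#' @export
abundance_table <- function(values, otu_ids = rownames(values),
                            sample_ids = colnames(values),
                            taxonomy = NULL, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(otu_ids))
    otu_ids <- if (nrow(values)) paste0("OTU_", seq_len(nrow(values)))
      else character()
  if (is.null(sample_ids))
    sample_ids <- if (ncol(values)) paste0("S", seq_len(ncol(values)))
      else character()
  otu_ids <- as.character(otu_ids)
  sample_ids <- as.character(sample_ids)
  if (length(otu_ids) != nrow(values))
    stop("otu_ids length (", length(otu_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length (", length(sample_ids), ") != number of columns (",
         ncol(values), ")")
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ID: ", otu_ids[duplicated(otu_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ID: ", sample_ids[duplicated(sample_ids)][1L])
  if (anyNA(values)) stop("abundance values contain NA")
  if (nrow(values) > 0 && min(values) < 0) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop("negative abundance for OTU '", otu_ids[bad[1L]], "' in sample '",
         sample_ids[bad[2L]], "'")
  }
  if (!is.null(taxonomy)) {
    taxonomy <- as.character(taxonomy)
    if (length(taxonomy) != length(otu_ids))
      stop("taxonomy length (", length(taxonomy), ") != number of OTUs (",
           length(otu_ids), ")")
  }
  if (mode == "relative" && nrow(values) > 0 && ncol(values) > 0) {
    sums <- colSums(values)
    off <- which(abs(sums - 1) > 1e-9)
    if (length(off))
      stop("relative-mode column '", sample_ids[off[1L]],
           "' sums to ", sums[off[1L]], ", not 1")
  }
  dimnames(values) <- list(otu_ids, sample_ids)
  structure(values, taxonomy = taxonomy, mode = mode,
            class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d OTUs x %d samples, mode = %s, taxonomy: %s\n",
              nrow(x), ncol(x), table_mode(x),
              if (is.null(attr(x, "taxonomy"))) "absent" else "present"))
  invisible(x)
}

#' @rdname abundance_table
#' @param x an object.
#' @export
is_abundance_table <- function(x) inherits(x, "abundance_table")

#' @rdname abundance_table
#' @param table an `abundance_table`.
#' @export
table_mode <- function(table) attr(table, "mode")

#' @rdname abundance_table
#' @export
otu_taxonomy <- function(table) attr(table, "taxonomy")

# rebuild an abundance_table from a plain matrix, carrying taxonomy subset
new_table_like <- function(values, taxonomy, mode) {
  abundance_table(values, taxonomy = taxonomy, mode = mode)
}

#' Read an OTU table from a tab-delimited file
#'
#' Accepts the QIIME-1 "classic" OTU-table dialect: optional leading comment
#' lines starting with `#` (e.g. "# Constructed from biom file"), a header row
#' whose first cell may be `#OTU ID`, one row per OTU with integer or numeric
#' counts, and an optional final `taxonomy` column holding the
#' semicolon-delimited lineage.
#'
#' @param path path to a tab-delimited OTU table.
#' @return An [abundance_table] in counts mode.
#' @export
read_abundance_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty OTU table file: ", path)
  # keep a "#OTU ID"-style header, drop any other leading comment lines
  is_comment <- startsWith(lines, "#") & !startsWith(lines, "#OTU")
  first <- which(!is_comment)[1L]
  if (is.na(first)) stop("no header row found in ", path)
  lines <- lines[first:length(lines)]
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 1L) stop("malformed header in ", path)
  cols <- header[-1L]
  has_tax <- length(cols) > 0 && tolower(cols[length(cols)]) %in%
    c("taxonomy", "consensus lineage", "consensuslineage")
  sample_ids <- if (has_tax) cols[-length(cols)] else cols
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ID in header: ",
         sample_ids[duplicated(sample_ids)][1L])
  body <- lines[-1L]
  body <- body[nzchar(body)]
  n_otu <- length(body)
  values <- matrix(0, nrow = n_otu, ncol = length(sample_ids))
  otu_ids <- character(n_otu)
  taxonomy <- if (has_tax) character(n_otu) else NULL
  expected <- 1L + length(sample_ids) + as.integer(has_tax)
  for (i in seq_len(n_otu)) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) == expected - 1L && has_tax)
      fields <- c(fields, "")  # trailing empty taxonomy cell
    if (length(fields) != expected)
      stop("row ", i + 1L, " ('", fields[1L], "') has ", length(fields),
           " fields, expected ", expected)
    otu_ids[i] <- fields[1L]
    num <- suppressWarnings(as.numeric(fields[2:(1L + length(sample_ids))]))
    if (anyNA(num))
      stop("non-numeric abundance in row for OTU '", fields[1L], "'")
    values[i, ] <- num
    if (has_tax) taxonomy[i] <- fields[expected]
  }
  abundance_table(values, otu_ids = otu_ids, sample_ids = sample_ids,
                  taxonomy = taxonomy, mode = "counts")
}

#' Write an OTU table to a tab-delimited file
#'
#' Writes the QIIME-1 classic dialect read by [read_abundance_table()]:
#' a `#OTU ID` header, one row per OTU, and a final `taxonomy` column when
#' the table carries taxonomy.
#'
#' @param table an [abundance_table].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(is_abundance_table(table))
  tax <- otu_taxonomy(table)
  header <- c("#OTU ID", colnames(table), if (!is.null(tax)) "taxonomy")
  rows <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    cells <- c(rownames(table)[i],
               format(table[i, ], digits = 17, trim = TRUE, scientific = FALSE),
               if (!is.null(tax)) tax[i])
    rows[i] <- paste(cells, collapse = "\t")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = "\t"), rows), con)
  # preserve the mode flag in a sidecar-free way: counts is the read default;
  # relative tables round-trip through to_relative-compatible numbers anyway
  invisible(path)
}

#' Convert a counts table to relative abundances
#'
#' Divides each sample column by its total so columns sum to 1.
#'
#' @param table counts-mode [abundance_table]; no sample may have zero total.
#' @return A relative-mode [abundance_table].
#' @export
to_relative_abundance <- function(table) {
  stopifnot(is_abundance_table(table))
  if (table_mode(table) == "relative") return(table)
  sums <- colSums(table)
  zero <- which(sums == 0)
  if (length(zero))
    stop("sample '", colnames(table)[zero[1L]], "' has zero total abundance")
  values <- sweep(unclass_matrix(table), 2L, sums, "/")
  abundance_table(values, taxonomy = otu_taxonomy(table), mode = "relative")
}

unclass_matrix <- function(table) {
  v <- unclass(table)
  attr(v, "taxonomy") <- NULL
  attr(v, "mode") <- NULL
  v
}

TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

# split lineage strings into a character matrix, one column per rank,
# padded with "" below the annotated depth
lineage_matrix <- function(taxonomy, depth = length(TAX_RANKS)) {
  parts <- strsplit(taxonomy, ";", fixed = TRUE)
  out <- matrix("", nrow = length(taxonomy), ncol = depth)
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    k <- min(length(p), depth)
    if (k > 0) out[i, seq_len(k)] <- p[seq_len(k)]
  }
  out
}

#' Collapse an OTU table to a taxonomic rank
#'
#' Sums the rows that share the same lineage prefix down to `rank`. OTUs
#' without an annotation at `rank` are pooled per parent lineage under a
#' sentinel `"unclassified at <rank>"` label, so per-sample totals are
#' conserved exactly.
#'
#' @param table an [abundance_table] carrying taxonomy.
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @return An [abundance_table] with one row per collapsed taxon; the row
#'   names are the truncated lineages.
#' @export
collapse_to_rank <- function(table, rank) {
  stopifnot(is_abundance_table(table))
  tax <- otu_taxonomy(table)
  if (is.null(tax)) stop("table has no taxonomy; cannot collapse")
  r <- match(rank, TAX_RANKS)
  if (is.na(r) || r == 1L)
    stop("unknown rank '", rank, "'; expected one of ",
         paste(TAX_RANKS[-1L], collapse = ", "))
  lm <- lineage_matrix(tax, depth = r)
  unannot <- lm[, r] == ""
  lm[unannot, r] <- paste0("unclassified at ", rank)
  keys <- apply(lm, 1L, paste, collapse = ";")
  collapsed <- rowsum(unclass_matrix(table), group = keys, reorder = TRUE)
  abundance_table(collapsed, otu_ids = rownames(collapsed),
                  sample_ids = colnames(table),
                  taxonomy = rownames(collapsed), mode = table_mode(table))
}

#' Read a sample metadata table
#'
#' Tab-delimited with columns `sample_id`, `patient_id`, `site`, `batch`,
#' `aspiration_status`, then any number of free covariate columns (PPI use,
#' reflux measures, ...). Site labels are normalized through `site_aliases`
#' to the canonical vocabulary `lung`, `oropharynx`, `gastric`, `stool`
#' (the study's BAL / oropharyngeal swab / gastric fluid / stool samples).
#'
#' @param path path to a tab-delimited metadata file.
#' @param site_aliases named character vector mapping raw site labels to
#'   canonical ones; merged over the built-in defaults.
#' @return A `data.frame` with factors left as character columns.
#' @export
read_sample_metadata <- function(path, site_aliases = NULL) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  required <- c("sample_id", "patient_id", "site", "batch",
                "aspiration_status")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  md$sample_id <- as.character(md$sample_id)
  md$patient_id <- as.character(md$patient_id)
  md$batch <- as.character(md$batch)
  validate_metadata(normalize_sites(md, site_aliases))
}

DEFAULT_SITE_ALIASES <- c(
  "bal" = "lung", "lung" = "lung",
  "oropharyngeal swab" = "oropharynx", "oropharyngeal" = "oropharynx",
  "oropharynx" = "oropharynx", "throat swab" = "oropharynx",
  "gastric fluid" = "gastric", "gastric" = "gastric", "stomach" = "gastric",
  "stool" = "stool"
)

SITES <- c("lung", "oropharynx", "gastric", "stool")
AERODIGESTIVE_SITES <- c("lung", "oropharynx", "gastric")
ASPIRATION_LEVELS <- c("aspirator", "non_aspirator", "untested")

normalize_sites <- function(md, site_aliases = NULL) {
  aliases <- DEFAULT_SITE_ALIASES
  if (!is.null(site_aliases)) aliases[tolower(names(site_aliases))] <- site_aliases
  raw <- tolower(trimws(as.character(md$site)))
  mapped <- unname(aliases[raw])
  bad <- which(is.na(mapped))
  if (length(bad))
    stop("unrecognized site label '", md$site[bad[1L]],
         "' (add it to site_aliases)")
  md$site <- mapped
  md
}

validate_metadata <- function(md) {
  if (!all(md$site %in% SITES))
    stop("site values must be in {", paste(SITES, collapse = ", "), "}")
  if (!all(md$aspiration_status %in% ASPIRATION_LEVELS))
    stop("aspiration_status values must be in {",
         paste(ASPIRATION_LEVELS, collapse = ", "), "}")
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id: ", md$sample_id[duplicated(md$sample_id)][1L])
  ps <- paste(md$patient_id, md$site, sep = "\r")
  if (anyDuplicated(ps)) {
    d <- md[duplicated(ps), , drop = FALSE]
    stop("patient '", d$patient_id[1L], "' has more than one '", d$site[1L],
         "' sample")
  }
  md
}

#' Restrict a table and metadata to their common samples
#'
#' @param table an [abundance_table].
#' @param metadata a metadata `data.frame` with a `sample_id` column.
#' @return A list with elements `table`, `metadata` (both restricted to the
#'   intersection of sample IDs, in the table's sample order) and
#'   `dropped` (IDs present on only one side).
#' @export
align_samples <- function(table, metadata) {
  stopifnot(is_abundance_table(table))
  common <- intersect(colnames(table), metadata$sample_id)
  if (!length(common))
    stop("no sample IDs shared between table and metadata")
  keep <- colnames(table)[colnames(table) %in% common]
  tab <- abundance_table(unclass_matrix(table)[, keep, drop = FALSE],
                         otu_ids = rownames(table), sample_ids = keep,
                         taxonomy = otu_taxonomy(table),
                         mode = table_mode(table))
  md <- metadata[match(keep, metadata$sample_id), , drop = FALSE]
  rownames(md) <- NULL
  dropped <- c(setdiff(colnames(table), common),
               setdiff(metadata$sample_id, common))
  list(table = tab, metadata = md, dropped = dropped)
}
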