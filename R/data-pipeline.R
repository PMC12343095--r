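# Preprocessing of drug-combination screens: validity and Loewe-score
# filters, synergism labeling, deduplication, and alignment of combination
# records with cell-line gene- and protein-expression matrices.

REQUIRED_COLUMNS <- c("drug_a", "drug_b", "smiles_a", "smiles_b",
                      "cell_line", "loewe")

#' Loewe synergy score from one dose-response point
#'
#' `S_Loewe = y_c - y_1 (x_1 + x_2)`: the observed combination efficacy
#' minus the dose-additive expectation built from drug A's single-agent
#' efficacy. The source formulation also writes the additive term with
#' `y_2`; the two agree only when the single-agent efficacies are equal, so
#' this helper deliberately implements the first (`y_1`) expression.
#'
#' @param yc Combination efficacy.
#' @param y1,y2 Single-agent efficacies of drugs A and B (`y2` accepted for
#'   completeness of the dose-response point; unused by the formula).
#' @param x1,x2 Drug concentrations.
#' @return The Loewe score.
#' @export
loewe_score <- function(yc, y1, x1, x2, y2 = NULL) {
  vals <- c(yc, y1, x1, x2)
  if (any(!is.finite(vals))) stop("value error: non-finite dose-response input")
  yc - y1 * (x1 + x2)
}

#' Label synergism from a Loewe score
#'
#' Positive scores are synergistic (label 1); zero and negative scores are
#' non-synergistic (label 0). Zero is assigned to the negative class so the
#' positive class is strictly synergistic.
#'
#' @param loewe Numeric vector of Loewe scores.
#' @return Integer vector of 0/1 labels.
#' @export
label_synergy <- function(loewe) {
  if (any(!is.finite(loewe))) stop("value error: non-finite Loewe score")
  as.integer(loewe > 0)
}

#' Read a combination table from CSV/TSV
#'
#' @param path File path; tab-separated when the extension is `.tsv`.
#' @return A data.frame with character drug/cell-line columns.
#' @export
read_combination_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "")
}

#' Read an omics matrix (cell lines x features)
#'
#' First column is the cell-line identifier; remaining columns are numeric
#' features. Parquet files are supported when the `arrow` package is
#' installed.
#'
#' @param path CSV/TSV/Parquet path.
#' @return Numeric matrix with cell-line rownames.
#' @export
read_omics_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading Parquet requires the 'arrow' package")
    }
    as.data.frame(arrow::read_parquet(path))
  } else {
    sep <- if (ext == "tsv") "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

is_blank <- function(x) {
  is.na(x) | (is.character(x) & !nzchar(trimws(x)))
}

#' Filter a raw combination table
#'
#' Applies the preprocessing rules in order: (1) rows with blank or
#' non-numeric required fields are invalid; (2) Loewe scores strictly above
#' 50 or strictly below -75 are outliers (the boundary values are retained);
#' (3) duplicate triplets of cell line and unordered drug-name pair keep
#' their first occurrence; (4) optionally, drugs must appear in a supplied
#' allow-list (standing in for database-membership filtering). A synergism
#' `label` column is derived from the surviving scores, and an audit vector
#' records each removal reason.
#'
#' @param records Data.frame with at least the columns
#'   `drug_a, drug_b, smiles_a, smiles_b, cell_line, loewe`.
#' @param allowlist Optional character vector of permitted drug identifiers.
#' @return List with `records` (filtered, labeled, row-renumbered) and
#'   `audit` (named counts: `input_rows`, `invalid_entry`,
#'   `score_out_of_range`, `not_in_allowlist`, `duplicate_triplet`,
#'   `output_rows`).
#' @export
filter_records <- function(records, allowlist = NULL) {
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  audit <- c(input_rows = nrow(records), invalid_entry = 0L,
             score_out_of_range = 0L, not_in_allowlist = 0L,
             duplicate_triplet = 0L, output_rows = 0L)

  loewe_num <- suppressWarnings(as.numeric(records$loewe))
  key_cols <- c("drug_a", "drug_b", "smiles_a", "smiles_b", "cell_line")
  blank <- Reduce(`|`, lapply(records[key_cols], is_blank)) |
    !is.finite(loewe_num)
  audit["invalid_entry"] <- sum(blank)
  records <- records[!blank, , drop = FALSE]
  records$loewe <- loewe_num[!blank]

  out_of_range <- records$loewe > 50 | records$loewe < -75
  audit["score_out_of_range"] <- sum(out_of_range)
  records <- records[!out_of_range, , drop = FALSE]

  if (!is.null(allowlist)) {
    banned <- !(records$drug_a %in% allowlist & records$drug_b %in% allowlist)
    audit["not_in_allowlist"] <- sum(banned)
    records <- records[!banned, , drop = FALSE]
  }

  pair_lo <- pmin(records$drug_a, records$drug_b)
  pair_hi <- pmax(records$drug_a, records$drug_b)
  key <- paste(records$cell_line, pair_lo, pair_hi, sep = "\r")
  dup <- duplicated(key)
  audit["duplicate_triplet"] <- sum(dup)
  records <- records[!dup, , drop = FALSE]

  records$label <- label_synergy(records$loewe)
  rownames(records) <- NULL
  audit["output_rows"] <- nrow(records)
  list(records = records, audit = audit)
}

#' Align combination records with omics matrices
#'
#' Restricts the dataset to cell lines present in **both** the
#' gene-expression and protein-expression matrices (the overlap
#' requirement), and packages records plus matrices into a dataset bundle.
#'
#' @param records Filtered combination records (see [filter_records()]).
#' @param gene_matrix,protein_matrix Numeric matrices with cell-line
#'   rownames (see [read_omics_matrix()]).
#' @param audit Optional audit vector to extend.
#' @return A `dataset_bundle`: list with `records`, `gene_matrix`,
#'   `protein_matrix`, `graphs`, `fingerprints`, `audit`.
#' @export
align_omics <- function(records, gene_matrix, protein_matrix, audit = NULL) {
  lines_common <- intersect(rownames(gene_matrix), rownames(protein_matrix))
  if (length(lines_common) == 0L) {
    stop("empty dataset: no cell line occurs in both omics matrices")
  }
  keep <- records$cell_line %in% lines_common
  if (!any(keep)) {
    stop("empty dataset: no record's cell line has both omics profiles")
  }
  dropped <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  rownames(records) <- NULL
  audit <- c(audit, no_omics_overlap = dropped)

  used <- intersect(lines_common, unique(records$cell_line))
  structure(list(
    records = records,
    gene_matrix = gene_matrix[used, , drop = FALSE],
    protein_matrix = protein_matrix[used, , drop = FALSE],
    graphs = NULL,
    fingerprints = NULL,
    scaler = NULL,
    audit = audit
  ), class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("<dataset_bundle>", nrow(x$records), "records,",
      length(unique(c(x$records$drug_a, x$records$drug_b))), "drugs,",
      nrow(x$gene_matrix), "cell lines;",
      if (is.null(x$graphs)) "not featurized" else "featurized", "\n")
  invisible(x)
}

#' Featurize every drug in a bundle
#'
#' Computes the molecular graph and (optionally) fingerprint of each unique
#' drug, keyed by drug identifier.
#'
#' @param bundle A `dataset_bundle`.
#' @param fp_bits,fp_radius Fingerprint settings.
#' @param fingerprints Compute fingerprints as well as graphs (default
#'   `TRUE`).
#' @return The bundle with `graphs` and `fingerprints` attached.
#' @export
featurize_bundle <- function(bundle, fp_bits = 2048L, fp_radius = 3L,
                             fingerprints = TRUE) {
  recs <- bundle$records
  ids <- unique(c(recs$drug_a, recs$drug_b))
  smiles <- c(recs$smiles_a, recs$smiles_b)[match(ids,
                                                  c(recs$drug_a, recs$drug_b))]
  bundle$graphs <- stats::setNames(
    lapply(seq_along(ids), function(i) smiles_to_graph(smiles[i], ids[i])),
    ids)
  if (fingerprints) {
    bundle$fingerprints <- stats::setNames(
      lapply(seq_along(ids), function(i) {
        smiles_to_fingerprint(smiles[i], d = fp_bits, radius = fp_radius,
                              drug_id = ids[i])
      }), ids)
  }
  bundle
}

#' Standardize omics matrices against a training set
#'
#' Per-feature z-scoring with mean and standard deviation computed on the
#' training cell lines only; the same transform is applied to every other
#' line. Missing entries are imputed to the training mean (hence zero after
#' scaling) and constant features map to zero.
#'
#' @param bundle A `dataset_bundle`.
#' @param training_line_ids Cell-line identifiers belonging to the training
#'   split.
#' @return The bundle with scaled matrices and the `scaler` (means and sds)
#'   stored.
#' @export
standardize_omics <- function(bundle, training_line_ids) {
  training_line_ids <- intersect(training_line_ids,
                                 rownames(bundle$gene_matrix))
  if (length(training_line_ids) == 0L) {
    stop("standardize_omics: no training cell lines present in the bundle")
  }
  scale_one <- function(m) {
    tr <- m[training_line_ids, , drop = FALSE]
    mu <- colMeans(tr, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    sdv <- apply(tr, 2L, stats::sd, na.rm = TRUE)
    sdv[!is.finite(sdv) | sdv == 0] <- 0
    for (j in seq_len(ncol(m))) {
      mj <- m[, j]
      mj[!is.finite(mj)] <- mu[j]
      m[, j] <- if (sdv[j] > 0) (mj - mu[j]) / sdv[j] else 0
    }
    list(m = m, mean = mu, sd = sdv)
  }
  g <- scale_one(bundle$gene_matrix)
  p <- scale_one(bundle$protein_matrix)
  bundle$gene_matrix <- g$m
  bundle$protein_matrix <- p$m
  bundle$scaler <- list(gene_mean = g$mean, gene_sd = g$sd,
                        protein_mean = p$mean, protein_sd = p$sd,
                        training_lines = training_line_ids)
  bundle
}
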