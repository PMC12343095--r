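# Seeded synthetic datasets with the statistical structure the model
# assumes: valid drug-like molecules with a planted synergy substructure
# (a chlorinated aromatic ring), cluster-structured omics profiles with an
# elevated protein "responder signature" in a known cell-line subset, and
# Loewe-like scores from an additive planted model plus Gaussian noise,
# clipped to the retained score interval [-75, 50].

# Scaffold templates; "%s" receives a substituent. The planted set carries
# a chlorophenyl fragment, the benign set never contains chlorine.
.templates_planted <- c(
  "Clc1ccc(%s)cc1", "Clc1ccc(O%s)cc1", "Clc1ccc(N%s)cc1",
  "Clc1ccc(C(=O)N%s)cc1", "Clc1ccc(S%s)cc1", "Clc1ccc(C(=O)O%s)cc1"
)
.templates_benign <- c(
  "CC(=O)Nc1ccc(%s)cc1", "O=C(O)c1ccc(%s)cc1", "N#Cc1ccc(%s)cc1",
  "OCc1ccc(%s)cc1", "O=S(=O)(N)c1ccc(%s)cc1", "CN1CCN(%s)CC1",
  "O=C(N1CCOCC1)%s", "Cc1ccc(O%s)cc1"
)
# Substituents avoid ring-bond number 1/2 (may still be open in the
# template) and chlorine.
.substituents <- c(
  "C", "CC", "CCC", "CCCC", "C(C)C", "CC(C)C", "CCO", "CO", "CCN",
  "COC", "CCOC", "C3CCCCC3", "C3CCOCC3", "CC(C)O"
)

#' Synthetic-fixture configuration
#'
#' Defines the generating process: dataset sizes, cluster structure, the
#' planted effect sizes and the observation noise. The defaults describe
#' the package's standard study fixture: 2,000 combinations over 40 drugs
#' (half carrying the planted substructure) and 12 cell lines (half of them
#' protein-signature responders), 200 genes and 400 proteins in 4 clusters,
#' with the protein effect dominant: a 100-protein responder signature
#' elevated by 3 in half the lines (`beta_prot = 10`), a substructure
#' effect `beta_sub = 10`, a weak gene term (`beta_gene = 5`) and noise
#' sd 4.
#'
#' @param n_drugs,n_cell_lines,n_combinations Dataset sizes.
#' @param n_genes,n_proteins Omics feature counts.
#' @param n_clusters Cell-line clusters in the omics profiles.
#' @param planted_fraction Fraction of drugs carrying the synergy
#'   substructure.
#' @param responder_fraction Fraction of cell lines with the elevated
#'   protein signature.
#' @param responder_delta Elevation added to signature proteins in
#'   responder lines.
#' @param signature_size,gene_signature_size Feature counts of the protein
#'   responder signature and the gene term.
#' @param cluster_sd,within_sd Between-cluster and within-cluster standard
#'   deviations of protein values. The within-cluster protein variation
#'   makes proteomic profiles line-specific.
#' @param gene_cluster_sd,gene_within_sd The same for gene expression. The
#'   default `gene_within_sd = 0` makes transcriptomes cluster-degenerate
#'   (lines within a cluster share an identical gene profile), so only the
#'   proteome carries line-specific state -- the fixture's idealization of
#'   functional proteomic information beyond transcriptomics.
#' @param beta_sub Synergy added when both drugs carry the substructure.
#' @param beta_prot Weight of the mean responder-signature protein level.
#' @param beta_gene Weight of the mean gene-signature level.
#' @param noise_sd Gaussian observation noise on the score.
#' @param seed Master seed; all generators derive from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_drugs = 40L, n_cell_lines = 12L,
                         n_combinations = 2000L, n_genes = 200L,
                         n_proteins = 400L, n_clusters = 4L,
                         planted_fraction = 0.5, responder_fraction = 0.5,
                         responder_delta = 3, signature_size = 100L,
                         gene_signature_size = 20L, cluster_sd = 0.25,
                         within_sd = 1, gene_cluster_sd = 1,
                         gene_within_sd = 0, beta_sub = 10, beta_prot = 10,
                         beta_gene = 5, noise_sd = 4, seed = 1L) {
  stopifnot(n_drugs >= 2L, n_cell_lines >= 1L, n_combinations >= 1L,
            n_genes >= 1L, n_proteins >= 1L, n_clusters <= n_cell_lines,
            noise_sd >= 0)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate synthetic drug molecules
#'
#' Draws valid drug-like SMILES by decorating scaffold templates with
#' substituents. A seeded subset of drugs carries the planted synergy
#' substructure (a chlorinated aromatic ring); the remaining drugs contain
#' no chlorine at all, so the two groups are separable in fingerprint
#' space. Every emitted SMILES is checked to parse.
#'
#' @param cfg A [synth_config()] (or `n_drugs`/`seed` via a default
#'   config).
#' @return Data.frame with `drug_id`, `smiles`, `planted`.
#' @export
gen_molecules <- function(cfg = synth_config()) {
  set.seed(cfg$seed + 101L)
  n <- cfg$n_drugs
  n_planted <- round(n * cfg$planted_fraction)
  planted <- seq_len(n) %in% sample.int(n, n_planted)
  seen <- character(0)
  smiles <- character(n)
  for (i in seq_len(n)) {
    repeat {
      tmpl <- sample(if (planted[i]) .templates_planted else
                       .templates_benign, 1L)
      s <- sprintf(tmpl, sample(.substituents, 1L))
      can <- canonicalize_smiles(s)
      if (!(can %in% seen)) {
        seen <- c(seen, can)
        smiles[i] <- s
        break
      }
    }
  }
  out <- data.frame(drug_id = sprintf("D%02d", seq_len(n)), smiles = smiles,
                    planted = planted, stringsAsFactors = FALSE)
  for (i in seq_len(n)) smiles_to_graph(out$smiles[i])  # validity contract
  out
}

#' Generate cluster-structured omics matrices
#'
#' Cell-line profiles are Gaussian around per-cluster means
#' (`cluster_sd` between clusters, `within_sd` within). A seeded protein
#' "responder signature" is elevated by `responder_delta` in a known subset
#' of lines; a gene signature (no elevation) defines the gene term of the
#' planted score model.
#'
#' @param cfg A [synth_config()].
#' @return List with `gene_matrix`, `protein_matrix` (cell lines x
#'   features, named), `clusters`, `responder_lines`,
#'   `signature_proteins`, `signature_genes`.
#' @export
gen_omics <- function(cfg = synth_config()) {
  set.seed(cfg$seed + 202L)
  lines <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
  clusters <- rep(seq_len(cfg$n_clusters), length.out = cfg$n_cell_lines)
  gene_names <- sprintf("G%03d", seq_len(cfg$n_genes))
  prot_names <- sprintf("P%03d", seq_len(cfg$n_proteins))

  draw <- function(p, csd, wsd) {
    centers <- matrix(stats::rnorm(cfg$n_clusters * p, sd = csd),
                      cfg$n_clusters, p)
    centers[clusters, , drop = FALSE] +
      matrix(stats::rnorm(cfg$n_cell_lines * p, sd = wsd),
             cfg$n_cell_lines, p)
  }
  G <- draw(cfg$n_genes, cfg$gene_cluster_sd %||% cfg$cluster_sd,
            cfg$gene_within_sd %||% cfg$within_sd)
  P <- draw(cfg$n_proteins, cfg$cluster_sd, cfg$within_sd)
  dimnames(G) <- list(lines, gene_names)
  dimnames(P) <- list(lines, prot_names)

  # Responders are stratified across clusters; otherwise a chance
  # cluster/responder correlation lets any branch read responder status
  # from global cluster structure instead of the planted signature.
  n_resp <- round(cfg$n_cell_lines * cfg$responder_fraction)
  responders <- character(0)
  for (cl in sample(unique(clusters))) {
    members <- lines[clusters == cl]
    take <- min(length(members),
                max(0L, round(length(members) * cfg$responder_fraction)))
    responders <- c(responders, sample(members, take))
  }
  if (length(responders) > n_resp) {
    responders <- sample(responders, n_resp)
  } else if (length(responders) < n_resp) {
    responders <- c(responders,
                    sample(setdiff(lines, responders),
                           n_resp - length(responders)))
  }
  responders <- sort(responders)
  sig_p <- sort(sample(prot_names, min(cfg$signature_size, cfg$n_proteins)))
  sig_g <- sort(sample(gene_names, min(cfg$gene_signature_size,
                                       cfg$n_genes)))
  P[responders, sig_p] <- P[responders, sig_p] + cfg$responder_delta

  list(gene_matrix = G, protein_matrix = P, clusters = clusters,
       responder_lines = responders, signature_proteins = sig_p,
       signature_genes = sig_g)
}

#' Sample combination-record skeletons
#'
#' Draws unique (cell line, unordered drug pair) triplets uniformly.
#'
#' @param cfg A [synth_config()].
#' @param molecules Output of [gen_molecules()].
#' @param omics Output of [gen_omics()].
#' @return Data.frame of records without scores.
#' @export
gen_records <- function(cfg, molecules, omics) {
  set.seed(cfg$seed + 303L)
  lines <- rownames(omics$gene_matrix)
  capacity <- choose(cfg$n_drugs, 2L) * length(lines)
  if (cfg$n_combinations > capacity) {
    stop("synth error: asked for ", cfg$n_combinations,
         " unique triplets but only ", capacity, " exist")
  }
  seen <- character(0)
  rows <- vector("list", cfg$n_combinations)
  got <- 0L
  while (got < cfg$n_combinations) {
    ab <- sample(molecules$drug_id, 2L)
    cl <- sample(lines, 1L)
    key <- paste(cl, min(ab), max(ab), sep = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    got <- got + 1L
    rows[[got]] <- data.frame(drug_a = ab[1L], drug_b = ab[2L],
                              cell_line = cl, stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, rows)
  recs$smiles_a <- molecules$smiles[match(recs$drug_a, molecules$drug_id)]
  recs$smiles_b <- molecules$smiles[match(recs$drug_b, molecules$drug_id)]
  recs$study <- "SYNTH"
  recs$tissue <- "synthetic"
  recs[c("drug_a", "drug_b", "smiles_a", "smiles_b", "cell_line",
         "study", "tissue")]
}

#' Attach planted Loewe-like scores to records
#'
#' `score = beta_sub * 1[both drugs planted]
#'        + beta_prot * mean(responder-signature protein level)
#'        + beta_gene * mean(gene-signature level)
#'        + Normal(0, noise_sd)`, clipped to `[-75, 50]`.
#' The ground-truth components are stored alongside each record in
#' `truth_*` columns.
#'
#' @param records Record skeletons from [gen_records()].
#' @param molecules,omics Generator outputs the ids resolve against.
#' @param cfg A [synth_config()].
#' @return Records with `loewe`, `label` and `truth_*` columns.
#' @export
gen_synergy <- function(records, molecules, omics, cfg) {
  set.seed(cfg$seed + 404L)
  planted <- stats::setNames(molecules$planted, molecules$drug_id)
  bad <- setdiff(unique(c(records$drug_a, records$drug_b)),
                 molecules$drug_id)
  if (length(bad)) stop("synth error: unknown drug id ", bad[1L])
  both <- planted[records$drug_a] & planted[records$drug_b]
  prot_term <- rowMeans(omics$protein_matrix[records$cell_line,
                                             omics$signature_proteins,
                                             drop = FALSE])
  gene_term <- rowMeans(omics$gene_matrix[records$cell_line,
                                          omics$signature_genes,
                                          drop = FALSE])
  det <- cfg$beta_sub * both + cfg$beta_prot * prot_term +
    cfg$beta_gene * gene_term
  noise <- stats::rnorm(nrow(records), sd = cfg$noise_sd)
  records$loewe <- pmin(pmax(det + noise, -75), 50)
  records$label <- label_synergy(records$loewe)
  records$truth_both_planted <- as.logical(both)
  records$truth_prot_term <- prot_term
  records$truth_gene_term <- gene_term
  records$truth_det <- det
  rownames(records) <- NULL
  records
}

#' Analytic synergism prevalence of the planted model
#'
#' `P(label = 1) = mean over records of Phi(det / noise_sd)` from the stored
#' deterministic score components, ignoring the (rarely binding) clip.
#'
#' @param records Records carrying `truth_det` columns.
#' @param cfg The generating [synth_config()].
#' @return Expected fraction of synergistic labels.
#' @export
analytic_prevalence <- function(records, cfg) {
  det <- records$truth_det
  if (cfg$noise_sd == 0) mean(det > 0) else
    mean(stats::pnorm(det / cfg$noise_sd))
}

#' Generate a complete in-memory dataset
#'
#' Orchestrates [gen_molecules()], [gen_omics()], [gen_records()],
#' [gen_synergy()] and returns the pieces plus a ground-truth manifest.
#'
#' @param cfg A [synth_config()].
#' @return List with `records`, `molecules`, `gene_matrix`,
#'   `protein_matrix`, `manifest`.
#' @export
gen_dataset <- function(cfg = synth_config()) {
  molecules <- gen_molecules(cfg)
  omics <- gen_omics(cfg)
  records <- gen_records(cfg, molecules, omics)
  records <- gen_synergy(records, molecules, omics, cfg)
  manifest <- list(
    seed = cfg$seed,
    n_drugs = cfg$n_drugs, n_cell_lines = cfg$n_cell_lines,
    n_combinations = nrow(records),
    betas = list(sub = cfg$beta_sub, prot = cfg$beta_prot,
                 gene = cfg$beta_gene),
    noise_sd = cfg$noise_sd,
    planted_drugs = molecules$drug_id[molecules$planted],
    responder_lines = omics$responder_lines,
    signature_proteins = omics$signature_proteins,
    signature_genes = omics$signature_genes
  )
  list(records = records, molecules = molecules,
       gene_matrix = omics$gene_matrix,
       protein_matrix = omics$protein_matrix,
       clusters = omics$clusters, manifest = manifest)
}

#' Write a dataset to disk in the pipeline's input formats
#'
#' Emits `combinations.csv`, `genes.csv`, `proteins.csv` and a ground-truth
#' `manifest.json` into `dir`.
#'
#' @param dataset Output of [gen_dataset()].
#' @param dir Output directory (created if missing).
#' @return Named vector of file paths, invisibly.
#' @export
write_fixture <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    combinations = file.path(dir, "combinations.csv"),
    genes = file.path(dir, "genes.csv"),
    proteins = file.path(dir, "proteins.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  utils::write.csv(dataset$records, paths[["combinations"]],
                   row.names = FALSE)
  gm <- data.frame(cell_line = rownames(dataset$gene_matrix),
                   dataset$gene_matrix, check.names = FALSE)
  utils::write.csv(gm, paths[["genes"]], row.names = FALSE)
  pm <- data.frame(cell_line = rownames(dataset$protein_matrix),
                   dataset$protein_matrix, check.names = FALSE)
  utils::write.csv(pm, paths[["proteins"]], row.names = FALSE)
  jsonlite::write_json(dataset$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Build a ready-to-train bundle from a dataset
#'
#' Runs the preprocessing pipeline (filtering, labeling, omics alignment)
#' over an in-memory dataset and optionally featurizes the drugs.
#'
#' @param dataset Output of [gen_dataset()].
#' @param featurize Compute graphs/fingerprints now (default `TRUE`).
#' @param fp_bits,fp_radius Fingerprint settings.
#' @return A `dataset_bundle`.
#' @export
dataset_to_bundle <- function(dataset, featurize = TRUE, fp_bits = 2048L,
                              fp_radius = 3L) {
  fl <- filter_records(dataset$records)
  bundle <- align_omics(fl$records, dataset$gene_matrix,
                        dataset$protein_matrix, audit = fl$audit)
  if (featurize) bundle <- featurize_bundle(bundle, fp_bits, fp_radius)
  bundle
}
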