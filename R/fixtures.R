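#' Configuration for the block-structured synthetic DTI generator
#'
#' The generator emulates the statistical premise of similarity-graph DTI
#' prediction: entities fall into latent blocks, entities in the same block
#' have correlated encodings, and interactions preferentially connect
#' matched protein/drug blocks, so that similar entities share interaction
#' partners.
#'
#' Encodings are drawn as `centroid + noise_sd * sqrt((1-rho)/rho) * eps`
#' with standard-normal centroids and noise, so at the default
#' `noise_sd = 1` the expected within-block correlation equals
#' `within_block_corr` (rho) and `noise_sd = 0` gives perfectly identical
#' same-block rows.
#'
#' @param n_proteins,n_drugs entity counts.
#' @param p_dim,q_dim encoding dimensions for proteins and drugs.
#' @param n_blocks number of latent entity clusters (shared between sides;
#'   protein block b is matched with drug block b). Must not exceed
#'   `min(n_proteins, n_drugs)`.
#' @param within_block_corr target expected Pearson correlation between
#'   same-block encodings, in \[0, 1\].
#' @param interaction_density fraction of the m x n grid that is positive,
#'   in (0, 1).
#' @param block_affinity probability that a positive is placed on a
#'   block-matched (drug, protein) cell rather than uniformly, in \[0, 1\].
#' @param noise_sd nonnegative multiplier on the correlation-calibrated
#'   noise scale (1 keeps the calibration, 0 removes noise entirely).
#' @param seed integer seed governing all draws.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 200L, n_drugs = 200L,
                             p_dim = 32L, q_dim = 32L, n_blocks = 8L,
                             within_block_corr = 0.9,
                             interaction_density = 0.05,
                             block_affinity = 0.9,
                             noise_sd = 1, seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins), n_drugs = as.integer(n_drugs),
              p_dim = as.integer(p_dim), q_dim = as.integer(q_dim),
              n_blocks = as.integer(n_blocks),
              within_block_corr = within_block_corr,
              interaction_density = interaction_density,
              block_affinity = block_affinity,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (cfg$n_blocks > min(cfg$n_proteins, cfg$n_drugs))
    stop("n_blocks must not exceed min(n_proteins, n_drugs)", call. = FALSE)
  if (cfg$within_block_corr < 0 || cfg$within_block_corr > 1)
    stop("within_block_corr must lie in [0, 1]", call. = FALSE)
  if (cfg$interaction_density <= 0 || cfg$interaction_density >= 1)
    stop("interaction_density must lie in (0, 1)", call. = FALSE)
  if (cfg$block_affinity < 0 || cfg$block_affinity > 1)
    stop("block_affinity must lie in [0, 1]", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

# Round-robin block assignment keeps block sizes within one of each other.
assign_blocks <- function(n, n_blocks) rep_len(seq_len(n_blocks), n)

block_encodings <- function(n, dim, blocks, rho, noise_sd, prefix) {
  n_blocks <- max(blocks)
  centroids <- matrix(stats::rnorm(n_blocks * dim), n_blocks, dim)
  scale <- if (rho > 0) noise_sd * sqrt((1 - rho) / rho) else noise_sd
  vals <- centroids[blocks, , drop = FALSE] +
    scale * matrix(stats::rnorm(n * dim), n, dim)
  encoding_matrix(vals, ids = sprintf("%s%03d", prefix, seq_len(n)),
                  source = "synthetic")
}

#' Generate a synthetic encoding/interaction dataset
#'
#' Draws block-structured protein and drug encodings and an interaction set
#' whose positives co-cluster with the encoding blocks: with probability
#' `block_affinity` a positive is placed on a cell whose protein block equals
#' its drug block, otherwise uniformly at random; cells are drawn without
#' replacement until `round(interaction_density * m * n)` positives exist.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return list with elements `proteins` and `drugs` ([encoding_matrix()]s),
#'   `interactions` (an [interaction_set()] of positives),
#'   `protein_blocks` and `drug_blocks` (named integer vectors).
#' @export
generate_synthetic_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  m <- cfg$n_proteins; n <- cfg$n_drugs
  n_pos <- round(cfg$interaction_density * m * n)
  if (n_pos > m * n)
    stop("infeasible interaction_density: more positives than cells",
         call. = FALSE)
  with_seed(cfg$seed, {
    pb <- assign_blocks(m, cfg$n_blocks)
    db <- assign_blocks(n, cfg$n_blocks)
    prot <- block_encodings(m, cfg$p_dim, pb, cfg$within_block_corr,
                            cfg$noise_sd, "P")
    drug <- block_encodings(n, cfg$q_dim, db, cfg$within_block_corr,
                            cfg$noise_sd, "D")
    # linear cell index = (drug-1)*m + protein; matched cells share a block
    matched <- which(outer(pb, db, "==") == TRUE)  # index into m x n grid
    chosen <- integer(0)
    taken <- logical(m * n)
    want_matched <- stats::rbinom(n_pos, 1L, cfg$block_affinity) == 1L
    free_matched <- sample(matched, length(matched))
    fm_ptr <- 1L
    for (i in seq_len(n_pos)) {
      cell <- NA_integer_
      if (want_matched[i]) {
        while (fm_ptr <= length(free_matched) && taken[free_matched[fm_ptr]])
          fm_ptr <- fm_ptr + 1L
        if (fm_ptr <= length(free_matched)) {
          cell <- free_matched[fm_ptr]; fm_ptr <- fm_ptr + 1L
        }
      }
      while (is.na(cell)) {
        cand <- sample.int(m * n, 1L)
        if (!taken[cand]) cell <- cand
      }
      taken[cell] <- TRUE
      chosen[i] <- cell
    }
    pi <- (chosen - 1L) %% m + 1L
    dj <- (chosen - 1L) %/% m + 1L
    pairs <- data.frame(drug_id = rownames(drug)[dj],
                        protein_id = rownames(prot)[pi],
                        label = 1L, stringsAsFactors = FALSE)
    list(proteins = prot, drugs = drug,
         interactions = interaction_set(pairs, drug_ids = rownames(drug),
                                        protein_ids = rownames(prot)),
         protein_blocks = stats::setNames(pb, rownames(prot)),
         drug_blocks = stats::setNames(db, rownames(drug)))
  })
}

# Small pool of valid template molecules; per-block drugs are mutations of
# one template by appending/extending simple alkyl/halide decorations that
# preserve SMILES validity.
drug_templates <- c(
  "CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "CCN(CC)CC",
  "c1ccc2ccccc2c1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "CN1CCCC1c1cccnc1",
  "COc1ccccc1", "CC(=O)Nc1ccc(O)cc1", "Clc1ccccc1", "OCC(O)CO",
  "CCCCCC", "N#Cc1ccccc1", "CC(N)C(=O)O", "c1ccsc1", "c1ccoc1"
)

#' Generate synthetic sequences matching a synthetic dataset
#'
#' Protein sequences are random strings over the 20-letter amino-acid
#' alphabet carrying a block-shared motif; drug SMILES are per-block template
#' molecules from a built-in list of valid structures, mutated by appending
#' validity-preserving alkyl extensions. Entity ids match
#' [generate_synthetic_dataset()] under the same `cfg`.
#'
#' @param cfg a [synthetic_config()].
#' @param protein_length length of the random part of each protein sequence.
#' @param motif_length length of the block-shared motif.
#' @return list with `proteins` (named AA sequences) and `drugs`
#'   (named SMILES strings).
#' @export
generate_synthetic_sequences <- function(cfg = synthetic_config(),
                                         protein_length = 80L,
                                         motif_length = 12L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(derive_seed(cfg$seed, "sequences"), {
    pb <- assign_blocks(cfg$n_proteins, cfg$n_blocks)
    db <- assign_blocks(cfg$n_drugs, cfg$n_blocks)
    motifs <- vapply(seq_len(cfg$n_blocks), function(b)
      paste(sample(aa, motif_length, replace = TRUE), collapse = ""),
      character(1))
    prots <- vapply(seq_len(cfg$n_proteins), function(i) {
      body <- paste(sample(aa, protein_length, replace = TRUE), collapse = "")
      at <- sample.int(protein_length - 1L, 1L)
      paste0(substr(body, 1, at), motifs[pb[i]],
             substr(body, at + 1L, protein_length))
    }, character(1))
    names(prots) <- sprintf("P%03d", seq_len(cfg$n_proteins))
    templates <- rep_len(drug_templates, cfg$n_blocks)
    drugs <- vapply(seq_len(cfg$n_drugs), function(j) {
      # append a variable-length alkyl chain: always yields valid SMILES
      paste0(templates[db[j]],
             paste(rep("C", sample.int(6L, 1L)), collapse = ""))
    }, character(1))
    names(drugs) <- sprintf("D%03d", seq_len(cfg$n_drugs))
    list(proteins = prots, drugs = drugs)
  })
}
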