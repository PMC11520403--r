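#' Top-N most similar neighbors of an entity
#'
#' Excludes the entity itself; ties at the cutoff are broken by ascending
#' entity id, making the result deterministic.
#'
#' @param similarity square symmetric similarity matrix with id dimnames.
#' @param entity_id the query entity.
#' @param N neighbor count, strictly less than the number of entities.
#' @return character vector of N ids ordered by decreasing similarity.
#' @export
top_n_neighbors <- function(similarity, entity_id, N) {
  check_similarity(similarity)
  ids <- rownames(similarity)
  if (!entity_id %in% ids) stop("unknown entity: ", entity_id, call. = FALSE)
  if (N >= length(ids))
    stop("N must be smaller than the number of entities", call. = FALSE)
  others <- setdiff(ids, entity_id)
  s <- similarity[entity_id, others]
  ord <- order(-s, others)  # similarity desc, then id asc
  others[ord][seq_len(N)]
}

#' Neighbor-support statistic for an interaction set
#'
#' For each entity on the chosen side, an interaction (e, c) counts as
#' *supported* if at least `min_support` of e's top-N most similar
#' neighbors also interact positively with counterpart c. Reported per
#' entity as a percentage of its interactions, and averaged over entities
#' with at least one interaction. High mean support indicates that the
#' similarity basis organizes entities so that neighbors share interaction
#' partners — the premise that makes graph attention useful.
#'
#' @param interactions an [interaction_set()].
#' @param similarity similarity matrix over the chosen side's entities.
#' @param N neighbor count (default 5).
#' @param min_support minimum number of neighbors sharing the interaction
#'   (default 3).
#' @param side `"drug"` or `"protein"`.
#' @return an object of class `neighbor_support_report`: data.frame
#'   `per_entity` (entity_id, n_interactions, n_supported, pct_supported),
#'   scalar `mean_pct`, and the parameters.
#' @export
neighbor_support <- function(interactions, similarity, N = 5L,
                             min_support = 3L,
                             side = c("drug", "protein")) {
  side <- match.arg(side)
  stopifnot(inherits(interactions, "interaction_set"))
  if (N < 1 || min_support < 1)
    stop("N and min_support must be positive", call. = FALSE)
  I <- interaction_matrix(interactions)     # proteins x drugs
  M <- if (side == "drug") t(I) else I      # entities x counterparts
  ents <- rownames(M)
  missing <- setdiff(ents, rownames(similarity))
  if (length(missing))
    stop(sprintf("entities absent from similarity matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  per <- lapply(ents, function(e) {
    partners <- which(M[e, ] == 1L)
    n_int <- length(partners)
    if (n_int == 0)
      return(data.frame(entity_id = e, n_interactions = 0L,
                        n_supported = 0L, pct_supported = NA_real_))
    nb <- top_n_neighbors(similarity, e, N)
    nb <- intersect(nb, rownames(M))
    votes <- if (length(nb)) colSums(M[nb, partners, drop = FALSE]) else
      numeric(n_int)
    n_sup <- sum(votes >= min_support)
    data.frame(entity_id = e, n_interactions = n_int,
               n_supported = n_sup,
               pct_supported = 100 * n_sup / n_int)
  })
  per <- do.call(rbind, per)
  structure(list(per_entity = per,
                 mean_pct = mean(per$pct_supported, na.rm = TRUE),
                 N = as.integer(N), min_support = as.integer(min_support),
                 side = side),
            class = "neighbor_support_report")
}

#' @export
print.neighbor_support_report <- function(x, ...) {
  cat(sprintf(
    "<neighbor_support> side %s, N = %d, min_support = %d: mean %.1f%% of interactions supported (%d entities with interactions)\n",
    x$side, x$N, x$min_support, x$mean_pct,
    sum(!is.na(x$per_entity$pct_supported))))
  invisible(x)
}

#' Zero-shot neighborhood-only interaction scoring
#'
#' Scores a (drug, protein) pair with no trained model: the
#' similarity-weighted vote of the drug's top-N neighbors' training
#' interactions with the protein,
#' `score = sum_n sim(d, n) I[n, p] / sum_n sim(d, n)`,
#' optionally averaged with the symmetric protein-side vote. Only training
#' interactions are consulted. If a side's neighbor similarities sum to
#' zero, that side scores 0 (with a warning).
#'
#' @param train_interactions an [interaction_set()] (or pairs data.frame) of
#'   training positives.
#' @param test_pairs data.frame with `drug_id`, `protein_id`.
#' @param drug_similarity,protein_similarity similarity matrices covering
#'   the respective entities; supply one or both (both sides are averaged
#'   when both are given).
#' @param N neighbor count.
#' @return numeric score per test pair, in \[0, 1\].
#' @export
zero_shot_predict <- function(train_interactions, test_pairs,
                              drug_similarity = NULL,
                              protein_similarity = NULL, N = 5L) {
  if (is.null(drug_similarity) && is.null(protein_similarity))
    stop("supply at least one similarity matrix", call. = FALSE)
  pairs <- if (inherits(train_interactions, "interaction_set"))
    train_interactions$pairs else train_interactions
  pos <- pairs[pairs$label == 1L, , drop = FALSE]
  pos_key <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pos)))
    assign(paste(pos$drug_id[i], pos$protein_id[i], sep = "\r"), TRUE,
           envir = pos_key)
  has_pos <- function(d, p) !is.null(pos_key[[paste(d, p, sep = "\r")]])
  warned <- FALSE
  side_score <- function(sim, e, counterpart, counterpart_is_protein) {
    nb <- top_n_neighbors(sim, e, min(N, nrow(sim) - 1L))
    w <- sim[e, nb]
    w <- pmax(w, 0)
    if (sum(w) == 0) {
      if (!warned) {
        warning("all-zero neighbor similarities; scoring 0", call. = FALSE)
        warned <<- TRUE
      }
      return(0)
    }
    votes <- vapply(nb, function(nbid)
      if (counterpart_is_protein) has_pos(nbid, counterpart)
      else has_pos(counterpart, nbid), logical(1))
    sum(w * votes) / sum(w)
  }
  vapply(seq_len(nrow(test_pairs)), function(i) {
    d <- test_pairs$drug_id[i]; p <- test_pairs$protein_id[i]
    s <- c()
    if (!is.null(drug_similarity))
      s <- c(s, side_score(drug_similarity, d, p, TRUE))
    if (!is.null(protein_similarity))
      s <- c(s, side_score(protein_similarity, p, d, FALSE))
    mean(s)
  }, numeric(1))
}

#' Dataset-level mean similarity summary
#'
#' Computes the four scalar similarity summaries of a dataset: mean
#' pairwise similarity of drugs and proteins, measured both on raw
#' sequences (Tanimoto on circular fingerprints; global-alignment identity)
#' and on encodings (Pearson correlation).
#'
#' @param protein_seqs named AA sequences (or NULL to skip).
#' @param drug_smiles named SMILES (or NULL to skip).
#' @param protein_encodings,drug_encodings [encoding_matrix()] objects (or
#'   NULL to skip).
#' @return data.frame with columns `modality`, `basis`, `mean_similarity`.
#' @export
similarity_table <- function(protein_seqs = NULL, drug_smiles = NULL,
                             protein_encodings = NULL,
                             drug_encodings = NULL) {
  rows <- list()
  add <- function(modality, basis, sim)
    rows[[length(rows) + 1L]] <<- data.frame(
      modality = modality, basis = basis,
      mean_similarity = mean_offdiag_similarity(sim))
  if (!is.null(drug_smiles))
    add("drug", "raw_sequence", tanimoto_similarity(drug_smiles))
  if (!is.null(protein_seqs))
    add("protein", "raw_sequence", protein_sequence_identity(protein_seqs))
  if (!is.null(drug_encodings))
    add("drug", "encoding", pearson_similarity(drug_encodings))
  if (!is.null(protein_encodings))
    add("protein", "encoding", pearson_similarity(protein_encodings))
  if (!length(rows)) stop("no inputs supplied", call. = FALSE)
  do.call(rbind, rows)
}
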