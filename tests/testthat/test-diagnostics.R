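test_that("top_n_neighbors ranks by similarity with id tie-break", {
  s <- rand_similarity(2, ids = c("a", "b"))
  expect_equal(top_n_neighbors(s, "a", 1), "b")
  set.seed(5)
  s6 <- rand_similarity(6, ids = sprintf("e%d", 1:6))
  s6["e1", "e4"] <- s6["e4", "e1"] <- 0.9
  expect_equal(top_n_neighbors(s6, "e1", 1), "e4")
  # force a tie at the cutoff: equal similarity resolved by ascending id
  tied <- matrix(0.5, 4, 4, dimnames = list(sprintf("e%d", 1:4),
                                            sprintf("e%d", 1:4)))
  diag(tied) <- 1
  expect_equal(top_n_neighbors(tied, "e3", 2), c("e1", "e2"))
  # oracle: stable sort by (-similarity, id)
  others <- setdiff(rownames(s6), "e2")
  want <- others[order(-s6["e2", others], others)][1:5]
  expect_equal(top_n_neighbors(s6, "e2", 5), want)
  expect_error(top_n_neighbors(s6, "e1", 6), "smaller")
  expect_error(top_n_neighbors(s6, "zz", 2), "unknown")
})

test_that("neighbor_support matches the brute-force triple loop", {
  for (trial in 1:50) {
    set.seed(trial)
    n_d <- sample(6:10, 1); n_p <- sample(4:8, 1)
    M <- matrix(rbinom(n_d * n_p, 1, 0.35), n_d, n_p,
                dimnames = list(sprintf("D%d", 1:n_d), sprintf("P%d", 1:n_p)))
    sim <- rand_similarity(n_d, ids = rownames(M))
    ints <- interaction_set(
      data.frame(drug_id = rownames(M)[row(M)[M == 1]],
                 protein_id = colnames(M)[col(M)[M == 1]],
                 label = 1L),
      drug_ids = rownames(M), protein_ids = colnames(M))
    N <- 3L; ms <- 2L
    rep <- neighbor_support(ints, sim, N = N, min_support = ms, side = "drug")
    expect_equal(rep$mean_pct, ref_neighbor_support(M, sim, N, ms))
  }
})

test_that("neighbor_support extremes and invariances hold", {
  # identical interaction rows: everything supported
  M <- matrix(1L, 5, 3, dimnames = list(paste0("D", 1:5), paste0("P", 1:3)))
  ints <- interaction_set(
    data.frame(drug_id = rownames(M)[row(M)], protein_id = colnames(M)[col(M)],
               label = 1L),
    drug_ids = rownames(M), protein_ids = colnames(M))
  sim <- rand_similarity(5, ids = rownames(M))
  full <- neighbor_support(ints, sim, N = 3, min_support = 3, side = "drug")
  expect_equal(full$mean_pct, 100)
  # disjoint partners: nothing supported
  M2 <- diag(5); dimnames(M2) <- list(paste0("D", 1:5), paste0("P", 1:5))
  ints2 <- interaction_set(
    data.frame(drug_id = paste0("D", 1:5), protein_id = paste0("P", 1:5),
               label = 1L),
    drug_ids = rownames(M2), protein_ids = colnames(M2))
  none <- neighbor_support(ints2, rand_similarity(5, rownames(M2)),
                           N = 3, min_support = 1, side = "drug")
  expect_equal(none$mean_pct, 0)
  # invariant under entity reordering
  set.seed(9)
  perm <- sample(5)
  ints_perm <- interaction_set(ints$pairs[sample(nrow(ints$pairs)), ],
                               drug_ids = rownames(M)[perm],
                               protein_ids = colnames(M))
  again <- neighbor_support(ints_perm, sim, N = 3, min_support = 3,
                            side = "drug")
  expect_equal(sort(again$per_entity$pct_supported),
               sort(full$per_entity$pct_supported))
  expect_error(neighbor_support(ints, rand_similarity(3, c("Dx", "Dy", "Dz")),
                                N = 2, min_support = 1), "absent.*D1")
})

test_that("zero-shot scores are similarity-weighted neighbor votes", {
  # 3 drugs: D1 queries; neighbors D2 (sim .8, interacts with P1) and
  # D3 (sim .2, does not)
  sim <- matrix(c(1, .8, .2, .8, 1, .5, .2, .5, 1), 3, 3,
                dimnames = list(c("D1", "D2", "D3"), c("D1", "D2", "D3")))
  train <- data.frame(drug_id = "D2", protein_id = "P1", label = 1L)
  got <- zero_shot_predict(train, data.frame(drug_id = "D1", protein_id = "P1"),
                           drug_similarity = sim, N = 2)
  expect_equal(got, 0.8 / (0.8 + 0.2))
  # all neighbors interact -> 1; none -> 0
  train_all <- data.frame(drug_id = c("D2", "D3"), protein_id = "P1", label = 1L)
  expect_equal(zero_shot_predict(train_all,
                                 data.frame(drug_id = "D1", protein_id = "P1"),
                                 drug_similarity = sim, N = 2), 1.0)
  expect_equal(zero_shot_predict(train_all,
                                 data.frame(drug_id = "D1", protein_id = "P9"),
                                 drug_similarity = sim, N = 2), 0.0)
  # zero similarities score 0 with a warning
  sim0 <- sim; sim0["D1", c("D2", "D3")] <- 0; sim0[c("D2", "D3"), "D1"] <- 0
  expect_warning(
    z <- zero_shot_predict(train_all,
                           data.frame(drug_id = "D1", protein_id = "P1"),
                           drug_similarity = sim0, N = 2),
    "all-zero")
  expect_equal(z, 0)
})

test_that("zero-shot prediction recovers block structure above the null", {
  ds <- generate_synthetic_dataset(synthetic_config(
    n_proteins = 60, n_drugs = 60, n_blocks = 4, p_dim = 16, q_dim = 16,
    block_affinity = 1, interaction_density = 0.08, seed = 12))
  sp <- make_split(ds$interactions, "warm", seed = 0)
  sim_d <- pearson_similarity(ds$drugs)
  sim_p <- pearson_similarity(ds$proteins)
  scores <- zero_shot_predict(sp$train, sp$test,
                              drug_similarity = sim_d,
                              protein_similarity = sim_p, N = 5)
  auc <- auroc(scores, sp$test$label)
  set.seed(3)
  null_auc <- mean(replicate(20,
    auroc(scores, sample(sp$test$label))))
  expect_gt(auc, null_auc + 0.2)
  expect_gt(auc, 0.7)
})

test_that("similarity_table summarizes all four modality/basis combinations", {
  cfg <- synthetic_config(n_proteins = 8, n_drugs = 8, n_blocks = 2,
                          p_dim = 8, q_dim = 8, interaction_density = 0.1,
                          seed = 3)
  ds <- generate_synthetic_dataset(cfg)
  sq <- generate_synthetic_sequences(cfg)
  tab <- similarity_table(protein_seqs = sq$proteins, drug_smiles = sq$drugs,
                          protein_encodings = ds$proteins,
                          drug_encodings = ds$drugs)
  expect_equal(nrow(tab), 4)
  expect_setequal(paste(tab$modality, tab$basis),
                  c("drug raw_sequence", "protein raw_sequence",
                    "drug encoding", "protein encoding"))
  # encoding means match the brute-force average
  expect_equal(tab$mean_similarity[tab$modality == "protein" &
                                     tab$basis == "encoding"],
               mean_offdiag_similarity(pearson_similarity(ds$proteins)))
  # a dataset of identical drugs has raw and encoding similarity 1
  same <- c(a = "CCO", b = "CCO", c = "CCO")
  tab2 <- similarity_table(drug_smiles = same)
  expect_equal(tab2$mean_similarity, 1)
})
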