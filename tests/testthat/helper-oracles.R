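# Independent reference implementations used as oracles. These deliberately
# use naive elementwise loops, not the package's vectorized paths.

# Pearson correlation of two vectors from the definition.
ref_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# One masked multi-head GAT layer evaluated node by node, pair by pair.
ref_gat_layer <- function(X_in, adj, heads, leaky_slope, act_f) {
  n <- nrow(X_in)
  out <- NULL
  for (head in heads) {
    W <- head$W; a <- head$a
    k <- ncol(W)
    emb <- matrix(0, n, k)
    for (i in seq_len(n)) {
      nbrs <- which(adj[i, ] == 1)
      logits <- numeric(length(nbrs))
      for (u in seq_along(nbrs)) {
        j <- nbrs[u]
        hi <- drop(t(W) %*% X_in[i, ])
        hj <- drop(t(W) %*% X_in[j, ])
        pre <- sum(a * c(hi, hj))
        logits[u] <- if (pre > 0) pre else leaky_slope * pre
      }
      alpha <- exp(logits - max(logits))
      alpha <- alpha / sum(alpha)
      agg <- numeric(k)
      for (u in seq_along(nbrs))
        agg <- agg + alpha[u] * drop(t(W) %*% X_in[nbrs[u], ])
      emb[i, ] <- act_f(agg)
    }
    out <- cbind(out, emb)
  }
  out
}

# AUROC by exhaustive enumeration of positive-negative pairs.
ref_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Average precision by explicit threshold enumeration.
ref_auprc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0; prev_r <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(labels[called] == 1)
    r <- tp / n_pos
    p <- tp / sum(called)
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}

# Neighbor support by brute-force triple loop over entities, interactions
# and neighbors.
ref_neighbor_support <- function(M, sim, N, min_support) {
  # M: entities x counterparts 0/1; sim over entities
  ents <- rownames(M)
  pct <- numeric(0)
  for (e in ents) {
    partners <- colnames(M)[M[e, ] == 1]
    if (length(partners) == 0) next
    others <- setdiff(ents, e)
    s <- sim[e, others]
    nb <- others[order(-s, others)][seq_len(N)]
    n_sup <- 0
    for (c in partners) {
      votes <- 0
      for (b in nb) if (M[b, c] == 1) votes <- votes + 1
      if (votes >= min_support) n_sup <- n_sup + 1
    }
    pct <- c(pct, 100 * n_sup / length(partners))
  }
  mean(pct)
}

# Random symmetric similarity matrix with unit diagonal.
rand_similarity <- function(n, ids = sprintf("e%02d", seq_len(n))) {
  s <- matrix(stats::runif(n * n), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(ids, ids)
  s
}

# Small random model pieces for the GAT oracle tests.
rand_adjacency <- function(n, p_edge = 0.5, force_nonempty = TRUE) {
  a <- matrix(stats::rbinom(n * n, 1, p_edge), n, n)
  a <- ((a + t(a)) > 0) * 1L
  diag(a) <- 1L
  a
}

small_fixture <- function(seed = 3, n_proteins = 60, n_drugs = 60,
                          n_blocks = 4, density = 0.08) {
  generate_synthetic_dataset(synthetic_config(
    n_proteins = n_proteins, n_drugs = n_drugs, p_dim = 16, q_dim = 16,
    n_blocks = n_blocks, interaction_density = density, seed = seed))
}
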