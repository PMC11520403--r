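#' Build a warm or cold-start train/validation/test split
#'
#' Positive pairs are partitioned by the requested mode, then negatives are
#' sampled uniformly without replacement from unobserved (drug, protein)
#' cells at the ratio the balance regime requires.
#'
#' Modes: `"warm"` partitions positive pairs directly (entities may recur
#' across subsets); `"cold_drug"` partitions *drugs* so no drug id is shared
#' between train/validation and test, using shuffled positive-count-weighted
#' greedy assignment so the test share of positive pairs approximates the
#' test fraction; `"cold_protein"` is symmetric.
#'
#' Negative sampling: `"balanced_1_1"` draws one negative per positive in
#' each subset, `"unbalanced_1_10"` draws ten (or every available negative
#' if the pool is smaller, with a warning). In cold modes, a subset's
#' negatives only involve that subset's entities on the cold side (test
#' negatives pair test drugs with any protein under `cold_drug`), so cold
#' entities never leak across subsets through negatives.
#'
#' @param interactions an [interaction_set()] of positive pairs.
#' @param mode `"warm"`, `"cold_drug"` or `"cold_protein"`.
#' @param balance `"balanced_1_1"` or `"unbalanced_1_10"`.
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer; the split is deterministic given the seed.
#' @return an object of class `data_split`: list with data.frames `train`,
#'   `val`, `test` (columns drug_id, protein_id, label) plus the split
#'   metadata.
#' @export
make_split <- function(interactions,
                       mode = c("warm", "cold_drug", "cold_protein"),
                       balance = c("balanced_1_1", "unbalanced_1_10"),
                       fractions = c(0.79, 0.01, 0.20), seed = 0L) {
  mode <- match.arg(mode)
  balance <- match.arg(balance)
  stopifnot(inherits(interactions, "interaction_set"))
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three nonnegative numbers summing to 1",
         call. = FALSE)
  pos <- interactions$pairs[interactions$pairs$label == 1L, , drop = FALSE]
  if (nrow(pos) < 3) stop("too few positive pairs to split", call. = FALSE)
  with_seed(seed, {
    parts <- switch(mode,
      warm = split_warm(pos, fractions),
      cold_drug = split_cold(pos, fractions, "drug_id"),
      cold_protein = split_cold(pos, fractions, "protein_id"))
    ratio <- if (balance == "balanced_1_1") 1L else 10L
    neg <- sample_negatives(parts, interactions, mode, ratio)
    out <- lapply(c(train = "train", val = "val", test = "test"), function(s) {
      df <- rbind(parts[[s]], neg[[s]])
      rownames(df) <- NULL
      df
    })
  })
  structure(c(out, list(mode = mode, balance = balance,
                        fractions = fractions, seed = as.integer(seed),
                        drug_ids = interactions$drug_ids,
                        protein_ids = interactions$protein_ids)),
            class = "data_split")
}

# Deterministic partition arithmetic: floor for train and val, remainder to
# test.
subset_sizes <- function(n, fractions) {
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  c(train = n_train, val = n_val, test = n - n_train - n_val)
}

split_warm <- function(pos, fractions) {
  n <- nrow(pos)
  sz <- subset_sizes(n, fractions)
  ord <- sample.int(n)
  list(train = pos[ord[seq_len(sz["train"])], , drop = FALSE],
       val = pos[ord[sz["train"] + seq_len(sz["val"])], , drop = FALSE],
       test = pos[ord[sz["train"] + sz["val"] + seq_len(sz["test"])], ,
                  drop = FALSE])
}

# Greedy entity partition: walk shuffled entities, filling test then val
# until their positive-pair quotas are met; remaining entities go to train.
split_cold <- function(pos, fractions, col) {
  counts <- table(pos[[col]])
  ents <- sample(names(counts))
  if (length(ents) < 3)
    stop("cold split infeasible: need at least 3 entities with positives",
         call. = FALSE)
  n <- nrow(pos)
  target_test <- fractions[3] * n
  target_val <- fractions[2] * n
  assign <- stats::setNames(rep("train", length(ents)), ents)
  got_test <- 0; got_val <- 0
  for (e in ents) {
    c_e <- as.numeric(counts[[e]])
    if (got_test < target_test) {
      assign[e] <- "test"; got_test <- got_test + c_e
    } else if (got_val < target_val) {
      assign[e] <- "val"; got_val <- got_val + c_e
    }
  }
  if (!any(assign == "train"))
    stop("cold split infeasible: no entities left for training", call. = FALSE)
  lab <- assign[pos[[col]]]
  list(train = pos[lab == "train", , drop = FALSE],
       val = pos[lab == "val", , drop = FALSE],
       test = pos[lab == "test", , drop = FALSE])
}

sample_negatives <- function(parts, interactions, mode, ratio) {
  m <- length(interactions$protein_ids)
  n <- length(interactions$drug_ids)
  pos_all <- interactions$pairs[interactions$pairs$label == 1L, ]
  pos_cells <- paste(pos_all$drug_id, pos_all$protein_id, sep = "\r")
  used <- new.env(parent = emptyenv())
  for (cell in pos_cells) assign(cell, TRUE, envir = used)
  draw <- function(drugs, prots, n_want) {
    total <- length(drugs) * length(prots)
    cand <- sample.int(total, total)  # shuffled cell order; take while free
    d_all <- drugs[(cand - 1L) %% length(drugs) + 1L]
    p_all <- prots[(cand - 1L) %/% length(drugs) + 1L]
    keys <- paste(d_all, p_all, sep = "\r")
    free <- !vapply(keys, function(k) !is.null(used[[k]]), logical(1),
                    USE.NAMES = FALSE)
    sel <- utils::head(which(free), n_want)
    for (k in keys[sel]) assign(k, TRUE, envir = used)
    out_d <- d_all[sel]; out_p <- p_all[sel]
    if (length(out_d) < n_want)
      warning(sprintf(
        "negative pool smaller than requested (%d < %d); using all available",
        length(out_d), n_want), call. = FALSE)
    data.frame(drug_id = out_d, protein_id = out_p,
               label = rep(0L, length(out_d)), stringsAsFactors = FALSE)
  }
  res <- list()
  for (s in c("train", "val", "test")) {
    p_s <- parts[[s]]
    n_want <- ratio * nrow(p_s)
    if (n_want == 0) {
      res[[s]] <- data.frame(drug_id = character(0), protein_id = character(0),
                             label = integer(0))
      next
    }
    drugs <- if (mode == "cold_drug") unique(p_s$drug_id)
             else interactions$drug_ids
    prots <- if (mode == "cold_protein") unique(p_s$protein_id)
             else interactions$protein_ids
    res[[s]] <- draw(drugs, prots, n_want)
  }
  res
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> mode %s, balance %s, seed %d\n",
              x$mode, x$balance, x$seed))
  for (s in c("train", "val", "test"))
    cat(sprintf("  %-5s %5d pairs (%d positive, %d negative)\n", s,
                nrow(x[[s]]), sum(x[[s]]$label == 1), sum(x[[s]]$label == 0)))
  invisible(x)
}

#' Binarize affinity-valued interactions at a density-matched threshold
#'
#' For dissociation-constant style affinities (smaller = stronger binding),
#' chooses the affinity threshold whose induced positive fraction is closest
#' to `target_density`; records with affinity at or below the threshold
#' become positives.
#'
#' @param records data.frame with columns `drug_id`, `protein_id`,
#'   `affinity` (positive reals, e.g. Kd).
#' @param target_density desired positive fraction in (0, 1).
#' @return an [interaction_set()] of the positive pairs, with attributes
#'   `threshold` and `achieved_density`.
#' @export
binarize_affinity <- function(records, target_density) {
  if (target_density <= 0 || target_density >= 1)
    stop("target_density must lie in (0, 1)", call. = FALSE)
  aff <- records$affinity
  if (any(aff <= 0)) stop("affinities must be positive", call. = FALSE)
  vals <- sort(unique(aff))
  if (length(vals) < 2)
    stop("constant affinities: no threshold separates the records",
         call. = FALSE)
  n <- length(aff)
  fracs <- vapply(vals, function(v) mean(aff <= v), numeric(1))
  best <- which.min(abs(fracs - target_density))
  thr <- vals[best]
  lab <- as.integer(aff <= thr)
  out <- interaction_set(data.frame(drug_id = records$drug_id,
                                    protein_id = records$protein_id,
                                    label = lab)[lab == 1L, ],
                         drug_ids = unique(records$drug_id),
                         protein_ids = unique(records$protein_id))
  attr(out, "threshold") <- thr
  attr(out, "achieved_density") <- fracs[best]
  out
}

#' Leak test samples of cold drugs into training
#'
#' For each drug with pairs in the test set, moves `min(n_leak, count - 1)`
#' of its test pairs (chosen at random under `seed`) into the training set,
#' always keeping at least one test pair per drug. The result is no longer
#' drug-exclusive by construction — this quantifies how much warm
#' information a cold-start drug needs.
#'
#' @param split a [make_split()] result with `mode = "cold_drug"`.
#' @param n_leak number of pairs to move per test drug (>= 1).
#' @param seed integer seed for the per-drug choices.
#' @return a new `data_split` with mode `"cold_drug_leaked"` and an
#'   attribute `n_leak`.
#' @export
leak_samples <- function(split, n_leak, seed = 0L) {
  stopifnot(inherits(split, "data_split"))
  if (split$mode != "cold_drug")
    stop("leak_samples requires a cold_drug split", call. = FALSE)
  if (n_leak < 1) stop("n_leak must be >= 1", call. = FALSE)
  test <- split$test
  with_seed(seed, {
    move <- logical(nrow(test))
    for (d in unique(test$drug_id)) {
      idx <- which(test$drug_id == d)
      k <- min(n_leak, length(idx) - 1L)
      if (k > 0) move[sample(idx, k)] <- TRUE
    }
    out <- split
    out$train <- rbind(split$train, test[move, , drop = FALSE])
    rownames(out$train) <- NULL
    out$test <- test[!move, , drop = FALSE]
    rownames(out$test) <- NULL
    out$mode <- "cold_drug_leaked"
    attr(out, "n_leak") <- as.integer(n_leak)
    out
  })
}

#' Read / write data splits
#'
#' TSV with columns `drug_id`, `protein_id`, `label`, `subset`.
#'
#' @param x a `data_split`.
#' @param path file path.
#' @export
write_split <- function(x, path) {
  df <- do.call(rbind, lapply(c("train", "val", "test"), function(s)
    if (nrow(x[[s]])) cbind(x[[s]], subset = s) else NULL))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @return `read_split()`: a `data_split` (metadata fields that are not
#'   recoverable from the file are set to `"external"` / `NA`).
#' @export
read_split <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "integer", "character"))
  out <- lapply(c(train = "train", val = "val", test = "test"), function(s) {
    sub <- df[df$subset == s, c("drug_id", "protein_id", "label")]
    rownames(sub) <- NULL
    sub
  })
  structure(c(out, list(mode = "external", balance = "external",
                        fractions = rep(NA_real_, 3), seed = NA_integer_,
                        drug_ids = unique(df$drug_id),
                        protein_ids = unique(df$protein_id))),
            class = "data_split")
}
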