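#' Neighborhood graphs from similarity matrices
#'
#' A neighborhood graph couples a symmetric similarity matrix with the
#' binary adjacency obtained by thresholding it. The adjacency masks the
#' attention coefficients of the graph-attention model; the raw similarity
#' feeds the diagnostics (top-N neighbors, neighbor support, zero-shot
#' scoring).
#'
#' @param similarity square symmetric numeric matrix with entity ids as
#'   dimnames.
#' @param threshold binarization threshold; similarities `>= threshold`
#'   become edges (ties count as connected, so `threshold = 1` keeps exact
#'   duplicates adjacent). Alternatively see `quantile`.
#' @param self_connections logical; keep the diagonal as self-edges.
#' @param basis provenance tag: `"pearson_encoding"`, `"tanimoto_morgan"`,
#'   `"alignment_identity"` or `"external"`.
#' @param quantile if non-NULL, overrides `threshold` with the given
#'   quantile of the off-diagonal similarity distribution (thresholds are
#'   tuned hyperparameters; quantiles adapt across encoders whose similarity
#'   scales differ).
#' @return an object of class `neighborhood_graph`: list with `ids`,
#'   `similarity`, `adjacency`, `threshold`, `self_connections`, `basis`.
#' @export
neighborhood_graph <- function(similarity, threshold = NULL,
                               self_connections = TRUE,
                               basis = "external", quantile = NULL) {
  check_similarity(similarity)
  if (!is.null(quantile)) {
    off <- similarity[upper.tri(similarity)]
    threshold <- stats::quantile(off, quantile, names = FALSE)
  }
  if (is.null(threshold))
    stop("provide a threshold or a quantile", call. = FALSE)
  adj <- binarize(similarity, threshold, self_connections)
  structure(list(ids = rownames(similarity), similarity = similarity,
                 adjacency = adj, threshold = threshold,
                 self_connections = self_connections, basis = basis),
            class = "neighborhood_graph")
}

#' @export
print.neighborhood_graph <- function(x, ...) {
  n <- length(x$ids)
  n_edges <- (sum(x$adjacency) - sum(diag(x$adjacency))) / 2
  cat(sprintf(
    "<neighborhood_graph> %d nodes, %d undirected edges (basis %s, threshold %.4g, self-connections %s)\n",
    n, n_edges, x$basis, x$threshold, x$self_connections))
  invisible(x)
}

check_similarity <- function(s, tol = 1e-8) {
  if (!is.matrix(s) || nrow(s) != ncol(s))
    stop("similarity must be a square matrix", call. = FALSE)
  if (is.null(rownames(s)))
    stop("similarity needs entity ids as dimnames", call. = FALSE)
  if (max(abs(s - t(s))) > tol)
    stop("similarity matrix is not symmetric", call. = FALSE)
  invisible(s)
}

#' Pearson correlation similarity between encoding rows
#'
#' Entry (i, j) is the Pearson correlation between the encoding vectors of
#' entities i and j; the diagonal is 1.
#'
#' @param mat an [encoding_matrix()] (or matrix with rownames), >= 2 rows,
#'   every row with nonzero variance.
#' @return symmetric similarity matrix with unit diagonal.
#' @export
pearson_similarity <- function(mat) {
  if (nrow(mat) < 2) stop("need at least two entities", call. = FALSE)
  v <- apply(mat, 1, stats::var)
  if (any(v == 0))
    stop(sprintf("zero-variance encoding row(s): %s",
                 paste(rownames(mat)[v == 0], collapse = ", ")), call. = FALSE)
  s <- stats::cor(t(unclass(mat)))
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

#' Threshold a similarity matrix into a binary adjacency
#'
#' Off-diagonal entries with `similarity >= threshold` become 1 (ties count
#' as connected); the diagonal is 1 iff `self_connections`.
#'
#' @param similarity square symmetric matrix.
#' @param threshold any real number.
#' @param self_connections logical.
#' @return binary integer matrix of the same shape.
#' @export
binarize <- function(similarity, threshold, self_connections = TRUE) {
  check_similarity(similarity)
  adj <- (similarity >= threshold) * 1L
  mode(adj) <- "integer"
  diag(adj) <- if (self_connections) 1L else 0L
  adj
}

#' Tanimoto similarity on circular (Morgan-style) fingerprints
#'
#' Fingerprints are Open Babel extended-connectivity fingerprints
#' (`ECFP{2*radius}`) computed through ChemmineOB and folded to `n_bits` by
#' modular OR. Entry (i, j) is the Jaccard coefficient of the two bit sets;
#' the diagonal is 1.
#'
#' @param smiles named character vector of SMILES strings; every string must
#'   parse.
#' @param radius circular neighborhood radius (2 is the community default).
#' @param n_bits folded fingerprint width.
#' @return symmetric similarity matrix.
#' @export
tanimoto_similarity <- function(smiles, radius = 2L, n_bits = 2048L) {
  fps <- morgan_fingerprints(smiles, radius, n_bits)
  n <- nrow(fps)
  s <- matrix(1, n, n, dimnames = list(rownames(fps), rownames(fps)))
  counts <- rowSums(fps)
  inter <- fps %*% t(fps)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    un <- counts[i] + counts[j] - inter[i, j]
    s[i, j] <- if (un == 0) 0 else inter[i, j] / un
  }
  s
}

#' @rdname tanimoto_similarity
#' @return `morgan_fingerprints()`: binary matrix, one row per molecule.
#' @export
morgan_fingerprints <- function(smiles, radius = 2L, n_bits = 2048L) {
  if (is.null(names(smiles))) names(smiles) <- seq_along(smiles)
  fptype <- paste0("ECFP", 2L * as.integer(radius))
  rows <- lapply(seq_along(smiles), function(i) {
    fp <- tryCatch({
      mol <- ChemmineOB::forEachMol("SMILES", smiles[[i]], identity)
      ChemmineOB::fingerprint_OB(mol, fptype)
    }, error = function(e)
      stop(sprintf("unparseable SMILES for '%s': %s",
                   names(smiles)[i], smiles[[i]]), call. = FALSE))
    fp <- as.numeric(fp)
    folded <- tapply(fp, (seq_along(fp) - 1L) %% n_bits, max)
    as.integer(folded > 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(smiles)
  out
}

#' Pairwise global-alignment identity between protein sequences
#'
#' Entry (i, j) is matches / alignment-length from a Needleman-Wunsch global
#' alignment with fixed scoring (match 1, mismatch 0, gap opening -8, gap
#' extension -2); values lie in \[0, 1\] with 1 for identical sequences. An
#' externally computed similarity matrix (e.g. from an MSA tool) can be used
#' instead via [neighborhood_graph()] with `basis = "external"`.
#'
#' @param seqs named character vector of nonempty amino-acid sequences.
#' @return symmetric similarity matrix.
#' @export
protein_sequence_identity <- function(seqs) {
  if (any(!nzchar(seqs)))
    stop(sprintf("empty sequence for: %s",
                 paste(names(seqs)[!nzchar(seqs)], collapse = ", ")),
         call. = FALSE)
  n <- length(seqs)
  ids <- names(seqs) %||% as.character(seq_len(n))
  s <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n < 2) return(s)
  mat <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(mat) <- 1
  for (i in seq_len(n - 1)) {
    al <- Biostrings::pairwiseAlignment(
      rep(seqs[i], n - i), seqs[(i + 1):n], type = "global",
      substitutionMatrix = mat, gapOpening = 8, gapExtension = 2)
    ident <- Biostrings::nmatch(al) / Biostrings::nchar(al)
    s[i, (i + 1):n] <- ident
    s[(i + 1):n, i] <- ident
  }
  s
}

#' Mean off-diagonal similarity
#'
#' Arithmetic mean over unordered off-diagonal pairs of a symmetric
#' similarity matrix — the scalar summary used for dataset-level similarity
#' tables.
#'
#' @param similarity square symmetric matrix, n >= 2.
#' @return scalar mean.
#' @export
mean_offdiag_similarity <- function(similarity) {
  check_similarity(similarity)
  if (nrow(similarity) < 2) stop("need n >= 2 entities", call. = FALSE)
  mean(similarity[upper.tri(similarity)])
}

#' Read / write id-indexed square matrices (similarity or adjacency)
#'
#' TSV with an `id` header column and one column per entity.
#'
#' @param path file path.
#' @return `read_matrix_tsv()`: numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_matrix_tsv
#' @param m matrix with dimnames.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Adjacency actually used by the GAT: isolated rows (possible when
# self_connections = FALSE and the threshold is strict) get a forced
# self-edge, since a softmax over an empty neighborhood is undefined.
# Diagnostics keep using the raw adjacency.
gat_adjacency <- function(graph) {
  adj <- graph$adjacency
  iso <- which(rowSums(adj) == 0)
  if (length(iso)) {
    warning(sprintf("%d isolated node(s) given forced self-edges for attention: %s",
                    length(iso),
                    paste(utils::head(graph$ids[iso], 5), collapse = ", ")),
            call. = FALSE)
    adj[cbind(iso, iso)] <- 1L
  }
  adj
}
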