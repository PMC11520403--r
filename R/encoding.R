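#' Construct an encoding matrix
#'
#' An encoding matrix holds one fixed-length real vector per entity (protein
#' or drug), with entity ids as row names. It is the common currency between
#' the sequence encoders, the neighborhood-graph builders and the predictive
#' model.
#'
#' @param values numeric matrix, one row per entity, all entries finite.
#' @param ids character vector of unique entity ids (defaults to rownames).
#' @param source provenance tag: one of `"protein_lm"`, `"chemical_lm"`,
#'   `"mock"`, `"file"`, `"synthetic"`.
#' @return a numeric matrix of class `encoding_matrix` with row names set to
#'   the entity ids and a `source` attribute.
#' @export
encoding_matrix <- function(values, ids = rownames(values), source = "file") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("encoding values must be numeric", call. = FALSE)
  if (is.null(ids)) stop("entity ids are required", call. = FALSE)
  ids <- as.character(ids)
  if (length(ids) != nrow(values))
    stop("number of ids does not match number of rows", call. = FALSE)
  stop_if_not_ids(ids)
  if (nrow(values) > 0 && any(!is.finite(values)))
    stop("encoding matrix contains non-finite entries", call. = FALSE)
  rownames(values) <- ids
  attr(values, "source") <- source
  class(values) <- c("encoding_matrix", class(values))
  values
}

#' @export
print.encoding_matrix <- function(x, ...) {
  cat(sprintf("<encoding_matrix> %d entities x %d dims (source: %s)\n",
              nrow(x), ncol(x), attr(x, "source") %||% "?"))
  if (nrow(x) > 0) {
    show <- unclass(x)[seq_len(min(4L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE]
    print(round(show, 4))
    if (nrow(x) > 4L) cat("...\n")
  }
  invisible(x)
}

#' Create an encoder backend handle
#'
#' Encoders map sequences to fixed-length vectors. Three backends share one
#' contract: `"mock"` (a deterministic, dependency-free k-mer hashing encoder
#' suitable for testing and simulation), `"file"` (reads a precomputed
#' id-indexed encoding matrix, e.g. exported from a pretrained language
#' model), and `"lm"` (an adapter slot for a pretrained protein/chemical
#' language model; such models are not bundled, so requesting this backend
#' signals a missing optional dependency rather than bad input).
#'
#' @param backend one of `"mock"`, `"file"`, `"lm"`.
#' @param dim output dimension (mock backend; conventional sizes are 1280 for
#'   protein LMs and 768 for chemical LMs, but tests use small dims).
#' @param seed integer seed making the mock encoder a pure function of
#'   (sequence, seed, dim).
#' @param path path to a precomputed encoding TSV (file backend).
#' @param pooling `"mean"` or `"cls"`: how an LM backend would reduce
#'   per-token states to one vector (mean over positions is the default).
#' @param k k-mer length used by the mock encoder.
#' @return an object of class `dtigat_encoder`.
#' @export
encoder_backend <- function(backend = c("mock", "file", "lm"),
                            dim = 64L, seed = 1L, path = NULL,
                            pooling = c("mean", "cls"), k = 3L) {
  backend <- match.arg(backend)
  pooling <- match.arg(pooling)
  structure(list(backend = backend, dim = as.integer(dim),
                 seed = as.integer(seed), path = path,
                 pooling = pooling, k = as.integer(k)),
            class = "dtigat_encoder")
}

# Deterministic mock encoder: feature-hashed k-mer counts projected through
# per-k-mer Gaussian rows whose RNG streams are derived from (seed, k-mer).
# Equal sequences give bitwise-equal rows; similar sequences (shared k-mers)
# give correlated rows.
mock_encode <- function(seqs, ids, dim, seed, k) {
  if (any(!nzchar(seqs))) {
    bad <- ids[!nzchar(seqs)]
    stop(sprintf("empty sequence for: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  cache <- new.env(parent = emptyenv())
  proj_for <- function(km) {
    if (is.null(cache[[km]]))
      cache[[km]] <- with_seed(derive_seed(seed, km), stats::rnorm(dim))
    cache[[km]]
  }
  rows <- vapply(seqs, function(s) {
    n <- nchar(s)
    kk <- min(k, n)
    kmers <- substring(s, seq_len(n - kk + 1L), seq_len(n - kk + 1L) + kk - 1L)
    counts <- table(kmers)
    v <- numeric(dim)
    for (i in seq_along(counts)) v <- v + as.numeric(counts[[i]]) * proj_for(names(counts)[i])
    v / sqrt(sum(counts^2))
  }, numeric(dim))
  encoding_matrix(t(rows), ids = ids, source = "mock")
}

lm_unavailable <- function(modality) {
  cond <- structure(
    class = c("dtigat_missing_dependency", "error", "condition"),
    list(message = sprintf(
      paste0("no pretrained %s language model is bundled with this package ",
             "(missing optional dependency, not bad input); encode offline ",
             "and use encoder_backend('file', path = ...), or use the mock ",
             "backend"), modality),
      call = NULL))
  stop(cond)
}

encode_common <- function(seqs, backend, modality) {
  if (!inherits(backend, "dtigat_encoder"))
    stop("backend must be created with encoder_backend()", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids)) stop("records must be named by entity id", call. = FALSE)
  stop_if_not_ids(ids)
  switch(backend$backend,
    mock = mock_encode(unname(seqs), ids, backend$dim, backend$seed, backend$k),
    file = {
      mat <- read_encodings(backend$path)
      missing <- setdiff(ids, rownames(mat))
      if (length(missing))
        stop(sprintf("ids absent from %s: %s", backend$path,
                     paste(missing, collapse = ", ")), call. = FALSE)
      encoding_matrix(unclass(mat)[ids, , drop = FALSE], source = "file")
    },
    lm = lm_unavailable(modality))
}

#' Encode protein sequences
#'
#' @param records named character vector of amino-acid sequences (names are
#'   entity ids), e.g. from [read_fasta()]. Ambiguity codes (X/U/B) are
#'   tolerated.
#' @param backend an [encoder_backend()] handle.
#' @return an [encoding_matrix()] with rows in input order.
#' @export
encode_proteins <- function(records, backend = encoder_backend("mock")) {
  encode_common(records, backend, "protein")
}

#' Encode drug SMILES strings
#'
#' @param records named character vector of SMILES strings (names are ids),
#'   e.g. from [read_smiles()].
#' @inheritParams encode_proteins
#' @return an [encoding_matrix()] with rows in input order.
#' @export
encode_drugs <- function(records, backend = encoder_backend("mock", k = 2L)) {
  encode_common(records, backend, "drug")
}

#' Read a FASTA file of protein sequences
#'
#' The id of each record is the first whitespace-delimited token of its
#' header line.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  stop_if_not_ids(names(seqs), "FASTA ids")
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a two-column id/SMILES TSV
#'
#' No header row is expected; each line is `id<TAB>SMILES`.
#'
#' @param path TSV path.
#' @return named character vector of SMILES strings.
#' @export
read_smiles <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2) stop("expected two tab-separated columns: id, SMILES",
                         call. = FALSE)
  stop_if_not_ids(df[[1]], "SMILES ids")
  stats::setNames(df[[2]], df[[1]])
}

#' @rdname read_smiles
#' @param smiles named character vector of SMILES strings.
#' @export
write_smiles <- function(smiles, path) {
  utils::write.table(data.frame(id = names(smiles), smiles = unname(smiles)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write encoding matrices
#'
#' The on-disk format is a TSV with header `id<TAB>e0<TAB>...<TAB>e{dim-1}`,
#' one row per entity. `write_encodings()` followed by `read_encodings()` is
#' the identity on (ids, values) up to decimal float representation.
#'
#' @param path file path.
#' @return `read_encodings()`: an [encoding_matrix()].
#' @export
read_encodings <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          comment.char = "", colClasses = NA)
  if (nrow(df) == 0)
    stop("empty encoding file (no rows, dimension undefined): ", path,
         call. = FALSE)
  if (names(df)[1] != "id")
    stop("first column of an encoding file must be 'id'", call. = FALSE)
  ids <- as.character(df[[1]])
  stop_if_not_ids(ids, "encoding ids")
  vals <- df[, -1, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad))
    stop(sprintf("non-numeric cells in column(s) %s of %s",
                 paste(names(vals)[bad], collapse = ", "), path), call. = FALSE)
  encoding_matrix(as.matrix(vals), ids = ids, source = "file")
}

#' @rdname read_encodings
#' @param mat an [encoding_matrix()] (or plain matrix with rownames).
#' @export
write_encodings <- function(mat, path) {
  df <- data.frame(id = rownames(mat), unclass(mat), check.names = FALSE)
  names(df) <- c("id", paste0("e", seq_len(ncol(mat)) - 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
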