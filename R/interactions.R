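#' Construct an interaction set
#'
#' Holds (drug_id, protein_id, label) records over a declared entity
#' universe. Positives are observed interactions; rows with label 0 are
#' sampled negatives (absent until a split draws them).
#'
#' @param pairs data.frame with columns `drug_id`, `protein_id`, `label`
#'   (0/1).
#' @param drug_ids,protein_ids the full entity universes (default: the ids
#'   occurring in `pairs`).
#' @return a list of class `interaction_set` with elements `pairs`,
#'   `drug_ids`, `protein_ids`.
#' @export
interaction_set <- function(pairs,
                            drug_ids = unique(pairs$drug_id),
                            protein_ids = unique(pairs$protein_id)) {
  req <- c("drug_id", "protein_id", "label")
  if (!all(req %in% names(pairs)))
    stop("pairs needs columns drug_id, protein_id, label", call. = FALSE)
  pairs <- pairs[req]
  pairs$drug_id <- as.character(pairs$drug_id)
  pairs$protein_id <- as.character(pairs$protein_id)
  pairs$label <- as.integer(pairs$label)
  if (nrow(pairs) && !all(pairs$label %in% c(0L, 1L)))
    stop("labels must be 0 or 1", call. = FALSE)
  stop_if_not_ids(drug_ids, "drug ids"); stop_if_not_ids(protein_ids, "protein ids")
  unknown_d <- setdiff(pairs$drug_id, drug_ids)
  unknown_p <- setdiff(pairs$protein_id, protein_ids)
  if (length(unknown_d) || length(unknown_p))
    stop(sprintf("pair ids outside the declared universe: %s",
                 paste(c(unknown_d, unknown_p), collapse = ", ")), call. = FALSE)
  if (anyDuplicated(pairs[c("drug_id", "protein_id")]))
    stop("duplicate (drug, protein) pairs", call. = FALSE)
  structure(list(pairs = pairs, drug_ids = as.character(drug_ids),
                 protein_ids = as.character(protein_ids)),
            class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf(
    "<interaction_set> %d drugs x %d proteins; %d positives, %d negatives\n",
    length(x$drug_ids), length(x$protein_ids),
    sum(x$pairs$label == 1L), sum(x$pairs$label == 0L)))
  invisible(x)
}

#' Dense 0/1 interaction matrix view
#'
#' @param x an [interaction_set()].
#' @return integer matrix (proteins x drugs) with 1 at positive cells.
#' @export
interaction_matrix <- function(x) {
  stopifnot(inherits(x, "interaction_set"))
  I <- matrix(0L, length(x$protein_ids), length(x$drug_ids),
              dimnames = list(x$protein_ids, x$drug_ids))
  pos <- x$pairs[x$pairs$label == 1L, ]
  I[cbind(pos$protein_id, pos$drug_id)] <- 1L
  I
}

#' Read / write interaction pair tables
#'
#' TSV with header columns `drug_id`, `protein_id`, `label` and optionally
#' `subset` (train/val/test, as written for data splits).
#'
#' @param path file path.
#' @return `read_interactions()`: an [interaction_set()] (a `subset` column,
#'   if present, is kept in `$pairs`).
#' @export
read_interactions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  df$label <- as.integer(df$label)
  subset_col <- df$subset
  x <- interaction_set(df)
  if (!is.null(subset_col)) x$pairs$subset <- subset_col
  x
}

#' @rdname read_interactions
#' @param x an [interaction_set()] or a pairs data.frame.
#' @export
write_interactions <- function(x, path) {
  df <- if (inherits(x, "interaction_set")) x$pairs else x
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
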