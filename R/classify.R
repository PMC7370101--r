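#' Classify proteins into aquaporin subfamilies and groups
#'
#' Nearest-annotated-reference classification: each query is globally aligned
#' to every reference template and assigned the subfamily and group of the
#' best reference by normalized identity (matches / aligned non-gap
#' columns). A call is `classified` only when identity reaches
#' `min_identity` over at least `min_columns` aligned columns; otherwise
#' `unclassified` (the best reference is still reported).
#'
#' @param proteins Tibble with columns `id`, `sequence`.
#' @param references Reference tibble (default the packaged
#'   [aqp_reference_set()]); at least one reference per subfamily expected.
#' @param min_identity Identity threshold for a confident call.
#' @param min_columns Minimum aligned (non-gap) columns.
#' @return A tibble: `id`, `subfamily`, `group`, `best_reference`,
#'   `identity`, `aligned_columns`, `status`.
#' @export
classify_proteins <- function(proteins, references = aqp_reference_set(),
                              min_identity = 0.35, min_columns = 150L) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  if (is.null(references) || nrow(references) == 0) {
    abort("Reference set is empty.", class = "aqpkit_config_error")
  }
  n <- nrow(proteins)
  best_idx <- rep(1L, n); best_ident <- rep(-1, n); best_cols <- rep(0L, n)
  for (r in seq_len(nrow(references))) {
    stats <- identities_to_reference(proteins$sequence,
                                     references$sequence[r])
    ident <- vapply(stats, `[[`, numeric(1), "identity")
    cols <- vapply(stats, `[[`, numeric(1), "aligned_columns")
    upd <- ident > best_ident
    best_idx[upd] <- r; best_ident[upd] <- ident[upd]
    best_cols[upd] <- cols[upd]
  }
  tibble(
    id = proteins$id,
    subfamily = references$subfamily[best_idx],
    group = references$group[best_idx],
    best_reference = references$id[best_idx],
    identity = best_ident,
    aligned_columns = as.integer(best_cols),
    status = ifelse(best_ident >= min_identity & best_cols >= min_columns,
                    "classified", "unclassified")
  )
}

#' Build a neighbor-joining tree from protein sequences
#'
#' Pairwise p-distances (mismatches over aligned non-gap columns of a global
#' alignment) feed standard neighbor-joining agglomeration; negative branch
#' lengths are clamped to zero.
#'
#' @param proteins Tibble with columns `id`, `sequence` (>= 3 records).
#' @return A Newick string with the input ids as leaf labels. The `phylo`
#'   object is attached as attribute `phylo`.
#' @export
build_nj_tree <- function(proteins) {
  n <- nrow(proteins)
  if (n < 3) {
    abort("At least 3 records are required for a tree.",
          class = "aqpkit_input_error")
  }
  d <- matrix(0, n, n, dimnames = list(proteins$id, proteins$id))
  for (i in seq_len(n - 1)) {
    stats <- identities_to_reference(proteins$sequence[(i + 1):n],
                                     proteins$sequence[i])
    p <- 1 - vapply(stats, `[[`, numeric(1), "identity")
    d[i, (i + 1):n] <- p
    d[(i + 1):n, i] <- p
  }
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  newick <- ape::write.tree(tree)
  attr(newick, "phylo") <- tree
  newick
}
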