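#' Pairwise shared-signal-peptide counts
#'
#' Symmetric matrix of intersection sizes |A ∩ B| over the predicted
#' signal-peptide sets of a strain panel; the diagonal holds the set sizes.
#' "Shared" means exact amino-acid string equality (case-insensitive) — the
#' comparison the screening study's in-house script performs.
#'
#' @param sets list of [sp_strain_set] objects (>= 2, unique strain ids).
#' @return Integer matrix with strain ids as dimnames.
#' @export
shared_counts <- function(sets) {
  ids <- vapply(sets, `[[`, "", "strain_id")
  if (length(sets) < 2) stop("need at least 2 strain sets", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate strain ids: %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  n <- length(sets)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    m[i, i] <- length(sets[[i]]$peptides)
    for (j in seq_len(n)[-seq_len(i)]) {
      m[i, j] <- m[j, i] <-
        length(intersect(sets[[i]]$peptides, sets[[j]]$peptides))
    }
  }
  m
}

#' Percent-shared (Jaccard) similarity matrix
#'
#' Converts pairwise shared counts into the percentage of shared signal
#' peptides over the total unique-plus-shared peptides of each strain pair,
#' i.e. 100 x |A ∩ B| / |A ∪ B| (the Jaccard index scaled to percent),
#' reported to one decimal. The diagonal is 100 for nonempty sets; an empty
#' set gets 0 off-diagonal with a warning.
#'
#' @inheritParams shared_counts
#' @return An object of class `sp_similarity`: list with `strains`, `shared`
#'   (integer matrix) and `percent` (numeric matrix, one decimal).
#' @examples
#' panel <- gen_strain_panel(n_strains = 3, set_size = 30,
#'                           target_jaccard = 0.5, seed = 1)
#' percent_shared(panel)$percent
#' @export
percent_shared <- function(sets) {
  shared <- shared_counts(sets)
  sizes <- diag(shared)
  if (any(sizes == 0)) {
    warning(sprintf("empty peptide set(s): %s; off-diagonal similarity set to 0",
                    paste(rownames(shared)[sizes == 0], collapse = ", ")),
            call. = FALSE)
  }
  n <- nrow(shared)
  union <- outer(sizes, sizes, `+`) - shared
  pct <- matrix(0, n, n, dimnames = dimnames(shared))
  ok <- union > 0
  pct[ok] <- 100 * shared[ok] / union[ok]
  diag(pct) <- 100
  pct <- round_half_up(pct, 1)
  structure(list(strains = rownames(shared), shared = shared, percent = pct),
            class = "sp_similarity")
}

#' @export
print.sp_similarity <- function(x, ...) {
  cat(sprintf("Shared signal-peptide similarity over %d strains\n",
              length(x$strains)))
  print(x$percent, ...)
  invisible(x)
}

#' Presence of query signal peptides across a strain panel
#'
#' For each query peptide, the per-strain presence (exact sequence match
#' against the strain's predicted signal-peptide set) and the percentage of
#' panel strains containing it — the computation behind "presence of the
#' identified signal peptides in other strains of the same species/genus".
#'
#' @param queries an [sp_records] data frame or a named character vector of
#'   peptide sequences.
#' @param panel list of [sp_strain_set] objects.
#' @return Data frame with columns `id`, `n_present`, `percent` (one
#'   decimal); the per-strain logical matrix is attached as attribute
#'   `presence`.
#' @export
presence_table <- function(queries, panel) {
  if (!length(panel)) stop("empty strain panel", call. = FALSE)
  if (is.data.frame(queries)) {
    seqs <- stats::setNames(toupper(queries$sp_seq), queries$id)
  } else {
    seqs <- toupper(queries)
    if (is.null(names(seqs))) names(seqs) <- sprintf("q%02d", seq_along(seqs))
  }
  if (!length(seqs)) {
    out <- data.frame(id = character(), n_present = integer(),
                      percent = numeric(), stringsAsFactors = FALSE)
    attr(out, "presence") <- matrix(logical(0), 0, length(panel))
    return(out)
  }
  pres <- vapply(panel, function(s) seqs %in% s$peptides,
                 logical(length(seqs)))
  pres <- matrix(pres, nrow = length(seqs),
                 dimnames = list(names(seqs),
                                 vapply(panel, `[[`, "", "strain_id")))
  out <- data.frame(
    id = names(seqs),
    n_present = as.integer(rowSums(pres)),
    percent = round_half_up(100 * rowSums(pres) / length(panel), 1),
    stringsAsFactors = FALSE
  )
  attr(out, "presence") <- pres
  out
}

#' Mean off-diagonal similarity of a strain subset
#'
#' Mean and sample standard deviation of the upper-triangle pairwise
#' percent-shared values restricted to a subset of strains — the "average
#' similarity (± SD) across strains" summary.
#'
#' @param similarity an [sp_similarity] object from [percent_shared()].
#' @param subset strain ids (default: all strains); at least 2.
#' @return List with `mean`, `sd`, `n_pairs`.
#' @export
mean_offdiag <- function(similarity, subset = NULL) {
  stopifnot(inherits(similarity, "sp_similarity"))
  if (is.null(subset)) subset <- similarity$strains
  missing <- setdiff(subset, similarity$strains)
  if (length(missing)) {
    stop(sprintf("unknown strain(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (length(subset) < 2) stop("subset needs >= 2 strains", call. = FALSE)
  p <- similarity$percent[subset, subset, drop = FALSE]
  vals <- p[upper.tri(p)]
  list(mean = mean(vals), sd = sd(vals), n_pairs = length(vals))
}

#' Average-linkage clustering order for similarity heatmaps
#'
#' Agglomerative average-linkage (UPGMA) clustering on the distance
#' `100 - percent_shared`, with deterministic tie-breaking by lexicographic
#' strain id (strains are sorted before clustering, and `stats::hclust`
#' resolves equal-distance merges by lowest index). Returns the leaf order
#' and merge tree used to annotate exported heatmaps.
#'
#' @inheritParams mean_offdiag
#' @return List with `order` (strain ids in leaf order), `merge` and
#'   `height` (as in [stats::hclust]), and the `hclust` object itself.
#' @export
cluster_order <- function(similarity) {
  stopifnot(inherits(similarity, "sp_similarity"))
  ids <- sort(similarity$strains)
  if (length(ids) < 2) stop("need >= 2 strains to cluster", call. = FALSE)
  d <- as.dist(100 - similarity$percent[ids, ids])
  hc <- hclust(d, method = "average")
  hc$order <- .canonical_leaf_order(hc$merge)
  list(order = ids[hc$order], merge = hc$merge, height = hc$height,
       hclust = hc)
}

# Rotate each merge so the subtree holding the lexicographically smallest
# leaf (= smallest index: leaves are pre-sorted) comes first; makes the
# leaf order deterministic under tied merge heights.
.canonical_leaf_order <- function(merge) {
  leaves <- function(node) {
    if (node < 0) return(-node)
    a <- leaves(merge[node, 1]); b <- leaves(merge[node, 2])
    if (min(a) <= min(b)) c(a, b) else c(b, a)
  }
  leaves(nrow(merge))
}

#' Serialise and read square similarity matrices
#'
#' Square TSV with strain ids as the first row and column; percent values to
#' one decimal, shared counts as integers.
#'
#' @inheritParams mean_offdiag
#' @param path file path.
#' @param which `"percent"` or `"shared"`.
#' @return `write_similarity_tsv()` returns `path` invisibly;
#'   `read_similarity_tsv()` returns a numeric matrix.
#' @export
write_similarity_tsv <- function(similarity, path, which = c("percent", "shared")) {
  which <- match.arg(which)
  m <- similarity[[which]]
  df <- data.frame(strain = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Similarity heatmap
#'
#' Static heatmap of the percent-shared matrix in the clustering order of
#' [cluster_order()]. Requires the `pheatmap` package.
#'
#' @inheritParams mean_offdiag
#' @param ... passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_similarity <- function(similarity, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_similarity() needs the 'pheatmap' package", call. = FALSE)
  }
  hc <- cluster_order(similarity)$hclust
  ids <- sort(similarity$strains)
  invisible(pheatmap::pheatmap(similarity$percent[ids, ids],
                               cluster_rows = hc, cluster_cols = hc, ...))
}
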