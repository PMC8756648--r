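#' Per-strain signal-peptide sets
#'
#' A strain peptide set is the deduplicated collection of predicted signal
#' peptide sequences (the `sp_seq` part only, no downstream residues) of one
#' strain, used for pairwise shared-signal-peptide comparisons across a
#' panel.
#'
#' @param strain_id strain label.
#' @param peptides character vector of amino-acid sequences; duplicates are
#'   collapsed (set semantics) and case is normalised to upper.
#' @param accession free text, e.g. a GenBank assembly accession.
#' @inheritParams sp_records
#' @return An object of class `sp_strain_set`: a list with elements
#'   `strain_id`, `accession` and `peptides` (sorted unique sequences).
#' @export
sp_strain_set <- function(strain_id, peptides, accession = "",
                          allow_ambiguous = FALSE) {
  peptides <- check_aa(peptides, allow_ambiguous,
                       sprintf("strain '%s' peptides", strain_id))
  out <- list(strain_id = as.character(strain_id),
              accession = as.character(accession),
              peptides = sort(unique(peptides)))
  class(out) <- "sp_strain_set"
  out
}

#' @export
print.sp_strain_set <- function(x, ...) {
  cat(sprintf("Strain '%s': %d unique signal peptides\n",
              x$strain_id, length(x$peptides)))
  invisible(x)
}

#' Read one peptide FASTA per strain
#'
#' Each file becomes one [sp_strain_set]; duplicate sequences within a file
#' are collapsed and per-strain counts are reported. An empty file yields an
#' empty set with a warning rather than an error.
#'
#' @param paths FASTA file paths, one per strain.
#' @param strain_ids strain labels; defaults to the file base names without
#'   extension.
#' @inheritParams sp_records
#' @return List of [sp_strain_set] objects.
#' @export
read_strain_sets <- function(paths, strain_ids = NULL,
                             allow_ambiguous = FALSE) {
  if (is.null(strain_ids)) {
    strain_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  stopifnot(length(paths) == length(strain_ids))
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    aas <- Biostrings::readAAStringSet(paths[[i]])
    if (length(aas) == 0) {
      warning(sprintf("empty peptide FASTA for strain '%s': %s",
                      strain_ids[[i]], paths[[i]]), call. = FALSE)
      out[[i]] <- sp_strain_set(strain_ids[[i]], character(0))
      next
    }
    seqs <- as.character(aas)
    ids <- sub("\\s.*$", "", names(aas))
    check_aa(seqs, allow_ambiguous,
             sprintf("file '%s'", basename(paths[[i]])), ids = ids)
    n_in <- length(seqs)
    out[[i]] <- sp_strain_set(strain_ids[[i]], seqs,
                              allow_ambiguous = allow_ambiguous)
    message(sprintf("strain '%s': %d records, %d unique signal peptides",
                    strain_ids[[i]], n_in, length(out[[i]]$peptides)))
  }
  out
}

#' Write a strain peptide set as FASTA
#'
#' @param set an [sp_strain_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_strain_set <- function(set, path) {
  aas <- Biostrings::AAStringSet(set$peptides)
  names(aas) <- sprintf("%s_pep%04d", set$strain_id,
                        seq_along(set$peptides))
  Biostrings::writeXStringSet(aas, filepath = path)
  invisible(path)
}
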