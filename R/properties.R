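#' N-domain end position of a signal peptide
#'
#' The N-domain of a Sec signal peptide is defined operationally as the
#' stretch from the N-terminal methionine up to the last positively charged
#' residue (K or R). For sequences containing no K/R the N-domain collapses
#' to the initial residue alone (end index 1), which keeps the invariant
#' `1 <= n_domain_end <= length` and contributes a charge of 0 for the usual
#' Met start.
#'
#' @param sp_seq character vector of signal-peptide sequences.
#' @inheritParams sp_records
#' @return Integer vector of 1-based end indices.
#' @examples
#' n_domain_end("MKKFNFKTMLLLVLASCVFGVVVNVTTSLGPQTTITAQA")  # 7
#' @export
n_domain_end <- function(sp_seq, allow_ambiguous = FALSE) {
  if (any(!nzchar(sp_seq))) stop("empty sequence", call. = FALSE)
  sp_seq <- check_aa(sp_seq, allow_ambiguous, "sp_seq")
  vapply(strsplit(sp_seq, "", fixed = TRUE), function(x) {
    w <- which(x %in% c("K", "R"))
    if (length(w)) max(w) else 1L
  }, integer(1))
}

#' Net charge of the signal-peptide N-domain
#'
#' Sums per-residue charges over positions `1..n_domain_end(sp_seq)` with
#' aspartate and glutamate as -1, lysine and arginine as +1 and every other
#' residue (including histidine and the free N-terminal amino group) as 0.
#' `mode = "positive_count"` instead counts only the +1 contributions of
#' K/R, a variant needed to reproduce two published net charges whose
#' printed values omit the acidic subtraction (see the vignette).
#'
#' @inheritParams n_domain_end
#' @param mode `"signed"` (default, the stated -1/+1 scheme) or
#'   `"positive_count"`.
#' @return Integer vector of net charges.
#' @examples
#' net_charge("MKKFNFKTMLLLVLASCVFGVVVNVTTSLGPQTTITAQA")  # +3
#' @export
net_charge <- function(sp_seq, mode = c("signed", "positive_count"),
                       allow_ambiguous = FALSE) {
  mode <- match.arg(mode)
  sp_seq <- check_aa(sp_seq, allow_ambiguous, "sp_seq")
  ends <- n_domain_end(sp_seq, allow_ambiguous)
  chars <- strsplit(sp_seq, "", fixed = TRUE)
  vapply(seq_along(chars), function(i) {
    x <- chars[[i]][seq_len(ends[i])]
    pos <- sum(x %in% c("K", "R"))
    if (mode == "positive_count") return(as.integer(pos))
    as.integer(pos - sum(x %in% c("D", "E")))
  }, integer(1))
}

#' Hydrophobicity percentage of a signal peptide
#'
#' Percentage of residues belonging to the hydrophobic class
#' \{G, A, V, L, I, M, F, W, P\}, rounded half-up to the nearest integer
#' (exact integer arithmetic, so e.g. 23/40 = 57.5% rounds to 58).
#' Ambiguity codes, when allowed, count as hydrophilic.
#'
#' @inheritParams n_domain_end
#' @return Integer vector of percentages in \[0, 100\].
#' @examples
#' hydrophobicity_pct("MMMM")  # 100
#' @export
hydrophobicity_pct <- function(sp_seq, allow_ambiguous = FALSE) {
  sp_seq <- check_aa(sp_seq, allow_ambiguous, "sp_seq")
  chars <- strsplit(sp_seq, "", fixed = TRUE)
  counts <- vapply(chars, function(x) sum(x %in% AA_HYDROPHOBIC), integer(1))
  pct_int(counts, nchar(sp_seq))
}

#' Ala-X-Ala signal peptidase I motif
#'
#' TRUE when the residues at positions -3 and -1 relative to the cleavage
#' site (i.e. the third-from-last and last residues of `sp_seq`) are both
#' alanine — the canonical SPase I recognition pattern; position -2 is
#' unconstrained. The flag depends only on `sp_seq`, never on the retained
#' downstream residues.
#'
#' @inheritParams n_domain_end
#' @return Logical vector.
#' @examples
#' axa_motif("MKKAITTASFFLAIFVVFMVGSNAASA")  # TRUE (...ASA)
#' @export
axa_motif <- function(sp_seq, allow_ambiguous = FALSE) {
  sp_seq <- check_aa(sp_seq, allow_ambiguous, "sp_seq")
  n <- nchar(sp_seq)
  if (any(n < 3)) {
    stop("sequence shorter than 3 residues has no -3/-1 positions",
         call. = FALSE)
  }
  substr(sp_seq, n, n) == "A" & substr(sp_seq, n - 2, n - 2) == "A"
}

#' Per-peptide property table
#'
#' Assembles the per-peptide characterisation table: length, N-domain end,
#' N-domain net charge, hydrophobicity percentage, Ala-X-Ala motif flag and
#' the externally supplied transmembrane-helix flag (`NA` where no flag is
#' given — helix structure is predicted by external tools and never computed
#' here).
#'
#' @param records an [sp_records] data frame, or any data frame with columns
#'   `id` and `sp_seq` (optionally `downstream`, `annotation`).
#' @param helix_flags optional named logical vector keyed by id, or a
#'   2-column data frame / TSV as read by [read_helix_flags()].
#' @param charge_mode passed to [net_charge()].
#' @inheritParams sp_records
#' @return Data frame with columns `id`, `sequence`, `downstream`, `length`,
#'   `n_domain_end`, `net_charge`, `hydrophobicity_pct`, `axa_motif`,
#'   `tm_helix`, `annotation`.
#' @examples
#' tab <- table1_signal_peptides()
#' head(property_table(tab))
#' @export
property_table <- function(records, helix_flags = NULL,
                           charge_mode = "signed", allow_ambiguous = FALSE) {
  if (!all(c("id", "sp_seq") %in% names(records))) {
    stop("records needs columns 'id' and 'sp_seq'", call. = FALSE)
  }
  if (nrow(records) == 0) {
    return(data.frame(id = character(), sequence = character(),
                      downstream = character(), length = integer(),
                      n_domain_end = integer(), net_charge = integer(),
                      hydrophobicity_pct = integer(), axa_motif = logical(),
                      tm_helix = logical(), annotation = character(),
                      stringsAsFactors = FALSE))
  }
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup)) {
    stop(sprintf("duplicate ids: %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  if (is.data.frame(helix_flags)) {
    helix_flags <- stats::setNames(.parse_flag(helix_flags[[2]]),
                                   as.character(helix_flags[[1]]))
  }
  tm <- rep(NA, nrow(records))
  if (!is.null(helix_flags)) {
    hit <- match(records$id, names(helix_flags))
    tm[!is.na(hit)] <- helix_flags[hit[!is.na(hit)]]
  }
  data.frame(
    id = records$id,
    sequence = records$sp_seq,
    downstream = if ("downstream" %in% names(records)) records$downstream else "",
    length = nchar(records$sp_seq),
    n_domain_end = n_domain_end(records$sp_seq, allow_ambiguous),
    net_charge = net_charge(records$sp_seq, charge_mode, allow_ambiguous),
    hydrophobicity_pct = hydrophobicity_pct(records$sp_seq, allow_ambiguous),
    axa_motif = axa_motif(records$sp_seq, allow_ambiguous),
    tm_helix = as.logical(tm),
    annotation = if ("annotation" %in% names(records)) records$annotation else "",
    stringsAsFactors = FALSE
  )
}

.parse_flag <- function(x) {
  tolower(as.character(x)) %in% c("yes", "true", "1", "y")
}

#' Read transmembrane-helix flags
#'
#' 2-column TSV (`id`, `yes`/`no`) carrying externally predicted
#' transmembrane-helix calls for attachment to [property_table()].
#'
#' @param path TSV path (header optional; a first row `id<tab>...` is
#'   treated as a header).
#' @return Named logical vector.
#' @export
read_helix_flags <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (tolower(trimws(x[1, 1])) == "id") x <- x[-1, , drop = FALSE]
  stats::setNames(.parse_flag(x[[2]]), as.character(x[[1]]))
}

#' Write a property table as TSV
#'
#' Fixed, documented column order (`id`, `sequence`, `downstream`, `length`,
#' `n_domain_end`, `net_charge`, `hydrophobicity_pct`, `axa_motif`,
#' `tm_helix`, `annotation`), UTF-8, Unix newlines.
#'
#' @param props output of [property_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_property_table <- function(props, path) {
  write.table(props, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
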