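#' Construct a table of signal-peptide records
#'
#' A signal-peptide record holds the amino-acid sequence of a predicted
#' Sec/SPI signal peptide up to (and including) the residue immediately
#' before the cleavage site, plus up to two retained residues downstream of
#' the cut. The cleavage position is therefore always `nchar(sp_seq)`
#' (1-based): the bond cut lies between the last residue of `sp_seq` and the
#' first downstream residue.
#'
#' @param id character vector of short labels (e.g. `"LP_23790"`).
#' @param sp_seq amino-acid sequences (uppercase one-letter codes) ending at
#'   the residue before the cleavage site.
#' @param downstream residues retained after the cleavage site, length 0-2
#'   per record. Longer strings are truncated to 2 with a warning, since
#'   exactly two downstream residues are retained in fusion constructs.
#' @param annotation free-text predicted function of the source protein.
#' @param strain_id strain of origin (may be empty).
#' @param allow_ambiguous accept the ambiguity codes X/U/B/Z in addition to
#'   the 20 standard residues.
#' @param check_met warn for records whose first residue is not methionine
#'   (records originating from full CDS starts begin with M).
#'
#' @return A `data.frame` of class `sp_records` with columns `id`, `sp_seq`,
#'   `downstream`, `annotation`, `strain_id`.
#' @seealso [parse_arrow_notation()], [read_sp_fasta()]
#' @export
sp_records <- function(id, sp_seq, downstream = "", annotation = "",
                       strain_id = "", allow_ambiguous = FALSE,
                       check_met = TRUE) {
  n <- length(sp_seq)
  stopifnot(n == length(id))
  sp_seq <- as.character(sp_seq)
  if (any(!nzchar(sp_seq))) {
    stop("sp_seq must be non-empty", call. = FALSE)
  }
  sp_seq <- check_aa(sp_seq, allow_ambiguous, "sp_seq", ids = id)
  downstream <- toupper(rep_len(as.character(downstream), n))
  too_long <- nchar(downstream) > 2
  if (any(too_long)) {
    warning(sprintf(
      "downstream longer than 2 residues for %s; truncating to 2 (two residues are retained after the cleavage site)",
      paste(id[too_long], collapse = ", ")), call. = FALSE)
    downstream[too_long] <- substr(downstream[too_long], 1, 2)
  }
  downstream[nzchar(downstream)] <-
    check_aa(downstream[nzchar(downstream)], allow_ambiguous, "downstream",
             ids = id[nzchar(downstream)])
  if (check_met) {
    no_met <- substr(sp_seq, 1, 1) != "M"
    if (any(no_met)) {
      warning(sprintf("sequence does not start with methionine: %s",
                      paste(id[no_met], collapse = ", ")), call. = FALSE)
    }
  }
  out <- data.frame(
    id = as.character(id),
    sp_seq = sp_seq,
    downstream = downstream,
    annotation = rep_len(as.character(annotation), n),
    strain_id = rep_len(as.character(strain_id), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sp_records", "data.frame")
  out
}

#' Parse arrow-notation signal peptide cells
#'
#' Parses strings of the form `"MQLLK...SGLA↓AS"`, where the arrow marks
#' the predicted signal peptidase I cleavage site and the (up to two) letters
#' after it are the residues retained from the mature protein. The ASCII
#' pipe `"|"` is accepted as an arrow dialect.
#'
#' @param x character vector, one arrow-notation cell per element.
#' @param id optional record labels; defaults to `sp_01`, `sp_02`, ...
#' @param annotation,strain_id passed to [sp_records()].
#' @inheritParams sp_records
#'
#' @return An [sp_records] data frame.
#' @examples
#' parse_arrow_notation("MQLLKRIMVIVGTLILGLQVSSVSGLA|AS", id = "LP_23670")
#' @export
parse_arrow_notation <- function(x, id = NULL, annotation = "",
                                 strain_id = "", allow_ambiguous = FALSE) {
  x <- as.character(x)
  if (is.null(id)) id <- sprintf("sp_%02d", seq_along(x))
  parts <- lapply(seq_along(x), function(i) {
    cell <- gsub("↓", "|", x[[i]], fixed = TRUE)
    n_arrows <- lengths(regmatches(cell, gregexpr("|", cell, fixed = TRUE)))
    if (n_arrows != 1L) {
      stop(sprintf(
        "format error in '%s': expected exactly one cleavage-site arrow, found %d",
        x[[i]], n_arrows), call. = FALSE)
    }
    strsplit(cell, "|", fixed = TRUE)[[1]][1:2]
  })
  sp_seq <- vapply(parts, `[`, "", 1)
  downstream <- vapply(parts, `[`, "", 2)
  downstream[is.na(downstream)] <- ""
  sp_records(id = id, sp_seq = sp_seq, downstream = downstream,
             annotation = annotation, strain_id = strain_id,
             allow_ambiguous = allow_ambiguous)
}

#' Format records back to arrow notation
#'
#' Inverse of [parse_arrow_notation()]: `parse_arrow_notation(format_arrow_notation(x))`
#' reproduces `x`'s sequences exactly.
#'
#' @param records an [sp_records] data frame.
#' @param arrow arrow glyph to place at the cleavage site (default the
#'   down-arrow used in print; use `"|"` for an ASCII-safe table).
#' @return character vector of arrow-notation cells.
#' @export
format_arrow_notation <- function(records, arrow = "↓") {
  paste0(records$sp_seq, arrow, records$downstream)
}

#' Read and write signal-peptide FASTA
#'
#' Records are serialised as protein FASTA whose description line encodes
#' the extra fields as `id strain=<s> downstream=<xy> function=<text>`, so a
#' plain FASTA reader still recovers the signal-peptide sequence. A write
#' followed by a read reproduces the record table exactly.
#'
#' @param records an [sp_records] data frame.
#' @param path file path.
#' @inheritParams sp_records
#' @return `read_sp_fasta()` returns an [sp_records] data frame;
#'   `write_sp_fasta()` returns `path` invisibly.
#' @export
write_sp_fasta <- function(records, path) {
  headers <- sprintf("%s strain=%s downstream=%s function=%s",
                     records$id, records$strain_id, records$downstream,
                     records$annotation)
  aas <- Biostrings::AAStringSet(records$sp_seq)
  names(aas) <- headers
  Biostrings::writeXStringSet(aas, filepath = path)
  invisible(path)
}

#' @rdname write_sp_fasta
#' @export
read_sp_fasta <- function(path, allow_ambiguous = FALSE) {
  aas <- Biostrings::readAAStringSet(path)
  hdr <- names(aas)
  m <- regmatches(hdr, regexec(
    "^(\\S+) strain=(\\S*) downstream=(\\S*) function=(.*)$", hdr))
  id <- character(length(hdr)); strain <- down <- ann <- character(length(hdr))
  for (i in seq_along(hdr)) {
    if (length(m[[i]]) == 5) {
      id[i] <- m[[i]][2]; strain[i] <- m[[i]][3]
      down[i] <- m[[i]][4]; ann[i] <- m[[i]][5]
    } else {
      id[i] <- sub("\\s.*$", "", hdr[i]); strain[i] <- ""; down[i] <- ""
      ann[i] <- ""
    }
  }
  sp_records(id = id, sp_seq = as.character(aas), downstream = down,
             annotation = ann, strain_id = strain,
             allow_ambiguous = allow_ambiguous, check_met = FALSE)
}

#' @export
print.sp_records <- function(x, ...) {
  cat(sprintf("Signal peptide records: %d\n", nrow(x)))
  NextMethod()
}
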