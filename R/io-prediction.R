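#' Extract signal-peptide records from a cleavage-site prediction table
#'
#' Combines a proteome FASTA with the tabular output of a signal-peptide
#' predictor and slices out, for every protein classified as a Sec/SPI
#' signal peptide, the signal peptide (residues `1..k`, where the predicted
#' cleavage site lies between residues `k` and `k+1`) together with the two
#' residues retained downstream of the cut (`k+1..k+2`, or fewer at the end
#' of the protein). The predictor itself is external; only its output is
#' parsed.
#'
#' Two table dialects are accepted:
#' \describe{
#'   \item{summary format}{tab-separated with `#`-comment header lines, an
#'     ID column, a `Prediction` column whose secretory value is
#'     `SP(Sec/SPI)`, and a cleavage-site column containing
#'     `CS pos: k-k+1` (the "SignalP 5" style summary).}
#'   \item{minimal format}{a 3-column TSV with header `id`, `class`,
#'     `cut_after`; rows with `class` equal to `SP(Sec/SPI)` (or plain `SP`)
#'     are secretory.}
#' }
#'
#' @param proteome protein FASTA path or a [Biostrings::AAStringSet].
#' @param predictions prediction table path, or a data frame in the minimal
#'   dialect (`id`, `class`, `cut_after`).
#' @inheritParams sp_records
#' @return An [sp_records] data frame (one row per secretory protein) with
#'   attribute `n_skipped` counting the non-signal rows that were skipped.
#' @export
parse_prediction_table <- function(proteome, predictions,
                                   allow_ambiguous = FALSE) {
  if (!inherits(proteome, "AAStringSet")) {
    proteome <- Biostrings::readAAStringSet(proteome)
  }
  names(proteome) <- sub("\\s.*$", "", names(proteome))
  pred <- .read_predictions(predictions)

  secretory <- grepl("^SP(\\(Sec/SPI\\))?$", pred$class)
  n_skipped <- sum(!secretory)
  pred <- pred[secretory, , drop = FALSE]

  missing <- setdiff(pred$id, names(proteome))
  if (length(missing)) {
    stop(sprintf("reference error: predicted id(s) absent from proteome: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }

  prot <- as.character(proteome[pred$id])
  len <- nchar(prot)
  k <- pred$cut_after
  if (any(k < 1 | k > len)) {
    bad <- which(k < 1 | k > len)[1]
    stop(sprintf(
      "coordinate error for '%s': cleavage position %d outside protein of length %d",
      pred$id[bad], k[bad], len[bad]), call. = FALSE)
  }
  sp_seq <- substr(prot, 1, k)
  downstream <- substr(prot, k + 1, pmin(k + 2, len))
  out <- sp_records(id = pred$id, sp_seq = sp_seq, downstream = downstream,
                    allow_ambiguous = allow_ambiguous)
  attr(out, "n_skipped") <- n_skipped
  out
}

# Read either prediction-table dialect into data.frame(id, class, cut_after)
.read_predictions <- function(predictions) {
  if (is.data.frame(predictions)) {
    need <- c("id", "class", "cut_after")
    if (!all(need %in% names(predictions))) {
      stop("prediction data frame needs columns id, class, cut_after",
           call. = FALSE)
    }
    return(data.frame(id = as.character(predictions$id),
                      class = as.character(predictions$class),
                      cut_after = as.integer(predictions$cut_after),
                      stringsAsFactors = FALSE))
  }
  lines <- readLines(predictions, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)

  is_minimal <- length(body) > 0 &&
    identical(tolower(trimws(fields[[1]][1:3])), c("id", "class", "cut_after"))
  if (is_minimal) {
    fields <- fields[-1]
    cut <- vapply(fields, `[`, "", 3)
    cut[cut %in% c("", "NA", "-")] <- NA_character_
    return(data.frame(
      id = vapply(fields, `[`, "", 1),
      class = trimws(vapply(fields, `[`, "", 2)),
      cut_after = as.integer(cut),
      stringsAsFactors = FALSE))
  }

  # summary dialect: ID, Prediction, ..., last field may carry "CS pos: k-k+1"
  id <- vapply(fields, `[`, "", 1)
  cls <- trimws(vapply(fields, `[`, "", 2))
  cut_after <- vapply(fields, function(f) {
    cs <- grep("CS pos:", f, value = TRUE, fixed = TRUE)
    if (!length(cs)) return(NA_integer_)
    as.integer(sub(".*CS pos:\\s*(\\d+)-\\d+.*", "\\1", cs[1]))
  }, integer(1))
  secretory <- grepl("^SP(\\(Sec/SPI\\))?$", cls)
  if (any(secretory & is.na(cut_after))) {
    stop(sprintf("no 'CS pos:' field for secretory row(s): %s",
                 paste(id[secretory & is.na(cut_after)], collapse = ", ")),
         call. = FALSE)
  }
  data.frame(id = id, class = cls, cut_after = cut_after,
             stringsAsFactors = FALSE)
}

#' Write a prediction table in the minimal dialect
#'
#' Companion writer for the 3-column `id`/`class`/`cut_after` dialect read
#' by [parse_prediction_table()]; used mainly by the synthetic-data
#' generators.
#'
#' @param predictions data frame with columns `id`, `class`, `cut_after`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(predictions, path) {
  write.table(predictions[, c("id", "class", "cut_after")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
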