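#' Write a construct or assembly as a GenBank flat file
#'
#' Minimal GenBank emitter for the package's own construct records: LOCUS
#' line with length and topology, one `misc_feature` per annotated part
#' (1-based inclusive coordinates, `/label=` qualifier) and the ORIGIN
#' sequence block. [read_genbank()] parses the same subset back; a write
#' followed by a read reproduces sequence and part annotations.
#'
#' @param x an `sp_assembly`, an `sp_fusion`, or a plain DNA string.
#' @param path output path.
#' @param name LOCUS name (defaults to the record's id).
#' @return `path`, invisibly.
#' @export
write_genbank <- function(x, path, name = NULL) {
  if (inherits(x, "sp_assembly")) {
    seqs <- x$sequence; topo <- "circular"; features <- x$features
    if (is.null(name)) name <- x$id
  } else if (inherits(x, "sp_fusion")) {
    seqs <- x$fragment; topo <- "linear"
    pos <- 0L
    features <- do.call(rbind, lapply(names(x$parts), function(p) {
      w <- nchar(x$parts[[p]])
      out <- data.frame(part = p, start = pos + 1L, end = pos + w,
                        stringsAsFactors = FALSE)
      pos <<- pos + w
      out
    }))
    if (is.null(name)) name <- x$id
  } else {
    seqs <- check_dna(x, "sequence"); topo <- "linear"
    features <- data.frame(part = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
    if (is.null(name)) name <- "record"
  }

  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   SYN %s",
                     name, nchar(seqs), topo,
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (i in seq_len(nrow(features))) {
    writeLines(sprintf("     misc_feature    %d..%d",
                       features$start[i], features$end[i]), con)
    writeLines(sprintf("                     /label=\"%s\"",
                       features$part[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(seqs)
  starts <- seq(1, nchar(s), by = 60)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a GenBank flat file written by [write_genbank()]
#'
#' @param path GenBank file path.
#' @return List with `name`, `length`, `topology`, `sequence` (uppercase)
#'   and `features` (data frame `part`, `start`, `end`).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  if (is.na(locus)) stop("no LOCUS line", call. = FALSE)
  toks <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]]
  name <- toks[1]
  topology <- if (any(toks == "circular")) "circular" else "linear"

  feats <- data.frame(part = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  loc_lines <- grep("^\\s+misc_feature\\s+\\d+\\.\\.\\d+", lines)
  for (i in loc_lines) {
    m <- regmatches(lines[i], regexec("(\\d+)\\.\\.(\\d+)", lines[i]))[[1]]
    lab <- ""
    if (i < length(lines) && grepl("/label=", lines[i + 1], fixed = TRUE)) {
      lab <- sub('.*?/label="([^"]*)".*', "\\1", lines[i + 1])
    }
    feats <- rbind(feats, data.frame(part = lab,
                                     start = as.integer(m[2]),
                                     end = as.integer(m[3]),
                                     stringsAsFactors = FALSE))
  }

  origin <- which(lines == "ORIGIN")
  if (!length(origin)) stop("no ORIGIN block", call. = FALSE)
  body <- lines[(origin[1] + 1):length(lines)]
  body <- body[!grepl("^//", body)]
  seqs <- toupper(gsub("[^a-zA-Z]", "", paste(body, collapse = "")))
  list(name = name, length = nchar(seqs), topology = topology,
       sequence = seqs, features = feats)
}
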