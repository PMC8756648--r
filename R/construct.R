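#' Ribosome binding site used in the expression cassettes
#'
#' The Shine-Dalgarno sequence placed upstream of the signal-peptide start
#' codon in every library construct.
#' @format Character scalar `"AGGAGG"`.
#' @export
RBS_SEQ <- "AGGAGG"

# translate an in-frame CDS to one-letter amino acids ('*' for stop)
translate_cds <- function(dna) {
  dna <- check_dna(dna, "CDS")
  if (nchar(dna) %% 3 != 0) {
    stop("frame violation: CDS length not divisible by 3", call. = FALSE)
  }
  # no.init.codon: plain codon-table translation (alternative initiators
  # like CTG must not silently become M for internal parts)
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     no.init.codon = TRUE))
}

#' Slice a signal-peptide CDS and retained codons out of a gene
#'
#' Given the full coding sequence of a secretory gene and the predicted
#' cleavage position `k` (signal peptide = residues `1..k`), extracts the
#' signal-peptide CDS (first `3k` nt) and the two retained codons
#' (`3k+1..3k+6`) that encode the residues kept downstream of the cleavage
#' site in fusion constructs. Signal-peptide DNA is taken verbatim from the
#' source gene — no back-translation.
#'
#' @param gene_cds DNA string, in frame, starting with ATG.
#' @param k cleavage residue: the signal peptide spans residues `1..k`.
#' @return List with `sp_cds` and `retained_codons`.
#' @examples
#' extract_sp_cds("ATGAAACGTGCTTCTGGTTAA", k = 3)
#' @export
extract_sp_cds <- function(gene_cds, k) {
  gene_cds <- check_dna(gene_cds, "gene_cds")
  if (nchar(gene_cds) %% 3 != 0) {
    stop("frame violation: gene CDS length not divisible by 3", call. = FALSE)
  }
  if (substr(gene_cds, 1, 3) != "ATG") {
    stop("gene CDS must start with ATG", call. = FALSE)
  }
  if (k < 1 || 3 * (k + 2) > nchar(gene_cds)) {
    stop(sprintf(
      "coordinate error: cleavage residue %d leaves no room for 2 retained codons in a %d nt CDS",
      k, nchar(gene_cds)), call. = FALSE)
  }
  sp_cds <- substr(gene_cds, 1, 3 * k)
  aa <- translate_cds(sp_cds)
  if (grepl("*", aa, fixed = TRUE)) {
    stop("in-frame stop codon inside signal-peptide CDS", call. = FALSE)
  }
  list(sp_cds = sp_cds,
       retained_codons = substr(gene_cds, 3 * k + 1, 3 * k + 6))
}

#' Linearised vector with assembly landing sites
#'
#' Describes the linearised expression vector used for overlap assembly:
#' its sequence and the two terminal `overlap`-mers that incoming fragments
#' must carry. Promoter and terminator are vector-resident context (the
#' cassette is cloned between an existing promoter and terminator), so they
#' are part of this sequence, not of the fragment. Each terminal overlap
#' must occur exactly once in the vector, otherwise assembly would be
#' ambiguous.
#'
#' @param sequence linearised vector DNA.
#' @param overlap homology arm length in nt (default 20, the NEBuilder-style
#'   overlap used in the screening study).
#' @return Object of class `sp_vector`: list with `sequence`, `overlap`,
#'   `left` and `right` terminal overlaps.
#' @export
vector_spec <- function(sequence, overlap = 20) {
  sequence <- check_dna(sequence, "vector")
  if (nchar(sequence) < 2 * overlap) {
    stop(sprintf("vector shorter than two %d nt overlaps", overlap),
         call. = FALSE)
  }
  left <- substr(sequence, 1, overlap)
  right <- substr(sequence, nchar(sequence) - overlap + 1, nchar(sequence))
  for (term in unique(c(left, right))) {
    n_hits <- length(gregexpr(term, sequence, fixed = TRUE)[[1]])
    if (n_hits != 1) {
      stop(sprintf(
        "ambiguity error: terminal overlap '%s' occurs %d times in the vector",
        term, n_hits), call. = FALSE)
    }
  }
  structure(list(sequence = sequence, overlap = overlap,
                 left = left, right = right),
            class = "sp_vector")
}

#' @export
print.sp_vector <- function(x, ...) {
  cat(sprintf("Linearised vector: %d nt, %d nt terminal overlaps\n",
              nchar(x$sequence), x$overlap))
  invisible(x)
}

#' Build a signal-peptide::protease fusion fragment
#'
#' Assembles the library fragment for one signal peptide, in part order
#' `overlap_L + RBS + spacer + [sp_cds + retained_codons + mature_cds] +
#' overlap_R`. The bracketed open reading frame must translate to exactly
#' the record's signal peptide, its two retained downstream residues, and
#' the mature protein, ending at a single stop codon; any mismatch between
#' the DNA parts and the peptide record is rejected (the guard against
#' library cross-contamination). The fragment's terminal overlaps are the
#' vector's terminal overlaps, crossed so that the fragment circularises
#' with the linearised vector.
#'
#' @param sp a single signal-peptide record: one row of an [sp_records]
#'   data frame (or a list with `id`, `sp_seq`, `downstream`).
#' @param sp_cds DNA of the signal peptide (3 x length residues, ATG start).
#' @param retained_codons 6 nt encoding the two retained residues.
#' @param mature_cds in-frame mature-protein CDS including its stop codon.
#' @param vector an [vector_spec()] object.
#' @param spacer nt between RBS and start codon (default 7 nt; an empty
#'   spacer is tolerated with a warning).
#' @param rbs ribosome binding site sequence.
#' @return Object of class `sp_fusion`: list with `id`, `parts` (named
#'   character vector in assembly order), `orf`, `fragment`, `translation`.
#' @examples
#' vec <- vector_spec(paste0("ATGCATCGATCGTACGGCTAAGCTTGCACTGGATCCTTGA",
#'                           "CCAGTCGGGCTAGGTACCGAT"))
#' sp <- sp_records("toy", "MKR", "AS")
#' build_fusion(sp[1, ], "ATGAAACGT", "GCTTCT", "GGTTAA", vec)
#' @export
build_fusion <- function(sp, sp_cds, retained_codons, mature_cds, vector,
                         spacer = "AATTAAA", rbs = RBS_SEQ) {
  stopifnot(inherits(vector, "sp_vector"))
  sp_cds <- check_dna(sp_cds, "sp_cds")
  retained_codons <- check_dna(retained_codons, "retained_codons")
  mature_cds <- check_dna(mature_cds, "mature_cds")
  if (nzchar(spacer)) spacer <- check_dna(spacer, "spacer")

  if (substr(sp_cds, 1, 3) != "ATG") {
    stop("sp_cds must start with ATG", call. = FALSE)
  }
  sp_aa <- translate_cds(sp_cds)
  if (grepl("*", sp_aa, fixed = TRUE)) {
    stop("in-frame stop codon inside sp_cds", call. = FALSE)
  }
  if (!identical(sp_aa, toupper(sp$sp_seq))) {
    stop(sprintf(
      "consistency error for '%s': sp_cds translates to '%s', record says '%s'",
      sp$id, sp_aa, sp$sp_seq), call. = FALSE)
  }
  ret_aa <- translate_cds(retained_codons)
  if (!identical(ret_aa, toupper(sp$downstream))) {
    stop(sprintf(
      "consistency error for '%s': retained codons translate to '%s', record says '%s'",
      sp$id, ret_aa, sp$downstream), call. = FALSE)
  }
  mat_aa <- translate_cds(mature_cds)
  if (!grepl("\\*$", mat_aa) ||
      grepl("*", sub("\\*$", "", mat_aa), fixed = TRUE)) {
    stop("mature_cds must end with exactly one stop codon and contain no internal stop",
         call. = FALSE)
  }
  if (!nzchar(spacer)) {
    warning("empty RBS-start spacer: RBS directly abuts ATG", call. = FALSE)
  }

  orf <- paste0(sp_cds, retained_codons, mature_cds)
  parts <- c(overlap_L = vector$right, rbs = rbs, spacer = spacer,
             sp_cds = sp_cds, retained = retained_codons,
             mature_cds = mature_cds, overlap_R = vector$left)
  structure(list(id = sp$id, parts = parts,
                 orf = orf,
                 fragment = paste(parts, collapse = ""),
                 translation = translate_cds(orf)),
            class = "sp_fusion")
}

#' @export
print.sp_fusion <- function(x, ...) {
  cat(sprintf("Fusion fragment '%s': %d nt, ORF %d nt -> %s\n",
              x$id, nchar(x$fragment), nchar(x$orf), x$translation))
  invisible(x)
}

#' Assemble a fragment into the vector
#'
#' In-silico overlap assembly: the fragment's terminal overlaps are checked
#' base-by-base against the vector's terminal overlaps (fragment left vs
#' vector right, fragment right vs vector left); on success the two
#' molecules are merged into a circular record in which each overlap is
#' represented once, so `length(circle) = length(vector) + length(fragment)
#' - 2*overlap`. A mismatch reports the first differing position.
#'
#' @param fragment an [build_fusion()] object or a DNA string carrying the
#'   vector's terminal overlaps.
#' @param vector an [vector_spec()] object.
#' @return Object of class `sp_assembly`: list with `sequence` (circular,
#'   starting at vector position 1), `length`, `topology`, `features` (data
#'   frame of 1-based inclusive part coordinates).
#' @export
assemble <- function(fragment, vector) {
  stopifnot(inherits(vector, "sp_vector"))
  parts <- NULL
  frag_id <- "fragment"
  if (inherits(fragment, "sp_fusion")) {
    parts <- fragment$parts
    frag_id <- fragment$id
    fragment <- fragment$fragment
  }
  fragment <- check_dna(fragment, "fragment")
  ov <- vector$overlap
  if (nchar(fragment) < 2 * ov) {
    stop("fragment shorter than two overlaps", call. = FALSE)
  }
  frag_left <- substr(fragment, 1, ov)
  frag_right <- substr(fragment, nchar(fragment) - ov + 1, nchar(fragment))
  .check_overlap(frag_left, vector$right, "fragment start vs vector end")
  .check_overlap(frag_right, vector$left, "fragment end vs vector start")

  insert <- substr(fragment, ov + 1, nchar(fragment) - ov)
  circle <- paste0(vector$sequence, insert)
  len_v <- nchar(vector$sequence)

  features <- data.frame(part = "vector", start = 1L, end = len_v,
                         stringsAsFactors = FALSE)
  if (!is.null(parts)) {
    pos <- len_v - ov  # fragment coordinate origin within the circle
    feat <- lapply(names(parts), function(p) {
      w <- nchar(parts[[p]])
      st <- pos + 1L
      pos <<- pos + w
      # positions past the origin wrap around the circle
      data.frame(part = p,
                 start = ((st - 1L) %% nchar(circle)) + 1L,
                 end = ((pos - 1L) %% nchar(circle)) + 1L,
                 stringsAsFactors = FALSE)
    })
    features <- rbind(features, do.call(rbind, feat))
  }
  structure(list(id = frag_id, sequence = circle, length = nchar(circle),
                 topology = "circular", features = features),
            class = "sp_assembly")
}

.check_overlap <- function(a, b, where) {
  if (identical(a, b)) return(invisible(TRUE))
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)[1]
  stop(sprintf(
    "assembly error (%s): overlap mismatch at position %d ('%s' vs '%s')",
    where, pos, ca[pos], cb[pos]), call. = FALSE)
}

#' @export
print.sp_assembly <- function(x, ...) {
  cat(sprintf("Circular assembly '%s': %d nt, %d annotated parts\n",
              x$id, x$length, nrow(x$features)))
  invisible(x)
}
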