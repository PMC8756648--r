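# Independent brute-force oracles and small fixture builders shared across
# the test files. The oracles deliberately re-derive quantities from first
# principles (per-residue loops, pairwise membership scans) so they never
# share code with the implementation under test.

# per-residue N-domain charge: scan for the last K/R, then loop residues
oracle_net_charge <- function(seq) {
  x <- strsplit(seq, "")[[1]]
  last_pos <- 1L
  for (i in seq_along(x)) if (x[i] %in% c("K", "R")) last_pos <- i
  total <- 0L
  for (i in seq_len(last_pos)) {
    if (x[i] %in% c("K", "R")) total <- total + 1L
    if (x[i] %in% c("D", "E")) total <- total - 1L
  }
  total
}

# pairwise shared count by explicit double membership loop
oracle_shared <- function(a, b) {
  hits <- 0L
  for (p in a) {
    found <- FALSE
    for (q in b) if (identical(p, q)) found <- TRUE
    if (found) hits <- hits + 1L
  }
  hits
}

oracle_jaccard_pct <- function(a, b) {
  shared <- oracle_shared(a, b)
  100 * shared / (length(a) + length(b) - shared)
}

random_aa <- function(n, alphabet = spscreen::AA_STANDARD) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# panel of strain sets drawn from a common pool so intersections occur
random_panel <- function(n_strains, n_pep, pool_size = 60) {
  pool <- unique(replicate(pool_size * 2, random_aa(sample(8:20, 1))))
  pool <- pool[seq_len(min(pool_size, length(pool)))]
  lapply(seq_len(n_strains), function(i) {
    sp_strain_set(sprintf("s%02d", i),
                  sample(pool, min(n_pep, length(pool))))
  })
}

# fixed codon per amino acid, for synthesising CDS from peptide sequences
.codon_table <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT"
)

codonize <- function(aa) {
  paste(.codon_table[strsplit(aa, "")[[1]]], collapse = "")
}

# 200 nt toy linearised vector with unique terminal 20-mers
toy_vector_seq <- paste0(
  "TTTCCTCATGCAATTCAAAACCATGTCCGTAATGTAGGCGAAATAGTAAACCATTTTACG",
  "GAGGATACCAAATTCCTCCTTATTCAGGACCTAACCTGAGGTAAACCAGGTCTCTCCGCC",
  "CCCTTATAAAAGCTGTTGCACCTAGCCAAGTTCAACGGCAGCTGCAATGGAAATAGGCAA",
  "TGACGGATATATATTAAAAA")
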