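#' Parameters for the tripartite signal-peptide generator
#'
#' Describes the three-domain architecture the generator emulates: a
#' positively charged N-domain (initial Met plus 2-8 residues, enriched for
#' K/R and terminated by one), a hydrophobic H-domain core (10-18 residues
#' from the hydrophobic class), and a polar C-domain (4-8 residues) whose
#' -3/-1 positions are forced to alanine with probability `p_axa` to plant
#' the Ala-X-Ala signal peptidase I motif.
#'
#' @param n_len integer range (min, max) of N-domain residues after the Met.
#' @param kr_prob probability that a non-terminal N-domain residue is K/R.
#' @param h_len integer range of H-domain lengths.
#' @param c_len integer range of C-domain lengths (min >= 3, so the -3/-1
#'   positions exist).
#' @param p_axa probability of planting the Ala-X-Ala motif. The default
#'   0.34 is the genome-wide motif frequency observed among predicted
#'   *L. plantarum* signal peptides (53 of 155).
#' @param c_residues residue pool for C-domain draws (polar-biased); remove
#'   `"A"` to make `p_axa = 0` exclude the motif entirely.
#' @return List of class `sp_gen_params`.
#' @export
sp_gen_params <- function(n_len = c(2, 8), kr_prob = 0.5,
                          h_len = c(10, 18), c_len = c(4, 8),
                          p_axa = 0.34,
                          c_residues = c("S", "T", "N", "Q", "A", "G", "H", "Y")) {
  stopifnot(length(n_len) == 2, n_len[1] >= 1, n_len[1] <= n_len[2],
            length(h_len) == 2, h_len[1] >= 1, h_len[1] <= h_len[2],
            length(c_len) == 2, c_len[1] >= 3, c_len[1] <= c_len[2],
            kr_prob >= 0, kr_prob <= 1, p_axa >= 0, p_axa <= 1,
            all(c_residues %in% AA_STANDARD))
  structure(list(n_len = as.integer(n_len), kr_prob = kr_prob,
                 h_len = as.integer(h_len), c_len = as.integer(c_len),
                 p_axa = p_axa, c_residues = c_residues),
            class = "sp_gen_params")
}

.maybe_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else with_seed(seed, code)
}

.sample_range <- function(range, n) {
  sample(seq(range[1], range[2]), n, replace = TRUE)
}

# neutral pool for non-K/R N-domain draws (no D/E: the N-domain is
# positively charged by construction)
.N_NEUTRAL <- c("S", "T", "N", "Q", "H", "A", "G", "L", "I", "V")

#' Generate synthetic signal peptides
#'
#' Seeded generator of three-domain Sec signal peptides (see
#' [sp_gen_params()]). Every peptide starts with M, its N-domain ends with
#' a K/R, its H-domain is drawn from the hydrophobic class and its C-domain
#' from a polar pool; with probability `p_axa` the C-domain's -3/-1
#' positions are set to alanine. Identical seed and parameters give
#' identical output.
#'
#' @param n number of peptides.
#' @param params an [sp_gen_params()] object.
#' @param seed integer seed (`NULL` uses the ambient RNG stream).
#' @return An [sp_records] data frame with two random downstream residues
#'   per record; attributes `realized_motif_fraction` and
#'   `mean_hydrophobicity` report the realised statistics.
#' @export
gen_signal_peptides <- function(n, params = sp_gen_params(), seed = NULL) {
  stopifnot(inherits(params, "sp_gen_params"), n >= 0)
  .maybe_seed(seed, {
    seqs <- character(n)
    for (i in seq_len(n)) {
      n_n <- .sample_range(params$n_len, 1)
      ndom <- ifelse(runif(n_n) < params$kr_prob,
                     sample(c("K", "R"), n_n, replace = TRUE),
                     sample(.N_NEUTRAL, n_n, replace = TRUE))
      ndom[n_n] <- sample(c("K", "R"), 1)  # N-domain ends charged
      hdom <- sample(AA_HYDROPHOBIC, .sample_range(params$h_len, 1),
                     replace = TRUE)
      cdom <- sample(params$c_residues, .sample_range(params$c_len, 1),
                     replace = TRUE)
      if (runif(1) < params$p_axa) {
        nc <- length(cdom)
        cdom[c(nc - 2, nc)] <- "A"
      }
      seqs[i] <- paste(c("M", ndom, hdom, cdom), collapse = "")
    }
    downstream <- vapply(seq_len(n), function(i)
      paste(sample(AA_STANDARD, 2, replace = TRUE), collapse = ""), "")
    out <- sp_records(id = sprintf("sp_%04d", seq_len(n)), sp_seq = seqs,
                      downstream = downstream)
    if (n > 0) {
      attr(out, "realized_motif_fraction") <- mean(axa_motif(seqs))
      attr(out, "mean_hydrophobicity") <- mean(hydrophobicity_pct(seqs))
    }
    out
  })
}

# n unique peptide sequences (regenerates on collision)
.gen_unique_peptides <- function(n, params, max_tries = 50) {
  seqs <- character(0)
  for (i in seq_len(max_tries)) {
    seqs <- unique(c(seqs, gen_signal_peptides(n - length(seqs) + 10,
                                               params)$sp_seq))
    if (length(seqs) >= n) return(seqs[seq_len(n)])
  }
  stop("could not generate enough unique peptides", call. = FALSE)
}

#' Generate a strain panel with planted pairwise Jaccard similarity
#'
#' Constructive (exact, not sampled) panel generator: every strain receives
#' a shared core of peptides plus disjoint private peptides, sized so that
#' each within-block strain pair realises exactly the target Jaccard index
#' `J = core / (2 * set_size - core)`, i.e. `core = 2 * set_size * J /
#' (1 + J)`. The target must be integer-feasible for the given set size;
#' infeasible targets are rejected with the nearest feasible suggestion.
#' With `blocks`, each block of strains gets its own core and across-block
#' sharing is zero (two planted similarity blocks for clustering tests).
#'
#' @param n_strains number of strains.
#' @param set_size predicted signal peptides per strain.
#' @param target_jaccard planted within-block pairwise Jaccard index in
#'   \[0, 1\].
#' @param blocks optional list of integer vectors partitioning
#'   `1:n_strains` into similarity blocks.
#' @param params peptide generator parameters.
#' @param seed integer seed.
#' @return List of [sp_strain_set] objects (strain ids `strain_01`, ...)
#'   with attribute `target_jaccard`.
#' @examples
#' panel <- gen_strain_panel(2, set_size = 30, target_jaccard = 0.5, seed = 1)
#' percent_shared(panel)$percent  # off-diagonal exactly 50.0
#' @export
gen_strain_panel <- function(n_strains, set_size, target_jaccard,
                             blocks = NULL, params = sp_gen_params(),
                             seed = NULL) {
  stopifnot(n_strains >= 2, set_size >= 1,
            target_jaccard >= 0, target_jaccard <= 1)
  core <- 2 * set_size * target_jaccard / (1 + target_jaccard)
  if (abs(core - round(core)) > 1e-9) {
    c2 <- round(core)
    stop(sprintf(
      "infeasible target Jaccard %g for set size %d (core size %.3f not integer); nearest feasible target is %g",
      target_jaccard, set_size, core, c2 / (2 * set_size - c2)),
      call. = FALSE)
  }
  core <- as.integer(round(core))
  if (is.null(blocks)) blocks <- list(seq_len(n_strains))
  if (!setequal(unlist(blocks), seq_len(n_strains)) ||
      anyDuplicated(unlist(blocks))) {
    stop("blocks must partition 1:n_strains", call. = FALSE)
  }
  n_private <- set_size - core
  .maybe_seed(seed, {
    pool <- .gen_unique_peptides(
      length(blocks) * core + n_strains * n_private, params)
    sets <- vector("list", n_strains)
    used <- 0L
    for (b in seq_along(blocks)) {
      core_pep <- pool[seq_len(core) + used]
      used <- used + core
      for (s in blocks[[b]]) {
        priv <- pool[seq_len(n_private) + used]
        used <- used + n_private
        sets[[s]] <- sp_strain_set(sprintf("strain_%02d", s),
                                   c(core_pep, priv))
      }
    }
    attr(sets, "target_jaccard") <- target_jaccard
    sets
  })
}

#' Generate a synthetic screening plate batch
#'
#' Emulates 96-well fluorescence screening: each plate carries
#' `n_control_wells` wells of the benchmark-signal-peptide control plus
#' clone wells; readings are `control_mean * (1 + effect) * (1 + eps)` with
#' multiplicative zero-mean Gaussian noise of the stated coefficient of
#' variation, truncated at 0. Clones are spread over as many 96-well plates
#' as needed. The planted effects are attached as ground truth for recovery
#' tests.
#'
#' @param n_clones number of clones.
#' @param control_mean expected control fluorescence (> 0).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param effects planted relative effects: a numeric vector of length
#'   `n_clones`, or a named vector keyed by clone id (`clone_0001`, ...)
#'   with unnamed clones at 0.
#' @param n_control_wells control wells per plate.
#' @param replicates wells per clone.
#' @param seed integer seed.
#' @return Plate data frame (`plate_id`, `well`, `clone_id`,
#'   `fluorescence`, `is_control`) with attribute `effects` (named ground
#'   truth).
#' @export
gen_plate <- function(n_clones, control_mean = 1000, noise_cv = 0.05,
                      effects = NULL, n_control_wells = 8, replicates = 1,
                      seed = NULL) {
  stopifnot(n_clones >= 1, control_mean > 0, noise_cv >= 0,
            n_control_wells >= 1, n_control_wells < 96, replicates >= 1)
  ids <- sprintf("clone_%04d", seq_len(n_clones))
  eff <- stats::setNames(rep(0, n_clones), ids)
  if (!is.null(effects)) {
    if (is.null(names(effects))) {
      stopifnot(length(effects) == n_clones)
      eff[] <- effects
    } else {
      unknown <- setdiff(names(effects), ids)
      if (length(unknown)) {
        stop(sprintf("unknown clone id(s) in effects: %s",
                     paste(unknown, collapse = ", ")), call. = FALSE)
      }
      eff[names(effects)] <- effects
    }
  }
  clones_per_plate <- (96 - n_control_wells) %/% replicates
  n_plates <- ceiling(n_clones / clones_per_plate)
  .maybe_seed(seed, {
    rows <- list()
    for (p in seq_len(n_plates)) {
      on_plate <- ids[seq((p - 1) * clones_per_plate + 1,
                          min(p * clones_per_plate, n_clones))]
      clone_col <- c(rep("control", n_control_wells),
                     rep(on_plate, each = replicates))
      eff_col <- c(rep(0, n_control_wells),
                   rep(eff[on_plate], each = replicates))
      nw <- length(clone_col)
      noise <- pmax(0, 1 + rnorm(nw, 0, noise_cv))
      rows[[p]] <- data.frame(
        plate_id = sprintf("plate_%02d", p),
        well = paste0(LETTERS[(seq_len(nw) - 1) %/% 12 + 1],
                      (seq_len(nw) - 1) %% 12 + 1),
        clone_id = clone_col,
        fluorescence = control_mean * (1 + eff_col) * noise,
        is_control = clone_col == "control",
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "effects") <- eff
    validate_plate(out)
  })
}

#' Generate a proteome plus prediction table with planted signal peptides
#'
#' End-to-end fixture generator for [parse_prediction_table()]: secretory
#' proteins are a planted signal peptide followed by its two downstream
#' residues and a random mature tail, with a matching `SP(Sec/SPI)`
#' prediction row; non-secretory proteins are random sequences with class
#' `OTHER`. Extraction from the returned pair recovers exactly the planted
#' records.
#'
#' @param n_secretory,n_other protein counts.
#' @param params peptide generator parameters.
#' @param mature_len range of mature-tail lengths for secretory proteins.
#' @param seed integer seed.
#' @return List with `proteome` (a [Biostrings::AAStringSet]),
#'   `predictions` (minimal-dialect data frame) and `records` (the planted
#'   [sp_records]).
#' @export
gen_proteome <- function(n_secretory, n_other, params = sp_gen_params(),
                         mature_len = c(80, 300), seed = NULL) {
  stopifnot(n_secretory >= 0, n_other >= 0)
  .maybe_seed(seed, {
    rec <- gen_signal_peptides(n_secretory, params)
    if (n_secretory > 0) rec$id <- sprintf("sec_%04d", seq_len(n_secretory))
    sec_prot <- vapply(seq_len(n_secretory), function(i) {
      tail_len <- .sample_range(mature_len, 1)
      paste0(rec$sp_seq[i], rec$downstream[i],
             paste(sample(AA_STANDARD, tail_len, replace = TRUE),
                   collapse = ""))
    }, "")
    oth_prot <- vapply(seq_len(n_other), function(i) {
      paste0("M", paste(sample(AA_STANDARD, .sample_range(c(99, 399), 1),
                               replace = TRUE), collapse = ""))
    }, "")
    proteome <- Biostrings::AAStringSet(c(sec_prot, oth_prot))
    names(proteome) <- c(if (n_secretory) rec$id,
                         if (n_other) sprintf("oth_%04d", seq_len(n_other)))
    predictions <- data.frame(
      id = names(proteome),
      class = rep(c("SP(Sec/SPI)", "OTHER"), c(n_secretory, n_other)),
      cut_after = c(nchar(rec$sp_seq), rep(NA_integer_, n_other)),
      stringsAsFactors = FALSE
    )
    list(proteome = proteome, predictions = predictions, records = rec)
  })
}
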