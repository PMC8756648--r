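#' Read and validate plate-screen fluorescence tables
#'
#' Plate TSV with columns `plate_id`, `well`, `clone_id`, `fluorescence`,
#' `is_control`. Control wells carry the clone expressing the benchmark
#' signal peptide; protease activity is in fluorescence intensity units.
#' Validation requires nonnegative fluorescence and at least one control
#' well per plate.
#'
#' @param path TSV path.
#' @return Validated plate data frame.
#' @export
read_plate_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_plate(df)
}

#' @rdname read_plate_tsv
#' @param plate plate data frame.
#' @export
validate_plate <- function(plate) {
  need <- c("plate_id", "well", "clone_id", "fluorescence", "is_control")
  if (!all(need %in% names(plate))) {
    stop(sprintf("plate table needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  plate$is_control <- as.logical(plate$is_control)
  plate$fluorescence <- as.numeric(plate$fluorescence)
  if (any(plate$fluorescence < 0)) {
    stop("negative fluorescence values", call. = FALSE)
  }
  no_ctrl <- vapply(split(plate$is_control, plate$plate_id),
                    function(x) !any(x), logical(1))
  if (any(no_ctrl)) {
    stop(sprintf("no control wells on plate(s): %s",
                 paste(names(no_ctrl)[no_ctrl], collapse = ", ")),
         call. = FALSE)
  }
  plate
}

#' Relative secretion improvement over the control
#'
#' `(mean(clone) - mean(control)) / mean(control)`: the fractional gain in
#' extracellular protease activity of a clone over the benchmark
#' signal-peptide control (0.20 means 20% higher activity).
#'
#' @param clone_values fluorescence readings of the clone's wells.
#' @param control_values fluorescence readings of the control wells.
#' @return Fraction (single numeric).
#' @examples
#' relative_improvement(c(1100, 1200, 1300), c(1000, 1000, 1000))  # 0.2
#' @export
relative_improvement <- function(clone_values, control_values) {
  cm <- mean(as.numeric(control_values))
  if (!is.finite(cm) || cm <= 0) {
    stop("control mean must be positive", call. = FALSE)
  }
  (mean(as.numeric(clone_values)) - cm) / cm
}

#' Per-clone improvements across a plate batch
#'
#' Aggregates each clone's wells and expresses them relative to the mean of
#' the designated control wells. With `control = "per_plate"` (default)
#' every plate is normalised to its own controls, absorbing plate effects;
#' `"global"` uses one control mean across the whole batch.
#'
#' @param plate validated plate data frame (see [read_plate_tsv()]).
#' @param control `"per_plate"` or `"global"`.
#' @return Data frame with columns `clone_id`, `plate_id`, `improvement`.
#' @export
screen_improvements <- function(plate, control = c("per_plate", "global")) {
  control <- match.arg(control)
  plate <- validate_plate(plate)
  global_ctrl <- mean(plate$fluorescence[plate$is_control])
  out <- lapply(split(plate, plate$plate_id), function(p) {
    ctrl <- if (control == "per_plate") {
      mean(p$fluorescence[p$is_control])
    } else global_ctrl
    clones <- p[!p$is_control, , drop = FALSE]
    if (!nrow(clones)) return(NULL)
    means <- tapply(clones$fluorescence, clones$clone_id, mean)
    data.frame(clone_id = names(means),
               plate_id = p$plate_id[1],
               improvement = vapply(as.numeric(means), relative_improvement,
                                    numeric(1), control_values = ctrl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Shortlist clones at an improvement threshold
#'
#' Keeps clones whose relative improvement is at or above the threshold
#' (inclusive, matching the ">= 20%" / ">= 50%" criteria of the first
#' screening round). Raising the threshold can only shrink the shortlist.
#'
#' @param results data frame with an `improvement` column (e.g. from
#'   [screen_improvements()]).
#' @param threshold nonnegative fraction, e.g. `0.2` for 20%.
#' @return The shortlisted subset of `results`.
#' @export
shortlist <- function(results, threshold) {
  stopifnot(threshold >= 0)
  keep <- results$improvement >= threshold
  message(sprintf("%d of %d clones at improvement >= %g%%",
                  sum(keep), nrow(results), 100 * threshold))
  results[keep, , drop = FALSE]
}

#' Collapse shortlisted clones to unique signal peptides
#'
#' Shortlisted colonies are sequenced; multiple clones typically carry the
#' same signal peptide. This collapses sequenced clones to unique
#' signal-peptide sequences with per-sequence clone counts, sorted by count
#' descending then sequence. Clones without a sequence are excluded with a
#' warning.
#'
#' @param clones data frame with columns `clone_id` and `sp_seq` (NA or
#'   empty where sequencing failed).
#' @return Data frame with columns `sp_seq`, `n_clones`, `clone_ids`.
#' @export
dedupe_to_signal_peptides <- function(clones) {
  missing <- is.na(clones$sp_seq) | !nzchar(as.character(clones$sp_seq))
  if (any(missing)) {
    warning(sprintf("excluding %d clone(s) without sequence: %s",
                    sum(missing),
                    paste(clones$clone_id[missing], collapse = ", ")),
            call. = FALSE)
    clones <- clones[!missing, , drop = FALSE]
  }
  groups <- split(as.character(clones$clone_id),
                  toupper(as.character(clones$sp_seq)))
  out <- data.frame(
    sp_seq = names(groups),
    n_clones = lengths(groups),
    clone_ids = vapply(groups, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_clones, out$sp_seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Library oversampling fold
#'
#' Picked colonies divided by library size. Screens aim for a stated fold
#' (here 10-fold by default) so that every library member is sampled with
#' high probability.
#'
#' @param n_clones number of colonies picked.
#' @param library_size number of distinct signal peptides in the library
#'   (>= 1).
#' @param target_fold coverage target.
#' @return List with `fold` and `meets_target` (`fold >= target_fold`).
#' @examples
#' oversampling_fold(1630, 155)  # 10.5-fold
#' @export
oversampling_fold <- function(n_clones, library_size, target_fold = 10) {
  if (library_size < 1) stop("library_size must be >= 1", call. = FALSE)
  fold <- n_clones / library_size
  list(fold = fold, meets_target = fold >= target_fold)
}

#' Second-round triplicate confirmation
#'
#' Candidates surviving the first screening round are re-grown in
#' triplicate and compared against the control by a two-sample t-test. A
#' candidate is confirmed when its activity increase is positive and the
#' two-sided p-value is below `alpha`. Degenerate (zero-variance) replicate
#' sets inherit the p ∈ \{0, 1\} conventions of [student_t()].
#'
#' @param candidate,control numeric replicate measurements (>= 3 each).
#' @param alpha significance level.
#' @param variant passed to [student_t()].
#' @return List with `percent_increase`, `statistic`, `p_value`,
#'   `confirmed`.
#' @export
confirm_round2 <- function(candidate, control, alpha = 0.05,
                           variant = "pooled") {
  if (length(candidate) < 3 || length(control) < 3) {
    stop("second-round confirmation needs >= 3 replicates per group",
         call. = FALSE)
  }
  inc <- 100 * relative_improvement(candidate, control)
  tt <- student_t(candidate, control, variant = variant)
  list(percent_increase = inc, statistic = tt$statistic,
       p_value = tt$p_value, confirmed = inc > 0 && tt$p_value < alpha)
}

#' Write screen results
#'
#' @param results data frame (e.g. from [screen_improvements()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
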