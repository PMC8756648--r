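#' The 29 signal peptides characterised in the secretion screen
#'
#' Packaged fixture with the signal peptides shortlisted in the published
#' genome-wide PepG1 secretion screens of *Lactiplantibacillus plantarum*
#' (`LP_` prefix) and *Pediococcus acidilactici* (`PA_` prefix): 20 peptides
#' that directed protease secretion and 9 that did not. Sequences are stored
#' in arrow notation and parsed on load; the columns prefixed `printed_`
#' carry the values as printed in the study's characterisation table so that
#' the property calculations can be regression-tested against them, and
#' `tm_helix` the externally predicted transmembrane-helix flag.
#'
#' Two published idiosyncrasies are preserved deliberately: the printed
#' length of PA_07000 is 38 although its printed sequence has 37 residues,
#' and six printed net charges (LP_23680, PA_18600, PA_10610, PA_14540,
#' PA_13510, PA_07000) do not follow the literal "sum of signed charges up
#' to the last K/R" rule (see the package vignette).
#'
#' @return A data frame with columns `id`, `group` (`"secreting"` /
#'   `"non_secreting"`), `sp_seq`, `downstream`, `annotation`,
#'   `printed_length`, `printed_net_charge`, `printed_hydrophobicity`,
#'   `tm_helix`.
#' @examples
#' tab <- table1_signal_peptides()
#' table(tab$group)
#' @export
table1_signal_peptides <- function() {
  path <- system.file("extdata", "table1_signal_peptides.tsv",
                      package = "spscreen", mustWork = TRUE)
  raw <- read.delim(path, stringsAsFactors = FALSE)
  rec <- parse_arrow_notation(raw$arrow, id = raw$id,
                              annotation = raw$annotation)
  data.frame(
    id = rec$id,
    group = raw$group,
    sp_seq = rec$sp_seq,
    downstream = rec$downstream,
    annotation = rec$annotation,
    printed_length = as.integer(raw$printed_length),
    printed_net_charge = as.integer(raw$printed_net_charge),
    printed_hydrophobicity = as.integer(raw$printed_hydrophobicity),
    tm_helix = as.logical(raw$tm_helix),
    stringsAsFactors = FALSE
  )
}
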