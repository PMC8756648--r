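test_that("the N-domain ends at the last positively charged residue", {
  # LP_23790: K at 2, 3, 7 and none later
  expect_equal(n_domain_end("MKKFNFKTMLLLVLASCVFGVVVNVTTSLGPQTTITAQA"), 7)
  # no K/R at all: collapses to the initial residue
  expect_equal(n_domain_end("MAAALLL"), 1)
  # PA_15330 has a single R, fourth residue (M-N-Y-R)
  expect_equal(n_domain_end("MNYRSILFTTAIATMGAFSFGHSPVSA"), 4)
  expect_error(n_domain_end(""), "empty")
})

test_that("net charge follows the signed K/R +1, D/E -1 scheme over the N-domain", {
  expect_equal(net_charge("MKKFNFKTMLLLVLASCVFGVVVNVTTSLGPQTTITAQA"), 3)
  expect_equal(net_charge("MIKLRQVLKKILIVLMVFVLVFTAFSSSVDTVSA"), 4)
  expect_equal(net_charge("MKDRLLL"), 1)  # +1 -1 +1 inside N-domain
  # histidine is neutral; the free N-terminal amino group contributes 0
  expect_equal(net_charge("MHHKLLL"), 1)
  # positive-count mode ignores acidic residues
  expect_equal(net_charge("MKDRLLL", mode = "positive_count"), 2)
})

test_that("net charge agrees with a per-residue brute-force oracle", {
  set.seed(42)
  for (i in 1:60) {
    s <- paste0("M", random_aa(sample(5:40, 1)))
    expect_equal(net_charge(s), oracle_net_charge(s), info = s)
  }
})

test_that("hydrophobicity is the exact half-up percentage of GAVLIMFWP residues", {
  expect_equal(hydrophobicity_pct("MKKFNFKTMLLLVLASCVFGVVVNVTTSLGPQTTITAQA"), 59)
  expect_equal(hydrophobicity_pct("MMMM"), 100)
  expect_equal(hydrophobicity_pct("KKKK"), 0)
  # 23 hydrophobic of 40 = 57.5% must round up to 58 (printed value),
  # which naive floating-point rounding gets wrong
  expect_equal(hydrophobicity_pct("MNQNWQKPSPKLNWVRFYSIVTILVLVTSVAGLEMLRVSA"), 58)
})

test_that("hydrophobicity and hydrophilicity percentages complement each other", {
  set.seed(7)
  for (i in 1:40) {
    s <- random_aa(sample(3:50, 1))
    n <- nchar(s)
    k <- sum(strsplit(s, "")[[1]] %in% AA_HYDROPHOBIC)
    hydrophilic_pct <- spscreen:::pct_int(n - k, n)
    expect_true(abs(hydrophobicity_pct(s) + hydrophilic_pct - 100) <= 1)
  }
})

test_that("the Ala-X-Ala motif needs alanine at -3 and -1, independent of downstream residues", {
  expect_true(axa_motif("MKKFNFKTMLLLVLASCVFGVVVNVTTSLGPQTTITAQA"))  # ...AQA
  expect_false(axa_motif("MKRKWFSLLVAVFLIIGVAIGFGGILHSKSSG"))          # ...SSG
  expect_false(axa_motif("MAA"))  # -3 is M
  expect_true(axa_motif("AAA"))
  expect_error(axa_motif("MA"), "shorter than 3")

  # the flag is a function of sp_seq alone: appending the retained
  # downstream residues to the sequence may change the answer, proving the
  # implementation does not look past the cleavage site
  tab <- table1_signal_peptides()
  with_down <- paste0(tab$sp_seq, tab$downstream)
  expect_false(identical(axa_motif(tab$sp_seq), axa_motif(with_down)))
})

test_that("property_table reproduces the printed per-row characterisation", {
  tab <- table1_signal_peptides()
  props <- property_table(tab)

  # lengths match print except PA_07000, whose printed length (38)
  # contradicts its own printed 37-residue sequence
  mismatch <- tab$id[props$length != tab$printed_length]
  expect_identical(mismatch, "PA_07000")
  expect_equal(props$length[props$id == "LP_23790"], 39)
  expect_equal(props$length[props$id == "PA_13510"], 51)

  # hydrophobicity matches print on all 29 rows
  expect_equal(props$hydrophobicity_pct, tab$printed_hydrophobicity)

  # signed net charge matches print except six rows where the printed
  # value departs from the literal last-K/R rule (stray C-region K/R not
  # counted, or acidic residues not subtracted)
  known_charge_exceptions <- c("LP_23680", "PA_18600", "PA_13510",
                               "PA_10610", "PA_07000", "PA_14540")
  mismatch <- tab$id[props$net_charge != tab$printed_net_charge]
  expect_setequal(mismatch, known_charge_exceptions)
  expect_equal(props$net_charge[props$id == "LP_23790"], 3)
  expect_equal(props$net_charge[props$id == "LP_08330"], 4)

  # the two rows the K/R count reconciles
  pos <- property_table(tab, charge_mode = "positive_count")
  expect_equal(pos$net_charge[pos$id == "PA_13510"], 9)
  expect_equal(pos$net_charge[pos$id == "PA_07000"], 7)

  # motif column: 10 of 20 secreting, 6 of 9 non-secreting
  expect_equal(sum(props$axa_motif[tab$group == "secreting"]), 10)
  expect_equal(sum(props$axa_motif[tab$group == "non_secreting"]), 6)
})

test_that("property_table enforces its invariants and attaches helix flags", {
  tab <- table1_signal_peptides()
  flags <- stats::setNames(tab$tm_helix, tab$id)
  props <- property_table(tab, helix_flags = flags)
  expect_true(all(props$n_domain_end >= 1 & props$n_domain_end <= props$length))
  expect_true(all(abs(props$net_charge) <= props$length))
  expect_true(all(props$hydrophobicity_pct >= 0 & props$hydrophobicity_pct <= 100))
  expect_identical(props$tm_helix, tab$tm_helix)

  # without flags the helix column is unknown, never guessed
  expect_true(all(is.na(property_table(tab)$tm_helix)))

  expect_equal(nrow(property_table(tab[0, ])), 0)
  expect_error(property_table(rbind(tab, tab[1, ])), "duplicate ids.*LP_23790")
})

test_that("helix flags round-trip through the two-column TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\thelix", "LP_23790\tyes", "PA_15330\tno"), path)
  flags <- read_helix_flags(path)
  expect_identical(flags, c(LP_23790 = TRUE, PA_15330 = FALSE))
})
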