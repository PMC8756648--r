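make_set <- function(id, peptides) sp_strain_set(id, peptides)

test_that("shared counts are pairwise intersection sizes with set sizes on the diagonal", {
  a <- make_set("A", c("MKA", "MKC", "MKD"))
  b <- make_set("B", c("MKC", "MKD", "MKE"))
  m <- shared_counts(list(a, b))
  expect_equal(m["A", "B"], 2)
  expect_equal(m["B", "A"], 2)
  expect_equal(diag(m), c(A = 3, B = 3))

  expect_equal(shared_counts(list(a, make_set("A2", a$peptides)))["A", "A2"], 3)
  expect_equal(shared_counts(list(a, make_set("Z", c("MWW", "MYY"))))["A", "Z"], 0)
  expect_error(shared_counts(list(a, make_set("A", "MKA"))), "duplicate strain ids")
  expect_error(shared_counts(list(a)), "at least 2")
})

test_that("percent-shared is the Jaccard index scaled to percent", {
  a <- make_set("A", c("MKA", "MKC", "MKD"))
  b <- make_set("B", c("MKC", "MKD", "MKE"))
  sim <- percent_shared(list(a, b))
  expect_equal(sim$percent["A", "B"], 50.0)  # 2 shared / 4 in the union
  expect_equal(diag(sim$percent), c(A = 100, B = 100))

  ident <- percent_shared(list(a, make_set("A2", a$peptides)))
  expect_equal(ident$percent["A", "A2"], 100.0)
  disj <- percent_shared(list(a, make_set("Z", c("MWW", "MYY"))))
  expect_equal(disj$percent["A", "Z"], 0.0)

  expect_warning(empty <- percent_shared(list(a, make_set("E", character(0)))),
                 "empty peptide set")
  expect_equal(empty$percent["A", "E"], 0)
  expect_equal(empty$percent["E", "E"], 100)
})

test_that("similarity matrices agree with a brute-force membership oracle", {
  set.seed(11)
  for (trial in 1:20) {
    panel <- random_panel(sample(3:10, 1), sample(5:50, 1))
    sim <- percent_shared(panel)
    expect_true(isSymmetric(sim$shared))
    expect_true(isSymmetric(sim$percent))
    for (i in seq_along(panel)) for (j in seq_along(panel)) {
      expect_equal(sim$shared[i, j],
                   oracle_shared(panel[[i]]$peptides, panel[[j]]$peptides))
      if (i != j) {
        expect_lte(sim$shared[i, j], min(length(panel[[i]]$peptides),
                                         length(panel[[j]]$peptides)))
        # stored percent is rounded to one decimal of the exact Jaccard
        expect_lt(abs(sim$percent[i, j] -
                        oracle_jaccard_pct(panel[[i]]$peptides,
                                           panel[[j]]$peptides)), 0.051)
      }
    }
  }
})

test_that("Jaccard distance satisfies the triangle inequality on random triples", {
  set.seed(23)
  for (trial in 1:30) {
    panel <- random_panel(3, sample(5:40, 1))
    d <- 1 - percent_shared(panel)$percent / 100
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-9)
    expect_lte(d[1, 2], d[1, 3] + d[3, 2] + 1e-9)
    expect_lte(d[2, 3], d[2, 1] + d[1, 3] + 1e-9)
  }
})

test_that("presence of query peptides across a panel is the membership fraction", {
  panel <- list(make_set("s1", c("MKA", "MKC")),
                make_set("s2", c("MKA", "MKD")),
                make_set("s3", c("MKA", "MKE")),
                make_set("s4", c("MKC", "MKE")))
  q <- sp_records(c("q_hit", "q_rare", "q_none"),
                  c("MKA", "MKC", "MWW"), check_met = TRUE)
  pres <- presence_table(q, panel)
  expect_equal(pres$percent[pres$id == "q_hit"], 75.0)   # 3 of 4 strains
  expect_equal(pres$percent[pres$id == "q_rare"], 50.0)
  expect_equal(pres$percent[pres$id == "q_none"], 0.0)
  expect_identical(unname(attr(pres, "presence")["q_hit", ]),
                   c(TRUE, TRUE, TRUE, FALSE))

  single <- presence_table(c(q1 = "MKA"), panel[1])
  expect_equal(single$percent, 100.0)
  expect_equal(nrow(presence_table(q[0, ], panel)), 0)
})

test_that("mean off-diagonal similarity summarises the upper triangle", {
  panel <- gen_strain_panel(3, set_size = 30, target_jaccard = 0.5, seed = 2)
  m <- mean_offdiag(percent_shared(panel))
  expect_equal(m$mean, 50.0)
  expect_equal(m$sd, 0.0)
  expect_equal(m$n_pairs, 3)

  # hand-built matrix with pairwise percents {0, 100, 50}
  sim <- structure(list(
    strains = c("a", "b", "c"),
    shared = matrix(0L, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c"))),
    percent = matrix(c(100, 0, 100, 0, 100, 50, 100, 50, 100), 3, 3,
                     dimnames = list(c("a", "b", "c"), c("a", "b", "c")))),
    class = "sp_similarity")
  m2 <- mean_offdiag(sim)
  expect_equal(m2$mean, 50)
  expect_equal(m2$sd, 50)
  expect_equal(mean_offdiag(sim, c("a", "b"))$mean, 0)
  expect_equal(sd(c(0, 100)), 70.71068, tolerance = 1e-6)
  expect_error(mean_offdiag(sim, "a"), ">= 2 strains")
})

test_that("average-linkage clustering groups planted blocks and breaks ties lexicographically", {
  # two identical strains plus one disjoint strain: the identical pair
  # (zero distance) must merge first
  sets <- list(make_set("x1", c("MKA", "MKC")),
               make_set("x2", c("MKA", "MKC")),
               make_set("y1", c("MWW", "MYY")))
  cl <- cluster_order(percent_shared(sets))
  expect_identical(sort(cl$order[1:2]), c("x1", "x2"))
  expect_identical(cl$merge[1, ], c(-1L, -2L))

  # two planted similarity blocks stay contiguous in the leaf order
  panel <- gen_strain_panel(4, set_size = 30, target_jaccard = 0.5,
                            blocks = list(c(1, 3), c(2, 4)), seed = 8)
  ord <- cluster_order(percent_shared(panel))$order
  pos <- match(sprintf("strain_%02d", 1:4), ord)
  expect_equal(abs(pos[1] - pos[3]), 1)  # block {1,3} adjacent
  expect_equal(abs(pos[2] - pos[4]), 1)  # block {2,4} adjacent

  # all pairwise distances equal: deterministic lexicographic order
  flat <- gen_strain_panel(4, set_size = 30, target_jaccard = 0.5, seed = 9)
  expect_identical(cluster_order(percent_shared(flat))$order,
                   sprintf("strain_%02d", 1:4))
})

test_that("similarity matrices round-trip through the square TSV", {
  panel <- gen_strain_panel(3, set_size = 20, target_jaccard = 0.25, seed = 4)
  sim <- percent_shared(panel)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_tsv(sim, path)
  back <- read_similarity_tsv(path)
  expect_equal(back, sim$percent)
  write_similarity_tsv(sim, path, which = "shared")
  expect_equal(read_similarity_tsv(path), sim$shared + 0)
})
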