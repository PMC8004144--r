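test_that("all 96 descriptors match brute-force oracles on random graphs", {
  specs <- expand.grid(lag = 1:8, property = c("m", "v", "e", "p"),
                       family = c("ATS", "MATS", "GATS"),
                       stringsAsFactors = FALSE)
  for (seed in 1:50) {
    g <- rand_graph(sample(4:12, 1), seed = seed)
    for (r in seq_len(nrow(specs))) {
      k <- specs$property[r]; l <- specs$lag[r]
      got <- switch(specs$family[r], ATS = ats(g, k, l),
                    MATS = mats(g, k, l), GATS = gats(g, k, l))
      want <- switch(specs$family[r], ATS = oracle_ats(g, k, l),
                     MATS = oracle_mats(g, k, l), GATS = oracle_gats(g, k, l))
      if (is.na(want)) expect_true(is.na(got))
      else expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("descriptors are invariant under atom relabeling", {
  for (seed in 1:10) {
    g <- rand_graph(sample(5:10, 1), seed = seed)
    perm <- sample(g$n_atoms)
    gp <- permute_graph(g, perm)
    for (fam in list(ats, mats, gats))
      for (k in c("m", "e"))
        for (l in c(1, 2, 4))
          expect_equal(fam(g, k, l), fam(gp, k, l), tolerance = 1e-12)
  }
})

test_that("ATS is monotone non-decreasing in any atomic property value", {
  g <- rand_graph(8, seed = 3)
  base <- ats(g, "m", 2)
  g2 <- g
  g2$props[4, "m"] <- g2$props[4, "m"] + 0.5
  expect_gte(ats(g2, "m", 2), base)
})

test_that("two-atom heteronuclear closed forms: MATS = -1, GATS = 1 at lag 1", {
  for (pr in list(c(1, 2), c(0.3, 5), c(2, 2.0001))) {
    adj <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
    props <- matrix(rep(pr, 4), 2, 4,
                    dimnames = list(NULL, c("m", "v", "e", "p")))
    g <- make_graph(adj, props)
    expect_equal(mats(g, "m", 1), -1)
    expect_equal(gats(g, "m", 1), 1)
  }
})

test_that("lags beyond the diameter give ATS 0 and flagged MATS/GATS", {
  g <- build_graph(read_structure("CCC", "smiles"))
  gp <- g; gp$props[] <- 1
  expect_equal(ats(gp, "m", 1), 2)   # two bonded pairs, unit properties
  expect_equal(ats(gp, "m", 5), 0)
  g$props[, "m"] <- c(1, 2, 1)
  expect_true(is.na(mats(gp, "m", 1)))  # zero variance -> undefined
  expect_equal(mats(g, "m", 2), oracle_mats(g, "m", 2))
  expect_true(is.na(gats(g, "m", 5)))   # no pairs at the lag
})

test_that("descriptor block has 96 deterministic columns and flags", {
  g1 <- build_graph(read_structure("CCO", "smiles"))
  g2 <- build_graph(read_structure("c1ccccc1", "smiles"))
  tbl <- descriptor_block(list(a = g1, b = g2))
  expect_equal(dim(tbl), c(2, 96))
  expect_equal(colnames(tbl)[1:3], c("ATS1m", "ATS2m", "ATS3m"))
  spec <- attr(tbl, "descriptor_spec")
  expect_equal(nrow(unique(spec)), 96)
  expect_equal(unique(spec$family), c("ATS", "MATS", "GATS"))
  # all-carbon molecule: every MATS/GATS cell undefined (constant props)
  expect_true(all(is.na(tbl["b", grepl("^MATS|^GATS", colnames(tbl))])))
  expect_true(all(is.finite(tbl["b", grepl("^ATS", colnames(tbl))])))
  # single molecule still emits the full block
  expect_equal(dim(descriptor_block(list(g1))), c(1, 96))
})

test_that("descriptor names parse and render bijectively", {
  p <- parse_descriptor_name("MATS7e")
  expect_equal(p$family, "MATS")
  expect_equal(p$lag, 7L)
  expect_equal(p$property, "e")
  expect_equal(descriptor_name(p$family, p$lag, p$property), "MATS7e")
  expect_error(parse_descriptor_name("MATS9e"), "not a valid")
  expect_error(parse_descriptor_name("XTS1m"), "not a valid")
})

test_that("as-printed audit formulas differ from the standard forms", {
  g <- rand_graph(7, seed = 5)
  expect_false(isTRUE(all.equal(mats(g, "e", 1), mats(g, "e", 1, as_printed = TRUE))))
  expect_false(isTRUE(all.equal(gats(g, "e", 1), gats(g, "e", 1, as_printed = TRUE))))
})
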