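toy_cx <- function(...) gen_toy_complex(toy_complex_spec(list(...)))

test_that("contact detection respects the 4.0 A cutoff boundary", {
  near <- toy_cx(list(resname = "LEU", resnum = 515, type = "hydrophobic",
                      distance = 3.9))
  far <- toy_cx(list(resname = "LEU", resnum = 515, type = "hydrophobic",
                     distance = 4.1))
  expect_true("C" %in% detect_contacts(near)$category)
  expect_equal(nrow(detect_contacts(far)), 0)
  # raising the cutoff only adds contacts (monotonicity)
  r40 <- detect_contacts(near, cutoff = 4.0)
  r45 <- detect_contacts(near, cutoff = 4.5)
  expect_true(all(r40$residue %in% r45$residue))
  expect_gte(nrow(r45), nrow(r40))
})

test_that("contact categories follow the atom-class rules", {
  cx <- toy_cx(list(resname = "LEU", resnum = 515, type = "hydrophobic",
                    distance = 3.5),
               list(resname = "THR", resnum = 550, type = "polar",
                    distance = 3.2))
  rc <- detect_contacts(cx)
  leu <- rc[rc$resname == "LEU", ]
  expect_setequal(leu$category, c("C", "H"))
  thr <- rc[rc$resname == "THR", ]
  expect_true(all(c("C", "P") %in% thr$category))
  expect_true(all(rc$backbone_or_sidechain == "S"))
})

test_that("hydrogen-bond criteria are enforced exactly at their boundaries", {
  hb_n <- function(...) nrow(detect_hbonds(toy_cx(list(...))))
  base <- list(resname = "SER", resnum = 512, type = "hbond_donor")
  expect_equal(hb_n(resname = "SER", resnum = 512, type = "hbond_donor",
                    distance = 2.0, donor_angle = 170, acceptor_angle = 120), 1)
  expect_equal(hb_n(resname = "SER", resnum = 512, type = "hbond_donor",
                    distance = 2.5, donor_angle = 170, acceptor_angle = 120), 1)
  expect_equal(hb_n(resname = "SER", resnum = 512, type = "hbond_donor",
                    distance = 2.6, donor_angle = 170, acceptor_angle = 120), 0)
  expect_equal(hb_n(resname = "SER", resnum = 512, type = "hbond_donor",
                    distance = 2.0, donor_angle = 119, acceptor_angle = 120), 0)
  expect_equal(hb_n(resname = "SER", resnum = 512, type = "hbond_donor",
                    distance = 2.0, donor_angle = 120, acceptor_angle = 90), 1)
  expect_equal(hb_n(resname = "SER", resnum = 512, type = "hbond_donor",
                    distance = 2.0, donor_angle = 170, acceptor_angle = 89), 0)
})

test_that("hydrogen-bond roles follow the donor side", {
  cx <- toy_cx(list(resname = "SER", resnum = 512, type = "hbond_donor",
                    distance = 2.0),
               list(resname = "TYR", resnum = 511, type = "hbond_acceptor",
                    distance = 2.1))
  hb <- detect_hbonds(cx)
  expect_equal(hb$category[hb$resname == "SER"], "D")
  expect_equal(hb$category[hb$resname == "TYR"], "A")
})

test_that("hydrogen-bond detection is invariant under rigid motion", {
  cx <- toy_cx(list(resname = "SER", resnum = 512, type = "hbond_donor",
                    distance = 2.0))
  th <- 35 * pi / 180
  rot <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  move <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
    df$x <- xyz[, 1] + 5; df$y <- xyz[, 2] - 3; df$z <- xyz[, 3] + 1
    df
  }
  cx2 <- cx
  cx2$protein <- move(cx2$protein)
  cx2$ligand$atoms <- move(cx2$ligand$atoms)
  a <- detect_hbonds(cx); b <- detect_hbonds(cx2)
  expect_equal(a$category, b$category)
  expect_equal(a$min_dist, b$min_dist, tolerance = 1e-10)
})

test_that("idealized hydroxyl placement finds the donatable orientation", {
  # serine-like OH 2.9 A from the ligand carbonyl O, no explicit H
  cx <- toy_cx(list(resname = "SER", resnum = 512, type = "hbond_donor",
                    distance = 2.0))
  cx$protein <- cx$protein[cx$protein$element != "H", ]
  hb <- detect_hbonds(cx, place_hydrogens = TRUE)
  expect_true("D" %in% hb$category)
  expect_equal(nrow(detect_hbonds(cx, place_hydrogens = FALSE)), 0)
})

test_that("occurrence percentages are exact rational counts", {
  on <- toy_cx(list(resname = "LEU", resnum = 515, type = "hydrophobic",
                    distance = 3.5))
  off <- toy_cx(list(resname = "LEU", resnum = 515, type = "hydrophobic",
                     distance = 4.3))
  agg <- aggregate_ifp(list(on, on, off, off))
  expect_equal(agg["A:LEU515", "C"], 50)
  expect_equal(agg["A:LEU515", "H"], 50)
  one <- aggregate_ifp(list(on))
  expect_true(all(one %in% c(0, 100)))
  # 82 donors in 100 complexes -> D = 82%
  don <- toy_cx(list(resname = "SER", resnum = 512, type = "hbond_donor",
                     distance = 2.0))
  no_don <- toy_cx(list(resname = "SER", resnum = 512, type = "hbond_donor",
                        distance = 2.0, donor_angle = 100))
  agg2 <- aggregate_ifp(c(rep(list(don), 82), rep(list(no_don), 18)))
  expect_equal(agg2["A:SER512", "D"], 82)
})

test_that("every hydrogen bond implies a contact for that residue", {
  cx <- toy_cx(list(resname = "SER", resnum = 512, type = "hbond_donor",
                    distance = 2.0),
               list(resname = "TYR", resnum = 511, type = "hbond_acceptor",
                    distance = 2.1))
  agg <- aggregate_ifp(list(cx))
  hb_res <- rownames(agg)[agg[, "A"] > 0 | agg[, "D"] > 0]
  expect_true(all(agg[hb_res, "C"] > 0))
})

test_that("distances resolve unique atoms at 0.1 A precision", {
  protein <- data.frame(
    chain = "A", resname = c("TYR", "SER"), resnum = c(511, 512),
    name = c("OH", "OG"), element = "O",
    x = c(0, 0), y = c(0, 0), z = c(0, 5.93), stringsAsFactors = FALSE)
  lig <- list(atoms = data.frame(name = "O1", element = "O",
                                 x = 0, y = 3, z = 0))
  cx <- complex_frame(protein, lig)
  d <- measure_distances(cx, list(
    distance_spec("D1", list(resnum = 511, atom = "OH"),
                  list(resnum = 512, atom = "OG")),
    distance_spec("zero", list(resnum = 511, atom = "OH"),
                  list(resnum = 511, atom = "OH")),
    distance_spec("d1", list(resnum = 511, atom = "OH"),
                  list(ligand = TRUE, atom = "O1"))))
  expect_equal(unname(d["D1"]), 5.9)
  expect_equal(unname(d["zero"]), 0)
  expect_equal(unname(d["d1"]), 3)
  expect_error(
    measure_distances(cx, list(distance_spec("bad", list(atom = "OH"),
                                             list(atom = "OO")))),
    "bad")
  protein2 <- rbind(protein, protein[1, ])
  cx2 <- complex_frame(protein2, lig)
  expect_error(
    measure_distances(cx2, list(distance_spec("amb",
                                              list(resnum = 511, atom = "OH"),
                                              list(ligand = TRUE, atom = "O1")))),
    "ambiguous")
})

test_that("antagonist rule verdicts cover the pass, fail and partial cases", {
  ok <- antagonist_rule(c(D1 = 9, D2 = 8, D3 = 7), c(d1 = 6, d2 = 5, d3 = 4))
  expect_true(ok$compatible)
  expect_true(all(ok$pairs$pass))
  # the agonist-bound pattern: third pair inverted
  bad <- antagonist_rule(c(D1 = 9, D2 = 8, D3 = 5), c(d1 = 6, d2 = 5, d3 = 6))
  expect_false(bad$compatible)
  expect_equal(bad$pairs$pass, c(TRUE, TRUE, FALSE))
  # series A supplies only d1
  partial <- antagonist_rule(c(D1 = 9, D2 = 8, D3 = 7), c(d1 = 5.9))
  expect_true(partial$compatible)
  expect_equal(nrow(partial$pairs), 1)
  expect_error(antagonist_rule(c(D1 = 9), c(d2 = 1)), "no matching")
})
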