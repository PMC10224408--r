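fake_panel <- function(id = "x", mw = 300, mlogp = 2, lipinski_no = 5,
                       lipinski_nhoh = 2, wlogp = 2,
                       molar_refractivity = 80, total_atoms = 40,
                       rotatable_bonds = 5, tpsa = 80, xlogp = 2, rings = 2,
                       carbons = 15, heteroatoms = 5, hba = 5, hbd = 2) {
  tibble::tibble(
    id = id, smiles = NA_character_, mw = mw, mlogp = mlogp,
    lipinski_no = lipinski_no, lipinski_nhoh = lipinski_nhoh, wlogp = wlogp,
    molar_refractivity = molar_refractivity, total_atoms = total_atoms,
    rotatable_bonds = rotatable_bonds, tpsa = tpsa, xlogp = xlogp,
    rings = rings, carbons = carbons, heteroatoms = heteroatoms,
    hba = hba, hbd = hbd
  )
}

test_that("printed bounds are inclusive: the boundary panel passes Lipinski", {
  p <- fake_panel(mw = 500, mlogp = 4.15, lipinski_no = 10,
                  lipinski_nhoh = 5)
  v <- count_rule_violations(evaluate_rules(p))
  expect_equal(v$lipinski_violations, 0L)

  # one unit over any bound breaks it
  for (tweak in list(c(mw = 500.01), c(mlogp = 4.16), c(lipinski_no = 11),
                     c(lipinski_nhoh = 6))) {
    args <- as.list(tweak)
    p2 <- do.call(fake_panel, args)
    v2 <- count_rule_violations(evaluate_rules(p2))
    expect_equal(v2$lipinski_violations, 1L, info = names(tweak))
  }
})

test_that("Muegge strict counts are strict: 4 carbons or 1 heteroatom violate", {
  v <- count_rule_violations(evaluate_rules(fake_panel(carbons = 4)))
  expect_equal(v$muegge_violations, 1L)
  v <- count_rule_violations(evaluate_rules(fake_panel(carbons = 5,
                                                       heteroatoms = 1)))
  expect_equal(v$muegge_violations, 1L)
  v <- count_rule_violations(evaluate_rules(fake_panel()))
  expect_equal(v$muegge_violations, 0L)
})

test_that("benzene's panel violates the expected Ghose and Muegge bounds", {
  p <- compute_descriptors(tibble::tibble(id = "benzene",
                                          smiles = "c1ccccc1"))
  long <- evaluate_rules(p)
  failed <- long[!long$pass, c("rule", "field")]
  expect_true(all(c("mw", "total_atoms") %in%
                    failed$field[failed$rule == "ghose"]))
  expect_true(all(c("mw", "heteroatoms") %in%
                    failed$field[failed$rule == "muegge"]))
})

test_that("Lipinski violations match a four-line brute-force check", {
  set.seed(7)
  for (k in 1:25) {
    p <- fake_panel(mw = runif(1, 100, 700), mlogp = runif(1, -2, 6),
                    lipinski_no = sample(0:14, 1),
                    lipinski_nhoh = sample(0:8, 1))
    v <- count_rule_violations(evaluate_rules(p))
    brute <- (p$mw > 500) + (p$mlogp > 4.15) + (p$lipinski_no > 10) +
      (p$lipinski_nhoh > 5)
    expect_equal(v$lipinski_violations, as.integer(brute))
  }
})

test_that("increasing MW never lowers a violation count above the lower bounds", {
  # every rule's MW lower bound sits at or below 200, so on the 200+ range
  # violation counts must be nondecreasing in MW
  mws <- c(200, 250, 360, 481, 501, 550, 601, 650)
  v <- count_rule_violations(evaluate_rules(
    fake_panel(id = as.character(mws), mw = mws)))
  v <- v[match(as.character(mws), v$id), ]
  for (col in grep("_violations", names(v), value = TRUE)) {
    expect_true(all(diff(v[[col]]) >= 0), info = col)
  }
})

test_that("rule evaluation is order-free and deterministic", {
  p <- fake_panel(mw = 550, tpsa = 160)
  b <- rule_bounds()
  r1 <- count_rule_violations(evaluate_rules(p, b))
  r2 <- count_rule_violations(evaluate_rules(p, b[rev(seq_len(nrow(b))), ]))
  expect_identical(r1, r2)
})

test_that("indeterminate descriptors are excluded from counts with warning", {
  p <- fake_panel(mlogp = NA_real_, mw = 600)
  expect_warning(long <- evaluate_rules(p), "indeterminate")
  v <- count_rule_violations(long)
  expect_equal(v$lipinski_violations, 1L)  # only the MW criterion counts
})

test_that("rule bound overrides replace individual criteria", {
  b <- rule_bounds(list(lipinski.mw = c(-Inf, 450)))
  v <- count_rule_violations(evaluate_rules(fake_panel(mw = 470), b))
  expect_equal(v$lipinski_violations, 1L)
  expect_error(rule_bounds(list(nope.mw = c(0, 1))), "unknown rule bound")
})

test_that("CNS MPO sums six unit desirabilities", {
  best <- cns_mpo(tibble::tibble(clogp = 2, clogd = 1, mw = 300, tpsa = 70,
                                 hbd = 0, basic_pka = 7))
  expect_equal(best$cns_mpo, 6)
  worst <- cns_mpo(tibble::tibble(clogp = 6, clogd = 5, mw = 600, tpsa = 10,
                                  hbd = 5, basic_pka = 11))
  expect_equal(worst$cns_mpo, 0)
  # linear ramp: clogp 4 sits halfway down the 3 -> 5 ramp
  mid <- cns_mpo(tibble::tibble(clogp = 4, clogd = 1, mw = 300, tpsa = 70,
                                hbd = 0, basic_pka = 7))
  expect_equal(mid$cns_mpo, 5.5)
  expect_equal(mid$d_clogp, 0.5)
})

test_that("CNS MPO components stay in [0,1] and missing inputs poison the total", {
  set.seed(11)
  x <- tibble::tibble(clogp = runif(20, -2, 8), clogd = runif(20, -2, 6),
                      mw = runif(20, 100, 700), tpsa = runif(20, 0, 250),
                      hbd = sample(0:8, 20, TRUE),
                      basic_pka = runif(20, 3, 12))
  m <- cns_mpo(x)
  comp <- as.matrix(m[, startsWith(names(m), "d_")])
  expect_true(all(comp >= 0 & comp <= 1))
  expect_equal(m$cns_mpo, rowSums(comp))
  x$clogd[1] <- NA
  expect_true(is.na(cns_mpo(x)$cns_mpo[1]))
})

test_that("bioactivity interpretation follows the printed thresholds", {
  r <- interpret_bioactivity(c(0.87, 0.5, 0.21, 0.2, 0.01, 0, -0.5, -0.51))
  expect_equal(r$category,
               c("active", "active", "active", "active", "active",
                 "moderate", "moderate", "inactive"))
  expect_equal(r$highlight,
               c("double_star", "star", "star", "none", "none", "none",
                 "none", "none"))
})
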