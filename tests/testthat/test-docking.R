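test_that("Ki formula behaves as printed", {
  expect_equal(ki_from_dg(0), 1)
  # independent closed-form evaluation at the printed constants
  expect_equal(ki_from_dg(-8.1), 2.7182^(-8100 / (1.98719 * 298.15)),
               tolerance = 1e-12)
  expect_equal(ki_from_dg(-8.1), 1.1551e-6, tolerance = 1e-3)
  # strictly increasing in dg
  expect_true(ki_from_dg(-6.8) > ki_from_dg(-7.6))
  expect_true(all(diff(ki_from_dg(seq(-12, 2, by = 0.5))) > 0))
  # truncating the base to 2.7182 shifts the result by about 3e-5 per unit
  # of exponent, so by under 0.15% anywhere in |dg| <= 20
  dg <- seq(-20, 20, by = 2.5)
  exact <- ki_from_dg(dg, dock_constants(e_base = exp(1)))
  trunc <- ki_from_dg(dg)
  expect_true(all(abs(trunc / exact - 1) < 1.5e-3))
})

test_that("FullFitness averages the most favourable 30% of element energies", {
  expect_equal(fullfitness(-5), -5)
  expect_equal(fullfitness(seq(-10, -1)), mean(c(-10, -9, -8)))
  e <- c(-3.2, -9.9, -1.1, -7.4)
  expect_equal(fullfitness(e), fullfitness(sample(e)))
  expect_error(fullfitness(numeric()), "empty")
})

test_that("FullFitness matches a sort-and-average oracle exhaustively to N = 12", {
  set.seed(21)
  for (n in 1:12) {
    e <- rnorm(n, -2000, 5)
    k <- floor(0.3 * n + 0.5)        # half-up rounding, floor(x + .5)
    if (k < 1) k <- 1
    oracle <- mean(sort(e)[1:k])
    expect_equal(fullfitness(e), oracle, info = paste("n =", n))
  }
})

test_that("FullFitness is translation-equivariant", {
  e <- rnorm(9, -2100, 4)
  expect_equal(fullfitness(e + 17.3), fullfitness(e) + 17.3)
})

test_that("binding-site selection takes the lowest binding free energy", {
  tab <- tibble::tibble(cluster = c(1, 6, 33), dg = c(-8.1, -7.6, -6.8))
  expect_equal(select_binding_site(tab), 1)
  expect_equal(select_binding_site(tab[2, ]), 6)
  tie <- tibble::tibble(cluster = c(4, 2), dg = c(-5, -5))
  expect_message(best <- select_binding_site(tie), "tie")
  expect_equal(best, 2)
  expect_error(select_binding_site(tab[0, ]), "no clusters")
})

test_that("cluster tables aggregate energies into FullFitness and Ki", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    cluster = rep(c(1, 2), each = 10),
    element = rep(1:10, 2),
    energy = c(seq(-10, -1), seq(-20, -11)),
    dg = rep(c(-8.1, -7.6), each = 10)
  ), f)
  tab <- read_cluster_table(f)
  expect_equal(tab$fullfitness, c(-9, -19))
  expect_equal(tab$ki, ki_from_dg(c(-8.1, -7.6)))
  expect_equal(select_binding_site(tab), 1)
})

test_that("identical poses give zero lower and upper RMSD bounds", {
  a <- make_pose(c("C", "C", "O"), cbind(c(0, 1.5, 3), 0, 0))
  r <- rmsd_symmetry(a, a)
  expect_equal(r$rmsd_lb, 0)
  expect_equal(r$rmsd_ub, 0)
})

test_that("swapping same-element atoms zeroes the lower bound only", {
  a <- make_pose(c("C", "C", "O"), cbind(c(0, 1.5, 3), 0, 0))
  b <- a[c(2, 1, 3), ]
  r <- rmsd_symmetry(a, b)
  expect_equal(r$rmsd_lb, 0)
  expect_gt(r$rmsd_ub, 0)
  # the max symmetrises
  expect_equal(rmsd_symmetry(b, a)$rmsd_lb, r$rmsd_lb)
})

test_that("the 1-D toy example reproduces the hand-computed bound", {
  a <- make_pose(c("C", "C"), cbind(c(0, 2), 0, 0))
  b <- make_pose(c("C", "C"), cbind(c(0, 0.1), 0, 0))
  r <- rmsd_symmetry(a, b)
  # directed a->b: min distances 0 and 1.9; b->a: 0 and 0.1
  expect_equal(r$rmsd_lb, sqrt((0^2 + 1.9^2) / 2), tolerance = 1e-6)
  expect_equal(round(r$rmsd_lb, 4), 1.3435)
})

test_that("rmsd lower bound matches the brute-force oracle on random poses", {
  set.seed(31)
  for (k in 1:60) {
    n <- sample(2:6, 1)
    elems <- sample(c("C", "N", "O"), n, replace = TRUE)
    a <- make_pose(elems, matrix(runif(3 * n, 0, 5), ncol = 3))
    b <- make_pose(sample(elems), matrix(runif(3 * n, 0, 5), ncol = 3))
    r <- rmsd_symmetry(a, b)
    expect_equal(r$rmsd_lb, oracle_rmsd_lb(a, b), tolerance = 1e-10)
    expect_equal(rmsd_symmetry(b, a)$rmsd_lb, r$rmsd_lb, tolerance = 1e-10)
    if (identical(a$element, b$element)) {
      expect_lte(r$rmsd_lb, r$rmsd_ub + 1e-10)
    }
  }
})

test_that("element-composition mismatches are rejected; hydrogens ignored", {
  a <- make_pose(c("C", "O"), cbind(c(0, 1.5), 0, 0))
  b <- make_pose(c("C", "N"), cbind(c(0, 1.5), 0, 0))
  expect_error(rmsd_symmetry(a, b), "element composition")
  withH <- make_pose(c("C", "O", "H"), cbind(c(0, 1.5, 2.3), 0, 0))
  expect_equal(rmsd_symmetry(a[, ], withH)$rmsd_lb, 0)
})

test_that("polar contacts respect the inclusive distance window", {
  lig <- make_pose("O", cbind(0, 0, 0))
  rec <- make_pose("N", cbind(0, 0, 2))
  rec$resname <- "THR"; rec$resno <- 223L
  hits <- polar_contacts(lig, rec)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$distance, 2)
  expect_equal(hits$resname, "THR")

  expect_equal(nrow(polar_contacts(lig, make_pose("N", cbind(0, 0, 3)))), 0)
  expect_equal(nrow(polar_contacts(lig, make_pose("N", cbind(0, 0, 2.81)))), 1)
  expect_equal(nrow(polar_contacts(lig, make_pose("N", cbind(0, 0, 1.49)))), 1)
  # carbon partners are not polar contacts
  expect_equal(nrow(polar_contacts(lig, make_pose("C", cbind(0, 0, 2)))), 0)
})

test_that("polar hydrogens count as donors, apolar hydrogens do not", {
  # H bonded to O (0.96 A) vs H bonded to C
  lig <- make_pose(c("O", "H", "C", "H"),
                   rbind(c(0, 0, 0), c(0.96, 0, 0),
                         c(5, 0, 0), c(6.09, 0, 0)))
  rec <- make_pose(c("N", "N"), rbind(c(0.96, 0, 2), c(6.09, 0, 2)))
  hits <- polar_contacts(lig, rec)
  expect_true(any(hits$ligand_element == "H" & hits$distance == 2))
  # the carbon-bound hydrogen at exactly 2 A contributes nothing
  expect_false(any(hits$ligand_name == "H4"))
})

test_that("active torsions follow the standard rotatable-bond pattern", {
  expect_equal(count_active_torsions("CC")$n, 0)    # terminal bond
  expect_equal(count_active_torsions("CCCC")$n, 1)  # single central bond
  # phosphorus-embedded fragment: both C-P single bonds rotate
  tor <- count_active_torsions("CCP(=O)(O)CC")
  expect_equal(tor$n, 2)
  expect_setequal(paste0(tor$bonds$element1, tor$bonds$element2),
                  c("CP", "PC"))
  expect_equal(count_active_torsions("c1ccccc1")$n, 0)  # ring bonds excluded
})

test_that("pose files round-trip through the PDB subset reader", {
  fx <- gen_dock_fixtures(fixture_spec())
  paths <- write_dock_fixtures(fx, withr::local_tempdir())
  p <- read_poses(paths$cluster1)
  expect_equal(max(p$model), fixture_spec()$dock$elements_per_cluster)
  m1 <- dplyr::filter(p, model == 1)
  orig <- dplyr::filter(fx$poses, cluster == 1, element_id == 1)
  expect_equal(m1$element, orig$element)
  expect_equal(m1$x, orig$x, tolerance = 1e-3)  # PDB stores 3 decimals
})

test_that("minimal PDBQT poses parse with charge columns ignored", {
  f <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00    +0.123 C ",
    "ATOM      2  O1  LIG A   1       1.500   0.000   0.000  1.00  0.00    -0.345 OA",
    "ENDMDL"
  ), f)
  p <- read_poses(f)
  expect_equal(p$element, c("C", "O"))
  expect_equal(p$x, c(0, 1.5))
})
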