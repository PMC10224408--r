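# Frozen reference values for the contribution methods (Wildman-Crippen
# logP/MR, Ertl TPSA, average-mass MW), computed independently with a
# second cheminformatics toolkit's implementation of the same published
# parameter tables and frozen here.
crippen_reference <- function() {
  read.csv(text = "name,smiles,wlogp,mr,tpsa,mw
ethanol,CCO,-0.0014,12.7598,20.23,46.07
benzene,c1ccccc1,1.6866,26.4420,0.00,78.11
toluene,Cc1ccccc1,1.9950,31.1790,0.00,92.14
glutamic_acid,N[C@@H](CCC(O)=O)C(O)=O,-0.7369,32.4810,100.62,147.13
paracetamol,CC(=O)Nc1ccc(O)cc1,1.3506,42.4105,49.33,151.16
aspirin,CC(=O)Oc1ccccc1C(=O)O,1.3101,44.7103,63.60,180.16
caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C,-1.0293,51.1960,61.82,194.19
ibuprofen,CC(C)Cc1ccc(C(C)C(=O)O)cc1,3.0732,61.0348,37.30,206.28
naproxen,COc1ccc2cc(C(C)C(=O)O)ccc2c1,3.0365,66.5508,46.53,230.26
nicotine,CN1CCC[C@H]1c1cccnc1,1.8483,48.8420,16.13,162.24
phenol,Oc1ccccc1,1.3922,28.1068,20.23,94.11
pyridine,c1ccncc1,1.0816,24.2370,12.89,79.10
chlorobenzene,Clc1ccccc1,2.3400,31.4520,0.00,112.56
glycine,NCC(O)=O,-0.9703,16.6902,63.32,75.07
cyclohexane,C1CCCCC1,2.3406,27.7020,0.00,84.16
hexane,CCCCCC,2.5866,29.8160,0.00,86.18
anisole,COc1ccccc1,1.6952,32.9940,9.23,108.14
benzamide,NC(=O)c1ccccc1,0.7855,34.9599,43.09,121.14
furan,c1ccoc1,1.2796,18.7080,13.14,68.07
alanine,CC(N)C(O)=O,-0.5818,21.2852,63.32,89.09",
  stringsAsFactors = FALSE)
}

test_that("panel reproduces the published contribution methods on the fixture set", {
  ref <- crippen_reference()
  p <- compute_descriptors(tibble::tibble(id = ref$name, smiles = ref$smiles))
  expect_equal(p$wlogp, ref$wlogp, tolerance = 0.01)
  expect_equal(p$molar_refractivity, ref$mr, tolerance = 0.01)
  expect_equal(p$tpsa, ref$tpsa, tolerance = 0.01)
  expect_equal(p$mw, ref$mw, tolerance = 0.01)
})

test_that("simple molecules give hand-checkable counts", {
  p <- compute_descriptors(tibble::tibble(
    id = c("ethanol", "benzene", "glu"),
    smiles = c("CCO", "c1ccccc1", "N[C@@H](CCC(O)=O)C(O)=O")
  ))
  # ethanol: 46.07 Da, one donor, no rotatable bonds by the standard pattern
  expect_equal(p$mw[1], 46.07, tolerance = 0.01)
  expect_equal(p$hbd[1], 1L)
  expect_equal(p$rotatable_bonds[1], 0L)
  expect_equal(p$lipinski_no[1], 1L)
  expect_equal(p$lipinski_nhoh[1], 1L)
  # benzene: all-aromatic carbocycle, no polar atoms
  expect_equal(p$heavy_aromatic_atoms[2], 6L)
  expect_equal(p$fraction_csp3[2], 0)
  expect_equal(p$tpsa[2], 0)
  expect_equal(p$rings[2], 1L)
  # glutamic acid: Ertl fragment sums, 2 carboxyls + primary amine
  expect_equal(p$tpsa[3], 100.62, tolerance = 0.01)
  expect_equal(p$rotatable_bonds[3], 4L)
  expect_equal(p$lipinski_no[3], 5L)   # 1 N + 4 O
  expect_equal(p$lipinski_nhoh[3], 4L) # NH2 + 2 OH
})

test_that("homologation adds one CH2 mass unit and never loses torsions", {
  chain <- vapply(2:8, function(k) paste(rep("C", k), collapse = ""),
                  character(1))
  p <- compute_descriptors(chain)
  expect_equal(diff(p$mw), rep(14.027, 6), tolerance = 0.01)
  expect_true(all(diff(p$rotatable_bonds) >= 0))
  expect_true(all(diff(p$heavy_atoms) == 1L))
})

test_that("atom-count invariants hold across a mixed set", {
  smiles <- c("CCO", "c1ccccc1", "CC(=O)Nc1ccc(O)cc1", "NCC(O)=O",
              "CN1CCC[C@H]1c1cccnc1", "Clc1ccccc1")
  p <- compute_descriptors(smiles)
  expect_true(all(p$heavy_aromatic_atoms <= p$heavy_atoms))
  expect_true(all(p$heavy_atoms <= p$total_atoms))
  expect_true(all(p$fraction_csp3 >= 0 & p$fraction_csp3 <= 1))
  expect_true(all(p$tpsa >= 0))
  expect_equal(p$heteroatoms, p$heavy_atoms - p$carbons)
})

test_that("xlogp is proxied by wlogp unless supplied externally", {
  p <- compute_descriptors("CCO")
  expect_equal(p$xlogp, p$wlogp)
  expect_true(p$xlogp_proxied)
  p2 <- compute_descriptors(tibble::tibble(id = "e", smiles = "CCO",
                                           xlogp = -0.32))
  expect_equal(p2$xlogp, -0.32)
  expect_false(p2$xlogp_proxied)
})

test_that("unparseable structures fail loudly", {
  expect_error(suppressWarnings(compute_descriptors("C1CC")), "unparseable")
})
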