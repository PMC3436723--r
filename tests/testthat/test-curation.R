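test_that("small-component filter drops counter-ions below the cutoff", {
  benz_cl <- mol_combine(mol_benzene(), npl_mol("Cl", charge = -1L))
  kept <- filter_small_components(benz_cl, 6L)
  expect_equal(mol_n_atoms(kept), 6L)
  expect_true(all(kept$element == "C"))

  ten <- npl_mol(rep("C", 10), bonds = bond_df(1,2,1, 2,3,1, 3,4,1, 4,5,1,
                                               5,6,1, 6,7,1, 7,8,1, 8,9,1,
                                               9,10,1))
  expect_identical(graph_profile(filter_small_components(ten, 6L)),
                   graph_profile(ten))

  two_small <- mol_combine(
    npl_mol(rep("C", 5), bonds = bond_df(1,2,1, 2,3,1, 3,4,1, 4,5,1)),
    npl_mol(rep("C", 5), bonds = bond_df(1,2,1, 2,3,1, 3,4,1, 4,5,1))
  )
  expect_null(filter_small_components(two_small, 6L))
})

test_that("element whitelist keeps As/Se organics but rejects metals", {
  fe_complex <- npl_mol(c(rep("C", 6), "Fe"),
                        bonds = bond_df(1,2,1, 2,3,1, 3,4,1, 4,5,1, 5,6,1,
                                        6,1,1, 1,7,1))
  expect_false(filter_elements(fe_complex))
  seleno <- parse_smiles("C[Se]CCC(N)C(=O)O")  # selenomethionine
  expect_true(filter_elements(seleno))
  expect_true(filter_elements(mol_ethanol()))
})

test_that("ring-sugar detection matches the pyranose definition", {
  hits <- find_ring_sugars(mol_glucose())
  expect_length(hits, 1L)
  expect_equal(hits[[1]], 1:6)  # the ring atoms
  expect_length(find_ring_sugars(mol_cyclohexane()), 0L)
  thf <- npl_mol(c("O", rep("C", 4)),
                 bonds = bond_df(1,2,1, 2,3,1, 3,4,1, 4,5,1, 5,1,1))
  expect_length(find_ring_sugars(thf), 0L)
})

test_that("linear-sugar detection needs three oxygenated chain carbons", {
  glycerol <- parse_smiles("OCC(O)CO")
  expect_length(find_linear_sugars(glycerol), 1L)
  hexane <- parse_smiles("CCCCCC")
  expect_length(find_linear_sugars(hexane), 0L)
  glycol <- parse_smiles("OCCO")
  expect_length(find_linear_sugars(glycol), 0L)
})

test_that("sugar removal leaves the aglycone and deletes the bridge oxygen", {
  aglycone <- remove_sugars(mol_phenyl_glucoside())
  expect_equal(mol_n_atoms(aglycone), 6L)
  expect_true(all(aglycone$element == "C"))

  taxane_like <- small_fixture_set(1, seed = 3)$mol[[1]]
  no_sugar <- remove_sugars(taxane_like)
  if (length(find_ring_sugars(taxane_like)) == 0 &&
      length(find_linear_sugars(taxane_like)) == 0) {
    expect_identical(graph_profile(no_sugar), graph_profile(taxane_like))
  }

  expect_null(remove_sugars(mol_glucose()))
})

test_that("curate composes the rules and accounts for every uuid", {
  benz_cl <- mol_combine(mol_benzene("m1"), npl_mol("Cl", charge = -1L))
  fe <- npl_mol(c(rep("C", 6), "Fe"),
                bonds = bond_df(1,2,1, 2,3,1, 3,4,1, 4,5,1, 5,6,1, 6,1,1, 1,7,1))
  fe$uuid <- "m2"
  glc <- mol_glucose("m3")
  mols <- tibble::tibble(uuid = c("m1", "m2", "m3"),
                         name = NA_character_,
                         mol = list(benz_cl, fe, glc))
  out <- curate(mols)
  expect_equal(out$kept$uuid, "m1")
  expect_equal(mol_n_atoms(out$kept$mol[[1]]), 6L)
  expect_equal(out$stats$n[out$stats$reason == "metal_element"], 1L)
  expect_equal(out$stats$n[out$stats$reason == "empty_after_curation"], 1L)
  expect_setequal(c(out$kept$uuid, out$discarded$uuid), mols$uuid)

  empty <- curate(tibble::tibble(uuid = character(), name = character(),
                                 mol = list()))
  expect_equal(nrow(empty$kept), 0L)
  expect_true(all(empty$stats$n == 0L))
})

test_that("curation is idempotent and never violates its own postconditions", {
  cfg <- fixture_config(seed = 11, n_np = 30, n_sm = 30,
                        counterion_fraction = 0.5, metal_fraction = 0.2,
                        sugar_fraction = 0.5)
  mols <- rbind(generate_np_like(cfg), generate_synthetic_like(cfg))
  out <- curate(mols)
  config <- curation_config()
  total_in <- sum(vapply(mols$mol, mol_n_atoms, integer(1)))
  total_kept <- sum(vapply(out$kept$mol, mol_n_atoms, integer(1)))
  expect_lte(total_kept, total_in)
  for (m in out$kept$mol) {
    expect_true(all(m$element %in% config$allowed_elements))
    expect_gte(mol_n_atoms(m), config$min_fragment_atoms)
    expect_equal(max(mol_components(m)), 1L)
  }
  expect_setequal(c(unique(out$kept$uuid), out$discarded$uuid), mols$uuid)
  expect_equal(length(intersect(out$kept$uuid, out$discarded$uuid)), 0L)

  again <- curate(out$kept)
  expect_equal(nrow(again$kept), nrow(out$kept))
  expect_equal(nrow(again$discarded), 0L)
  for (i in seq_len(nrow(out$kept))) {
    expect_identical(graph_profile(again$kept$mol[[i]]),
                     graph_profile(out$kept$mol[[i]]))
  }
})

test_that("tidy() and glance() summarise a curation outcome", {
  out <- curate(edge_cases())
  td <- tidy(out)
  expect_setequal(td$uuid, edge_cases()$uuid)
  expect_equal(td$n_fragments[td$uuid == "edge-sugar-bridge"], 2L)
  gl <- glance(out)
  expect_equal(gl$n_input, 6L)
  expect_equal(gl$n_kept + gl$n_discarded, 6L)
})
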