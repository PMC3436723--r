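test_that("SDF reading assigns distinct UUIDs and keeps file order", {
  mols <- small_fixture_set(3)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(mols["mol"], path)  # drop uuid column: fresh ids on read
  got <- read_molecules(path, "sdf")
  expect_equal(nrow(got), 3L)
  expect_equal(length(unique(got$uuid)), 3L)
  expect_equal(attr(got, "skipped"), 0L)
})

test_that("an NPL_UUID data field survives a round trip", {
  mols <- small_fixture_set(5)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(mols, path)
  got <- read_molecules(path, "sdf")
  expect_identical(got$uuid, mols$uuid)
})

test_that("unparsable SMILES lines are skipped, not fatal", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "garbage("), path)
  got <- suppressMessages(read_molecules(path, "smiles"))
  expect_equal(nrow(got), 1L)
  expect_equal(attr(got, "skipped"), 1L)
  expect_equal(sort(got$mol[[1]]$element), c("C", "C", "O"))
})

test_that("an empty or fully unparsable file is an empty-input error", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(character(), path)
  expect_error(read_molecules(path, "sdf"), class = "npl_empty_input")
  expect_error(read_molecules("does/not/exist.sdf"), class = "npl_input_error")
})

test_that("V3000 connection tables are rejected with a clear error", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("t", "", "", "  0  0  0  0  0  0  0  0  0  0999 V3000",
               "M  END", "$$$$"), path)
  expect_error(read_molecules(path, "sdf"), regexp = "V3000",
               class = "npl_input_error")
})

test_that("formal charges round-trip through M CHG lines", {
  nitro_arene <- parse_smiles("O=[N+]([O-])c1ccccc1")
  nitro_arene$uuid <- "q"
  path <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(list(nitro_arene), path)
  got <- read_molecules(path, "sdf")$mol[[1]]
  expect_equal(sort(got$charge), sort(nitro_arene$charge))
  expect_equal(sum(got$charge == 1L), 1L)
  expect_equal(sum(got$charge == -1L), 1L)
})

test_that("benzene survives an SDF round trip with ring intact", {
  path <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(list(mol_benzene()), path)
  got <- read_molecules(path, "sdf")$mol[[1]]
  expect_equal(mol_n_atoms(got), 6L)
  expect_equal(length(got$bond_a), 6L)
  expect_true(all(got$element == "C"))
  expect_true(all(got$aromatic))
  expect_setequal(got$bond_order, c(1L, 2L))
})

test_that("SDF round trip preserves the molecular graph for seeded fixtures", {
  mols <- small_fixture_set(50)
  path <- withr::local_tempfile(fileext = ".sdf")
  expect_equal(write_molecules(mols, path), 50L)
  got <- read_molecules(path, "sdf")
  expect_equal(nrow(got), 50L)
  for (i in seq_len(50)) {
    expect_identical(graph_profile(got$mol[[i]]),
                     graph_profile(mols$mol[[i]]))
  }
})

test_that("SMILES writing produces lines OpenBabel can read back", {
  mols <- small_fixture_set(5)
  path <- withr::local_tempfile(fileext = ".smi")
  write_molecules(mols, path, format = "smiles")
  got <- read_molecules(path, "smiles")
  expect_equal(nrow(got), 5L)
  for (i in seq_len(5)) {
    expect_identical(graph_profile(got$mol[[i]])$atoms,
                     graph_profile(mols$mol[[i]])$atoms)
  }
})

test_that("writing zero records yields an empty file and returns 0", {
  path <- withr::local_tempfile(fileext = ".sdf")
  expect_equal(write_molecules(list(), path), 0L)
  expect_true(file.exists(path))
  expect_error(read_molecules(path, "sdf"), class = "npl_empty_input")
})

test_that("signature files round-trip byte-identically", {
  sigs <- tibble::tibble(
    uuid = sprintf("u%02d", 1:10),
    signature = sprintf("[C,h%d]", 0:9)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  expect_equal(write_signatures(sigs, path), 10L)
  expect_identical(read_signatures(path), sigs)
  first <- readBin(path, "raw", file.size(path))
  write_signatures(read_signatures(path), path)
  expect_identical(readBin(path, "raw", file.size(path)), first)
})

test_that("malformed signature lines are skipped; empty file is valid", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("u1\t[C,h4]", "no-tab-here"), path)
  got <- suppressMessages(read_signatures(path))
  expect_equal(nrow(got), 1L)
  writeLines(character(), path)
  expect_equal(nrow(read_signatures(path)), 0L)
  writeLines("only bad", path)
  expect_error(read_signatures(path), class = "npl_input_error")
})

test_that("score files keep six decimals and round-trip", {
  sc <- tibble::tibble(uuid = c("a", "b"), np_likeness = c(0.4620981, -1.25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scores(sc, path)
  lines <- readLines(path)
  expect_match(lines[1], "^a\t0\\.462098$")
  got <- read_scores(path)
  expect_equal(got$np_likeness, c(0.462098, -1.25), tolerance = 1e-12)
})

test_that("UUIDs are unique, RFC-4122 shaped, and seed-reproducible", {
  ids <- npl_uuid(200)
  expect_equal(length(unique(ids)), 200L)
  expect_true(all(grepl(
    "^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-[89ab][0-9a-f]{3}-[0-9a-f]{12}$",
    ids
  )))
  expect_identical(npl_uuid(5, seed = 9), npl_uuid(5, seed = 9))
  expect_false(any(npl_uuid(5, seed = 9) %in% npl_uuid(5, seed = 10)))
})
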