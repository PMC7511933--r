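# parsing the substrate table and enumerating expected species

test_that("packaged library parses into the documented panel composition", {
  lib <- table1_library()
  expect_s3_class(lib, "substrate_library")
  expect_identical(nrow(lib), 20L)
  expect_identical(sum(lib$enzyme_class == "protease"), 14L)
  expect_identical(sum(lib$enzyme_class == "kinase"), 4L)
  expect_identical(sum(lib$enzyme_class == "phosphatase"), 2L)
})

test_that("header-only file loads as an empty library", {
  tmp <- tempfile(fileext = ".tsv")
  header <- readLines(table1_path(), n = 1)
  writeLines(header, tmp)
  lib <- load_library(tmp)
  expect_identical(nrow(lib), 0L)
})

test_that("malformed libraries are rejected with informative errors", {
  lines <- readLines(table1_path())

  bad_residue <- lines
  bad_residue[2] <- sub("GTPGPQGLLGAPGI", "GTPGPQGBLGAPGI", bad_residue[2])
  tmp1 <- tempfile(fileext = ".tsv")
  writeLines(bad_residue, tmp1)
  expect_error(load_library(tmp1), "id=1.*alphabet|alphabet.*id=1")

  no_cleavage <- lines
  no_cleavage[2] <- sub("\t7\t", "\t\t", no_cleavage[2])
  tmp2 <- tempfile(fileext = ".tsv")
  writeLines(no_cleavage, tmp2)
  expect_error(load_library(tmp2), "cleavage_index")

  tmp3 <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsequence", "1\tGG"), tmp3)
  expect_error(load_library(tmp3), "missing column")

  expect_error(load_library(tempfile()), "not found")
})

test_that("protease substrates split into the published fragments", {
  lib <- table1_library()
  sp <- enumerate_expected_species(lib[lib$id == 1, ])
  expect_identical(sp$sequence[sp$role == "cleavage_product_1"], "GTPGPQG")
  expect_identical(sp$sequence[sp$role == "cleavage_product_2"], "LLGAPGI")
  m <- stats::setNames(sp$mass_average, sp$role)
  water <- residue_mass_table()$water_average
  expect_equal(m[["cleavage_product_1"]] + m[["cleavage_product_2"]] - water,
               m[["substrate"]], tolerance = 1e-12)
})

test_that("kinase and phosphatase products differ by the phospho delta", {
  lib <- table1_library()
  reg <- modification_registry()
  hpo3 <- reg$delta_average[reg$name == "phospho"]

  kin <- enumerate_expected_species(lib[lib$id == 15, ])
  expect_equal(kin$mass_average[kin$role == "phosphorylated_product"] -
                 kin$mass_average[kin$role == "substrate"], hpo3,
               tolerance = 1e-12)

  pho <- enumerate_expected_species(lib[lib$id == 19, ])
  expect_equal(pho$mass_average[pho$role == "substrate"] -
                 pho$mass_average[pho$role == "dephosphorylated_product"],
               hpo3, tolerance = 1e-12)
})

test_that("full panel enumerates 20 substrates plus 34 products", {
  pan <- table1_panel()
  expect_identical(nrow(pan), 54L)
  expect_identical(sum(pan$role == "substrate"), 20L)
  expect_identical(sum(grepl("cleavage", pan$role)), 28L)
  expect_identical(sum(pan$role == "phosphorylated_product"), 4L)
  expect_identical(sum(pan$role == "dephosphorylated_product"), 2L)
})

test_that("mass conservation holds for every protease cleavage pair", {
  pan <- table1_panel()
  water <- residue_mass_table()$water_average
  for (sid in 1:14) {
    rows <- pan[pan$substrate_id == sid, ]
    m <- stats::setNames(rows$mass_average, rows$role)
    expect_equal(m[["cleavage_product_1"]] + m[["cleavage_product_2"]] - water,
                 m[["substrate"]], tolerance = 1e-12)
  }
})

test_that("phospho symmetry: one constant shift for all kinase substrates", {
  pan <- table1_panel()
  shifts <- vapply(15:18, function(sid) {
    rows <- pan[pan$substrate_id == sid, ]
    rows$mass_average[rows$role == "phosphorylated_product"] -
      rows$mass_average[rows$role == "substrate"]
  }, 0)
  expect_true(all(abs(shifts - shifts[1]) < 1e-12))
})

test_that("monoisotopic mass never exceeds average mass", {
  pan <- table1_panel()
  expect_true(all(pan$mass_monoisotopic <= pan$mass_average))
})

test_that("protonated target m/z is neutral mass plus one proton", {
  pan <- table1_panel()
  proton <- residue_mass_table()$proton_mass
  expect_equal(pan$target_mz, pan$mass_average + proton, tolerance = 1e-12)
  neutral <- expected_species(table1_library(), adduct = "neutral")
  expect_equal(neutral$target_mz, neutral$mass_average, tolerance = 1e-12)
})
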