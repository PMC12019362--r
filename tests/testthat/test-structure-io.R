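test_that("a minimal single-record PDB file parses into one chain/residue/atom", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1      11.104  13.207   2.100  1.00 20.00           C",
    "END"), f)
  m <- read_structure(f, quiet = TRUE)
  expect_s3_class(m, "structure_model")
  expect_equal(chain_ids(m), "A")
  expect_equal(nrow(m$atoms), 1)
  expect_equal(as.numeric(m$atoms[1, c("x", "y", "z")]), c(11.104, 13.207, 2.100))
})

test_that("synthetic hexamers round-trip through both formats within 0.001 A", {
  m <- compact_fixture()$model
  for (fmt in c("pdb", "mmcif")) {
    f <- tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    write_structure(m, f, fmt)
    m2 <- suppressWarnings(read_structure(f, quiet = TRUE))
    expect_equal(chain_ids(m2), chain_ids(m))
    expect_equal(nrow(m2$atoms), nrow(m$atoms))
    a <- m$atoms[order(m$atoms$chain, m$atoms$resno, m$atoms$elety), ]
    b <- m2$atoms[order(m2$atoms$chain, m2$atoms$resno, m2$atoms$elety), ]
    expect_lte(max(abs(as.matrix(a[, c("x", "y", "z")]) -
                         as.matrix(b[, c("x", "y", "z")]))), 1e-3)
    expect_equal(ligand_table(m2)$ligand, ligand_table(m)$ligand)
  }
})

test_that("read-write-read is idempotent and gzip is transparent", {
  m <- compact_fixture()$model
  f1 <- tempfile(fileext = ".pdb")
  write_structure(m, f1)
  m1 <- read_structure(f1, quiet = TRUE)
  f2 <- tempfile(fileext = ".pdb")
  write_structure(m1, f2)
  expect_identical(readLines(f1)[-1], readLines(f2)[-1])   # header label differs only
  fgz <- tempfile(fileext = ".pdb.gz")
  con <- gzfile(fgz, "wt"); writeLines(readLines(f1), con); close(con)
  mgz <- read_structure(fgz, quiet = TRUE)
  expect_equal(nrow(mgz$atoms), nrow(m1$atoms))
})

test_that("ligand extraction partitions atoms between protein and ligands", {
  m <- compact_fixture()$model
  expect_equal(sum(m$atoms$het) + sum(!m$atoms$het), nrow(m$atoms))
  lt <- ligand_table(m)
  expect_setequal(unique(lt$ligand), c("ATP", "ADP", "MG"))
  # ATP has 3 phosphorus atoms, ADP 2
  expect_true(all(lt$n_phosphorus[lt$ligand == "ATP"] == 3))
  expect_true(all(lt$n_phosphorus[lt$ligand == "ADP"] == 2))
  # solvent is discarded on read
  f <- tempfile(fileext = ".pdb")
  write_structure(m, f)
  lines <- readLines(f)
  lines <- append(lines, "HETATM 9000  O   HOH A 901      50.000  50.000  50.000  1.00  0.00           O",
                  after = length(lines) - 1)
  writeLines(lines, f)
  expect_message(m2 <- read_structure(f), "solvent")
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
})

test_that("invalid inputs raise informative errors", {
  expect_error(read_structure(tempfile()), "not found")
  expect_error(structure_model(data.frame()), "lacks column|empty")
  a <- data.frame(elety = "P", element = "P", resid = "ATP", chain = "A",
                  resno = 1L, insert = "", x = 0, y = 0, z = 0, o = 1, b = 0,
                  het = TRUE)
  expect_error(structure_model(a), "zero protein chains")
  m <- compact_fixture()$model
  m$atoms$chain <- paste0(m$atoms$chain, "X")
  expect_error(write_structure(m, tempfile(fileext = ".pdb")), "chain id")
  bad <- data.frame(elety = "CA", element = "C", resid = "GLY", chain = "A",
                    resno = 1L, insert = "", x = 0, y = 0, z = 0, o = 2, b = 0,
                    het = FALSE)
  expect_error(structure_model(bad), "occupancy")
})

test_that("highest-occupancy altloc wins and ATP analogues are flagged", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.30 20.00           C",
    "ATOM      2  CA BGLY A   1       5.000   0.000   0.000  0.70 20.00           C",
    "HETATM    3  PA  ANP A 601       1.000   0.000   0.000  1.00 20.00           P",
    "END"), f)
  m <- suppressMessages(read_structure(f, quiet = TRUE))
  prot <- m$atoms[!m$atoms$het, ]
  expect_equal(nrow(prot), 1)
  expect_equal(prot$x, 5.0)
  lt <- ligand_table(m)
  expect_equal(lt$ligand, "ATP")
  expect_true(lt$analog)
})
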