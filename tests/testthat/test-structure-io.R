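# PDB parsing, altloc resolution, radius assignment and round trips.

test_that("a minimal two-chain file parses into a two-chain complex", {
  df <- data.frame(chain = c("A", "B"), resno = 1,
                   resid = c("ALA", "GLY"), elety = "CA",
                   x = c(0, 10), y = 0, z = 0)
  cx <- read_complex(make_pdb(df), "A", "B")
  expect_s3_class(cx, "ppi_complex")
  expect_equal(nrow(cx$atoms), 2)
  expect_setequal(unique(cx$atoms$chain), c("A", "B"))
  expect_equal(cx$atoms$resid, c("ALA", "GLY"))
})

test_that("alternate locations keep the highest-occupancy conformer", {
  df <- data.frame(chain = c("A", "A", "B"), resno = c(1, 1, 1),
                   resid = c("SER", "SER", "GLY"),
                   elety = c("OG", "OG", "CA"),
                   x = c(1.0, 2.0, 10), y = 0, z = 0,
                   alt = c("A", "B", " "), o = c(0.6, 0.4, 1))
  cx <- read_complex(make_pdb(df), "A", "B")
  og <- cx$atoms[cx$atoms$elety == "OG", ]
  expect_equal(nrow(og), 1)
  expect_equal(og$x, 1.0)
  # occupancy tie resolves towards altloc A
  df$o <- c(0.5, 0.5, 1)
  cx2 <- read_complex(make_pdb(df), "A", "B")
  expect_equal(cx2$atoms$x[cx2$atoms$elety == "OG"], 1.0)
})

test_that("missing and empty chains fail with named errors", {
  df <- data.frame(chain = "A", resno = 1, resid = "ALA", elety = "CA",
                   x = 0, y = 0, z = 0)
  path <- make_pdb(df)
  expect_error(read_complex(path, "A", "C"), "chain not found.*C")
  expect_error(read_complex(path, "A", "A"), "distinct")
})

test_that("waters and hydrogens are handled per policy", {
  df <- data.frame(chain = c("A", "A", "B"), resno = c(1, 2, 1),
                   resid = c("ALA", "HOH", "GLY"),
                   elety = c("CA", "O", "CA"),
                   x = c(0, 5, 10), y = 0, z = 0)
  cx <- read_complex(make_pdb(df), "A", "B")
  expect_false(any(cx$atoms$resid == "HOH"))
  expect_true(all(!cx$atoms$is_h))
})

test_that("MSE maps to MET and stays in the standard set", {
  df <- data.frame(chain = c("A", "B"), resno = 1,
                   resid = c("MSE", "GLY"), elety = c("CA", "CA"),
                   x = c(0, 8), y = 0, z = 0)
  cx <- read_complex(make_pdb(df), "A", "B")
  expect_equal(cx$atoms$resid[1], "MET")
  expect_true(all(cx$atoms$is_standard))
})

test_that("radius assignment covers standard atoms and element fallbacks", {
  tbl <- ppi_radius_table()
  df <- data.frame(chain = c("A", "A", "B"), resno = c(1, 1, 1),
                   resid = c("ALA", "ALA", "PHE"),
                   elety = c("CA", "CB", "CZ"),
                   x = c(0, 1.5, 10), y = 0, z = 0)
  cx <- assign_radii(read_complex(make_pdb(df), "A", "B"))
  expect_equal(cx$atoms$radius[cx$atoms$elety == "CB"],
               tbl$by_class[["C_aliphatic"]])
  expect_equal(cx$atoms$radius[cx$atoms$elety == "CZ"],
               tbl$by_class[["C_aromatic"]])
})

test_that("every heavy atom of a synthetic complex gets a radius", {
  for (d in fixture_dimers()[1:3]) {
    at <- d$complex$atoms
    expect_false(anyNA(at$radius[!at$is_h]))
    expect_true(all(at$radius[!at$is_h] > 0))
  }
})

test_that("parse/write/parse round trip preserves the structure", {
  d <- fixture_dimers()[[4]]
  path <- tempfile(fileext = ".pdb")
  write_complex(d$complex, path)
  cx2 <- read_complex(path, "A", "B")
  expect_equal(nrow(cx2$atoms), nrow(d$complex$atoms))
  expect_equal(cx2$atoms$elety, d$complex$atoms$elety)
  expect_equal(cx2$atoms$chain, d$complex$atoms$chain)
  expect_equal(cx2$atoms$x, d$complex$atoms$x, tolerance = 1e-8)
  # second round trip is exact (coordinates already at 3 decimals)
  path2 <- tempfile(fileext = ".pdb")
  write_complex(assign_radii(cx2), path2)
  cx3 <- read_complex(path2, "A", "B")
  expect_identical(cx3$atoms$x, cx2$atoms$x)
  # no residue with zero atoms, no duplicated residue key
  key <- with(cx2$atoms, paste(chain, resno, insert, elety))
  expect_false(anyDuplicated(key) > 0)
})

test_that("writing fails on empty complexes and huge coordinates", {
  d <- fixture_dimers()[[1]]
  cx <- d$complex
  cx$atoms <- cx$atoms[0, ]
  expect_error(write_complex(cx, tempfile()), "empty")
  cx2 <- d$complex
  cx2$atoms$x[1] <- 123456.0
  expect_error(write_complex(cx2, tempfile()), "column width")
})
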