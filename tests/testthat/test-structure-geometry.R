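# PDB parsing, chain counting, distances and missing-residue gaps.

tiny_pdb <- function(lines, path = withr::local_tempfile(fileext = ".pdb",
                                                         .local_envir =
                                                           parent.frame())) {
  writeLines(lines, path)
  path
}

atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, alt = " ", het = FALSE) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial,
          if (nchar(name) < 4) paste0(" ", name) else name, alt, resname,
          chain, resno, x, y, z, occ, 0, substr(name, 1, 1))
}

test_that("a handcrafted fixture parses to exact coordinates", {
  p <- tiny_pdb(c(atom_line(1, "N", "GLY", "A", 1, 1.234, -2.5, 3.75),
                  atom_line(2, "CA", "GLY", "A", 1, 2, 0, 0),
                  atom_line(3, "C", "GLY", "A", 1, 0.001, 99.999, -0.25)))
  m <- read_pdb(p)
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$x[m$atoms$atom == "N"], 1.234)
  expect_equal(m$atoms$z[m$atoms$atom == "C"], -0.25)
  expect_equal(nrow(m$diagnostics), 0)
  expect_true(all(m$atoms$is_polymer))
})

test_that("alt-locs resolve to highest occupancy, ties to A", {
  p <- tiny_pdb(c(atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.6,
                            alt = "A"),
                  atom_line(2, "CA", "ALA", "A", 1, 5, 0, 0, occ = 0.4,
                            alt = "B"),
                  atom_line(3, "CA", "ALA", "A", 2, 1, 1, 1, occ = 0.5,
                            alt = "B"),
                  atom_line(4, "CA", "ALA", "A", 2, 9, 9, 9, occ = 0.5,
                            alt = "A")))
  m <- read_pdb(p)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[m$atoms$resno == 1], 0)    # 0.6 beats 0.4
  expect_equal(m$atoms$x[m$atoms$resno == 2], 9)    # tie -> alt A
})

test_that("malformed records are diagnosed by line, not fatal", {
  p <- tiny_pdb(c("HEADER    TEST",
                  atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
                  "ATOM      2  CA  ALA A   2    xxxxxxxxyyyyyyyyzzzzzzzz",
                  atom_line(3, "CA", "ALA", "A", 3, 3, 0, 0)))
  m <- read_pdb(p)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$diagnostics$line, 3L)
  expect_error(read_pdb(tiny_pdb("REMARK nothing")), "no ATOM")
})

test_that("polymer chains are counted with the residue filter", {
  water <- lapply(1:30, function(i)
    atom_line(100 + i, "O", "HOH", "W", i, i, 0, 0, het = TRUE))
  chain_a <- lapply(1:25, function(i)
    atom_line(i, "CA", "ALA", "A", i, i, 1, 0))
  m <- read_pdb(tiny_pdb(c(unlist(chain_a), unlist(water))))
  expect_equal(count_polymer_chains(m), 1L)
  chain_b <- lapply(1:25, function(i)
    atom_line(200 + i, "CA", "GLY", "B", i, i, 5, 0))
  m2 <- read_pdb(tiny_pdb(c(unlist(chain_a), unlist(chain_b),
                            unlist(water))))
  expect_equal(count_polymer_chains(m2), 2L)
  # a short peptide falls under the filter
  expect_equal(count_polymer_chains(m2, min_residues = 26), 0L)
})

test_that("atom distances obey the 3-4-5 fixture and metric identities", {
  p <- tiny_pdb(c(atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
                  atom_line(2, "CA", "ALA", "A", 2, 3, 4, 0),
                  atom_line(3, "CA", "ALA", "A", 3, -1, 2, 2)))
  m <- read_pdb(p)
  s <- function(r) list(chain = "A", resno = r, atom = "CA")
  expect_equal(atom_distance(m, s(1), s(2)), 5)
  expect_equal(atom_distance(m, s(1), s(1)), 0)
  expect_equal(atom_distance(m, s(2), s(1)), 5)
  # triangle inequality on all atom triples
  d12 <- atom_distance(m, s(1), s(2))
  d13 <- atom_distance(m, s(1), s(3))
  d23 <- atom_distance(m, s(2), s(3))
  expect_lte(d12, d13 + d23)
  expect_lte(d13, d12 + d23)
  expect_lte(d23, d12 + d13)
  expect_error(atom_distance(m, list(chain = "B", resno = 1, atom = "CA"),
                             s(1)), "matches no atom")
})

test_that("chain gaps find missing runs and stay inside observed bounds", {
  resnos <- c(1:3, 7:10)
  p <- tiny_pdb(vapply(seq_along(resnos), function(i)
    atom_line(i, "CA", "ALA", "A", resnos[i], i, 0, 0), ""))
  m <- read_pdb(p)
  g <- chain_gaps(m, "A")
  expect_equal(g$first_missing, 4)
  expect_equal(g$last_missing, 6)
  # contiguous chain: no gaps
  p2 <- tiny_pdb(vapply(1:10, function(i)
    atom_line(i, "CA", "ALA", "A", i, i, 0, 0), ""))
  expect_equal(nrow(chain_gaps(read_pdb(p2), "A")), 0)
})

test_that("the synthetic stand-in reproduces its documented facts", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_model_pdb(path, "wild_type")
  m <- read_pdb(path)
  expect_equal(nrow(m$diagnostics), 0)
  expect_equal(count_polymer_chains(m), 2L)
  for (ch in c("A", "B")) {
    dd <- dyad_distances(m, ch)
    expect_equal(unname(attr(dd, "closest")[["his"]]), 3.2,
                 tolerance = 1e-6)
    expect_equal(unname(attr(dd, "closest")[["nucleophile"]]), 3.2,
                 tolerance = 1e-6)
    g <- chain_gaps(m, ch)
    expect_true(any(g$first_missing == 153 & g$last_missing == 210))
  }
  # the mutant variant exposes CB instead of SG
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_model_pdb(path2, "c139a")
  m2 <- read_pdb(path2)
  dd2 <- dyad_distances(m2, "A")
  expect_true("CB" %in% dd2$atom[dd2$role == "nucleophile"])
  expect_false("SG" %in% dd2$atom)
})

test_that("coordinates agree with an independent PDB reader", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_model_pdb(path, "wild_type")
  m <- read_pdb(path)
  ref <- bio3d::read.pdb(path)
  expect_equal(nrow(m$atoms), nrow(ref$atom))
  a <- m$atoms[order(m$atoms$chain, m$atoms$resno, m$atoms$atom), ]
  b <- ref$atom[order(ref$atom$chain, ref$atom$resno, ref$atom$elety), ]
  expect_equal(a$x, b$x)
  expect_equal(a$y, b$y)
  expect_equal(a$z, b$z)
  expect_equal(a$atom, b$elety)
})
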