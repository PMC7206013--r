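# Unit cells, symmetry, systematic absences and SHELX-style hkl I/O.

test_that("unit cell validation rejects impossible geometries", {
  expect_error(unit_cell(-10, 10, 10), "positive")
  expect_error(unit_cell(10, 10, 10, alpha = 0), "between 0 and 180")
  expect_error(unit_cell(10, 10, 10, 170, 170, 170), "impossible")
  expect_equal(cell_volume(unit_cell(10, 20, 30)), 6000)
})

test_that("resolution follows the orthogonal closed form and the metric
          oracle for oblique cells", {
  expect_equal(resolution_of(unit_cell(10, 10, 10), c(1, 0, 0)), 10.0)
  expect_equal(resolution_of(unit_cell(10, 20, 30), c(0, 2, 0)), 10.0)
  # oblique cells: cross-product reciprocal-basis oracle
  cells <- list(unit_cell(10, 10, 10, 90, 90, 120),
                unit_cell(11, 13, 17, 85, 95, 103))
  hkls <- rbind(c(1, 1, 0), c(1, 2, 3), c(-2, 1, -1))
  for (cell in cells) for (i in seq_len(nrow(hkls))) {
    expect_equal(resolution_of(cell, hkls[i, ]),
                 brute_resolution(cell, hkls[i, ]), tolerance = 1e-10)
  }
  expect_error(resolution_of(toy_cell(), c(0, 0, 0)), "no resolution")
})

test_that("operator sets of all built-in groups are closed with identity", {
  for (s in c("P1", "P21", "C2", "P212121", "P43212")) {
    sg <- space_group(s)
    expect_s3_class(sg, "space_group")
    expect_true(any(vapply(sg$operators, function(op)
      all(op$rot == diag(3)) && all(op$trans == 0), TRUE)))
  }
  # a broken set is refused
  expect_error(space_group("broken", operators = list(
    sg_op(diag(3)), sg_op(c(0, -1, 0, 1, 0, 0, 0, 0, 1)))),
    "not closed")
})

test_that("map_to_asu merges Friedel mates and rotation images", {
  p1 <- space_group("P1")
  a <- map_to_asu(c(1, 2, 3), p1)
  b <- map_to_asu(c(-1, -2, -3), p1)
  expect_equal(a[, c("h", "k", "l")], b[, c("h", "k", "l")])
  expect_equal(b$friedel_sign, -1L)

  p212121 <- space_group("P212121")
  expect_equal(map_to_asu(c(2, 3, 5), p212121)[, c("h", "k", "l")],
               map_to_asu(c(-2, -3, 5), p212121)[, c("h", "k", "l")])
})

test_that("map_to_asu is idempotent and partitions match brute-force
          orbits", {
  set.seed(7)
  for (sym in c("P21", "P212121", "P43212")) {
    sg <- space_group(sym)
    hkl <- matrix(sample(-6:6, 300, replace = TRUE), 100, 3)
    hkl <- hkl[rowSums(abs(hkl)) > 0, , drop = FALSE]
    canon <- map_to_asu(hkl, sg)
    again <- map_to_asu(as.matrix(canon[, c("h", "k", "l")]), sg)
    expect_equal(canon[, c("h", "k", "l")], again[, c("h", "k", "l")])
    expect_true(all(again$friedel_sign == 1L))
    # two indices share a canonical id iff their explicit orbits coincide
    for (i in sample(nrow(hkl), 10)) {
      orb <- brute_orbit(hkl[i, , drop = FALSE], sg)
      members <- canon[, 1] == canon[i, 1] & canon[, 2] == canon[i, 2] &
        canon[, 3] == canon[i, 3]
      in_orbit <- vapply(seq_len(nrow(hkl)), function(j)
        any(apply(orb, 1, function(o) all(o == hkl[j, ]))), TRUE)
      expect_equal(members, in_orbit)
    }
  }
})

test_that("resolution is invariant across each orbit", {
  sg <- space_group("P43212")
  cell <- unit_cell(30, 30, 40)  # tetragonal metric for this group
  hkl <- rbind(c(1, 2, 3), c(3, 1, 2), c(0, 2, 5))
  for (i in seq_len(nrow(hkl))) {
    orb <- brute_orbit(hkl[i, , drop = FALSE], sg)
    ds <- resolution_of(cell, orb)
    expect_equal(max(ds) - min(ds), 0, tolerance = 1e-10)
  }
})

test_that("systematic absences reproduce the textbook screw/centring rules
          and brute-force enumeration", {
  p21 <- space_group("P21")
  expect_true(is_absent(c(0, 1, 0), p21))
  expect_false(is_absent(c(0, 2, 0), p21))
  expect_false(any(is_absent(rbind(c(1, 0, 0), c(1, 2, 3)),
                             space_group("P1"))))
  # axial rules: P212121 (h00) h odd, (0k0) k odd, (00l) l odd;
  # P43212 (00l) l != 4n; C2 h+k odd
  p212121 <- space_group("P212121")
  expect_equal(is_absent(rbind(c(1, 0, 0), c(2, 0, 0), c(0, 3, 0),
                               c(0, 4, 0), c(0, 0, 5), c(0, 0, 6)),
                         p212121),
               c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  p43212 <- space_group("P43212")
  expect_equal(is_absent(rbind(c(0, 0, 1), c(0, 0, 2), c(0, 0, 4)),
                         p43212), c(TRUE, TRUE, FALSE))
  expect_true(is_absent(c(1, 2, 0), space_group("C2")))

  # exhaustive agreement with the operator-enumeration oracle
  grid <- as.matrix(expand.grid(h = -4:4, k = -4:4, l = -4:4))
  grid <- grid[rowSums(abs(grid)) > 0, ]
  for (sym in c("P1", "P21", "C2", "P212121", "P43212")) {
    sg <- space_group(sym)
    oracle <- vapply(seq_len(nrow(grid)), function(i) {
      h <- grid[i, ]
      any(vapply(sg$operators, function(op) {
        all(h %*% op$rot == h) &&
          abs(sum(h * op$trans) - round(sum(h * op$trans))) > 1e-9
      }, TRUE))
    }, TRUE)
    expect_equal(is_absent(grid, sg), oracle)
  }
})

test_that("hkl files round-trip and malformed lines get line diagnostics", {
  tab <- observation_table(c(1, 2, -3), c(0, 1, 2), c(4, -5, 6),
                           c(100.25, 0.5, -3.75), c(1.25, 0.5, 2),
                           c(0L, 3L, 12L), "x1")
  path <- withr::local_tempfile(fileext = ".hkl")
  write_hkl(tab, path)
  back <- read_hkl(path, crystal_id = "x1")
  expect_equal(back, tab, ignore_attr = TRUE)
  expect_equal(nrow(attr(back, "diagnostics")), 0)

  # 1000 random observations survive a write/read cycle exactly
  set.seed(1)
  n <- 1000
  big <- observation_table(sample(-99:99, n, TRUE), sample(-99:99, n, TRUE),
                           sample(-99:99, n, TRUE),
                           round(stats::runif(n, -500, 500), 2),
                           round(stats::runif(n, 0.01, 50), 2),
                           sample(0:99, n, TRUE), "xx")
  write_hkl(big, path)
  expect_equal(read_hkl(path, "xx"), big, ignore_attr = TRUE)

  # one corrupt line -> 2 parsed + 1 diagnostic naming the line
  writeLines(c("   1   2   3  100.00    1.00   1",
               "   1   2   X  100.00    1.00   1",
               "   1   2   4   50.00    2.00   1"), path)
  got <- read_hkl(path)
  expect_equal(nrow(got), 2)
  expect_equal(attr(got, "diagnostics")$line, 2L)
  # non-positive sigma is also diagnosed, not imported
  writeLines(c("   1   2   3  100.00    0.00   1"), path)
  got <- read_hkl(path)
  expect_equal(nrow(got), 0)
  expect_match(attr(got, "diagnostics")$message, "sigma")
  expect_error(read_hkl(file.path(tempdir(), "absent-file.hkl")),
               "cannot read")
})

test_that("metadata sidecars round-trip cells, wedges and space groups", {
  ds <- crystal_dataset("c7", unit_cell(25.1, 30.2, 35.3), observation_table(
    1, 2, 3, 10, 1, 0L, "c7"), wedge_start = 100, wedge_width = 20,
    wavelength = 0.92)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sidecar(ds, space_group("P212121"), path)
  meta <- read_sidecar(path)
  expect_equal(as.numeric(meta$cell), as.numeric(ds$cell))
  expect_equal(meta$wedge_width, 20)
  expect_equal(meta$sg$symbol, "P212121")
  expect_length(meta$sg$operators, 4)

  # non-builtin symbol forces an explicit operator list through the sidecar
  custom <- space_group("P2", operators = list(
    sg_op(diag(3)), sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1))))
  write_sidecar(ds, custom, path)
  meta <- read_sidecar(path)
  expect_length(meta$sg$operators, 2)
  expect_equal(map_to_asu(c(1, 2, 3), meta$sg),
               map_to_asu(c(1, 2, 3), custom))
})

test_that("unique-reflection enumeration nests with resolution", {
  sg <- space_group("P212121")
  e3 <- enumerate_unique_hkl(toy_cell(), sg, 3)
  e2 <- enumerate_unique_hkl(toy_cell(), sg, 2)
  expect_gt(nrow(e2), nrow(e3))
  key <- function(df) paste(df$h, df$k, df$l)
  expect_true(all(key(e3) %in% key(e2)))
  expect_false(any(is_absent(as.matrix(e3[, c("h", "k", "l")]), sg)))
  expect_error(enumerate_unique_hkl(unit_cell(2, 2, 2), sg, 3),
               "admits no reflections")
})
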