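# PDB parsing, model policy, alt-loc resolution, assembly construction,
# admission filtering and color-coded output.

make_pdb_lines <- function(n = 3, chain = "A", altloc = NULL, x = NULL,
                           b = 10, model = NULL) {
  x <- x %||% (seq_len(n) - 1) * 3.8
  alt <- altloc %||% rep(" ", n)
  atoms <- sprintf(
    "ATOM  %5d  CA %s%s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), alt, "ALA", chain, seq_len(n), x, 0, 0, 1.0, b)
  if (is.null(model)) c(atoms, "END")
  else c(sprintf("MODEL     %4d", model[1]), atoms, "ENDMDL", "END")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("parsing a generated toy recovers atoms, nodes and coordinates", {
  f <- fixture_path("linear_chain", n = 3)
  s <- read_structure(f)
  expect_s3_class(s, "gnm_structure")
  nodes <- select_nodes(s)
  expect_equal(nrow(nodes$xyz), 3)
  expect_equal(nodes$label$elety, rep("CA", 3))
  expect_equal(nodes$xyz[, 1], c(0, 3.8, 7.6), tolerance = 1e-9)
})

test_that("multi-model files keep only the requested model", {
  f <- tempfile(fileext = ".pdb")
  lines <- c("MODEL        1",
             make_pdb_lines(3)[1:3], "ENDMDL",
             "MODEL        2",
             sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
                     1:3, 1:3, (0:2) * 3.8 + 100, 0, 0, 1.0, 10),
             "ENDMDL", "END")
  writeLines(lines, f)
  s1 <- read_structure(f)                 # default: first model
  expect_equal(nrow(s1$atom), 3)
  expect_lt(max(s1$atom$x), 10)
  s2 <- read_structure(f, model = 2)
  expect_gt(min(s2$atom$x), 99)
  expect_error(read_structure(f, model = 3), "model")
})

test_that("REMARK 350 operators are parsed and the first is the identity", {
  f <- fixture_path("dimer_biomt", n = 12)
  s <- read_structure(f)
  expect_length(s$assembly_ops, 1)
  ops <- s$assembly_ops[[1]]
  expect_length(ops, 2)
  expect_equal(ops[[1]]$rotation, diag(3), tolerance = 1e-6)
  expect_equal(ops[[1]]$translation, c(0, 0, 0), tolerance = 1e-6)
  # rotations orthogonal within tolerance
  for (op in ops)
    expect_lt(max(abs(crossprod(op$rotation) - diag(3))), 1e-4)
})

test_that("alt-loc resolution keeps the highest occupancy, ties to smallest label", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CA AALA A   2       3.800   0.000   0.000  0.40 11.00           C",
    "ATOM      3  CA BALA A   2       3.800   0.500   0.000  0.60 12.00           C",
    "ATOM      4  CA AALA A   3       7.600   0.000   0.000  0.50 13.00           C",
    "ATOM      5  CA BALA A   3       7.600   0.500   0.000  0.50 14.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s$atom), 3)
  expect_equal(s$atom$alt[s$atom$resno == 2], "B")   # occupancy 0.6 wins
  expect_equal(s$atom$alt[s$atom$resno == 3], "A")   # tie -> smallest label
})

test_that("unreadable and empty files raise parse errors", {
  expect_error(read_structure(tempfile()), "cannot read")
  f <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), f)
  expect_error(read_structure(f), "")
})

test_that("identity-operator assembly preserves coordinates and chain id", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "REMARK 350 BIOMOLECULE: 1",
    "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A",
    "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000",
    make_pdb_lines(5)), f)
  s <- read_structure(f)
  a <- build_assembly(s, "first_assembly")
  expect_equal(a$atom$x, s$atom$x)
  expect_equal(unique(a$atom$chain), "A")
})

test_that("translation operator yields a shifted copy under a fresh chain id", {
  f <- fixture_path("dimer_biomt", n = 10)
  s <- read_structure(f)
  a <- build_assembly(s, "first_assembly")
  expect_equal(sort(unique(a$atom$chain)), c("A", "B"))
  xa <- a$atom[a$atom$chain == "A", ]
  xb <- a$atom[a$atom$chain == "B", ]
  expect_equal(nrow(xb), nrow(xa))
  expect_equal(xb$y, xa$y + 9, tolerance = 1e-6)
  expect_equal(xb$x, xa$x, tolerance = 1e-6)
  # m operators x n chains -> m*n distinct chain ids
  expect_equal(length(unique(a$atom$chain)),
               2 * length(unique(s$atom$chain)))
})

test_that("a duplicated identity operator warns but keeps both copies", {
  f <- tempfile(fileext = ".pdb")
  id_block <- function(k) c(
    sprintf("REMARK 350   BIOMT1 %3d  1.000000  0.000000  0.000000        0.00000", k),
    sprintf("REMARK 350   BIOMT2 %3d  0.000000  1.000000  0.000000        0.00000", k),
    sprintf("REMARK 350   BIOMT3 %3d  0.000000  0.000000  1.000000        0.00000", k))
  writeLines(c("REMARK 350 BIOMOLECULE: 1",
               "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A",
               id_block(1), id_block(2), make_pdb_lines(4)), f)
  s <- read_structure(f)
  expect_warning(a <- build_assembly(s, "first_assembly"), "duplicate")
  expect_equal(nrow(a$atom), 2 * nrow(s$atom))
  expect_equal(length(unique(a$atom$chain)), 2)
})

test_that("operators referencing absent chains raise an assembly error", {
  f <- fixture_path("dimer_biomt", n = 10)
  s <- read_structure(f)
  s$assembly_ops[[1]][[2]]$chains <- "Z"
  expect_error(build_assembly(s, "first_assembly"), "absent chain")
})

test_that("admission window is sharp at 12 and 20000 nodes", {
  verdict_for <- function(n_nodes) {
    nodes <- structure(list(xyz = matrix(0, n_nodes, 3),
                            label = data.frame(chain = "A",
                                               resno = seq_len(n_nodes),
                                               insert = "", elety = "CA",
                                               resid = "ALA"),
                            node_class = rep("protein", n_nodes),
                            b = rep(NA_real_, n_nodes)),
                       class = "gnm_nodes")
    admit_structure(nodes)
  }
  expect_false(verdict_for(11)$accepted)
  expect_equal(verdict_for(11)$reason, "too few nodes")
  expect_true(verdict_for(12)$accepted)
  expect_true(verdict_for(20000)$accepted)
  expect_false(verdict_for(20001)$accepted)
  expect_equal(verdict_for(20001)$reason, "too many nodes")
  # soft cap is configurable
  expect_true(verdict_for(20872)$accepted ||
                admit_structure(structure(list(xyz = matrix(0, 20872, 3)),
                                          class = "gnm_nodes"),
                                max_nodes = 21000)$accepted)
})

test_that("C-alpha-only depositions are rejected only when the filter is on", {
  f <- fixture_path("linear_chain", n = 15, ca_only = TRUE)
  s <- read_structure(f)
  nodes <- select_nodes(s)
  v <- admit_structure(nodes, s)
  expect_false(v$accepted)
  expect_equal(v$reason, "calpha-only")
  expect_true(admit_structure(nodes, s, calpha_only_filter = FALSE)$accepted)
  # a file with backbone oxygens passes
  f2 <- fixture_path("linear_chain", n = 15)
  s2 <- read_structure(f2)
  expect_true(admit_structure(select_nodes(s2), s2)$accepted)
})

test_that("colored PDB output rescales to [0, 99.99] and round-trips", {
  f <- fixture_path("linear_chain", n = 5)
  s <- read_structure(f)
  nodes <- select_nodes(s)
  out <- tempfile(fileext = ".pdb")

  # constant vector -> all zero B columns
  write_colored_pdb(s, nodes, rep(3.3, 5), out)
  expect_true(all(read_structure(out)$atom$b == 0))

  # endpoints of the rescale
  write_colored_pdb(s, nodes, c(0, 1, 0, 0, 0), out)
  b <- read_structure(out)$atom$b
  expect_equal(sort(unique(b)), c(0, 99.99))

  # round-trip recovers rescaled values to 2 decimals
  vals <- c(0.1, 2.5, 7.7, 3.2, 9.9)
  write_colored_pdb(s, nodes, vals, out)
  s2 <- read_structure(out)
  expected <- (vals - min(vals)) / diff(range(vals)) * 99.99
  got <- s2$atom$b[s2$atom$elety == "CA"]
  expect_equal(got, expected, tolerance = 0.005)

  expect_error(write_colored_pdb(s, nodes, 1:3, out), "contract")
})

test_that("parse-write-parse round-trip preserves nodes, chains and coordinates", {
  f <- fixture_path("helix", n = 20, noise = 0.3, seed = 4)
  s1 <- read_structure(f)
  out <- tempfile(fileext = ".pdb")
  gnmkit:::write_structure(s1, out)
  s2 <- read_structure(out)
  expect_equal(nrow(s2$atom), nrow(s1$atom))
  expect_equal(s2$atom$chain, s1$atom$chain)
  expect_equal(s2$atom$resno, s1$atom$resno)
  expect_equal(s2$atom$x, s1$atom$x, tolerance = 5e-4)
  expect_equal(s2$atom$y, s1$atom$y, tolerance = 5e-4)
  expect_equal(s2$atom$z, s1$atom$z, tolerance = 5e-4)
})
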