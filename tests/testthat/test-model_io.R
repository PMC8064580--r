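test_that("PDB subset reader round-trips toy ATOM/HETATM records", {
  f <- write_toy_pdb()
  s <- read_pdb_subset(f)
  expect_s3_class(s, "structure")
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$name, c("CZ", "CA"))
  expect_equal(s$atoms$resname, c("ARG", "ASP"))
  expect_equal(s$atoms$resno, c(397L, 500L))
  expect_true(s$atoms$het[2])
  expect_equal(unlist(s$atoms[1, c("x", "y", "z")], use.names = FALSE), c(1, 2, 3))
})

test_that("PDB reader rejects empty input and duplicate atom keys, skips altLoc B", {
  f <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f)
  expect_error(read_pdb_subset(f), "no atoms|Error")
  expect_error(read_pdb_subset(tempfile(fileext = ".pdb")), "not found")

  dup <- c(toy_pdb_lines(),
           "ATOM      3  CZ  ARG A 397       7.000   8.000   9.000  1.00  0.00           C")
  expect_error(read_pdb_subset(write_toy_pdb(dup)), "duplicate")

  alt <- c("ATOM      1  CZ AARG A 397       1.000   2.000   3.000  1.00  0.00           C",
           "ATOM      2  CG BARG A 398       9.000   2.000   3.000  1.00  0.00           C",
           toy_pdb_lines()[2])
  s <- suppressMessages(read_pdb_subset(write_toy_pdb(alt)))
  expect_false(398L %in% s$atoms$resno)   # altLoc-B-only atom dropped
  expect_true(397L %in% s$atoms$resno)    # altLoc A kept
})

test_that("atom selection matches by exact fields with unique/all modes", {
  s <- fixture_system()$structure
  hit <- select_atom(s, "ARG:397:CZ")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$name, "CZ")
  expect_equal(hit$resno, 397L)

  all_ca <- select_atom(s, atom_selector(name = "CA"), mode = "all")
  expect_gte(nrow(all_ca), 3L)  # SER277, PRO356, bound ligand CA
  expect_error(select_atom(s, atom_selector(resno = 999)), "closest residue")
  expect_error(select_atom(s, atom_selector(name = "CA"), mode = "unique"),
               "matches [0-9]+ atoms")

  sel <- parse_selector("ARG:397:CZ")
  expect_equal(sel$resname, "ARG")
  expect_equal(sel$resno, 397L)
  expect_equal(sel$name, "CZ")
  expect_equal(parse_selector("CA")$name, "CA")
})

test_that("trajectory writer/reader round-trips coordinates, times and bias flags", {
  set.seed(7)
  for (i in 1:5) {
    nf <- sample(2:6, 1); np <- sample(1:4, 1)
    co <- array(rnorm(nf * np * 3, sd = 30), c(nf, np, 3))
    fl <- matrix(sample(c(TRUE, FALSE), nf * np, replace = TRUE), nf, np)
    tr <- trajectory(sort(runif(nf, 0, 100)), co, sprintf("B%d", seq_len(np)), fl)
    f <- tempfile(fileext = ".xyz")
    write_trajectory(tr, f)
    tr2 <- read_trajectory(f)
    expect_equal(tr2$coords, tr$coords, tolerance = 1e-6)
    expect_equal(tr2$times, tr$times, tolerance = 1e-6)
    expect_identical(tr2$flags, tr$flags)
    expect_identical(tr2$labels, tr$labels)
  }
})

test_that("trajectory format errors are reported with frame context", {
  co <- array(rnorm(6), c(2, 1, 3))
  tr <- trajectory(0:1, co, "CA")
  f <- tempfile(fileext = ".xyz")
  write_trajectory(tr, f)
  lines <- readLines(f)
  # corrupt the second frame's atom count
  lines[4] <- "2"
  f2 <- tempfile(); writeLines(lines, f2)
  expect_error(read_trajectory(f2), "frame 2")
  expect_error(trajectory(c(0, 0), co, "CA"), "strictly increasing")
  expect_error(trajectory(numeric(0), array(0, c(0, 1, 3)), "CA"), "at least one frame")
})

test_that("binding events survive a JSON-lines round trip", {
  ev <- data.frame(ligand = c("CA", "CA"), start = c(1.5, 40),
                   end = c(12, 55.25), residency = c(10.5, 15.25))
  f <- tempfile(fileext = ".jsonl")
  write_events_jsonl(ev, f)
  expect_equal(length(readLines(f)), 2L)
  ev2 <- read_events_jsonl(f)
  expect_equal(ev2$start, ev$start)
  expect_equal(ev2$residency, ev$residency)
  # empty event table round-trips to zero rows
  f0 <- tempfile()
  write_events_jsonl(ev[0, ], f0)
  expect_equal(nrow(read_events_jsonl(f0)), 0L)
})
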