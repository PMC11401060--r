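# seq_features: group schemes, neighbor frequency, window deltas,
# substitution scores and AAindex parsing.

test_that("assign_group follows both published schemes and partitions", {
  five <- group_scheme("five")
  seven <- group_scheme("seven")
  expect_equal(assign_group("A", five), "hydrophobic")
  expect_equal(assign_group("G", five), "special")
  expect_equal(assign_group("V", seven), "aliphatic")
  expect_equal(assign_group("D", seven), "short_charged_polar")
  # each scheme assigns every canonical letter to exactly one group
  for (scheme in list(five, seven)) {
    expect_setequal(names(scheme$assignment), pathomiss:::AA_ONE)
    expect_false(any(is.na(scheme$assignment)))
    expect_equal(sum(table(scheme$assignment)), 20)
  }
  expect_error(assign_group("B", five), "non-canonical")
})

test_that("neighbor_frequency counts the 15-residue window over length", {
  nf <- neighbor_frequency(strrep("L", 100), 50)
  expect_equal(unname(nf["hydrophobic_freq"]), 14 / 100)
  expect_equal(sum(nf), 14 / 100)
  # truncation at the N-terminus: only 2 leading residues exist
  expect_equal(sum(neighbor_frequency(strrep("L", 100), 3)), 9 / 100)
  ng <- neighbor_frequency(strrep("G", 50), 25)
  expect_equal(unname(ng["structure_breaking_freq"]), 14 / 50)
  expect_error(neighbor_frequency("", 1), "empty")
})

test_that("neighbor_frequency ignores residues outside the window", {
  set.seed(11)
  for (rep in 1:20) {
    letters1 <- sample(pathomiss:::AA_ONE, 60, replace = TRUE)
    pos <- sample(10:50, 1)
    base <- neighbor_frequency(paste(letters1, collapse = ""), pos)
    far <- sample(c(1:(pos - 8), (pos + 8):60), 1)
    letters2 <- letters1
    letters2[far] <- sample(pathomiss:::AA_ONE, 1)
    modified <- neighbor_frequency(paste(letters2, collapse = ""), pos)
    expect_equal(base, modified)
    expect_true(all(base >= 0 & base <= 14 / 60))
  }
})

test_that("window_delta matches its definition and the k = 0 oracle", {
  toy <- property_table("toy", stats::setNames(
    c(1, 3, rep(0, 18)), c("A", "L", setdiff(pathomiss:::AA_ONE,
                                             c("A", "L")))))
  expect_equal(window_delta("AAAAA", 3, "L", toy, k = 1), -2.0)
  expect_equal(window_delta("AAAAA", 3, "A", toy, k = 1), 0.0)
  # k = 0 collapses to direct table lookup on random cases
  kd <- builtin_property_catalog()$KYTJ820101
  set.seed(5)
  for (i in 1:25) {
    s <- paste(sample(pathomiss:::AA_ONE, 30, replace = TRUE),
               collapse = "")
    pos <- sample(30, 1)
    mt <- sample(pathomiss:::AA_ONE, 1)
    wt <- substr(s, pos, pos)
    expect_equal(window_delta(s, pos, mt, kd, k = 0),
                 kd$values[[wt]] - kd$values[[mt]])
    expect_equal(window_delta(s, pos, mt, kd, k = 2, normalized = TRUE),
                 window_delta(s, pos, mt, kd, k = 2) / 30)
  }
  expect_error(window_delta("AAAAA", 3, "U", toy), "non-canonical")
})

test_that("substitution_score honors symmetry and flags absent pairs", {
  b62 <- builtin_substitution_catalog()$HENS920102
  set.seed(7)
  for (i in 1:30) {
    pair <- sample(pathomiss:::AA_ONE, 2)
    expect_equal(substitution_score(pair[1], pair[2], b62),
                 substitution_score(pair[2], pair[1], b62))
  }
  expect_equal(substitution_score("A", "A", b62), b62$scores["A", "A"])
  scores <- matrix(NA_real_, 20, 20,
                   dimnames = list(pathomiss:::AA_ONE,
                                   pathomiss:::AA_ONE))
  scores["A", "L"] <- 2
  asym <- substitution_table("asym", scores, symmetric = FALSE)
  expect_equal(substitution_score("A", "L", asym), 2)
  expect_error(substitution_score("L", "A", asym), "absent")
})

test_that("parse_aaindex reads I blocks, M blocks and skips junk", {
  props <- builtin_property_catalog()
  expect_true(all(c("KYTJ820101", "KLEP840101", "FAUJ880112", "pI", "MW",
                    "MV", "MEIH800101", "VASM830102", "CHAM830107") %in%
                    names(props)))
  kd <- props$KYTJ820101$values
  expect_equal(unname(kd[c("I", "R", "G")]), c(4.5, -4.5, -0.4))
  expect_equal(unname(props$KLEP840101$values[c("K", "D", "A")]),
               c(1, -1, 0))
  expect_equal(unname(props$FAUJ880112$values[c("D", "E", "K")]),
               c(1, 1, 0))
  # an AAindex-2 style triangular matrix file round-trips BLOSUM62
  b62 <- pathomiss:::get_blosum62()
  lines <- c("H TESTB62", "D BLOSUM62 written as a lower triangle",
             paste("M rows =", paste(pathomiss:::AA_ONE, collapse = ""),
                   ", cols =", paste(pathomiss:::AA_ONE, collapse = "")))
  for (i in seq_len(20)) {
    lines <- c(lines, paste(b62[i, seq_len(i)], collapse = " "))
  }
  lines <- c(lines, "//")
  f <- tempfile()
  writeLines(lines, f)
  parsed <- parse_aaindex(f)
  expect_named(parsed, "TESTB62")
  expect_true(parsed$TESTB62$symmetric)
  expect_equal(parsed$TESTB62$scores, b62[pathomiss:::AA_ONE,
                                          pathomiss:::AA_ONE])
})
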