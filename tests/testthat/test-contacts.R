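# contacts_signatures: mutant builder, contact typing, deltas, signatures.

test_that("side-chain swap: G->A adds exactly CB, X->G strips, resn updates", {
  h <- polyA_helix()
  g_at_10 <- build_mutant_model(h, mutation_record("HLX", 10, "A", "G"))
  expect_equal(nrow(g_at_10$atoms), nrow(h$atoms) - 1)
  expect_false("CB" %in% g_at_10$atoms$atom[g_at_10$atoms$resi == 10])
  back <- build_mutant_model(g_at_10, mutation_record("HLX", 10, "G", "A"))
  expect_equal(nrow(back$atoms), nrow(h$atoms))
  added <- back$atoms[back$atoms$resi == 10 & back$atoms$atom == "CB", ]
  expect_equal(nrow(added), 1)
  # every other residue's coordinates bit-identical
  other <- h$atoms$resi != 10
  expect_identical(h$atoms[other, c("x", "y", "z")],
                   back$atoms[back$atoms$resi != 10, c("x", "y", "z")])
  w <- build_mutant_model(h, mutation_record("HLX", 10, "A", "W"))
  expect_equal(unique(w$atoms$resn[w$atoms$resi == 10]), "TRP")
  expect_equal(substr(w$sequence, 10, 10), "W")
})

test_that("externally modeled mutant structures take precedence and validate", {
  h <- polyA_helix()
  m <- mutation_record("HLX", 10, "A", "V")
  ext <- build_mutant_model(h, m)  # stands in for an external model
  expect_identical(build_mutant_model(h, m, mutant_structure = ext), ext)
  wrong <- build_mutant_model(h, mutation_record("HLX", 10, "A", "L"))
  expect_error(build_mutant_model(h, m, mutant_structure = wrong),
               "does not carry V")
  expect_error(build_mutant_model(h, mutation_record("HLX", 10, "G", "V")),
               "does not map")
})

test_that("type_contacts sees helix hydrogen bonds and empty neighborhoods", {
  map <- load_pharmacophore_map()
  prof <- type_contacts(polyA_helix(), 15, map)
  expect_gte(prof[["HydrogenBond"]], 1)  # i,i+4 backbone bonds
  expect_gte(prof[["Polar"]], 1)
  expect_equal(prof[["Ionic"]], 0)
  # 3-residue chain: everything within |delta| <= 1 is excluded
  prof0 <- type_contacts(build_ideal_helix("AAA"), 2, map)
  expect_true(all(unclass(prof0) == 0))
  # buried leucines in the bundle pack hydrophobically
  profL <- type_contacts(leu_bundle(), 9, map)
  expect_gte(profL[["Hydrophobic"]], 1)
  expect_equal(profL[["Ionic"]], 0)
})

test_that("contact_delta: zero on identity, signed mutant minus WT", {
  p <- type_contacts(polyA_helix(), 15)
  expect_true(all(contact_delta(p, p) == 0))
  wt <- structure(stats::setNames(c(0L, 2L, 3L, 1L, 0L, 0L),
                                  pathomiss:::INTERACTION_TYPES),
                  class = "interaction_profile")
  mut <- structure(stats::setNames(c(0L, 2L, 1L, 1L, 0L, 0L),
                                   pathomiss:::INTERACTION_TYPES),
                   class = "interaction_profile")
  d <- contact_delta(wt, mut)
  expect_equal(unname(d["WeakPolar"]), -2)
  fv <- pathomiss:::contact_feature_vector(wt, mut)
  expect_equal(unname(fv["ITPolar"]), 2)       # WT count survives the delta
  expect_equal(unname(fv["ITd_WeakPolar"]), -2)
})

test_that("graph signatures count class pairs cumulatively (brute-force oracle)", {
  map <- load_pharmacophore_map()
  # phe site with a methionine sulfur across the bundle interface
  b <- build_helix_bundle("LLFLL", "LLMLL", separation = 7,
                          protein_id = "FM")
  sig <- graph_signature(b, 3, map, cutoffs = seq(1, 11, 0.5))
  # independent brute force: distances from site-residue atoms to SD
  atoms <- b$atoms
  site <- atoms[atoms$resi == 3, ]
  aro <- site[site$atom %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), ]
  sd_atom <- atoms[atoms$atom == "SD", ]
  d <- sqrt((aro$x - sd_atom$x)^2 + (aro$y - sd_atom$y)^2 +
              (aro$z - sd_atom$z)^2)
  for (cut in c(4.5, 6, 8, 11)) {
    expect_equal(unname(sig[[sprintf("Aro:Sul-%.2f", cut)]]),
                 sum(d <= cut))
  }
  # cumulative monotonicity within every class pair
  pair_of <- sub("-[0-9.]+$", "", names(sig))
  for (p in unique(pair_of)) {
    v <- sig[pair_of == p]
    expect_true(all(diff(v) >= 0))
  }
})

test_that("pharmacophore changes count atoms and atom order never matters", {
  map <- load_pharmacophore_map()
  seqv <- "LLDLLLLL"
  h <- build_ideal_helix(seqv, protein_id = "PD")
  ch <- pathomiss:::pharmacophore_change(
    h, mutation_record("PD", 3, "D", "A"), map)
  expect_equal(unname(ch[["Neg"]]), -2)  # Asp carboxylate oxygens
  sig2 <- graph_signature(h, 3, map, mutation =
                            mutation_record("PD", 3, "D", "A"))
  expect_equal(unname(sig2[["Neg"]]), -2)
  # permuting the atom table changes nothing
  perm <- withr::with_seed(3, sample.int(nrow(h$atoms)))
  hp <- protein_record("PD", seqv, h$atoms[perm, ], unname(h$plddt))
  expect_equal(unclass(type_contacts(hp, 3, map)),
               unclass(type_contacts(h, 3, map)))
  expect_equal(graph_signature(hp, 3, map), graph_signature(h, 3, map))
})
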