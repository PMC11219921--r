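test_that("parse_complex reads fixed-column records, altlocs and chains", {
  toy <- gen_toy_structure(4)
  atoms <- parse_complex(toy$text, "A", c("B", "C"))
  expect_equal(nrow(atoms), 4 + 4)        # 4 CA + 4 DNA P
  expect_equal(sort(unique(atoms$role)), c("dna", "protein"))
  expect_equal(sum(atoms$role == "dna"), 4)
  expect_true(all(atoms$element %in% c("C", "P")))

  expect_error(parse_complex(toy$text, "Z", c("B", "C")), "Z")
  dna_only <- toy$text[substr(toy$text, 22, 22) %in% c("B", "C") |
                         !startsWith(toy$text, "ATOM")]
  expect_error(parse_complex(dna_only, "A", c("B", "C")), "A")

  # altloc: highest occupancy retained; hydrogens dropped
  pdb <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  H   ALA A   1       1.000   0.000   0.000  1.00  0.00           H",
    "ATOM      4  P    DA B   1       0.000   3.000   0.000  1.00  0.00           P")
  at <- parse_complex(pdb, "A", "B")
  expect_equal(nrow(at), 2)
  expect_equal(at$x[at$role == "protein"], 0.0)   # occupancy 0.6 copy
  expect_false(any(at$element == "H"))
})

test_that("min_dna_distance matches lattice truth and bin boundaries", {
  toy <- gen_toy_structure(5)
  atoms <- parse_complex(toy$text, "A", c("B", "C"))
  d <- min_dna_distance(atoms)
  expect_equal(d$dna_distance, toy$truth$dna_distance, tolerance = 1e-6)
  expect_equal(d$distance_bin, floor(toy$truth$dna_distance))

  # half-open 1-angstrom bins around 5
  near <- gen_toy_structure(2, dna_atoms = data.frame(
    x = c(0, 10), y = c(4.999, 5.001), z = 0, chain = "B"))
  db <- min_dna_distance(parse_complex(near$text, "A", "B"))
  expect_equal(db$distance_bin, c(4, 5))

  # symmetric in chain order / record order
  atoms_rev <- atoms[rev(seq_len(nrow(atoms))), ]
  d2 <- min_dna_distance(atoms_rev)
  expect_equal(d2[order(d2$resid), ], d[order(d$resid), ],
               ignore_attr = TRUE)
})

test_that("min_dna_distance equals the brute-force oracle on random structures", {
  for (seed in 1:25) {
    set.seed(seed)
    n_res <- sample(2:5, 1)
    prot <- data.frame(resid = rep(seq_len(n_res), each = 3),
                       x = runif(3 * n_res, 0, 30),
                       y = runif(3 * n_res, 0, 30),
                       z = runif(3 * n_res, 0, 30),
                       role = "protein")
    dna <- data.frame(resid = 1:8, x = runif(8, 0, 30), y = runif(8, 0, 30),
                      z = runif(8, 0, 30), role = "dna")
    atoms <- rbind(prot, dna)
    d <- min_dna_distance(atoms)
    oracle <- min_dist_oracle(prot, dna)
    expect_equal(d$dna_distance, unname(oracle[as.character(d$resid)]),
                 tolerance = 1e-10)
  }
})

test_that("relative_sasa matches burial constructions and an external oracle", {
  # frozen oracle: biotite.structure.sasa (probe 1.4, single-atom radii,
  # 5000 points) on the deterministic 3-residue toy complex
  toy <- gen_toy_structure(3)
  s <- relative_sasa(parse_complex(toy$text), n_points = 600)
  biotite_ref <- c(87.4806, 97.7696, 107.9620)
  expect_equal(s$sasa, biotite_ref, tolerance = 0.02)

  # a fully caged residue is buried; an isolated one is exposed and close
  # to the single-sphere closed form 4*pi*(1.7+1.4)^2
  caged <- gen_toy_structure(3, cage_residues = 2)
  sc <- relative_sasa(parse_complex(caged$text), n_points = 300)
  expect_lt(sc$rel_sasa[sc$resid == 2], 5)
  lone <- relative_sasa(parse_complex(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "A", character(0)), n_points = 500)
  expect_equal(lone$sasa, 4 * pi * 3.1^2, tolerance = 1e-6)
  expect_equal(lone$rel_sasa, 100 * 4 * pi * 3.1^2 / 104.0, tolerance = 1e-6)
  expect_true(lone$accessible)

  # sampling convergence: doubling the point count moves rel_sasa < 1 point
  s1 <- relative_sasa(parse_complex(toy$text), n_points = 400)
  s2 <- relative_sasa(parse_complex(toy$text), n_points = 800)
  expect_true(all(abs(s1$rel_sasa - s2$rel_sasa) < 1))

  bad <- sub(" C$", "XX", toy$text[1])
  expect_error(relative_sasa(parse_complex(c(bad, toy$text[-1]))),
               "unknown element")
})

test_that("region_of partitions the construct", {
  r <- region_of(1:150)
  expect_equal(unname(table(r)[c("NTS", "Linker", "CTS", "other")]),
               c(60L, 16L, 57L, 17L), ignore_attr = TRUE)
  expect_equal(region_of(c(4, 63, 64, 79, 80, 136, 3, 137)),
               c("NTS", "NTS", "Linker", "Linker", "CTS", "CTS",
                 "other", "other"))
})

test_that("per_residue_median summarises scores by position", {
  sc <- data.frame(variant = c("A5G", "A5T", "A5P", "K9E", "WT"),
                   score = c(-1, 0, 1, 0.4, 99))
  med <- per_residue_median(sc)
  expect_equal(med$median_score[med$position == 5], 0)
  expect_equal(med$median_score[med$position == 9], 0.4)
  expect_false(any(is.na(med$position)))
  # duplicating the whole set leaves medians unchanged
  med2 <- per_residue_median(rbind(sc, sc))
  expect_equal(med2$median_score, med$median_score)
})

test_that("context_association links scores to burial, distance and region", {
  # residues 1..6 at increasing DNA distance; scores strictly lower near DNA
  set.seed(21)
  ctx <- data.frame(resid = 1:6, accessible = rep(c(TRUE, FALSE), 3),
                    distance_bin = c(3, 4, 5, 6, 7, 8))
  scores <- do.call(rbind, lapply(1:6, function(p) {
    data.frame(variant = paste0("A", p, c("G", "T", "P", "W")),
               score = -3 + 0.5 * p + rnorm(4, 0, 0.05))
  }))
  res <- context_association(scores, ctx)
  med <- res$dna_distance$medians
  expect_equal(med$group, as.character(c(3, 4, 5, 6, 7, 8)))
  expect_true(all(diff(med$median) > 0))   # monotone increasing with distance
  expect_true(!is.null(res$accessibility$comparisons))

  # a single populated group reports medians only
  one <- context_association(scores, transform(ctx, accessible = TRUE))
  expect_null(one$accessibility$comparisons)
  expect_equal(nrow(one$accessibility$medians), 1)
})

test_that("write_bfactor_pdb stamps per-position medians", {
  toy <- gen_toy_structure(3)
  med <- data.frame(position = c(1, 3), median_score = c(-1.25, 2.5))
  out <- tempfile(fileext = ".pdb")
  write_bfactor_pdb(toy$text, med, out, protein_chain = "A")
  lines <- readLines(out)
  ca <- lines[startsWith(lines, "ATOM") & substr(lines, 22, 22) == "A"]
  expect_equal(as.numeric(substr(ca, 61, 66)), c(-1.25, 0, 2.5))
})
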