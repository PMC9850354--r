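# Structure model, mass calculation and candidate lookup.

test_that("residue and adduct masses are reproduced from the element table", {
  reg <- monosaccharide_registry()
  expect_equal(reg["Hex", "native_mass"], 162.0528, tolerance = 1e-4)
  expect_equal(reg["HexNAc", "native_mass"], 203.0794, tolerance = 1e-4)
  expect_equal(reg["dHex", "native_mass"], 146.0579, tolerance = 1e-4)
  expect_equal(reg["Hex", "permethyl_mass"], 204.0998, tolerance = 1e-4)
  expect_equal(reg["HexNAc", "permethyl_mass"], 245.1263, tolerance = 1e-4)
  expect_equal(reg["dHex", "permethyl_mass"], 174.0892, tolerance = 1e-4)
  expect_equal(formula_mass("H2O"), 18.0106, tolerance = 1e-4)
})

test_that("native mass matches hand-computed values", {
  expect_equal(native_mass(glycan_composition(dHex = 2, Hex = 3, HexNAc = 1)),
               999.364, tolerance = 1e-3)
  expect_equal(native_mass(glycan_composition(Hex = 3, HexNAc = 1)),
               3 * 162.0528 + 203.0794 + 18.0106, tolerance = 1e-3)
  # empty composition: water only
  expect_equal(native_mass(glycan_composition()), 18.011, tolerance = 1e-3)
})

test_that("permethylated sodiated m/z reproduces nominal MALDI labels", {
  mz_of <- function(...) permethylated_mz(glycan_composition(...))
  expect_equal(floor(mz_of(Hex = 3, HexNAc = 1)), 926)
  expect_equal(floor(mz_of(dHex = 2, Hex = 3, HexNAc = 1)), 1274)
  expect_equal(floor(mz_of(Hex = 4, HexNAc = 2)), 1375)
  expect_equal(floor(mz_of(dHex = 1, Hex = 4, HexNAc = 2)), 1549)
  expect_equal(floor(mz_of(dHex = 2, Hex = 4, HexNAc = 2)), 1723)
  expect_equal(round(mz_of(dHex = 3, Hex = 4, HexNAc = 2)), 1898)
  expect_error(permethylated_mz(glycan_composition()), "empty")
})

test_that("composition arithmetic is componentwise and guards negatives", {
  a <- glycan_composition(Hex = 2, HexNAc = 1)
  b <- glycan_composition(Hex = 1, dHex = 1)
  expect_equal(unclass(a + b)[c("Hex", "HexNAc", "dHex")],
               c(Hex = 3L, HexNAc = 1L, dHex = 1L))
  expect_equal(unclass((a + b) - b), unclass(a))
  expect_error(a - b, "negative")
  # mass additivity: one water is double-counted when compositions are summed
  expect_equal(native_mass(a + b), native_mass(a) + native_mass(b) - 18.0106,
               tolerance = 1e-4)
})

test_that("the parser handles linear chains, branches and single residues", {
  lnt <- gly_lnt()
  expect_length(lnt$residue, 4L)
  expect_equal(sum(!is.na(lnt$parent)), 3L)  # linear: 3 edges, no branch
  expect_equal(max(table(lnt$parent[!is.na(lnt$parent)])), 1L)
  expect_equal(format(glycan_composition_of(lnt)), "Hex3.HexNAc1")
  expect_equal(lnt$residue[1], "Glc")  # root = reducing end

  g1 <- pat_lewis_b()
  expect_length(g1$residue, 6L)
  expect_equal(format(glycan_composition_of(g1)), "Hex3.HexNAc1.dHex2")
  kids_per_node <- table(g1$parent[!is.na(g1$parent)])
  expect_equal(sort(as.integer(kids_per_node)), c(1L, 1L, 1L, 2L))
  branch_node <- as.integer(names(kids_per_node)[kids_per_node == 2L])
  expect_equal(g1$residue[branch_node], "GlcNAc")

  single <- parse_glycan("Glc")
  expect_length(single$residue, 1L)
  expect_equal(format(glycan_composition_of(single)), "Hex1")
})

test_that("parse errors name the offending position", {
  expect_error(parse_glycan("Gal(b1-3"), "position 4")
  expect_error(parse_glycan("Xyz(b1-3)Glc"), "unknown residue name 'Xyz'")
  expect_error(parse_glycan("Gal(b1-3)[Fuc(a1-4)GlcNAc"), "unbalanced")
  expect_error(parse_glycan("[Fuc(a1-4)]"), "end in a residue")
})

test_that("parse -> serialize -> parse is the identity on canonical forms", {
  for (s in c("Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)Glc",
              "Fuc(a1-2)Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)Glc",
              "Gal(b1-3)GlcNAc(b1-3)[Gal(b1-4)GlcNAc(b1-6)]Gal(b1-4)Glc",
              "Glc")) {
    g <- parse_glycan(s)
    expect_identical(serialize_glycan(parse_glycan(serialize_glycan(g))),
                     serialize_glycan(g))
  }
  # branch order is normalized: swapped branches parse to the same tree
  a <- parse_glycan("Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)Glc")
  b <- parse_glycan("Fuc(a1-4)[Gal(b1-3)]GlcNAc(b1-3)Gal(b1-4)Glc")
  expect_identical(serialize_glycan(a), serialize_glycan(b))
})

test_that("isomorphism ignores linkage annotations", {
  a <- parse_glycan("Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)Glc")
  b <- parse_glycan("Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-3)Gal(b1-4)Glc")
  expect_true(glycan_isomorphic(a, b))
  expect_false(glycan_isomorphic(a, pat_lewis_b()))
  # brute-force check on small trees: signature equality agrees with an
  # exhaustive search over child permutations
  brute_iso <- function(x, y) {
    rec <- function(gx, ix, gy, iy, kx, ky) {
      if (gx$class[ix] != gy$class[iy]) return(FALSE)
      cx <- kx[[ix]]; cy <- ky[[iy]]
      if (length(cx) != length(cy)) return(FALSE)
      if (!length(cx)) return(TRUE)
      perms <- function(v) if (length(v) <= 1) list(v) else {
        do.call(c, lapply(seq_along(v), function(i) {
          lapply(perms(v[-i]), function(p) c(v[i], p))
        }))
      }
      for (p in perms(cy)) {
        if (all(vapply(seq_along(cx), function(k) {
          rec(gx, cx[k], gy, p[k], kx, ky)
        }, logical(1)))) return(TRUE)
      }
      FALSE
    }
    rec(x, which(is.na(x$parent)), y, which(is.na(y$parent)),
        gipsmix:::.glycan_children(x), gipsmix:::.glycan_children(y))
  }
  trees <- list(a, b, pat_lewis_b(), pat_h_core(), pat_lewis_x(), gly_lnt())
  for (i in seq_along(trees)) {
    for (j in seq_along(trees)) {
      expect_identical(glycan_isomorphic(trees[[i]], trees[[j]]),
                       brute_iso(trees[[i]], trees[[j]]))
    }
  }
})

test_that("candidate lookup finds the isomer family at the observed m/z", {
  db <- gips_db("standards")
  cand <- find_candidates(db, 1274.64, tol = 0.5)
  expect_length(cand, 8L)
  expect_setequal(
    vapply(cand, `[[`, character(1), "id"),
    c("LNDFH-I", "LNnDFH-I", "DFH-syn-1", "DFH-syn-2", "DFH-syn-3",
      "LNDFH-II", "LNnDFH-II", "DFH-syn-4"))
  # exact tolerance returns the same family; far query returns nothing
  exact <- permethylated_mz(glycan_composition(dHex = 2, Hex = 3, HexNAc = 1))
  expect_length(find_candidates(db, exact, tol = 0.001), 8L)
  expect_length(find_candidates(db, 5000, tol = 0.5), 0L)
})

test_that("branching patterns partition the candidate records", {
  db <- gips_db("standards")
  cand <- find_candidates(db, 1274.64, tol = 0.5)
  reps <- branching_pattern_classes(cand)
  expect_length(reps, 3L)
  members <- lapply(reps, attr, "members")
  expect_setequal(unlist(members), seq_along(cand))      # covers the input
  expect_equal(sum(lengths(members)), length(cand))      # disjoint classes
  # representative of the Lewis-x pattern class contains LNnDFH-II
  ids <- lapply(reps, attr, "member_ids")
  expect_true(any(vapply(ids, function(x) "LNnDFH-II" %in% x, logical(1))))
  # single record maps to itself; linkage-only variants collapse to 1 class
  expect_length(branching_pattern_classes(cand[1]), 1L)
  two <- list(parse_glycan("Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)Glc"),
              parse_glycan("Gal(b1-4)GlcNAc(b1-6)Gal(b1-4)Glc"))
  expect_length(branching_pattern_classes(two), 1L)
})

test_that("databases load with consistent index masses", {
  for (which in c("standards", "hmo")) {
    db <- gips_db(which)
    expect_gt(length(db$records), 10L)
    for (r in db$records) {
      expect_equal(r$permethylated_mz, permethylated_mz(r$composition))
      expect_equal(r$native_mass, native_mass(r$composition))
    }
  }
})
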