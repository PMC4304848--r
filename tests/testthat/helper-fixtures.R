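# Shared fixtures (built once per test run) and independent oracles.

# A compact synthetic structure, its filtered tessellation, and a potential
# trained on a small independent corpus.
fix_structure <- generate_structure(60, seed = 101)
fix_tess <- tessellate(fix_structure, cutoff = 12)
fix_corpus <- generate_corpus(5, size_range = c(50, 90), seed = 202)
fix_potential <- train_potential(fix_corpus)

# Four points spanning a single tetrahedron, as a structure.
toy_structure <- as_structure(data.frame(
  seq_number = 1:4,
  aa = c("A", "C", "D", "E"),
  x = c(0, 3.8, 0, 0), y = c(0, 0, 3.8, 0), z = c(0, 0, 0, 3.8)))

# Brute-force Delaunay: every 4-subset whose circumsphere contains no other
# point, enumerated directly from the empty-circumsphere definition.
delaunay_oracle <- function(pts) {
  n <- nrow(pts)
  combs <- utils::combn(n, 4)
  diam <- max(apply(pts, 2, function(v) diff(range(v))))
  out <- list()
  for (k in seq_len(ncol(combs))) {
    idx <- combs[, k]
    P <- pts[idx, , drop = FALSE]
    A <- 2 * sweep(P[2:4, , drop = FALSE], 2, P[1, ])
    if (abs(det(A)) < 1e-10 * max(abs(A))^3) next  # flat quadruple
    b <- rowSums(P[2:4, , drop = FALSE]^2) - sum(P[1, ]^2)
    cc <- solve(A, b)
    r2 <- sum((P[1, ] - cc)^2)
    d2 <- rowSums(sweep(pts, 2, cc)^2)
    if (all(d2[-idx] > r2 + 1e-9 * diam^2)) out[[length(out) + 1]] <- idx
  }
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2], m[, 3], m[, 4]), , drop = FALSE]
}

# Convex-hull volume via the divergence theorem over boundary facets
# (facets belonging to exactly one tetrahedron), an independent route to the
# volume that the raw simplex volumes must sum to.
hull_volume_oracle <- function(tess) {
  simp <- tess$simplices
  combs <- utils::combn(4, 3)
  vol <- 0
  for (r in seq_len(nrow(simp))) {
    for (k in 1:4) {
      f <- sort(simp[r, combs[, k]])
      shared <- sum(apply(simp, 1, function(s) all(f %in% s)))
      if (shared != 1) next
      opp <- setdiff(simp[r, ], f)
      a <- tess$coords[f[1], ]; b <- tess$coords[f[2], ]
      cc <- tess$coords[f[3], ]; d <- tess$coords[opp, ]
      sv <- det(rbind(b - a, cc - a, d - a)) / 6  # signed, apex = opp vertex
      # outward orientation: contribution of the facet w.r.t. origin, signed
      # so that the opposite (interior) vertex lies on the negative side
      tri <- det(rbind(a, b, cc)) / 6
      vol <- vol + if (sv > 0) -tri else tri
    }
  }
  abs(vol)
}

# The 30 experimentally targeted thymidylate synthase positions with their
# native residues, and the 13-residue substitution set of the mutagenesis
# design.
ts_positions <- c(
  E14 = "E", D20 = "D", R21 = "R", T22 = "T", G23 = "G", T24 = "T",
  G25 = "G", T26 = "T", L27 = "L", S28 = "S", I29 = "I", F30 = "F",
  G31 = "G", Q33 = "Q", R35 = "R", W80 = "W", D81 = "D", D105 = "D",
  D110 = "D", N121 = "N", R126 = "R", R127 = "R", C146 = "C", H147 = "H",
  Q151 = "Q", R166 = "R", D169 = "D", N177 = "N", G204 = "G", E223 = "E")
ts_natives <- setNames(unname(ts_positions),
                       as.integer(sub("^[A-Z]", "", names(ts_positions))))
ts_substitution_set <- c("A", "C", "E", "F", "G", "H", "K", "L", "P",
                         "Q", "R", "S", "Y")

# Distribution of all 263 residue positions over quadrants by polarity
# (apolar / charged / polar), used in the chi-square analyses.
ts_quadrant_polarity_counts <- matrix(
  c(8, 6, 21,
    11, 44, 38,
    7, 8, 9,
    77, 1, 33),
  nrow = 4, byrow = TRUE,
  dimnames = list(c("Q1", "Q2", "Q3", "Q4"),
                  c("apolar", "charged", "polar")))

# A labeled variant feature set for ML tests: noiseless threshold labels.
make_labeled_features <- function(n_variants, epsilon = 0, seed = 77) {
  vd <- generate_variant_dataset(fix_structure, fix_potential, n_variants,
                                 epsilon = epsilon, seed = seed,
                                 tess = fix_tess)
  encode_dataset(vd, fix_structure, fix_tess, fix_potential)
}
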