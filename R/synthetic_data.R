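#' Generate a protein-like C-alpha trace
#'
#' A compact self-avoiding random walk emulating a coarse-grained protein
#' backbone: consecutive C-alpha spacing of `step` Angstrom (within 1%), all
#' pairwise distances at least `min_separation`, and confinement to a sphere
#' whose radius scales as `3.3 * n^(1/3)` so the resulting tessellations have
#' protein-like edge-length spectra (mostly under 12 Angstrom).  Residues are
#' drawn from `composition`; secondary structure is labeled coil.
#'
#' @param n_residues Number of residues (`>= 4`).
#' @param step Consecutive C-alpha distance in Angstrom (default 3.8).
#' @param min_separation Minimum pairwise distance in Angstrom (default 3.5).
#' @param composition Named probability vector over the 20 residues
#'   (default uniform).
#' @param seed Integer seed; identical seeds give identical structures.
#' @param compactness Multiplier on the confinement radius (default 1).
#' @return A `quadpot_structure` with positions numbered from 1.
#' @examples
#' st <- generate_structure(50, seed = 1)
#' range(sqrt(rowSums(diff(as.matrix(st[c("x", "y", "z")]))^2)))
#' @export
generate_structure <- function(n_residues, step = 3.8, min_separation = 3.5,
                               composition = NULL, seed = 1L,
                               compactness = 1) {
  stopifnot(n_residues >= 4)
  if (is.null(composition)) {
    composition <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  stopifnot(all(names(composition) %in% AA_ALPHABET),
            abs(sum(composition) - 1) < 1e-6)
  radius <- compactness * 3.3 * n_residues^(1 / 3)
  withr::with_seed(seed, {
    for (restart in 1:50) {
      pts <- matrix(NA_real_, n_residues, 3)
      pts[1, ] <- c(0, 0, 0)
      ok <- TRUE
      for (i in 2:n_residues) {
        placed <- FALSE
        for (try in 1:200) {
          dir <- stats::rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          len <- step * stats::runif(1, 0.99, 1.01)
          cand <- pts[i - 1, ] + dir * len
          if (sqrt(sum(cand^2)) > radius) next
          if (i > 2) {
            d2 <- rowSums(sweep(pts[1:(i - 2), , drop = FALSE], 2, cand)^2)
            if (min(d2) < min_separation^2) next
          }
          pts[i, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) abort("self-avoiding walk failed; relax the constraints")
    aa <- sample(names(composition), n_residues, replace = TRUE,
                 prob = composition)
    new_structure(
      tibble(seq_number = seq_len(n_residues), icode = "", aa = aa,
             x = pts[, 1], y = pts[, 2], z = pts[, 3], ss = "C"),
      chain_id = "A")
  })
}

#' Generate a synthetic training corpus
#'
#' A list of independent synthetic structures standing in for a structure
#' training corpus, with sizes drawn uniformly from `size_range`.
#'
#' @param n_structures Number of chains (`>= 1`).
#' @param size_range Integer range of chain lengths (default 60 to 120).
#' @param composition Residue composition (default uniform).
#' @param seed Integer seed.
#' @return A list of `quadpot_structure` objects.
#' @export
generate_corpus <- function(n_structures, size_range = c(60, 120),
                            composition = NULL, seed = 1L) {
  stopifnot(n_structures >= 1)
  sizes <- withr::with_seed(seed,
    sample(seq(size_range[1], size_range[2]), n_structures, replace = TRUE))
  purrr::map(seq_len(n_structures), function(i) {
    generate_structure(sizes[i], composition = composition,
                       seed = seed * 1000L + i)
  })
}

#' Generate a labeled synthetic variant dataset
#'
#' Samples variants uniformly over (position, replacement != native), scores
#' each with [residual_score()], and labels it detrimentally affected (`A`)
#' when the residual score falls below the threshold `tau`, unaffected (`U`)
#' otherwise; labels are then flipped independently with probability
#' `epsilon`.  By default `tau` is the median residual score of the sampled
#' variants, which targets a near-balanced class split.
#'
#' @param structure A `quadpot_structure`.
#' @param potential A `quadpot_potential` covering the needed quadruplets.
#' @param n_variants Number of distinct variants to sample.
#' @param tau Labeling threshold on the residual score (default: median).
#' @param epsilon Label-flip noise in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param tess Optional precomputed filtered tessellation of `structure`.
#' @param cutoff Edge cutoff when `tess` is not supplied.
#' @return A tibble `position`, `native`, `replacement`, `residual_score`,
#'   `activity`, with `tau` as an attribute.
#' @export
generate_variant_dataset <- function(structure, potential, n_variants,
                                     tau = NULL, epsilon = 0, seed = 1L,
                                     tess = NULL, cutoff = 12) {
  stopifnot(epsilon >= 0, epsilon < 0.5)
  if (is.null(tess)) tess <- tessellate(structure, cutoff = cutoff)
  all_v <- enumerate_variants(
    setNames(structure$aa, structure$seq_number), AA_ALPHABET)
  if (n_variants > nrow(all_v)) abort("n_variants exceeds the variant space")
  picked <- withr::with_seed(seed, sample(nrow(all_v), n_variants))
  vars <- all_v[sort(picked), , drop = FALSE]
  vars$residual_score <- purrr::map_dbl(seq_len(nrow(vars)), function(i) {
    suppressWarnings(
      residual_score(tess, structure, potential, vars[i, , drop = FALSE]))
  })
  if (is.null(tau)) tau <- median(vars$residual_score)
  lab <- ifelse(vars$residual_score < tau, "A", "U")
  if (epsilon > 0) {
    flip <- withr::with_seed(seed + 1L,
                             stats::runif(nrow(vars)) < epsilon)
    lab <- ifelse(flip, ifelse(lab == "U", "A", "U"), lab)
  }
  vars$activity <- lab
  attr(vars, "tau") <- tau
  vars
}
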