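#' Parse a variant string
#'
#' Accepts compact notation such as `"E14C"` (native, position, replacement)
#' or a list/tibble row with `position`, `native`, `replacement`.
#'
#' @param variant Variant in any accepted form.
#' @return A list with `position`, `native`, `replacement`.
#' @export
parse_variant <- function(variant) {
  if (is.list(variant)) {
    v <- list(position = as.integer(variant$position),
              native = as.character(variant$native),
              replacement = as.character(variant$replacement))
  } else {
    m <- regmatches(variant,
                    regexec("^([A-Z])([0-9]+)([A-Z])$", as.character(variant)))[[1]]
    if (length(m) != 4) abort(paste0("cannot parse variant '", variant, "'"))
    v <- list(position = as.integer(m[3]), native = m[2], replacement = m[4])
  }
  if (!all(c(v$native, v$replacement) %in% AA_ALPHABET)) {
    abort("variant uses a letter outside the 20-letter alphabet")
  }
  v
}

check_native <- function(sequence, tess, v) {
  idx <- match(v$position, tess$positions)
  if (is.na(idx)) abort(paste0("position ", v$position, " not in structure"))
  if (sequence[idx] != v$native) {
    abort(paste0("native mismatch at position ", v$position, ": structure has ",
                 sequence[idx], ", variant says ", v$native))
  }
  idx
}

#' Total potential of a structure
#'
#' Assigns each retained tetrahedron the score of its residue quadruplet and
#' sums over all tetrahedra.
#'
#' @param tess A `quadpot_tessellation` (edge-filtered).
#' @param sequence A `quadpot_structure`, or a character vector of one-letter
#'   codes covering the tessellation vertices (named by position, or aligned).
#' @param potential A `quadpot_potential`.
#' @return The total potential (scalar).
#' @export
total_potential <- function(tess, sequence, potential) {
  seqv <- resolve_sequence(sequence, tess)
  sum(lookup_scores(potential, simplex_keys(tess, seqv)))
}

#' Residue environment scores (3D-1D potential profile)
#'
#' The environment score `q_i` of a position is the sum of the scores of all
#' tetrahedra sharing its C-alpha as a vertex; the vector over positions is
#' the 3D-1D potential profile.  Each tetrahedron contributes its score to
#' exactly four positions, so `sum(q) = 4 * total_potential`.  Isolated
#' vertices score 0.
#'
#' @inheritParams total_potential
#' @return A tibble `position`, `aa`, `q`.
#' @export
potential_profile <- function(tess, sequence, potential) {
  seqv <- resolve_sequence(sequence, tess)
  q <- numeric(nrow(tess$coords))
  if (nrow(tess$simplices) > 0) {
    sc <- lookup_scores(potential, simplex_keys(tess, seqv))
    for (col in 1:4) {
      contrib <- tapply(sc, tess$simplices[, col], sum)
      vi <- as.integer(names(contrib))
      q[vi] <- q[vi] + as.vector(contrib)
    }
  }
  tibble(position = tess$positions, aa = seqv, q = q)
}

#' Residual profile of a single-residue variant
#'
#' Introduces the substitution by relabeling the residue at the mutated
#' C-alpha vertex -- the tessellation itself is unaltered -- and records the
#' environmental perturbation `EP_i = q_i_mut - q_i_wt` at every position.
#' EP is nonzero only at the mutated position and its tessellation neighbors.
#' The EP score at the mutated position is the variant's residual score and
#' equals `tp_mut - tp_wt`.
#'
#' @inheritParams total_potential
#' @param variant A variant (see [parse_variant()]); the native letter must
#'   match the structure.
#' @return A tibble `position`, `aa`, `ep` with attribute `residual_score`.
#' @examples
#' st <- generate_structure(40, seed = 2)
#' pot <- train_potential(generate_corpus(3, seed = 3))
#' tess <- tessellate(st, cutoff = 12)
#' rp <- residual_profile(tess, st, pot, paste0(st$aa[10], st$seq_number[10], "W"))
#' attr(rp, "residual_score")
#' @export
residual_profile <- function(tess, sequence, potential, variant) {
  seqv <- resolve_sequence(sequence, tess)
  v <- parse_variant(variant)
  idx <- check_native(seqv, tess, v)
  mut <- seqv
  mut[idx] <- v$replacement

  q_wt <- numeric(nrow(tess$coords))
  q_mut <- numeric(nrow(tess$coords))
  touched <- which(apply(tess$simplices == idx, 1L, any))
  if (nrow(tess$simplices) == 0) touched <- integer()
  if (length(touched) == 0 && v$replacement != v$native) {
    warn(paste0("position ", v$position,
                " is isolated (no incident tetrahedra); all-zero profile"))
  }
  for (k in touched) {
    s <- tess$simplices[k, ]
    dq <- lookup_scores(potential, canonical_key(mut[s])) -
      lookup_scores(potential, canonical_key(seqv[s]))
    q_mut[s] <- q_mut[s] + dq
  }
  ep <- q_mut - q_wt
  out <- tibble(position = tess$positions, aa = seqv, ep = ep)
  class(out) <- c("quadpot_residual_profile", class(out))
  attr(out, "residual_score") <- ep[idx]
  attr(out, "variant") <- v
  out
}

#' Residual score of a variant
#'
#' Computed by two independent routes -- the EP score at the mutated position
#' and the total-potential difference `tp_mut - tp_wt` -- which are asserted
#' to agree within `1e-9`.
#'
#' @inheritParams residual_profile
#' @return The residual score (scalar).
#' @export
residual_score <- function(tess, sequence, potential, variant) {
  seqv <- resolve_sequence(sequence, tess)
  v <- parse_variant(variant)
  idx <- check_native(seqv, tess, v)
  rp <- suppressWarnings(residual_profile(tess, seqv, potential, v))
  via_profile <- attr(rp, "residual_score")
  mut <- seqv
  mut[idx] <- v$replacement
  via_tp <- total_potential(tess, mut, potential) -
    total_potential(tess, seqv, potential)
  if (abs(via_profile - via_tp) > 1e-9) {
    abort("internal inconsistency: profile and total-potential routes disagree")
  }
  via_profile
}

#' Comprehensive mutational profile
#'
#' For each position, the mean of the residual scores of all 19 possible
#' replacements of the native residue.  Isolated positions score 0.
#'
#' @inheritParams total_potential
#' @return A tibble `position`, `aa`, `q` (native environment score), `cmp`.
#' @export
comprehensive_mutational_profile <- function(tess, sequence, potential) {
  seqv <- resolve_sequence(sequence, tess)
  prof <- potential_profile(tess, seqv, potential)
  n <- nrow(tess$coords)
  cmp <- numeric(n)
  incident <- purrr::map(seq_len(n), function(i) {
    which(apply(tess$simplices == i, 1L, any))
  })
  if (nrow(tess$simplices) == 0) incident <- purrr::map(seq_len(n), ~integer())
  for (i in seq_len(n)) {
    ks <- incident[[i]]
    if (length(ks) == 0) next
    wt_keys <- simplex_keys_subset(tess, seqv, ks)
    wt_score <- sum(lookup_scores(potential, wt_keys))
    alts <- setdiff(AA_ALPHABET, seqv[i])
    res <- vapply(alts, function(aa) {
      mut <- seqv
      mut[i] <- aa
      sum(lookup_scores(potential, simplex_keys_subset(tess, mut, ks))) - wt_score
    }, numeric(1))
    cmp[i] <- mean(res)
  }
  tibble(position = prof$position, aa = prof$aa, q = prof$q, cmp = cmp)
}

simplex_keys_subset <- function(tess, sequence, rows) {
  aa <- matrix(sequence[as.vector(tess$simplices[rows, , drop = FALSE])],
               nrow = length(rows))
  canonical_key(aa)
}
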