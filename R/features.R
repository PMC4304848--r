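#' Six nearest tessellation neighbors of a position
#'
#' Neighbors (edge-connected positions) ordered by ascending C-alpha
#' Euclidean distance (the length of the connecting tetrahedral edge), ties
#' broken by ascending sequence number, truncated to at most six.
#'
#' @param tess A `quadpot_tessellation` (edge-filtered).
#' @param position Residue position.
#' @return A tibble `position`, `distance`, at most 6 rows.
#' @export
nearest_six_neighbors <- function(tess, position) {
  v <- vertex_of_position(tess, position)
  e <- tess_edges(tess)
  inc <- e[e$i == v | e$j == v, , drop = FALSE]
  other <- ifelse(inc$i == v, inc$j, inc$i)
  nb <- tibble(position = tess$positions[other], distance = inc$length)
  nb <- dplyr::arrange(nb, .data$distance, .data$position)
  utils::head(nb, 6L)
}

#' Build the 27-attribute feature vector of one variant
#'
#' The attributes are: mutated position number; native and replacement
#' residues; residual score; EP scores, residue identities and sequence
#' offsets (neighbor minus mutated position number) of the six nearest
#' neighbors, each triple ordered by proximity; mean volume and mean
#' tetrahedrality of the tetrahedra incident to the mutated position;
#' secondary structure (H/S/C); depth (S/U/B); and the count of tessellation
#' edges shared with surface positions.  Positions with fewer than six
#' neighbors are padded (EP 0, identity `"-"`, offset 0) and flagged in the
#' auxiliary `padded` column, which is not one of the 27 attributes.
#'
#' @param structure A `quadpot_structure`.
#' @param tess Its edge-filtered tessellation.
#' @param potential A `quadpot_potential`.
#' @param variant A variant (see [parse_variant()]).
#' @param label Optional activity label, `"U"` (unaffected) or `"A"`
#'   (detrimentally affected).
#' @param depth Optional precomputed [classify_depth()] table (recomputed
#'   when `NULL`).
#' @return A one-row tibble with the 27 attribute columns, `padded`, and
#'   (when given) `activity`.
#' @export
build_feature_vector <- function(structure, tess, potential, variant,
                                 label = NULL, depth = NULL) {
  v <- parse_variant(variant)
  seqv <- resolve_sequence(structure, tess)
  idx <- check_native(seqv, tess, v)
  rp <- suppressWarnings(residual_profile(tess, seqv, potential, v))

  nb <- nearest_six_neighbors(tess, v$position)
  k <- nrow(nb)
  ep_n <- rep(0, 6)
  aa_n <- rep("-", 6)
  off_n <- rep(0L, 6)
  if (k > 0) {
    ord_idx <- match(nb$position, rp$position)
    ep_n[seq_len(k)] <- rp$ep[ord_idx]
    aa_n[seq_len(k)] <- seqv[match(nb$position, tess$positions)]
    off_n[seq_len(k)] <- as.integer(nb$position - v$position)
  }

  inc <- which(apply(tess$simplices == idx, 1L, any))
  if (nrow(tess$simplices) == 0) inc <- integer()
  if (length(inc) > 0) {
    geo <- purrr::map_dfr(inc, function(r) {
      tetrahedron_geometry(tess$coords[tess$simplices[r, ], , drop = FALSE])
    })
    mean_vol <- mean(geo$volume)
    mean_tet <- mean(geo$tetrahedrality)
  } else {
    mean_vol <- 0
    mean_tet <- 0
  }

  if (is.null(depth)) depth <- suppressWarnings(classify_depth(tess))
  dep <- depth$depth[match(v$position, depth$position)]
  sec <- surface_edge_count(tess, v$position, depth = depth)
  ss <- structure$ss[match(v$position, structure$seq_number)]

  out <- tibble(
    position = v$position, native = v$native, replacement = v$replacement,
    residual_score = attr(rp, "residual_score"),
    ep_n1 = ep_n[1], ep_n2 = ep_n[2], ep_n3 = ep_n[3],
    ep_n4 = ep_n[4], ep_n5 = ep_n[5], ep_n6 = ep_n[6],
    aa_n1 = aa_n[1], aa_n2 = aa_n[2], aa_n3 = aa_n[3],
    aa_n4 = aa_n[4], aa_n5 = aa_n[5], aa_n6 = aa_n[6],
    offset_n1 = off_n[1], offset_n2 = off_n[2], offset_n3 = off_n[3],
    offset_n4 = off_n[4], offset_n5 = off_n[5], offset_n6 = off_n[6],
    mean_volume = mean_vol, mean_tetrahedrality = mean_tet,
    ss = ss, depth = dep, surface_edges = as.integer(sec),
    padded = k < 6L)
  if (!is.null(label)) {
    stopifnot(label %in% c("U", "A"))
    out$activity <- label
  }
  out
}

#' Names of the 27 input attributes
#' @return Character vector of the 27 feature-column names, in order.
#' @export
feature_attribute_names <- function() {
  c("position", "native", "replacement", "residual_score",
    paste0("ep_n", 1:6), paste0("aa_n", 1:6), paste0("offset_n", 1:6),
    "mean_volume", "mean_tetrahedrality", "ss", "depth", "surface_edges")
}

#' Enumerate single-residue variants over a substitution design
#'
#' All `(position, native, replacement)` triples obtained by introducing each
#' residue of `substitution_set` at each position, excluding identity
#' replacements.  A position whose native residue belongs to the set thus
#' yields one fewer variant.
#'
#' @param natives Named character vector (names = positions) or a tibble with
#'   `position`, `native`.
#' @param substitution_set Character vector of replacement residues.
#' @return A tibble `position`, `native`, `replacement`, ordered by
#'   (position, replacement).
#' @export
enumerate_variants <- function(natives, substitution_set) {
  if (!is.data.frame(natives)) {
    natives <- tibble(position = as.integer(names(natives)),
                      native = unname(natives))
  }
  stopifnot(all(natives$native %in% AA_ALPHABET),
            all(substitution_set %in% AA_ALPHABET))
  out <- tidyr::crossing(natives, replacement = substitution_set) |>
    dplyr::filter(.data$replacement != .data$native) |>
    dplyr::arrange(.data$position, .data$replacement)
  out[c("position", "native", "replacement")]
}

#' Encode a variant list as a feature table
#'
#' One row per variant with the 27 input attributes (plus `padded` and, when
#' labels are supplied, `activity`), in deterministic
#' (position, replacement) order.
#'
#' @param variants Tibble with `position`, `native`, `replacement` and
#'   optionally `activity`.
#' @param structure,tess,potential As in [build_feature_vector()].
#' @param labels Optional vector of `"U"`/`"A"` labels aligned with
#'   `variants` (overrides an `activity` column).
#' @return A tibble of feature vectors.
#' @export
encode_dataset <- function(variants, structure, tess, potential,
                           labels = NULL) {
  if (is.null(labels) && "activity" %in% names(variants)) {
    labels <- variants$activity
  }
  if (!is.null(labels)) stopifnot(length(labels) == nrow(variants))
  if (anyDuplicated(variants[c("position", "replacement")]) > 0) {
    abort("duplicate variant in input")
  }
  ord <- order(variants$position, variants$replacement)
  variants <- variants[ord, , drop = FALSE]
  if (!is.null(labels)) labels <- labels[ord]
  depth <- suppressWarnings(classify_depth(tess))
  rows <- purrr::map(seq_len(nrow(variants)), function(i) {
    build_feature_vector(structure, tess, potential,
                         variants[i, , drop = FALSE],
                         label = if (is.null(labels)) NULL else labels[i],
                         depth = depth)
  })
  if (length(rows) == 0) {
    proto <- tibble(position = integer(), native = character(),
                    replacement = character(), residual_score = numeric())
    for (nm in paste0("ep_n", 1:6)) proto[[nm]] <- numeric()
    for (nm in paste0("aa_n", 1:6)) proto[[nm]] <- character()
    for (nm in paste0("offset_n", 1:6)) proto[[nm]] <- integer()
    proto$mean_volume <- numeric()
    proto$mean_tetrahedrality <- numeric()
    proto$ss <- character()
    proto$depth <- character()
    proto$surface_edges <- integer()
    proto$padded <- logical()
    return(proto)
  }
  dplyr::bind_rows(rows)
}
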