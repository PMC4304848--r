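#' Delaunay tessellation of a C-alpha point set
#'
#' Computes the 3D Delaunay triangulation of the residue C-alpha coordinates.
#' Tetrahedra satisfy the empty-circumsphere property and tile the convex
#' hull.  Degenerate inputs (cospherical or coplanar configurations, e.g.
#' lattice-like point sets) are resolved by a deterministic joggle: a fixed
#' pseudo-random perturbation of at most 1e-6 Angstrom per coordinate, flagged
#' in the result.
#'
#' @param x A `quadpot_structure` or a numeric matrix of points (n x 3).
#' @param cutoff Optional edge-length cutoff in Angstrom; when supplied the
#'   raw tessellation is immediately passed through
#'   [filter_by_edge_length()].  The default `NULL` returns the raw
#'   tessellation.
#' @return A `quadpot_tessellation`: list with `coords` (n x 3), `positions`
#'   (residue numbering for each vertex), `simplices` (m x 4 matrix of vertex
#'   indices), `cutoff` (NA for raw), and `joggled`.
#' @examples
#' st <- generate_structure(n_residues = 30, seed = 1)
#' tess <- tessellate(st, cutoff = 12)
#' nrow(tess$simplices)
#' @export
tessellate <- function(x, cutoff = NULL) {
  if (inherits(x, "quadpot_structure")) {
    coords <- structure_coords(x)
    positions <- x$seq_number
  } else {
    coords <- as.matrix(x)
    positions <- if (is.null(rownames(coords))) seq_len(nrow(coords)) else
      as.integer(rownames(coords))
  }
  storage.mode(coords) <- "double"
  if (nrow(coords) < 4) abort("at least 4 points are required to tessellate")
  if (anyDuplicated(coords) > 0) abort("coincident points cannot be tessellated")

  res <- .delaunay3d_cpp(coords)
  # Joggle schedule: the nominal 1e-6 A perturbation first; highly structured
  # inputs (lattices with collinear/cocircular runs) can defeat it within
  # double precision, so later attempts escalate to at most 1e-3 A -- still
  # negligible against the 3.8 A backbone scale.
  amplitudes <- c(1e-6, 1e-6, 1e-4, 5e-4, 1e-3, 1e-3, 2e-3, 5e-3)
  amplitude <- 0
  attempt <- 0L
  while (res$degenerate && attempt < length(amplitudes)) {
    attempt <- attempt + 1L
    amplitude <- amplitudes[attempt]
    pts <- coords + amplitude * joggle_perturbation(length(coords), attempt)
    res <- .delaunay3d_cpp(pts)
  }
  joggled <- attempt > 0L
  if (res$degenerate) {
    abort("degenerate point configuration; tessellation failed even after joggle")
  }
  if (joggled) {
    warn(sprintf(
      "degenerate point configuration: applied deterministic joggle (%g A)",
      amplitude))
  }
  tess <- structure(
    list(coords = coords, positions = as.integer(positions),
         simplices = res$simplices, cutoff = NA_real_, joggled = joggled,
         joggle_amplitude = amplitude),
    class = "quadpot_tessellation")
  if (!is.null(cutoff)) tess <- filter_by_edge_length(tess, cutoff) else tess
}

# Deterministic unit-amplitude perturbations from a Lehmer generator,
# independent of R's global RNG state.
joggle_perturbation <- function(n, attempt) {
  m <- 2147483647
  x <- (12345 + 7919 * attempt) %% m
  u <- numeric(n)
  for (i in seq_len(n)) {
    x <- (48271 * x) %% m
    u[i] <- x / m
  }
  (u - 0.5) * 2
}

#' @export
print.quadpot_tessellation <- function(x, ...) {
  cat("<quadpot_tessellation>\n")
  cat("  vertices: ", nrow(x$coords), "\n", sep = "")
  cat("  simplices:", nrow(x$simplices), "\n")
  cat("  cutoff:   ",
      if (is.na(x$cutoff)) "none (raw)" else paste0(x$cutoff, " A"), "\n",
      sep = "")
  if (isTRUE(x$joggled)) cat("  joggled:  yes\n")
  invisible(x)
}

#' Remove tetrahedra with edges beyond a cutoff
#'
#' Drops every tetrahedron having any edge longer than `cutoff` (strictly;
#' edges of exactly the cutoff length are retained).  Long edges typically
#' connect non-interacting surface residues added only to complete the convex
#' hull, so filtering exposes surface clefts and pockets.  Vertices may become
#' simplex-free (isolated).
#'
#' @param tess A `quadpot_tessellation`.
#' @param cutoff Edge-length cutoff in Angstrom (default 12).
#' @return The filtered tessellation, with `cutoff` recorded.
#' @export
filter_by_edge_length <- function(tess, cutoff = 12) {
  stopifnot(inherits(tess, "quadpot_tessellation"))
  keep <- apply(tess$simplices, 1L, function(s) {
    max(simplex_edge_lengths(tess$coords[s, , drop = FALSE])) <= cutoff
  })
  if (nrow(tess$simplices) == 0) keep <- logical(0)
  tess$simplices <- tess$simplices[keep, , drop = FALSE]
  tess$cutoff <- cutoff
  tess
}

# The 6 edge lengths of a 4 x 3 coordinate block (fixed pair order
# 1-2, 1-3, 1-4, 2-3, 2-4, 3-4).
simplex_edge_lengths <- function(p) {
  prs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  sqrt(rowSums((p[prs[, 1], , drop = FALSE] - p[prs[, 2], , drop = FALSE])^2))
}

# Unique undirected vertex-index edges of the retained simplices, with
# lengths; tibble(i, j, length), i < j.
tess_edges <- function(tess) {
  if (nrow(tess$simplices) == 0) {
    return(tibble(i = integer(), j = integer(), length = numeric()))
  }
  prs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  a <- as.vector(tess$simplices[, prs[, 1]])
  b <- as.vector(tess$simplices[, prs[, 2]])
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  e <- dplyr::distinct(tibble(i = lo, j = hi))
  e$length <- sqrt(rowSums((tess$coords[e$i, , drop = FALSE] -
                              tess$coords[e$j, , drop = FALSE])^2))
  e
}

vertex_of_position <- function(tess, position) {
  v <- match(position, tess$positions)
  if (is.na(v)) abort(paste0("position ", position, " is not a vertex"))
  v
}

#' Tessellation neighbors of a residue position
#'
#' The structural neighborhood of a position: all residues whose C-alphas are
#' connected to it by a tetrahedral edge of the (typically filtered)
#' tessellation.
#'
#' @param tess A `quadpot_tessellation`.
#' @param position Residue position (author numbering).
#' @return Integer vector of neighbor positions (empty for isolated vertices).
#' @export
residue_neighbors <- function(tess, position) {
  v <- vertex_of_position(tess, position)
  e <- tess_edges(tess)
  nb <- sort(unique(c(e$j[e$i == v], e$i[e$j == v])))
  tess$positions[nb]
}

#' Volume and tetrahedrality of one tetrahedron
#'
#' Volume is `|det|/6` of the edge-vector matrix.  Tetrahedrality measures
#' distortion from regularity: `sum_{i>j} (l_i - l_j)^2 / (15 * lbar^2)` over
#' all 15 pairs of the 6 edge lengths, zero iff all edges are equal.
#'
#' @param coords A 4 x 3 matrix of vertex coordinates.
#' @return A one-row tibble: `volume`, `tetrahedrality`, `l1`..`l6`,
#'   `mean_edge`.
#' @export
tetrahedron_geometry <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 4, ncol(coords) == 3)
  l <- simplex_edge_lengths(coords)
  vol <- abs(det(rbind(coords[2, ] - coords[1, ],
                       coords[3, ] - coords[1, ],
                       coords[4, ] - coords[1, ]))) / 6
  lbar <- mean(l)
  tet <- if (lbar > 0) sum(outer(l, l, "-")[lower.tri(matrix(0, 6, 6))]^2) /
    (15 * lbar^2) else NA_real_
  tibble(volume = vol, tetrahedrality = tet,
         l1 = l[1], l2 = l[2], l3 = l[3], l4 = l[4], l5 = l[5], l6 = l[6],
         mean_edge = lbar)
}

#' Per-simplex geometry table
#'
#' @param tess A `quadpot_tessellation`.
#' @return A tibble with one row per retained simplex: the four vertex
#'   positions `p1`..`p4`, edge lengths `l1`..`l6`, `volume`,
#'   `tetrahedrality`.
#' @export
simplex_geometry <- function(tess) {
  stopifnot(inherits(tess, "quadpot_tessellation"))
  rows <- purrr::map(seq_len(nrow(tess$simplices)), function(k) {
    s <- tess$simplices[k, ]
    g <- tetrahedron_geometry(tess$coords[s, , drop = FALSE])
    dplyr::bind_cols(tibble(p1 = tess$positions[s[1]], p2 = tess$positions[s[2]],
                            p3 = tess$positions[s[3]], p4 = tess$positions[s[4]]),
                     g[c("l1", "l2", "l3", "l4", "l5", "l6",
                         "volume", "tetrahedrality")])
  })
  if (length(rows) == 0) {
    return(tibble(p1 = integer(), p2 = integer(), p3 = integer(),
                  p4 = integer(), l1 = numeric(), l2 = numeric(),
                  l3 = numeric(), l4 = numeric(), l5 = numeric(),
                  l6 = numeric(), volume = numeric(),
                  tetrahedrality = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Tessellation-based residue depth
#'
#' Classifies every position as surface (`S`), undersurface (`U`) or buried
#' (`B`).  A position is on the surface when it is a vertex of a triangular
#' facet belonging to exactly one tetrahedron (an unshared, i.e. boundary,
#' facet); undersurface when it is not on the surface but is connected to a
#' surface position by a tetrahedral edge; buried otherwise.  Isolated
#' vertices (all incident tetrahedra removed by the edge filter) sit on the
#' structure's exterior and are labeled `S` with a warning.
#'
#' @param tess A `quadpot_tessellation` (normally edge-filtered).
#' @return A tibble with columns `position`, `depth`.
#' @export
classify_depth <- function(tess) {
  stopifnot(inherits(tess, "quadpot_tessellation"))
  n <- nrow(tess$coords)
  m <- nrow(tess$simplices)
  depth <- rep("B", n)
  if (m > 0) {
    combs <- utils::combn(4, 3)
    fac <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
      f <- tess$simplices[, combs[, k], drop = FALSE]
      t(apply(f, 1, sort))
    }))
    key <- paste(fac[, 1], fac[, 2], fac[, 3])
    once <- key[!(key %in% key[duplicated(key)])]
    surf_v <- unique(as.integer(unlist(strsplit(once, " ", fixed = TRUE))))
    depth[surf_v] <- "S"
    if (isTRUE(tess$joggled)) {
      # The joggle can push a vertex that lies exactly on the boundary (e.g.
      # on a lattice face) infinitesimally inside, costing it its unshared
      # facets.  Restore S for vertices within joggle reach of a boundary
      # facet.
      bfac <- matrix(as.integer(unlist(strsplit(once, " ", fixed = TRUE))),
                     ncol = 3, byrow = TRUE)
      reach <- 20 * max(tess$joggle_amplitude, 1e-6)
      cand <- setdiff(seq_len(n), surf_v)
      for (v in cand) {
        p <- tess$coords[v, ]
        for (r in seq_len(nrow(bfac))) {
          d <- point_triangle_distance(p, tess$coords[bfac[r, 1], ],
                                       tess$coords[bfac[r, 2], ],
                                       tess$coords[bfac[r, 3], ])
          if (d <= reach) { depth[v] <- "S"; break }
        }
      }
      surf_v <- which(depth == "S")
    }
    e <- tess_edges(tess)
    near_s <- unique(c(e$i[depth[e$j] == "S"], e$j[depth[e$i] == "S"]))
    depth[setdiff(near_s, surf_v)] <- "U"
  }
  used <- if (m > 0) unique(as.vector(tess$simplices)) else integer()
  isolated <- setdiff(seq_len(n), used)
  if (length(isolated) > 0) {
    depth[isolated] <- "S"
    warn(paste0(length(isolated),
                " isolated vertex/vertices labeled surface (S)"))
  }
  tibble(position = tess$positions, depth = depth)
}

# Euclidean distance from a point to a triangle (Ericson-style region test).
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    t <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + t * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - c)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    t <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + t * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    t <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + t * (c - b)))^2)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  sqrt(sum((p - (a + v * ab + w * ac))^2))
}

#' Count tessellation edges shared with surface positions
#'
#' The number of retained edges between a position and surface-labeled
#' positions; zero by definition for buried positions.
#'
#' @param tess A `quadpot_tessellation`.
#' @param position Residue position; `NULL` returns counts for all positions.
#' @param depth Optional precomputed [classify_depth()] table.
#' @return An integer (single position) or a tibble `position`,
#'   `surface_edges`.
#' @export
surface_edge_count <- function(tess, position = NULL, depth = NULL) {
  if (is.null(depth)) depth <- suppressWarnings(classify_depth(tess))
  is_s <- depth$depth[match(tess$positions, depth$position)] == "S"
  e <- tess_edges(tess)
  cnt <- integer(nrow(tess$coords))
  tab_i <- table(e$i[is_s[e$j]])
  tab_j <- table(e$j[is_s[e$i]])
  cnt[as.integer(names(tab_i))] <- cnt[as.integer(names(tab_i))] + as.integer(tab_i)
  cnt[as.integer(names(tab_j))] <- cnt[as.integer(names(tab_j))] + as.integer(tab_j)
  if (!is.null(position)) {
    return(cnt[vertex_of_position(tess, position)])
  }
  tibble(position = tess$positions, surface_edges = cnt)
}
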