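#' Read a PDB file into a C-alpha coarse-grained structure
#'
#' Parses a PDB entry (via [bio3d::read.pdb()]) and reduces the selected chain
#' to one record per residue: author sequence number, one-letter amino acid
#' code, and the C-alpha coordinates.  Alternate locations are resolved to the
#' highest-occupancy conformer (ties broken by file order), residues without a
#' C-alpha atom are dropped with a warning, and nonstandard residues are
#' mapped (MSE to M, SEC to C) or dropped.  Three-state secondary structure
#' (H/S/C) is assigned from the HELIX/SHEET records of the same entry.
#'
#' @param pdb Path to a PDB file, or a character scalar holding raw PDB text
#'   (recognised by embedded newlines).
#' @param chain Chain identifier.  `NULL` selects the first chain containing
#'   C-alpha atoms.
#' @return A `quadpot_structure`: a tibble with columns `seq_number`, `icode`,
#'   `aa`, `x`, `y`, `z`, `ss`, plus a `chain_id` attribute.
#' @examples
#' pdb <- example_pdb_text()
#' read_structure(pdb, chain = "A")
#' @export
read_structure <- function(pdb, chain = NULL) {
  path <- as_pdb_path(pdb)
  parsed <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- parsed$atom

  if (is.null(chain)) {
    ch <- unique(atoms$chain[atoms$elety == "CA"])
    if (length(ch) == 0) abort("no C-alpha atoms found in PDB input")
    chain <- ch[[1]]
  }
  ca <- atoms[atoms$elety == "CA" & atoms$chain %in% chain &
                atoms$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(ca) == 0) {
    abort(paste0("chain '", chain, "' not found or has no C-alpha atoms"))
  }
  ca$insert[is.na(ca$insert)] <- ""
  ca$alt[is.na(ca$alt)] <- ""
  ca$o[is.na(ca$o)] <- 1
  ca$.file_order <- seq_len(nrow(ca))

  # altloc resolution: highest occupancy, ties -> first in file
  ca <- dplyr::as_tibble(ca) |>
    dplyr::group_by(.data$resno, .data$insert) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$.file_order, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.file_order)

  aa1 <- unname(AA_THREE_TO_ONE[ca$resid])
  if (anyNA(aa1)) {
    dropped <- unique(ca$resid[is.na(aa1)])
    warn(paste0("dropping nonstandard residue(s): ",
                paste(dropped, collapse = ", ")))
  }
  ca <- ca[!is.na(aa1), , drop = FALSE]
  aa1 <- aa1[!is.na(aa1)]
  if (nrow(ca) < 4) {
    abort(paste0("chain '", chain, "' has fewer than 4 usable C-alpha ",
                 "residues; tessellation is impossible"))
  }

  out <- tibble(
    seq_number = as.integer(ca$resno),
    icode = ca$insert,
    aa = aa1,
    x = ca$x, y = ca$y, z = ca$z,
    ss = "C"
  )
  if (anyDuplicated(out[c("seq_number", "icode")]) > 0) {
    abort("duplicate (seq_number, insertion code) after altloc resolution")
  }
  out <- new_structure(out, chain_id = chain)
  assign_secondary_structure(out, parsed)
}

#' Assign three-state secondary structure from HELIX/SHEET records
#'
#' Residues covered by a HELIX record become `H`, residues covered by a SHEET
#' record become `S`, and everything else is coil `C`.  A per-residue label
#' vector can be supplied instead (e.g. from an external assignment program).
#'
#' @param structure A `quadpot_structure`.
#' @param pdb The PDB source the structure was read from (path, text, or a
#'   `bio3d` pdb object).  Ignored when `ss` is given.
#' @param ss Optional character vector of explicit labels in `{H, S, C}`,
#'   one per residue.
#' @return The structure with its `ss` column replaced.
#' @export
assign_secondary_structure <- function(structure, pdb = NULL, ss = NULL) {
  stopifnot(inherits(structure, "quadpot_structure"))
  if (!is.null(ss)) {
    if (length(ss) != nrow(structure) || !all(ss %in% c("H", "S", "C"))) {
      abort("`ss` must supply one of H/S/C for every residue")
    }
    structure$ss <- as.character(ss)
    return(structure)
  }
  parsed <- if (inherits(pdb, "pdb")) pdb else bio3d::read.pdb(as_pdb_path(pdb), verbose = FALSE)
  chain <- attr(structure, "chain_id")
  lab <- rep("C", nrow(structure))
  lab[in_ss_ranges(structure$seq_number, parsed$helix, chain)] <- "H"
  lab[in_ss_ranges(structure$seq_number, parsed$sheet, chain)] <- "S"
  if (all(lab == "C") &&
      (length(parsed$helix$start) == 0 && length(parsed$sheet$start) == 0)) {
    warn("no HELIX/SHEET records found; all residues labeled coil")
  }
  structure$ss <- lab
  structure
}

in_ss_ranges <- function(seq_numbers, rec, chain) {
  hit <- rep(FALSE, length(seq_numbers))
  if (is.null(rec) || length(rec$start) == 0) return(hit)
  keep <- rec$chain %in% chain
  starts <- as.integer(rec$start)[keep]
  ends <- as.integer(rec$end)[keep]
  for (i in seq_along(starts)) {
    hit <- hit | (seq_numbers >= starts[i] & seq_numbers <= ends[i])
  }
  hit
}

new_structure <- function(df, chain_id) {
  structure(df, chain_id = chain_id,
            class = c("quadpot_structure", class(df)))
}

as_pdb_path <- function(pdb) {
  stopifnot(is.character(pdb), length(pdb) == 1)
  if (!grepl("\n", pdb) && file.exists(pdb)) return(pdb)
  if (!grepl("\n", pdb)) abort(paste0("file not found: ", pdb))
  tmp <- tempfile(fileext = ".pdb")
  writeLines(strsplit(pdb, "\n", fixed = TRUE)[[1]], tmp)
  tmp
}

#' Construct a structure from a residue table
#'
#' For programmatically built structures (lattices, decoys, tests).  The
#' table must have `seq_number`, `aa`, `x`, `y`, `z`; `icode` defaults to
#' empty and `ss` to coil.
#'
#' @param df A data frame of residues.
#' @param chain_id Chain identifier (default `"A"`).
#' @return A `quadpot_structure`.
#' @export
as_structure <- function(df, chain_id = "A") {
  need <- c("seq_number", "aa", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort(paste0("missing column(s): ",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (!all(df$aa %in% AA_ALPHABET)) abort("invalid amino acid letter")
  out <- tibble(seq_number = as.integer(df$seq_number),
                icode = if ("icode" %in% names(df)) df$icode else "",
                aa = df$aa, x = df$x, y = df$y, z = df$z,
                ss = if ("ss" %in% names(df)) df$ss else "C")
  if (anyDuplicated(out[c("seq_number", "icode")]) > 0) {
    abort("duplicate residue numbering")
  }
  new_structure(out, chain_id = chain_id)
}

#' Coordinates of a structure as a matrix
#' @param structure A `quadpot_structure`.
#' @return Numeric matrix with one row per residue and columns x, y, z.
#' @export
structure_coords <- function(structure) {
  m <- cbind(structure$x, structure$y, structure$z)
  rownames(m) <- as.character(structure$seq_number)
  m
}

#' Residue sequence of a structure
#' @param structure A `quadpot_structure`.
#' @return Character vector of one-letter codes named by author seq number.
#' @export
structure_sequence <- function(structure) {
  setNames(structure$aa, as.character(structure$seq_number))
}

#' A minimal PDB entry for examples
#'
#' Four glycine residues with one helix record; enough to parse, tessellate
#' (a single tetrahedron) and score.
#' @return A character scalar of PDB text.
#' @export
example_pdb_text <- function() {
  paste(
    c("HELIX    1   1 GLY A    1  GLY A    2  1                                   2",
      pdb_atom_line(1, "GLY", "A", 1, 0, 0, 0),
      pdb_atom_line(2, "GLY", "A", 2, 3.8, 0, 0),
      pdb_atom_line(3, "GLY", "A", 3, 0, 3.8, 0),
      pdb_atom_line(4, "GLY", "A", 4, 0, 0, 3.8),
      "END"),
    collapse = "\n")
}

# Fixed-width ATOM record for a C-alpha.
pdb_atom_line <- function(serial, resid, chain, resno, x, y, z,
                          occ = 1, alt = "") {
  sprintf("ATOM  %5d  CA %1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
          serial, substr(paste0(alt, " "), 1, 1), resid, chain, resno,
          x, y, z, occ)
}
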