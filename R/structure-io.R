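# PDB input/output and the typed two-chain complex container.
#
# A ppi_complex holds one atom table (bio3d-style columns) restricted to the
# two chains of interest. Raw record parsing and writing go through bio3d;
# altloc resolution, hydrogen flagging, residue aliasing and validation are
# handled here.

#' Read a two-chain complex from a PDB file
#'
#' Parses fixed-column PDB ATOM records (first model only), keeps the two
#' requested chains, drops HETATM records and waters, resolves alternate
#' locations by highest occupancy (ties broken towards altloc "A", then
#' lexicographically), and flags hydrogens (retained but excluded from area
#' and contact calculations downstream). Modified residues with a known
#' parent (e.g. MSE) are renamed to the parent code; other non-standard
#' residues are kept for occlusion but marked non-standard.
#'
#' @param path path to a PDB file.
#' @param chain_a,chain_b single-character chain identifiers.
#' @param complex_id optional identifier; defaults to the file basename.
#' @return An object of class `ppi_complex`: a list with `complex_id`,
#'   `chain_a`, `chain_b` and `atoms`, a data.frame with columns `chain`,
#'   `resid`, `resno`, `insert`, `elety`, `elesy`, `x`, `y`, `z`, `o`,
#'   `alt`, `is_h`, `is_standard`, `radius`.
#' @export
read_complex <- function(path, chain_a, chain_b, complex_id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  if (is.null(complex_id)) complex_id <- sub("\\.pdb$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "DOD", "WAT")), ,
           drop = FALSE]
  build_complex(at, chain_a, chain_b, complex_id)
}

# Shared constructor from a bio3d-style atom data.frame.
build_complex <- function(at, chain_a, chain_b, complex_id) {
  if (chain_a == chain_b) stop("chain identifiers must be distinct")
  for (ch in c(chain_a, chain_b)) {
    if (!any(at$chain == ch, na.rm = TRUE)) {
      stop("chain not found: '", ch, "'")
    }
  }
  at <- at[at$chain %in% c(chain_a, chain_b), , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1.0

  at <- resolve_altloc(at)
  at$resid <- canonical_residue(at$resid)

  elesy <- at$elesy
  missing_el <- is.na(elesy) | elesy == ""
  elesy[missing_el] <- element_from_name(at$elety[missing_el])
  at$elesy <- toupper(elesy)
  at$is_h <- at$elesy %in% c("H", "D")
  at$is_standard <- at$resid %in% standard_residues()

  for (ch in c(chain_a, chain_b)) {
    sub <- at[at$chain == ch, ]
    if (sum(sub$is_standard) == 0) {
      stop("empty chain: no standard residues in chain '", ch, "'")
    }
  }
  key <- paste(at$chain, at$resno, at$insert)
  atom_key <- paste(key, at$elety)
  if (anyDuplicated(atom_key)) {
    stop("duplicated atom records after altloc resolution")
  }
  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z))) {
    stop("non-finite coordinates in input")
  }
  rownames(at) <- NULL
  cols <- c("chain", "resid", "resno", "insert", "elety", "elesy",
            "x", "y", "z", "o", "alt", "is_h", "is_standard")
  at$radius <- NA_real_
  structure(list(complex_id = complex_id, chain_a = chain_a,
                 chain_b = chain_b, atoms = at[, c(cols, "radius")]),
            class = "ppi_complex")
}

# Keep one conformer per (chain, residue, atom name): highest occupancy,
# ties towards altloc "A" / lexicographically first.
resolve_altloc <- function(at) {
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  if (!anyDuplicated(key)) return(at)
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
     drop = FALSE]
}

# Infer an element symbol from a PDB atom name.
element_from_name <- function(elety) {
  vapply(elety, function(a) {
    a <- gsub("[0-9']", "", toupper(a))
    if (nchar(a) == 0) return("X")
    two <- substr(a, 1, 2)
    if (two %in% c("SE", "CL", "BR", "FE", "ZN", "MG")) return(two)
    substr(a, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.ppi_complex <- function(x, ...) {
  at <- x$atoms
  for (ch in c(x$chain_a, x$chain_b)) {
    sub <- at[at$chain == ch, ]
    cat(sprintf("  chain %s: %d residues, %d atoms\n", ch,
                length(unique(paste(sub$resno, sub$insert))), nrow(sub)))
  }
  invisible(x)
}

#' Assign van der Waals radii to all atoms
#'
#' Heavy atoms get the class radius (carbonyl, aliphatic or aromatic carbon,
#' N, O, S) from the table; unknown atoms fall back to their element entry.
#' Hydrogens get radius 0 and are excluded from area calculations.
#'
#' @param cx a `ppi_complex`.
#' @param table a radius table from [ppi_radius_table()].
#' @return The complex with the `radius` column populated.
#' @export
assign_radii <- function(cx, table = ppi_radius_table()) {
  stopifnot(inherits(cx, "ppi_complex"))
  at <- cx$atoms
  r <- numeric(nrow(at))
  bc <- table$by_class
  for (i in seq_len(nrow(at))) {
    el <- at$elesy[i]
    if (at$is_h[i]) { r[i] <- 0; next }
    nm <- at$elety[i]
    rs <- at$resid[i]
    r[i] <-
      if (el == "C") {
        if (nm %in% c("C", "CA")) {
          if (nm == "C") bc[["C_carbonyl"]] else bc[["C_aliphatic"]]
        } else if (nm %in% table$aromatic[[rs]]) {
          bc[["C_aromatic"]]
        } else bc[["C_aliphatic"]]
      } else if (el %in% c("N", "O", "S")) {
        bc[[el]]
      } else if (el %in% names(table$element)) {
        table$element[[el]]
      } else {
        stop("no radius for atom '", nm, "' (element '", el,
             "') in residue ", rs, " ", at$resno[i])
      }
  }
  cx$atoms$radius <- r
  cx
}

#' Write a complex to a PDB file
#'
#' Emits standard fixed-column ATOM records (via bio3d) for the two chains.
#' Coordinates survive a write/read round trip to three decimals.
#'
#' @param cx a `ppi_complex` with at least one atom.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_complex <- function(cx, path) {
  stopifnot(inherits(cx, "ppi_complex"))
  at <- cx$atoms
  if (nrow(at) == 0) stop("cannot write an empty complex")
  if (any(abs(c(at$x, at$y, at$z)) >= 10000)) {
    stop("coordinate magnitude exceeds PDB fixed-column width")
  }
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(
                     at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   insert = ifelse(at$insert == "", NA, at$insert),
                   elety = at$elety, o = at$o, b = rep(0, nrow(at)),
                   elesy = at$elesy)
  invisible(path)
}

#' Heavy atoms with assigned radii
#'
#' Convenience accessor used by the area and contact modules: drops
#' hydrogens and checks radii are assigned.
#' @param cx a `ppi_complex`.
#' @return Atom data.frame restricted to heavy atoms.
#' @export
heavy_atoms <- function(cx) {
  at <- cx$atoms[!cx$atoms$is_h, , drop = FALSE]
  if (anyNA(at$radius)) {
    stop("radii not assigned; call assign_radii() first")
  }
  at
}
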