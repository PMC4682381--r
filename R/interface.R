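# Interface and surface residue detection from the change in accessible
# surface area on complex formation.

#' Detect interface residues by change in accessible area
#'
#' Computes each chain's SASA in isolation and in the complex with identical
#' quadrature parameters (deterministic lattice, so the per-residue
#' difference is free of lattice noise) and flags as interface every residue
#' losing more than `dasa_cutoff` (default 0.1 A^2) of accessible area on
#' complex formation. Small negative differences are clamped to zero.
#'
#' @param cx a `ppi_complex` with radii assigned.
#' @param probe probe radius, A.
#' @param n_points quadrature points per atom.
#' @param dasa_cutoff interface threshold on the per-residue area loss, A^2.
#' @return Object of class `ppi_accessibility`: a data.frame with one row
#'   per residue (`chain`, `resno`, `insert`, `resid`, `is_standard`,
#'   `asa_isolated`, `asa_complex`, `delta_asa`, `relative_asa_complex`,
#'   `is_interface`, `is_surface`), with the per-atom area table in
#'   attribute `atom_table`. `is_surface` is `NA` until [detect_surface()]
#'   is applied.
#' @export
detect_interface <- function(cx, probe = 1.4, n_points = 960,
                             dasa_cutoff = 0.1) {
  stopifnot(inherits(cx, "ppi_complex"))
  at <- heavy_atoms(cx)
  ia <- at$chain == cx$chain_a
  no_contact <- min_interchain_distance(at, ia) >
    2 * (max(at$radius) + 2 * probe)
  if (no_contact) {
    warning("chains have no inter-chain contact; zero interface residues")
  }

  s_all <- compute_sasa(at, probe = probe, n_points = n_points)
  s_a <- compute_sasa(at[ia, , drop = FALSE], probe = probe,
                      n_points = n_points)
  s_b <- compute_sasa(at[!ia, , drop = FALSE], probe = probe,
                      n_points = n_points)

  iso_atom <- numeric(nrow(at))
  iso_atom[ia] <- s_a$atom_area
  iso_atom[!ia] <- s_b$atom_area
  cplx_atom <- s_all$atom_area
  atom_table <- data.frame(at[, c("chain", "resid", "resno", "insert",
                                  "elety", "elesy")],
                           asa_isolated = iso_atom, asa_complex = cplx_atom,
                           delta_asa = iso_atom - cplx_atom,
                           stringsAsFactors = FALSE)

  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  first <- !duplicated(key)
  iso_res <- rowsum(iso_atom, key, reorder = FALSE)[, 1]
  cplx_res <- rowsum(cplx_atom, key, reorder = FALSE)[, 1]
  delta <- pmax(0, iso_res - cplx_res)

  res <- data.frame(
    chain = at$chain[first], resno = at$resno[first],
    insert = at$insert[first], resid = at$resid[first],
    is_standard = at$is_standard[first],
    asa_isolated = unname(iso_res), asa_complex = unname(cplx_res),
    delta_asa = unname(delta), stringsAsFactors = FALSE)
  res$relative_asa_complex <- ifelse(
    res$is_standard,
    relative_residue_sasa(res$asa_complex, res$resid), NA_real_)
  res$is_interface <- res$delta_asa > dasa_cutoff
  res$is_surface <- NA
  attr(res, "atom_table") <- atom_table
  attr(res, "dasa_cutoff") <- dasa_cutoff
  attr(res, "complex_id") <- cx$complex_id
  class(res) <- c("ppi_accessibility", "data.frame")
  res
}

min_interchain_distance <- function(at, ia) {
  a <- as.matrix(at[ia, c("x", "y", "z")])
  b <- as.matrix(at[!ia, c("x", "y", "z")])
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  sqrt(max(0, min(outer(rowSums(a^2), rowSums(b^2), "+") -
                    2 * tcrossprod(a, b))))
}

#' Total interface area of a complex
#'
#' Sum of the per-residue area losses over both chains: the total two-chain
#' buried area, equal (to quadrature identity) to
#' ASA(A) + ASA(B) - ASA(complex). Reported un-halved; divide by two for a
#' per-side figure.
#'
#' @param acc a `ppi_accessibility` from [detect_interface()].
#' @param halved logical; report the one-sided (halved) area instead.
#' @return Interface area in A^2.
#' @export
interface_area <- function(acc, halved = FALSE) {
  stopifnot(inherits(acc, "ppi_accessibility"))
  a <- sum(acc$delta_asa)
  if (halved) a / 2 else a
}

#' Flag surface residues
#'
#' A residue is surface when its relative accessibility in the bound complex
#' is at least `rel_threshold` (default 5%) and it is not an interface
#' residue, i.e. the "rest of the surface" against which interface polarity
#' is compared. Both the threshold and the interface exclusion are
#' adjustable.
#'
#' @param acc a `ppi_accessibility`.
#' @param rel_threshold relative-accessibility cutoff (fraction).
#' @param exclude_interface logical; drop interface residues from the
#'   surface set (default `TRUE`).
#' @return The accessibility table with `is_surface` filled in.
#' @export
detect_surface <- function(acc, rel_threshold = 0.05,
                           exclude_interface = TRUE) {
  stopifnot(inherits(acc, "ppi_accessibility"))
  surf <- !is.na(acc$relative_asa_complex) &
    acc$relative_asa_complex >= rel_threshold
  if (exclude_interface) surf <- surf & !acc$is_interface
  acc$is_surface <- surf
  acc
}

#' Write the per-residue accessibility table as TSV
#'
#' @param acc a `ppi_accessibility`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_accessibility <- function(acc, path) {
  out <- cbind(complex_id = attr(acc, "complex_id"), as.data.frame(acc))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
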