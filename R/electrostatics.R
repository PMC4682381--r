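# Screened-Coulomb interface electrostatics and the charge-complementarity
# score. A uniform interior dielectric (default 4) with Debye-type
# exponential screening approximates the qualitative behaviour of a
# Poisson-Boltzmann surface map; it is an approximation, adequate for
# discriminating same-charge from opposite-charge interfaces, not for
# absolute potentials.

#' Charge model for interface electrostatics
#'
#' Formal charges placed on charged-group heavy atoms: -0.5 on each
#' carboxylate oxygen of Asp/Glu, +1 on Lys NZ, +1/3 on each of Arg
#' NE/NH1/NH2; optionally -0.5 on each terminal OXT. Coulomb constant
#' 332 kcal A/(mol e^2), interior dielectric epsilon, Debye screening
#' constant kappa.
#'
#' @param epsilon relative dielectric (default 4).
#' @param kappa screening constant, 1/A (default 0.1; 0 = bare Coulomb).
#' @param charge_his logical; +0.5 on His ND1/NE2.
#' @param termini logical; include C-terminal OXT charge.
#' @return List of class `ppi_charge_model`.
#' @export
charge_model <- function(epsilon = 4, kappa = 0.1, charge_his = FALSE,
                         termini = FALSE) {
  stopifnot(epsilon > 0, kappa >= 0)
  q <- list(
    ASP = c(OD1 = -0.5, OD2 = -0.5),
    GLU = c(OE1 = -0.5, OE2 = -0.5),
    LYS = c(NZ = 1),
    ARG = c(NE = 1 / 3, NH1 = 1 / 3, NH2 = 1 / 3)
  )
  if (charge_his) q$HIS <- c(ND1 = 0.5, NE2 = 0.5)
  structure(list(charges = q, epsilon = epsilon, kappa = kappa,
                 termini = termini), class = "ppi_charge_model")
}

# Per-atom partial charges for one atom table.
atom_charges <- function(at, model) {
  q <- numeric(nrow(at))
  for (i in seq_len(nrow(at))) {
    qs <- model$charges[[at$resid[i]]]
    if (!is.null(qs) && at$elety[i] %in% names(qs)) {
      q[i] <- qs[[at$elety[i]]]
    } else if (model$termini && at$elety[i] == "OXT") {
      q[i] <- -0.5
    }
  }
  q
}

#' Screened-Coulomb potential at interface atom positions
#'
#' Evaluates, at every interface atom position x, the potential generated by
#' each chain's charges separately:
#' phi_c(x) = sum_q 332 q / (epsilon r) exp(-kappa r), with r floored at
#' 1 A to avoid the self-atom singularity.
#'
#' @param cx a `ppi_complex` with radii assigned.
#' @param acc a `ppi_accessibility` with interface flags.
#' @param model a [charge_model()].
#' @return data.frame of class `ppi_potential_samples`: `chain`, `resno`,
#'   `elety`, `x`, `y`, `z`, `phi_a`, `phi_b` (kcal/(mol e)).
#' @export
interface_potential <- function(cx, acc, model = charge_model()) {
  stopifnot(inherits(cx, "ppi_complex"), inherits(acc, "ppi_accessibility"))
  at <- heavy_atoms(cx)
  ikey <- paste(acc$chain, acc$resno, acc$insert)[acc$is_interface]
  sel <- paste(at$chain, at$resno, at$insert) %in% ikey
  pts <- at[sel, , drop = FALSE]
  if (nrow(pts) == 0) stop("no interface residues")
  q <- atom_charges(at, model)
  ia <- at$chain == cx$chain_a
  if (all(q[ia] == 0) && all(q[!ia] == 0)) {
    warning("no charged residues in either chain; potentials are zero")
  }
  phi_from <- function(src) {
    qq <- q[src]
    nz <- qq != 0
    if (!any(nz)) return(numeric(nrow(pts)))
    sx <- as.matrix(at[src, c("x", "y", "z")])[nz, , drop = FALSE]
    qq <- qq[nz]
    px <- as.matrix(pts[, c("x", "y", "z")])
    d <- sqrt(pmax(outer(rowSums(px^2), rowSums(sx^2), "+") -
                     2 * tcrossprod(px, sx), 0))
    d <- pmax(d, 1)
    as.vector((332 / model$epsilon) *
                (exp(-model$kappa * d) / d) %*% qq)
  }
  out <- data.frame(pts[, c("chain", "resno", "elety", "x", "y", "z")],
                    phi_a = phi_from(ia), phi_b = phi_from(!ia),
                    stringsAsFactors = FALSE)
  attr(out, "chain_a") <- cx$chain_a
  class(out) <- c("ppi_potential_samples", "data.frame")
  out
}

#' Interface charge-complementarity score
#'
#' Pearson correlation, over the interface sample points, between the
#' potential a point's own chain generates there and the potential the
#' partner chain impresses on it (for a chain-A point the pair is
#' (phi_a, phi_b); for a chain-B point, (phi_b, phi_a)). Pairing own field
#' with partner field removes the trivial own-proximity signal, so the
#' score reads the charge relationship across the interface: strongly
#' negative for opposite-charge (polar, class-B-like) interfaces where a
#' positive patch faces a negative one, positive for same-charge
#' (class-A-like) interfaces. Symmetric under chain relabelling.
#'
#' @param samples a `ppi_potential_samples` data.frame.
#' @return Correlation in \[-1, 1\], or `NA` when fewer than 3 samples or
#'   either field has zero variance (not computable).
#' @export
complementarity_score <- function(samples) {
  stopifnot(inherits(samples, "ppi_potential_samples"))
  if (nrow(samples) < 3) return(NA_real_)
  is_a <- samples$chain == attr(samples, "chain_a")
  own <- ifelse(is_a, samples$phi_a, samples$phi_b)
  partner <- ifelse(is_a, samples$phi_b, samples$phi_a)
  vo <- stats::var(own)
  vp <- stats::var(partner)
  if (!is.finite(vo) || !is.finite(vp) || vo == 0 || vp == 0) {
    return(NA_real_)
  }
  stats::cor(own, partner)
}

#' Export per-atom potential in the B-factor column
#'
#' Writes a copy of the complex with the total interface potential
#' (phi_a + phi_b, zero for non-interface atoms) in the B-factor column,
#' viewable in any molecular-graphics program.
#'
#' @param cx a `ppi_complex`.
#' @param samples output of [interface_potential()].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_potential_pdb <- function(cx, samples, path) {
  at <- cx$atoms
  b <- numeric(nrow(at))
  key <- paste(at$chain, at$resno, at$elety)
  skey <- paste(samples$chain, samples$resno, samples$elety)
  hit <- match(key, skey)
  b[!is.na(hit)] <- (samples$phi_a + samples$phi_b)[hit[!is.na(hit)]]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)), resno = at$resno,
                   resid = at$resid, chain = at$chain, elety = at$elety,
                   o = at$o, b = round(b, 2), elesy = at$elesy)
  invisible(path)
}
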