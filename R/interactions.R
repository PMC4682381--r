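# Geometric detection of intermolecular hydrogen bonds and salt bridges.
#
# Heavy-atom distance criteria only: the source analyses state a distance
# cutoff ("< 4 A" for H-bonds, within 4 A for salt bridges) and crystal
# structures at typical resolution carry no hydrogens. An optional
# angle-free strictness toggle controls < vs <=.

# All cross-chain atom pairs with distance below/at cutoff, as a data.frame.
cross_chain_pairs <- function(at, chain_a, cutoff, strict) {
  ia <- at$chain == chain_a
  a <- at[ia, , drop = FALSE]
  b <- at[!ia, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * tcrossprod(ax, bx)
  d2 <- pmax(d2, 0)
  hit <- if (strict) d2 < cutoff^2 else d2 <= cutoff^2
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  data.frame(
    chain_a = a$chain[idx[, 1]], resid_a = a$resid[idx[, 1]],
    resno_a = a$resno[idx[, 1]], atom_a = a$elety[idx[, 1]],
    chain_b = b$chain[idx[, 2]], resid_b = b$resid[idx[, 2]],
    resno_b = b$resno[idx[, 2]], atom_b = b$elety[idx[, 2]],
    distance = sqrt(d2[idx]), stringsAsFactors = FALSE)
}

atom_in_role <- function(resid, elety, role_table) {
  bb <- elety %in% role_table$backbone
  side <- mapply(function(rs, at) at %in% role_table[[rs]], resid, elety,
                 USE.NAMES = FALSE)
  bb | as.logical(side)
}

#' Detect intermolecular hydrogen bonds
#'
#' Finds all donor-acceptor heavy-atom pairs on different chains within the
#' distance cutoff (strictly below 4 A by default). Either chain may donate:
#' a pair counts if the chain-A atom donates to a chain-B acceptor or vice
#' versa; each atom pair is counted once.
#'
#' @param cx a `ppi_complex` with radii assigned.
#' @param cutoff distance cutoff, A.
#' @param strict logical; `TRUE` (default) uses `<`, `FALSE` uses `<=`.
#' @param table donor/acceptor chemistry from [donor_acceptor_table()].
#' @return data.frame of contacts (class `ppi_contacts`) with columns
#'   `kind`, `chain_a`, `resid_a`, `resno_a`, `atom_a`, `chain_b`,
#'   `resid_b`, `resno_b`, `atom_b`, `distance`; zero rows when none.
#' @export
detect_hbonds <- function(cx, cutoff = 4.0, strict = TRUE,
                          table = donor_acceptor_table()) {
  stopifnot(inherits(cx, "ppi_complex"))
  at <- heavy_atoms(cx)
  pr <- cross_chain_pairs(at, cx$chain_a, cutoff, strict)
  empty <- contacts_frame(NULL, "hbond")
  if (is.null(pr)) return(empty)
  don_a <- atom_in_role(pr$resid_a, pr$atom_a, table$donors)
  acc_a <- atom_in_role(pr$resid_a, pr$atom_a, table$acceptors)
  don_b <- atom_in_role(pr$resid_b, pr$atom_b, table$donors)
  acc_b <- atom_in_role(pr$resid_b, pr$atom_b, table$acceptors)
  keep <- (don_a & acc_b) | (don_b & acc_a)
  contacts_frame(pr[keep, , drop = FALSE], "hbond")
}

#' Detect intermolecular salt bridges
#'
#' Pairs of oppositely charged side-chain heavy atoms on different chains
#' within 4 A (inclusive by default): Asp/Glu carboxylate oxygens or the
#' C-terminal OXT against Lys NZ or Arg NE/NH1/NH2 (His ring nitrogens when
#' `charged_his`).
#'
#' @inheritParams detect_hbonds
#' @param charged_his logical; treat histidine as positively charged.
#' @return `ppi_contacts` data.frame; use [count_contacts()] for atom-pair
#'   and unique residue-pair counts.
#' @export
detect_salt_bridges <- function(cx, cutoff = 4.0, strict = FALSE,
                                charged_his = FALSE,
                                table = donor_acceptor_table(charged_his)) {
  stopifnot(inherits(cx, "ppi_complex"))
  at <- heavy_atoms(cx)
  pr <- cross_chain_pairs(at, cx$chain_a, cutoff, strict)
  empty <- contacts_frame(NULL, "saltbridge")
  if (is.null(pr)) return(empty)
  pos_a <- atom_in_role(pr$resid_a, pr$atom_a, table$positive)
  neg_a <- atom_in_role(pr$resid_a, pr$atom_a, table$negative)
  pos_b <- atom_in_role(pr$resid_b, pr$atom_b, table$positive)
  neg_b <- atom_in_role(pr$resid_b, pr$atom_b, table$negative)
  keep <- (pos_a & neg_b) | (neg_a & pos_b)
  contacts_frame(pr[keep, , drop = FALSE], "saltbridge")
}

contacts_frame <- function(pr, kind) {
  if (is.null(pr) || nrow(pr) == 0) {
    pr <- data.frame(chain_a = character(), resid_a = character(),
                     resno_a = integer(), atom_a = character(),
                     chain_b = character(), resid_b = character(),
                     resno_b = integer(), atom_b = character(),
                     distance = numeric(), stringsAsFactors = FALSE)
  }
  out <- cbind(kind = rep(kind, nrow(pr)), pr)
  rownames(out) <- NULL
  class(out) <- c("ppi_contacts", "data.frame")
  out
}

#' Count contacts as atom pairs and unique residue pairs
#'
#' The headline salt-bridge count is the number of unique residue pairs (an
#' ion pair with two carboxylate oxygens in range counts once); the atom
#' pair count is also reported.
#'
#' @param contacts a `ppi_contacts` data.frame.
#' @return List with `atom_pairs` and `residue_pairs`.
#' @export
count_contacts <- function(contacts) {
  list(atom_pairs = nrow(contacts),
       residue_pairs = length(unique(paste(
         contacts$chain_a, contacts$resno_a,
         contacts$chain_b, contacts$resno_b))))
}
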