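# Shared fixtures (built once per run) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

# Ten planted dimers spanning compositions; same family as the shipped
# default-potential training set.
fixture_dimers <- function() {
  if (is.null(.fixture_env$dimers)) {
    specs <- lapply(1:10, function(i) {
      dimer_spec(n_residues = 26, n_interface = 10,
                 interface_polar_frac = c(0.2, 0.3, 0.4, 0.5, 0.6,
                                          0.7, 0.8, 0.5, 0.3, 0.6)[i],
                 surface_polar_frac = c(0.6, 0.5, 0.6, 0.4, 0.5,
                                        0.4, 0.5, 0.7, 0.4, 0.3)[i],
                 charged_frac = c(0, 0.1, 0.2, 0.2, 0.3,
                                  0.3, 0.4, 0.1, 0, 0.2)[i],
                 n_hbonds = c(0, 1, 2, 2, 1, 2, 3, 1, 0, 2)[i],
                 n_salt_bridges = c(0, 1, 1, 2, 2, 1, 2, 0, 0, 1)[i],
                 charge_layout = if (i %in% c(1, 9)) "none" else "opposite",
                 seed = 2000 + i)
    })
    .fixture_env$dimers <- lapply(specs, build_dimer)
  }
  .fixture_env$dimers
}

fixture_accessibility <- function() {
  if (is.null(.fixture_env$acc)) {
    .fixture_env$acc <- lapply(fixture_dimers(), function(d) {
      detect_surface(detect_interface(d$complex))
    })
  }
  .fixture_env$acc
}

fixture_potential <- function() {
  if (is.null(.fixture_env$pot)) {
    .fixture_env$pot <- default_potential()
  }
  .fixture_env$pot
}

# Analytic accessible area of a sphere of expanded radius R1 occluded by a
# single sphere of expanded radius R2 at centre distance d (spherical cap).
two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  ca <- (d^2 + R1^2 - R2^2) / (2 * d)
  h <- R1 - ca
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# Brute-force all-pairs cross-chain contact scan (independent of the
# package's vectorised detection).
brute_force_contacts <- function(cx, kind = c("hbond", "saltbridge"),
                                 cutoff = 4, strict = (kind == "hbond"),
                                 charged_his = FALSE) {
  kind <- match.arg(kind)
  tab <- donor_acceptor_table(charged_his)
  at <- heavy_atoms(cx)
  a <- at[at$chain == cx$chain_a, ]
  b <- at[at$chain == cx$chain_b, ]
  in_role <- function(rs, nm, role) {
    nm %in% tab[[role]]$backbone || nm %in% tab[[role]][[rs]]
  }
  hits <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                     c(b$x[j], b$y[j], b$z[j]))^2))
    ok_d <- if (strict) d < cutoff else d <= cutoff
    if (!ok_d) next
    ok <- if (kind == "hbond") {
      (in_role(a$resid[i], a$elety[i], "donors") &&
         in_role(b$resid[j], b$elety[j], "acceptors")) ||
        (in_role(b$resid[j], b$elety[j], "donors") &&
           in_role(a$resid[i], a$elety[i], "acceptors"))
    } else {
      (in_role(a$resid[i], a$elety[i], "positive") &&
         in_role(b$resid[j], b$elety[j], "negative")) ||
        (in_role(a$resid[i], a$elety[i], "negative") &&
           in_role(b$resid[j], b$elety[j], "positive"))
    }
    if (ok) hits[[length(hits) + 1]] <-
      c(a$resno[i], a$elety[i], b$resno[j], b$elety[j])
  }
  hits
}

# Exhaustive rank-sum enumeration oracle: two-sided p as the probability of
# a rank-sum deviation at least as large as observed, over all
# choose(n, na) group assignments.
enumerate_ranksum_p <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  n <- length(r)
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  combs <- utils::combn(n, na)
  w_all <- apply(combs, 2, function(ix) sum(r[ix]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Minimal fixed-column PDB writer for crafted test geometries.
make_pdb <- function(df, path = tempfile(fileext = ".pdb")) {
  lines <- character(nrow(df))
  alt <- if ("alt" %in% names(df)) df$alt else rep(" ", nrow(df))
  occ <- if ("o" %in% names(df)) df$o else rep(1, nrow(df))
  for (i in seq_len(nrow(df))) {
    nm <- df$elety[i]
    nm_field <- if (nchar(nm) >= 4) nm else sprintf(" %-3s", nm)
    lines[i] <- sprintf(
      "ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, nm_field, alt[i], df$resid[i], df$chain[i], df$resno[i],
      df$x[i], df$y[i], df$z[i], occ[i], 0,
      substr(gsub("[0-9]", "", df$elety[i]), 1, 1))
  }
  writeLines(c(lines, "END"), path)
  path
}

# Apply a rigid-body transform to a complex's coordinates.
transform_complex <- function(cx, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(cx$atoms[, c("x", "y", "z")]) %*% t(rot)
  cx$atoms$x <- xyz[, 1] + shift[1]
  cx$atoms$y <- xyz[, 2] + shift[2]
  cx$atoms$z <- xyz[, 3] + shift[3]
  cx
}

rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Read a written complex back with the chain roles swapped.
swap_chains <- function(cx) {
  path <- tempfile(fileext = ".pdb")
  write_complex(cx, path)
  assign_radii(read_complex(path, cx$chain_b, cx$chain_a,
                            complex_id = cx$complex_id))
}

residue_set <- function(acc, flag) {
  paste(acc$chain, acc$resno)[acc[[flag]]]
}

manifest_set <- function(manifest, region) {
  with(manifest$residues[manifest$residues$region == region, ],
       paste(chain, resno))
}
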