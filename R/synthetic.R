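# Synthetic heterodimer generator with ground-truth manifests.
#
# Chains are built from idealized rigid residue stubs (CA, CB and one or two
# representative terminal atoms) placed on opposing faces of a planar
# contact region. Interface residues face their counterpart across the
# plane at controlled tip-to-tip gaps, so planted hydrogen bonds and salt
# bridges are realized to within coordinate precision; non-interface
# "surface" residues sit on a plane far enough from the partner chain that
# their accessible area is unchanged by complex formation. Region labels
# are therefore unambiguous by construction and the manifest is an exact
# oracle for the analysis modules.

#' Specification for one synthetic heterodimer
#'
#' @param n_residues residues per chain.
#' @param n_interface interface residues per chain.
#' @param interface_polar_frac,surface_polar_frac fraction of polar residues
#'   in each region (charged residues count as polar).
#' @param charged_frac fraction of interface residues that are charged.
#' @param n_hbonds planted inter-chain hydrogen bonds (Ser OG - Ser OG).
#' @param hbond_distance planted donor-acceptor distance, A.
#' @param n_salt_bridges planted inter-chain ion pairs (Lys NZ - Asp OD1).
#' @param saltbridge_distance planted ion-pair distance, A.
#' @param charge_layout `"opposite"` (chain A positive, chain B negative
#'   extra charges), `"same"` (both positive) or `"none"`; salt-bridge
#'   slots are always an opposite Lys/Asp pair.
#' @param contact_gap tip-to-tip gap for generic interface residues, A;
#'   must exceed the contact cutoffs (default 4.5) while keeping the tips
#'   mutually occluding.
#' @param seed integer seed controlling slot shuffling.
#' @return List of class `ppi_dimer_spec`.
#' @export
dimer_spec <- function(n_residues = 30, n_interface = 10,
                       interface_polar_frac = 0.5,
                       surface_polar_frac = 0.55,
                       charged_frac = 0, n_hbonds = 0,
                       hbond_distance = 2.9, n_salt_bridges = 0,
                       saltbridge_distance = 3.5,
                       charge_layout = c("opposite", "same", "none"),
                       contact_gap = 4.5, seed = 1) {
  charge_layout <- match.arg(charge_layout)
  spec <- list(n_residues = n_residues, n_interface = n_interface,
               interface_polar_frac = interface_polar_frac,
               surface_polar_frac = surface_polar_frac,
               charged_frac = charged_frac, n_hbonds = n_hbonds,
               hbond_distance = hbond_distance,
               n_salt_bridges = n_salt_bridges,
               saltbridge_distance = saltbridge_distance,
               charge_layout = charge_layout, contact_gap = contact_gap,
               seed = as.integer(seed))
  class(spec) <- "ppi_dimer_spec"
  validate_dimer_spec(spec)
  spec
}

validate_dimer_spec <- function(s) {
  n_int <- s$n_interface
  if (n_int > s$n_residues) {
    stop("infeasible spec: more interface residues than residues per chain")
  }
  fr <- c(s$interface_polar_frac, s$surface_polar_frac, s$charged_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  comp <- dimer_composition(s)
  if (comp$n_polar < comp$n_charged + s$n_hbonds) {
    stop("infeasible spec: planted charged + hydrogen-bond residues ",
         "exceed the interface polar residue budget")
  }
  if (s$n_salt_bridges > 0 && s$charge_layout == "none") {
    stop("infeasible spec: salt bridges require charges")
  }
  if (s$charged_frac > 0 && s$charge_layout == "none") {
    stop("infeasible spec: charged residues requested with layout 'none'")
  }
  if (max(s$n_hbonds + s$n_salt_bridges, 0) > n_int) {
    stop("infeasible spec: more planted contacts than interface residues")
  }
  if (s$contact_gap <= 4.0 || s$contact_gap >= 5.6) {
    stop("contact_gap must lie in (4, 5.6): beyond the contact cutoff but ",
         "still occluding")
  }
  invisible(s)
}

dimer_composition <- function(s) {
  n_int <- s$n_interface
  n_charged <- max(round(s$charged_frac * n_int), s$n_salt_bridges)
  n_polar <- round(s$interface_polar_frac * n_int)
  list(n_charged = n_charged, n_polar = n_polar)
}

# Stub residue template: atom names + coordinates given the tip position,
# the unit direction the side chain points along (towards the partner for
# interface residues), and a lateral unit vector.
stub_atoms <- function(restype, tip, dir, lat) {
  ca <- tip - 2.6 * dir + 0.8 * lat
  cb <- tip - 1.4 * dir
  tips <- switch(restype,
    LEU = list(CD1 = tip),
    THR = list(CG2 = tip),
    SER = list(OG = tip),
    LYS = list(NZ = tip),
    ASP = list(OD1 = tip, OD2 = tip + 2.2 * lat - 0.5 * dir),
    stop("no stub template for ", restype))
  atoms <- c(list(CA = ca, CB = cb), tips)
  data.frame(elety = names(atoms),
             do.call(rbind, lapply(atoms, function(p) {
               data.frame(x = p[1], y = p[2], z = p[3])
             })), row.names = NULL, stringsAsFactors = FALSE)
}

# Run code with a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a synthetic heterodimer with ground truth
#'
#' Constructs a two-chain complex realizing the composition and planted
#' contacts of the spec, with a manifest recording per-residue region and
#' polarity labels, the planted contact list, the expected polarity
#' percentages and the expected interface class. Deterministic for a fixed
#' spec (the seed only shuffles which grid slot receives which residue
#' type).
#'
#' @param spec a [dimer_spec()].
#' @return List with elements `complex` (a `ppi_complex`, radii assigned)
#'   and `manifest` (list: `residues`, `contacts`, `n_hbond_pairs`,
#'   `n_salt_bridges`, `expected`, `intended_class`).
#' @export
build_dimer <- function(spec) {
  stopifnot(inherits(spec, "ppi_dimer_spec"))
  validate_dimer_spec(spec)
  s <- spec
  n_int <- s$n_interface
  n_surf <- s$n_residues - n_int
  comp <- dimer_composition(s)

  # slot plan for interface residues, per chain: salt bridges, then extra
  # charged, then hydrogen bonds, then polar filler, then nonpolar filler
  k_sb <- s$n_salt_bridges
  k_ch_extra <- comp$n_charged - k_sb
  k_hb <- s$n_hbonds
  k_pol <- comp$n_polar - comp$n_charged - k_hb
  k_np <- n_int - comp$n_polar
  pos_type <- "LYS"; neg_type <- "ASP"
  extra_a <- if (s$charge_layout == "same") pos_type else pos_type
  extra_b <- if (s$charge_layout == "same") pos_type else neg_type
  type_a <- c(rep(pos_type, k_sb), rep(extra_a, k_ch_extra),
              rep("SER", k_hb), rep("THR", k_pol), rep("LEU", k_np))
  type_b <- c(rep(neg_type, k_sb), rep(extra_b, k_ch_extra),
              rep("SER", k_hb), rep("THR", k_pol), rep("LEU", k_np))
  gap <- c(rep(s$saltbridge_distance, k_sb),
           rep(s$contact_gap, k_ch_extra),
           rep(s$hbond_distance, k_hb),
           rep(s$contact_gap, k_pol + k_np))
  slot_kind <- c(rep("saltbridge", k_sb), rep("charged", k_ch_extra),
                 rep("hbond", k_hb), rep("filler", k_pol + k_np))

  # surface residues: polar (THR) / nonpolar (LEU)
  ns_pol <- round(s$surface_polar_frac * n_surf)
  surf_types <- c(rep("THR", ns_pol), rep("LEU", n_surf - ns_pol))

  # shuffle slot assignment (not the planted geometry) for spatial mixing
  ord <- with_seed(s$seed, {
    list(int = sample.int(max(n_int, 1)), surf = sample.int(max(n_surf, 1)))
  })
  if (n_int > 0) {
    perm <- ord$int
    type_a <- type_a[perm]; type_b <- type_b[perm]
    gap <- gap[perm]; slot_kind <- slot_kind[perm]
  }
  if (n_surf > 0) surf_types <- surf_types[ord$surf]

  grid <- function(n, spacing) {
    if (n == 0) return(NULL)
    ncol <- ceiling(sqrt(n))
    i <- seq_len(n) - 1
    cbind((i %% ncol) * spacing, (i %/% ncol) * spacing)
  }
  gi <- grid(n_int, 5.0)
  surf_z <- if (n_int > 0) 10 else 20
  gs <- grid(n_surf, 6.0)
  lat <- c(1, 0, 0)

  rows <- list(); contacts <- list()
  manifest_res <- list()
  scheme <- residue_class_scheme()
  add_residue <- function(chain, resno, restype, tip, dir, region) {
    df <- stub_atoms(restype, tip, dir, lat)
    df$chain <- chain; df$resno <- resno; df$resid <- restype
    rows[[length(rows) + 1]] <<- df
    manifest_res[[length(manifest_res) + 1]] <<- data.frame(
      chain = chain, resno = resno, resid = restype, region = region,
      polarity = if (restype %in% scheme$polar) "polar" else "nonpolar",
      charged = restype %in% scheme$charged, stringsAsFactors = FALSE)
  }

  for (k in seq_len(n_int)) {
    ta <- type_a[k]; tb <- type_b[k]; g <- gap[k]
    tip_a <- c(gi[k, 1], gi[k, 2], -g / 2)
    tip_b <- c(gi[k, 1], gi[k, 2], +g / 2)
    add_residue("A", k, ta, tip_a, c(0, 0, 1), "interface")
    add_residue("B", k, tb, tip_b, c(0, 0, -1), "interface")
    if (slot_kind[k] == "saltbridge") {
      contacts[[length(contacts) + 1]] <- data.frame(
        kind = "saltbridge", resno_a = k, atom_a = "NZ",
        resno_b = k, atom_b = "OD1", distance = g,
        stringsAsFactors = FALSE)
    } else if (slot_kind[k] == "hbond") {
      contacts[[length(contacts) + 1]] <- data.frame(
        kind = "hbond", resno_a = k, atom_a = "OG",
        resno_b = k, atom_b = "OG", distance = g,
        stringsAsFactors = FALSE)
    }
  }
  for (k in seq_len(n_surf)) {
    resno <- n_int + k
    tip_a <- c(gs[k, 1], gs[k, 2], -(surf_z + 2.8))
    tip_b <- c(gs[k, 1], gs[k, 2], +(surf_z + 2.8))
    add_residue("A", resno, surf_types[k], tip_a, c(0, 0, -1), "surface")
    add_residue("B", resno, surf_types[k], tip_b, c(0, 0, 1), "surface")
  }

  at <- do.call(rbind, rows)
  at$insert <- ""; at$alt <- ""; at$o <- 1
  at$elesy <- substr(at$elety, 1, 1)
  at$type <- "ATOM"
  cx <- build_complex(at, "A", "B",
                      sprintf("synthetic_%06d", s$seed))
  cx <- assign_radii(cx)

  res_df <- do.call(rbind, manifest_res)
  contacts_df <- if (length(contacts) > 0) do.call(rbind, contacts) else
    data.frame(kind = character(), resno_a = integer(),
               atom_a = character(), resno_b = integer(),
               atom_b = character(), distance = numeric(),
               stringsAsFactors = FALSE)
  expected <- manifest_expectations(res_df)
  manifest <- list(residues = res_df, contacts = contacts_df,
                   n_hbond_pairs = s$n_hbonds + s$n_salt_bridges,
                   n_salt_bridges = s$n_salt_bridges,
                   expected = expected,
                   intended_class = expected$class_label,
                   spec = unclass(s))
  list(complex = cx, manifest = manifest)
}

# Expected polarity percentages and class from the residue table.
manifest_expectations <- function(res_df) {
  intf <- res_df[res_df$region == "interface", , drop = FALSE]
  surf <- res_df[res_df$region == "surface", , drop = FALSE]
  pct <- function(x) if (length(x) == 0) NA_real_ else
    100 * mean(x)
  s_pct <- pct(surf$polarity == "polar")
  i_pct <- pct(intf$polarity == "polar")
  np_pct <- pct(intf$polarity == "nonpolar")
  list(surface_polar_pct = s_pct, interface_polar_pct = i_pct,
       interface_nonpolar_pct = np_pct,
       polarity_abundance = i_pct - np_pct,
       interface_charged_pct = pct(intf$charged),
       class_label = if (is.na(s_pct) || is.na(i_pct)) "not applicable"
                     else classify_interface(s_pct, i_pct))
}

#' Build a cohort of synthetic heterodimers emulating the two classes
#'
#' Class-A-like members draw their surface polar fraction from
#' Normal(0.55, noise) and interface polar fraction from
#' Normal(0.35, noise); class-B-like members reverse the two. Class-A
#' members get larger contact patches (12 interface residues per chain vs
#' 8) and fewer charged interface residues (10% vs 40%, with 1 vs 2 planted
#' salt bridges), mirroring the qualitative contrasts the class split shows
#' on real heterodimers: larger, more hydrophobic interfaces in class A;
#' smaller, more polar and charged interfaces in class B. Per-member seeds
#' derive from the master seed.
#'
#' @param n_class_a,n_class_b members per class.
#' @param noise standard deviation of the polar-fraction draws (0 =
#'   deterministic compositions).
#' @param seed master seed.
#' @param n_residues residues per chain.
#' @return List with `complexes` (list of `ppi_complex`), `manifests`
#'   (matching list) and `design` (data.frame `complex_id`,
#'   `intended_class`, `expected_class`).
#' @export
build_cohort <- function(n_class_a, n_class_b, noise = 0.05, seed = 1,
                         n_residues = 30) {
  stopifnot(n_class_a >= 1, n_class_b >= 1, noise >= 0)
  n <- n_class_a + n_class_b
  labels <- c(rep("A", n_class_a), rep("B", n_class_b))
  draws <- with_seed(seed, {
    data.frame(surf = stats::rnorm(n, ifelse(labels == "A", 0.55, 0.35),
                                   noise),
               intf = stats::rnorm(n, ifelse(labels == "A", 0.35, 0.55),
                                   noise))
  })
  draws$surf <- pmin(0.95, pmax(0.05, draws$surf))
  draws$intf <- pmin(0.95, pmax(0.05, draws$intf))

  complexes <- vector("list", n)
  manifests <- vector("list", n)
  design <- list()
  for (i in seq_len(n)) {
    cls <- labels[i]
    n_int <- if (cls == "A") 12 else 8
    cf <- if (cls == "A") 0.10 else 0.40
    k_sb_target <- if (cls == "A") 1 else 2
    n_polar <- round(draws$intf[i] * n_int)
    n_charged <- min(round(cf * n_int), n_polar)
    k_sb <- min(k_sb_target, n_charged)
    k_hb <- min(2, n_polar - n_charged)
    spec <- dimer_spec(
      n_residues = n_residues, n_interface = n_int,
      interface_polar_frac = draws$intf[i],
      surface_polar_frac = draws$surf[i],
      charged_frac = n_charged / n_int,
      n_hbonds = k_hb, n_salt_bridges = k_sb,
      charge_layout = if (n_charged > 0) "opposite" else "none",
      seed = (seed %% 100000L) * 10000L + i)
    built <- build_dimer(spec)
    built$complex$complex_id <- sprintf("cohort_%s%03d", cls, i)
    complexes[[i]] <- built$complex
    manifests[[i]] <- built$manifest
    design[[i]] <- data.frame(
      complex_id = built$complex$complex_id, intended_class = cls,
      expected_class = built$manifest$expected$class_label,
      stringsAsFactors = FALSE)
  }
  list(complexes = complexes, manifests = manifests,
       design = do.call(rbind, design))
}

#' Extended stub chain for reference-accessibility checks
#'
#' A single chain of residue stubs laid out along x with side chains
#' pointing +z, mimicking a fully extended conformation; used to derive
#' template-consistent reference accessibilities.
#'
#' @param resids character vector of stub residue types.
#' @param spacing CA-CA spacing along x, A.
#' @return Heavy-atom data.frame with radii assigned (columns as
#'   [heavy_atoms()]).
#' @export
build_extended_chain <- function(resids, spacing = 3.8) {
  rows <- lapply(seq_along(resids), function(k) {
    df <- stub_atoms(resids[k], c((k - 1) * spacing, 0, 2.6),
                     c(0, 0, 1), c(1, 0, 0))
    df$chain <- "A"; df$resno <- k; df$resid <- resids[k]
    df
  })
  at <- do.call(rbind, rows)
  at$insert <- ""; at$alt <- ""; at$o <- 1
  at$elesy <- substr(at$elety, 1, 1)
  at$is_h <- FALSE; at$is_standard <- TRUE
  rt <- ppi_radius_table()
  at$radius <- ifelse(at$elesy == "O", rt$by_class[["O"]],
                      ifelse(at$elesy == "N", rt$by_class[["N"]],
                             rt$by_class[["C_aliphatic"]]))
  at
}

#' Write a cohort to PDB files plus a manifest TSV
#'
#' @param cohort output of [build_cohort()].
#' @param dir output directory (created if needed).
#' @return Path to the manifest TSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$complexes, function(cx) {
    path <- file.path(dir, paste0(cx$complex_id, ".pdb"))
    write_complex(cx, path)
    data.frame(complex_id = cx$complex_id, pdb_path = path,
               chain_a = cx$chain_a, chain_b = cx$chain_b,
               stringsAsFactors = FALSE)
  })
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest_path)
}
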