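# Per-complex feature extraction and cohort-level class comparison.

#' Analysis configuration
#'
#' All thresholds of the pipeline in one object. Defaults follow the
#' standard criteria for this analysis: 1.4 A probe, 0.1 A^2 interface
#' threshold on the per-residue area change, 4 A contact cutoffs (strict
#' `<` for hydrogen bonds, inclusive for salt bridges), 5% relative-ASA
#' surface cutoff, interior dielectric 4.
#'
#' @param probe probe radius, A.
#' @param n_points quadrature points per atom.
#' @param dasa_cutoff interface threshold on residue area loss, A^2.
#' @param surface_rel_threshold relative-ASA surface cutoff (fraction).
#' @param hbond_cutoff,hbond_strict hydrogen-bond distance criterion.
#' @param sb_cutoff,sb_strict salt-bridge distance criterion.
#' @param charged_his treat histidine as charged throughout.
#' @param tie_epsilon tie band for classification, percentage points.
#' @param epsilon,kappa dielectric and screening constant for
#'   electrostatics.
#' @param potential a `ppi_potential` for binding-energy scoring, or `NULL`
#'   to use [default_potential()].
#' @param solvation sigma set for [delta_iG()].
#' @return List of class `ppi_config`.
#' @export
ppi_config <- function(probe = 1.4, n_points = 960, dasa_cutoff = 0.1,
                       surface_rel_threshold = 0.05,
                       hbond_cutoff = 4.0, hbond_strict = TRUE,
                       sb_cutoff = 4.0, sb_strict = FALSE,
                       charged_his = FALSE, tie_epsilon = 0,
                       epsilon = 4, kappa = 0.1, potential = NULL,
                       solvation = solvation_params()) {
  stopifnot(probe > 0, n_points >= 64, dasa_cutoff >= 0,
            surface_rel_threshold >= 0, hbond_cutoff > 0, sb_cutoff > 0,
            tie_epsilon >= 0, epsilon > 0, kappa >= 0)
  structure(list(probe = probe, n_points = n_points,
                 dasa_cutoff = dasa_cutoff,
                 surface_rel_threshold = surface_rel_threshold,
                 hbond_cutoff = hbond_cutoff, hbond_strict = hbond_strict,
                 sb_cutoff = sb_cutoff, sb_strict = sb_strict,
                 charged_his = charged_his, tie_epsilon = tie_epsilon,
                 epsilon = epsilon, kappa = kappa, potential = potential,
                 solvation = solvation),
            class = "ppi_config")
}

#' Extract the full feature row for one complex
#'
#' Runs area, interface, composition, contact, energetic and electrostatic
#' analysis in order and returns one feature row. Complexes with no
#' interface residues are returned with zero interface area and class
#' `"not applicable"` (excluded from class statistics downstream).
#'
#' @param cx a `ppi_complex` (radii are assigned if missing).
#' @param config a [ppi_config()].
#' @return One-row data.frame: `complex_id`, `n_interface`,
#'   `interface_area`, `surface_polar_pct`, `interface_polar_pct`,
#'   `polarity_abundance`, `interface_charged_pct`, `hbonds`,
#'   `salt_bridges`, `delta_iG`, `binding_energy`, `complementarity`,
#'   `class_label`.
#' @export
analyze_complex <- function(cx, config = ppi_config()) {
  stopifnot(inherits(cx, "ppi_complex"), inherits(config, "ppi_config"))
  if (anyNA(cx$atoms$radius[!cx$atoms$is_h])) cx <- assign_radii(cx)
  acc <- suppressWarnings(detect_interface(
    cx, probe = config$probe, n_points = config$n_points,
    dasa_cutoff = config$dasa_cutoff))
  acc <- detect_surface(acc, rel_threshold = config$surface_rel_threshold)
  if (!any(acc$is_interface)) {
    return(data.frame(
      complex_id = cx$complex_id, n_interface = 0L, interface_area = 0,
      surface_polar_pct = NA_real_, interface_polar_pct = NA_real_,
      polarity_abundance = NA_real_, interface_charged_pct = NA_real_,
      hbonds = 0L, salt_bridges = 0L, delta_iG = 0, binding_energy = 0,
      complementarity = NA_real_, class_label = "not applicable",
      stringsAsFactors = FALSE))
  }
  scheme <- residue_class_scheme(charged_his = config$charged_his)
  prof <- polarity_profile(acc, scheme)
  hb <- detect_hbonds(cx, cutoff = config$hbond_cutoff,
                      strict = config$hbond_strict,
                      table = donor_acceptor_table(config$charged_his))
  sb <- detect_salt_bridges(cx, cutoff = config$sb_cutoff,
                            strict = config$sb_strict,
                            charged_his = config$charged_his)
  pot <- if (is.null(config$potential)) default_potential() else
    config$potential
  be <- score_binding_energy(cx, pot)
  samples <- suppressWarnings(interface_potential(
    cx, acc, charge_model(epsilon = config$epsilon, kappa = config$kappa,
                          charge_his = config$charged_his)))
  data.frame(
    complex_id = cx$complex_id,
    n_interface = sum(acc$is_interface),
    interface_area = interface_area(acc),
    surface_polar_pct = prof$surface_polar_pct,
    interface_polar_pct = prof$interface_polar_pct,
    polarity_abundance = prof$polarity_abundance,
    interface_charged_pct = prof$interface_charged_pct,
    hbonds = count_contacts(hb)$atom_pairs,
    salt_bridges = count_contacts(sb)$residue_pairs,
    delta_iG = delta_iG(cx, acc, config$solvation),
    binding_energy = be$binding_energy,
    complementarity = complementarity_score(samples),
    class_label = classify_interface(prof,
                                     tie_epsilon = config$tie_epsilon),
    stringsAsFactors = FALSE)
}

#' Analyse a cohort of complexes and compare the classes
#'
#' Accepts either a list of `ppi_complex` objects or the path to a manifest
#' TSV with columns `complex_id`, `pdb_path`, `chain_a`, `chain_b`.
#' Failures of individual complexes are logged and skipped, never aborting
#' the cohort. When both classes have at least two members a Wilcoxon
#' rank-sum class-comparison report is attached; otherwise the report slot
#' carries the string `"insufficient n"`.
#'
#' @param x list of complexes or manifest path.
#' @param config a [ppi_config()].
#' @param mode test mode forwarded to [compare_classes()].
#' @return List of class `ppi_cohort`: `features` (data.frame, one row per
#'   analysed complex), `report` (a `ppi_class_report` or
#'   `"insufficient n"`), `failures` (named character vector of error
#'   messages).
#' @export
analyze_cohort <- function(x, config = ppi_config(),
                           mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (is.character(x)) {
    man <- utils::read.table(x, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (nrow(man) == 0) stop("empty manifest")
    x <- lapply(seq_len(nrow(man)), function(i) {
      read_complex(man$pdb_path[i], man$chain_a[i], man$chain_b[i],
                   complex_id = man$complex_id[i])
    })
  }
  if (length(x) == 0) stop("empty cohort")
  # share one potential table across the cohort
  if (is.null(config$potential)) config$potential <- default_potential()
  rows <- list(); failures <- character()
  for (cx in x) {
    res <- tryCatch(analyze_complex(cx, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[cx$complex_id] <- conditionMessage(res)
      message("skipping ", cx$complex_id, ": ", conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  if (length(rows) == 0) stop("no complex could be analysed")
  features <- do.call(rbind, rows)
  enough <- all(table(factor(features$class_label,
                             levels = c("A", "B"))) >= 2)
  report <- if (enough) compare_classes(features, mode = mode) else
    "insufficient n"
  structure(list(features = features, report = report,
                 failures = failures), class = "ppi_cohort")
}

#' @export
print.ppi_cohort <- function(x, ...) {
  cat(sprintf("ppi_cohort: %d complexes (A: %d, B: %d, other: %d)\n",
              nrow(x$features), sum(x$features$class_label == "A"),
              sum(x$features$class_label == "B"),
              sum(!x$features$class_label %in% c("A", "B"))))
  if (inherits(x$report, "ppi_class_report")) print(x$report)
  else cat("report:", x$report, "\n")
  invisible(x)
}
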