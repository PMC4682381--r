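# Residue-class composition of interface and surface, the polar-minus-
# nonpolar abundance statistic, and class A/B assignment.

#' Polarity composition of interface and surface
#'
#' Residue-count percentages of polar, nonpolar and charged residues among
#' the standard residues of the interface and of the rest of the surface,
#' pooled across both chains. The interface polarity abundance is the polar
#' minus nonpolar percentage at the interface.
#'
#' @param acc a `ppi_accessibility` with interface and surface flags set
#'   ([detect_interface()] then [detect_surface()]).
#' @param scheme a [residue_class_scheme()].
#' @param weight `"count"` (default) for residue-count percentages, or
#'   `"area"` for buried-area-weighted interface percentages (surface stays
#'   count-based).
#' @return List of class `ppi_polarity`: `surface_polar_pct` (S),
#'   `interface_polar_pct` (I), `interface_nonpolar_pct`,
#'   `polarity_abundance` (P% - NP%), `interface_charged_pct`,
#'   `n_interface`, `n_surface`.
#' @export
polarity_profile <- function(acc, scheme = residue_class_scheme(),
                             weight = c("count", "area")) {
  stopifnot(inherits(acc, "ppi_accessibility"))
  weight <- match.arg(weight)
  if (anyNA(acc$is_surface)) {
    stop("surface flags not set; call detect_surface() first")
  }
  std <- acc[acc$is_standard, , drop = FALSE]
  intf <- std[std$is_interface, , drop = FALSE]
  surf <- std[std$is_surface, , drop = FALSE]
  if (nrow(intf) == 0) stop("no interface residues")
  if (nrow(surf) == 0) stop("no surface residues")

  w_int <- if (weight == "area") intf$delta_asa else rep(1, nrow(intf))
  pct <- function(res, w, set) 100 * sum(w[res %in% set]) / sum(w)
  i_polar <- pct(intf$resid, w_int, scheme$polar)
  i_nonpolar <- pct(intf$resid, w_int, scheme$nonpolar)
  structure(list(
    surface_polar_pct = pct(surf$resid, rep(1, nrow(surf)), scheme$polar),
    interface_polar_pct = i_polar,
    interface_nonpolar_pct = i_nonpolar,
    polarity_abundance = i_polar - i_nonpolar,
    interface_charged_pct = pct(intf$resid, w_int, scheme$charged),
    n_interface = nrow(intf), n_surface = nrow(surf)
  ), class = "ppi_polarity")
}

#' Assign a complex to interface class A or B
#'
#' Class A: surface polarity exceeds interface polarity (S > I), the
#' classical nonpolar-driven interface. Class B: interface polarity exceeds
#' surface polarity (S < I), a polar-driven interface. Values within
#' `tie_epsilon` percentage points are reported as `"tie"` and excluded from
#' class statistics downstream.
#'
#' @param profile a `ppi_polarity`, or a numeric surface polar percentage
#'   when `interface_polar_pct` is given.
#' @param interface_polar_pct interface polar percentage (I), used with a
#'   numeric `profile` (S).
#' @param tie_epsilon half-width of the tie band, percentage points.
#' @return `"A"`, `"B"` or `"tie"`.
#' @export
classify_interface <- function(profile, interface_polar_pct = NULL,
                               tie_epsilon = 0) {
  if (inherits(profile, "ppi_polarity")) {
    s <- profile$surface_polar_pct
    i <- profile$interface_polar_pct
  } else {
    s <- profile
    i <- interface_polar_pct
  }
  stopifnot(is.numeric(s), is.numeric(i), tie_epsilon >= 0)
  if (abs(s - i) <= tie_epsilon) "tie" else if (s > i) "A" else "B"
}
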