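# Class-comparison statistics: exact and approximate Wilcoxon rank-sum
# tests, Benjamini-Hochberg q-values, and feature correlations.

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test for a location difference between two independent samples.
#' Exact mode enumerates the null distribution of the rank sum over all
#' choose(n, n_a) group assignments — ties handled by mid-ranks, with the
#' enumeration done by a shift-algorithm dynamic program over the doubled
#' (integer) mid-ranks, so it is exact with or without ties. The normal
#' approximation applies the tie-corrected variance and a 0.5 continuity
#' correction. `auto` uses the exact test up to a combined n of 30.
#'
#' A paired signed-rank variant is available via `paired = TRUE` (delegates
#' to [stats::wilcox.test()]), for designs where the two samples are
#' genuinely paired.
#'
#' @param a,b numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @param paired logical; paired signed-rank test instead of rank-sum.
#' @return List with `U` (Mann-Whitney U for sample `a`), `p_value`, and
#'   `method`.
#' @export
rank_sum_test <- function(a, b, mode = c("auto", "exact", "normal_approx"),
                          paired = FALSE) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  stopifnot(na >= 1, nb >= 1)
  if (paired) {
    wt <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
    return(list(U = unname(wt$statistic), p_value = wt$p.value,
                method = "signed-rank (paired)"))
  }
  n <- na + nb
  if (mode == "auto") mode <- if (n <= 30) "exact" else "normal_approx"
  if (mode == "exact" && n > 30) {
    stop("exact mode requires a combined sample size of at most 30")
  }
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  u_obs <- w_obs - na * (na + 1) / 2
  if (length(unique(c(a, b))) == 1) {
    return(list(U = u_obs, p_value = 1, method = mode))
  }
  if (mode == "exact") {
    p <- exact_ranksum_p(r, na)
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    mu <- na * nb / 2
    z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(0, z)))
  }
  list(U = u_obs, p_value = p, method = mode)
}

# Exact two-sided p for the rank-sum statistic via a subset-sum dynamic
# program over doubled mid-ranks (integers). Counts, among all
# choose(n, na) subsets of size na, those whose rank sum deviates from its
# null mean by at least the observed deviation.
exact_ranksum_p <- function(r, na) {
  n <- length(r)
  w <- as.integer(round(2 * r))     # doubled mid-ranks are integers
  total <- sum(w)
  mu2 <- na * (n + 1)               # doubled null mean of the rank sum
  w_obs2 <- sum(w[seq_len(na)])
  dev <- abs(w_obs2 - mu2)
  # f[k+1, s+1] = number of size-k subsets with doubled rank sum s
  f <- matrix(0, nrow = na + 1, ncol = total + 1)
  f[1, 1] <- 1
  for (x in w) {
    kmax <- na
    for (k in kmax:1) {
      nonzero <- which(f[k, ] > 0)
      if (length(nonzero) > 0) {
        f[k + 1, nonzero + x] <- f[k + 1, nonzero + x] + f[k, nonzero]
      }
    }
  }
  counts <- f[na + 1, ]
  sums2 <- seq_len(total + 1) - 1
  extreme <- abs(sums2 - mu2) >= dev - 1e-9
  sum(counts[extreme]) / sum(counts)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment
#' q_i = min over j with p_(j) >= p_(i) of m p_(j) / j, order preserved.
#' Delegates to the standard BH implementation.
#'
#' @param p numeric p-values in (0, 1].
#' @return q-values in the input order; empty input gives empty output.
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Compare feature distributions between interface classes
#'
#' Runs a two-sided Wilcoxon rank-sum test per feature between class-A and
#' class-B complexes, adjusts the family of p-values by Benjamini-Hochberg,
#' and reports Pearson correlations for the canonical feature pairs
#' (H-bonds vs interface area, binding energy vs interface area, solvation
#' gain vs interface area, binding energy vs solvation gain), overall and
#' within each class. Complexes labelled `"tie"` or `"not applicable"` are
#' excluded.
#'
#' @param features data.frame with a `class_label` column (`"A"`/`"B"`) and
#'   the feature columns.
#' @param feature_cols character; feature columns to test (defaults to the
#'   canonical seven that are present).
#' @param mode test mode passed to [rank_sum_test()].
#' @return List of class `ppi_class_report`: `tests` (data.frame `feature`,
#'   `n_a`, `mean_a`, `median_a`, `n_b`, `mean_b`, `median_b`, `U`,
#'   `p_value`, `q_value`) and `correlations` (data.frame `pair`, `group`,
#'   `r`).
#' @export
compare_classes <- function(features,
                            feature_cols = NULL,
                            mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  canonical <- c("interface_area", "polarity_abundance",
                 "interface_charged_pct", "delta_iG", "binding_energy",
                 "hbonds", "salt_bridges")
  if (is.null(feature_cols)) {
    feature_cols <- intersect(canonical, names(features))
  }
  stopifnot(length(feature_cols) > 0, "class_label" %in% names(features))
  feats <- features[features$class_label %in% c("A", "B"), , drop = FALSE]
  for (lab in c("A", "B")) {
    if (sum(feats$class_label == lab) < 2) {
      stop("fewer than 2 complexes in class ", lab)
    }
  }
  rows <- lapply(feature_cols, function(fc) {
    xa <- feats[[fc]][feats$class_label == "A"]
    xb <- feats[[fc]][feats$class_label == "B"]
    tt <- rank_sum_test(xa, xb, mode = mode)
    data.frame(feature = fc, n_a = sum(!is.na(xa)),
               mean_a = mean(xa, na.rm = TRUE),
               median_a = stats::median(xa, na.rm = TRUE),
               n_b = sum(!is.na(xb)), mean_b = mean(xb, na.rm = TRUE),
               median_b = stats::median(xb, na.rm = TRUE),
               U = tt$U, p_value = tt$p_value, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  tests$q_value <- bh_qvalues(tests$p_value)

  pairs <- list(c("hbonds", "interface_area"),
                c("binding_energy", "interface_area"),
                c("delta_iG", "interface_area"),
                c("binding_energy", "delta_iG"))
  cors <- list()
  for (pr in pairs) {
    if (!all(pr %in% names(feats))) next
    for (grp in c("all", "A", "B")) {
      sub <- if (grp == "all") feats else
        feats[feats$class_label == grp, , drop = FALSE]
      x <- sub[[pr[1]]]; y <- sub[[pr[2]]]
      ok <- stats::complete.cases(x, y)
      r <- if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
        stats::cor(x[ok], y[ok]) else NA_real_
      cors[[length(cors) + 1]] <- data.frame(
        pair = paste(pr, collapse = " vs "), group = grp, r = r,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(tests = tests,
                 correlations = do.call(rbind, cors)),
            class = "ppi_class_report")
}

#' @export
print.ppi_class_report <- function(x, ...) {
  cat("Class comparison (Wilcoxon rank-sum, BH-adjusted):\n")
  print(x$tests, digits = 4)
  cat("\nFeature correlations (Pearson r):\n")
  print(x$correlations, digits = 3)
  invisible(x)
}
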