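#' Classical fixed-effects one-way ANOVA
#'
#' Between/within decomposition computed from explicit sums of squares:
#' `F = (SSB / (k - 1)) / (SSW / (N - k))`, with the p-value from the F
#' distribution. Group summaries are reported as mean and standard
#' error. Degenerate input with zero between- and within-group variance
#' (all readings identical) is defined as F = 0, p = 1; equal means with
#' zero within-group variance likewise; distinct means with zero
#' within-group variance give p = 0.
#'
#' @param groups list of at least two [simulate_readings()] outputs or
#'   plain numeric vectors (each of length >= 2), optionally named.
#' @param alpha significance level for the `significant` flag.
#' @return object of class `anova_result`: list with `labels`, `means`,
#'   `se`, `n`, `F_statistic`, `df`, `p_value`, `significant`.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  vals <- lapply(groups, function(g)
    if (inherits(g, "measurement_set")) g$readings_T else as.numeric(g))
  if (any(vapply(vals, length, integer(1)) < 2))
    stop("each group needs >= 2 readings")
  labels <- names(groups)
  if (is.null(labels))
    labels <- vapply(seq_along(groups), function(i) {
      g <- groups[[i]]
      if (inherits(g, "measurement_set")) g$device
      else paste0("group", i)
    }, character(1))
  ni <- vapply(vals, length, integer(1))
  mi <- vapply(vals, mean, numeric(1))
  N <- sum(ni); k <- length(vals)
  grand <- sum(ni * mi) / N
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  if (ssw == 0 && ssb == 0) {
    F <- 0; p <- 1
  } else if (ssw == 0) {
    F <- Inf; p <- 0
  } else {
    F <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  }
  structure(list(labels = labels,
                 means = stats::setNames(mi, labels),
                 se = stats::setNames(vapply(vals, function(v)
                   stats::sd(v) / sqrt(length(v)), numeric(1)), labels),
                 n = stats::setNames(ni, labels),
                 F_statistic = F, df = c(df1 = df1, df2 = df2),
                 p_value = p, significant = p < alpha, alpha = alpha),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df["df1"], x$df["df2"], x$F_statistic, x$p_value,
              if (x$significant) " *" else " (n.s.)"))
  for (l in x$labels)
    cat(sprintf("  %-12s mean %.5g +/- %.3g (n = %d)\n",
                l, x$means[l], x$se[l], x$n[l]))
  invisible(x)
}

#' Per-distance comparison panel of the validation experiment
#'
#' For each distance, runs the omnibus one-way ANOVA over all groups
#' present plus two pairwise contrasts: human coil versus mouse coil
#' (expected significant: the clinical coil is far stronger) and
#' simulation versus measurement (expected non-significant when the
#' synthetic measurement noise is moderate). Pairwise contrasts are
#' two-group ANOVAs (equivalent to pooled-variance t tests) without
#' multiplicity correction, flagged as such in the output.
#'
#' @param sets list of [simulate_readings()] outputs covering the four
#'   device labels `human_coil`, `mouse_coil`, `simulation`,
#'   `measurement` at every distance.
#' @param distances_mm distances to analyse; defaults to those present.
#' @param alpha significance level.
#' @return object of class `comparison_panel`: list of per-distance
#'   entries, each with `omnibus`, `human_vs_mouse`,
#'   `simulation_vs_measurement` [one_way_anova()] results.
#' @export
distance_panel <- function(sets, distances_mm = NULL, alpha = 0.05) {
  dev <- vapply(sets, `[[`, character(1), "device")
  dst <- vapply(sets, `[[`, numeric(1), "distance_mm")
  if (is.null(distances_mm)) distances_mm <- sort(unique(dst))
  required <- c("human_coil", "mouse_coil", "simulation", "measurement")
  panel <- lapply(distances_mm, function(d) {
    idx <- which(dst == d)
    have <- dev[idx]
    missing <- setdiff(required, have)
    if (length(missing))
      stop("distance ", d, " mm: missing group(s) ",
           paste(missing, collapse = ", "))
    gr <- stats::setNames(sets[idx], have)
    list(distance_mm = d,
         omnibus = one_way_anova(gr, alpha),
         human_vs_mouse =
           one_way_anova(gr[c("human_coil", "mouse_coil")], alpha),
         simulation_vs_measurement =
           one_way_anova(gr[c("simulation", "measurement")], alpha))
  })
  structure(list(panel = panel, distances_mm = distances_mm,
                 alpha = alpha,
                 note = "pairwise contrasts are uncorrected two-group ANOVAs"),
            class = "comparison_panel")
}

#' @export
print.comparison_panel <- function(x, ...) {
  cat("<comparison_panel>\n")
  for (e in x$panel)
    cat(sprintf(
      "  %2g mm: omnibus p = %.3g; human vs mouse p = %.3g%s; sim vs meas p = %.3g%s\n",
      e$distance_mm, e$omnibus$p_value,
      e$human_vs_mouse$p_value,
      if (e$human_vs_mouse$significant) " *" else "",
      e$simulation_vs_measurement$p_value,
      if (e$simulation_vs_measurement$significant) " *" else " (n.s.)"))
  invisible(x)
}

#' Flatten a comparison panel to a data frame
#'
#' @param panel a [distance_panel()] result.
#' @return data frame with one row per distance and contrast.
#' @export
panel_to_df <- function(panel) {
  stopifnot(inherits(panel, "comparison_panel"))
  do.call(rbind, lapply(panel$panel, function(e) {
    data.frame(
      distance_mm = e$distance_mm,
      contrast = c("omnibus", "human_vs_mouse",
                   "simulation_vs_measurement"),
      F_statistic = c(e$omnibus$F_statistic,
                      e$human_vs_mouse$F_statistic,
                      e$simulation_vs_measurement$F_statistic),
      p_value = c(e$omnibus$p_value, e$human_vs_mouse$p_value,
                  e$simulation_vs_measurement$p_value),
      significant = c(e$omnibus$significant,
                      e$human_vs_mouse$significant,
                      e$simulation_vs_measurement$significant))
  }))
}
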