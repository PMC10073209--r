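# run an expression with a private RNG stream seeded by `seed`, without
# disturbing the caller's .Random.seed
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate replicate Tesla-meter readings
#'
#' Stands in for the gaussmeter probe of the in vivo validation: each
#' reading equals the model-predicted truth plus multiplicative and
#' additive Gaussian noise,
#' `reading = truth (1 + eps_rel) + eps_abs`,
#' `eps_rel ~ N(0, relative_sd)`, `eps_abs ~ N(0, absolute_sd)`, i.i.d.
#' Defaults (5% relative, 1 mT absolute, n = 5 replicates) are stated
#' assumptions of the synthetic experiment, not measured properties of
#' any instrument.
#'
#' @param truth_T true flux density, tesla (>= 0).
#' @param n number of replicates (>= 2).
#' @param relative_sd standard deviation of the multiplicative noise,
#'   fraction.
#' @param absolute_sd standard deviation of the additive noise, tesla.
#' @param seed integer seed; the same seed gives bit-identical readings.
#' @param device group label: `"mouse_coil"`, `"human_coil"`,
#'   `"simulation"` or `"measurement"`.
#' @param distance_mm coil-to-head distance this set belongs to, mm.
#' @return object of class `measurement_set`: list with `readings_T`,
#'   `device`, `distance_mm`, `truth_T`, `noise` and `seed`.
#' @export
simulate_readings <- function(truth_T, n = 5, relative_sd = 0.05,
                              absolute_sd = 1e-3, seed = 1,
                              device = c("mouse_coil", "human_coil",
                                         "simulation", "measurement"),
                              distance_mm = NA_real_) {
  device <- match.arg(device)
  if (!(truth_T >= 0)) stop("truth_T must be >= 0")
  if (n < 2) stop("at least 2 replicates required")
  if (relative_sd < 0 || absolute_sd < 0) stop("noise sds must be >= 0")
  readings <- with_seed(seed, {
    truth_T * (1 + stats::rnorm(n, 0, relative_sd)) +
      stats::rnorm(n, 0, absolute_sd)
  })
  structure(list(readings_T = readings, device = device,
                 distance_mm = distance_mm, truth_T = truth_T,
                 noise = list(relative_sd = relative_sd,
                              absolute_sd = absolute_sd),
                 seed = seed),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set> %s @ %.3g mm: n = %d, mean %.4g T (truth %.4g T)\n",
              x$device, x$distance_mm, length(x$readings_T),
              mean(x$readings_T), x$truth_T))
  invisible(x)
}

#' Synthetic stand-in for a clinical human figure-8 coil
#'
#' The clinical comparator device is modelled generically as a figure-8
#' winding with two 70 mm lobes (9 turns of 1.5 mm wire per lobe, 42 mm
#' bore) driven at 5 kA, giving ampere-turns that dominate the murine
#' coil at every stand-off distance used in the validation. All
#' parameters are synthetic: no clinical coil's internals are modelled.
#'
#' @return a [coil_spec()] labelled as synthetic.
#' @export
human_coil_spec <- function() {
  coil_spec(topology = "figure8",
            inner_diameter_mm = 42, outer_diameter_mm = 70,
            turns = 9, wire_width_mm = 1.5, wire_height_mm = 2,
            turn_gap_mm = 0.05, current_A = 5000, voltage_V = 2000,
            frequency_Hz = 20,
            label = "synthetic human figure-8 coil (70 mm lobes)")
}

#' Model-predicted flux density truth at a stand-off distance
#'
#' Peak |B| over the observation plane at `distance_mm`, computed by the
#' Biot-Savart solver for the murine coil (`mouse_coil_truth`) or the
#' synthetic clinical figure-8 stand-in (`human_coil_truth`).
#'
#' @param distance_mm coil-to-head distance, mm (>= 0).
#' @param spec coil specification; defaults to the murine coil or the
#'   synthetic human coil respectively.
#' @param extent_mm,spacing_mm observation window (see
#'   [field_map_on_plane()]).
#' @return flux density truth in tesla.
#' @export
mouse_coil_truth <- function(distance_mm, spec = coil_spec(),
                             extent_mm = 130, spacing_mm = 1) {
  if (any(distance_mm < 0)) stop("distance_mm must be >= 0")
  w <- build_winding(spec)
  vapply(distance_mm, function(d)
    max(field_map_on_plane(w, d, extent_mm, spacing_mm)$values),
    numeric(1))
}

#' @rdname mouse_coil_truth
#' @export
human_coil_truth <- function(distance_mm, spec = human_coil_spec(),
                             extent_mm = 220, spacing_mm = 2) {
  if (any(distance_mm < 0)) stop("distance_mm must be >= 0")
  w <- build_winding(spec)
  vapply(distance_mm, function(d)
    max(field_map_on_plane(w, d, extent_mm, spacing_mm)$values),
    numeric(1))
}

#' Full synthetic validation dataset
#'
#' Generates, for every distance, the four groups of the validation
#' experiment: noisy human-coil readings, noisy mouse-coil readings,
#' exact simulation predictions (zero noise: the model output is
#' deterministic) and noisy in vivo style measurements whose truth
#' equals the simulation prediction. Per-group seeds are derived from
#' `seed` so the whole dataset is reproducible from one integer.
#'
#' @param distances_mm stand-off distances, mm.
#' @param n replicates per group.
#' @param relative_sd,absolute_sd noise model for the measured groups.
#' @param seed base integer seed.
#' @param mouse_spec,human_spec coil specifications.
#' @return list with `sets` (list of [simulate_readings()] outputs) and
#'   `truths` (data frame device x distance).
#' @export
synthetic_validation_data <- function(distances_mm = c(0, 2, 5, 8),
                                      n = 5, relative_sd = 0.05,
                                      absolute_sd = 1e-3, seed = 1,
                                      mouse_spec = coil_spec(),
                                      human_spec = human_coil_spec()) {
  mouse_t <- mouse_coil_truth(distances_mm, mouse_spec)
  human_t <- human_coil_truth(distances_mm, human_spec)
  sets <- list()
  for (i in seq_along(distances_mm)) {
    d <- distances_mm[i]
    sub <- seed + 97L * (i - 1L)
    sets <- c(sets, list(
      simulate_readings(human_t[i], n, relative_sd, absolute_sd,
                        seed = sub + 1L, device = "human_coil",
                        distance_mm = d),
      simulate_readings(mouse_t[i], n, relative_sd, absolute_sd,
                        seed = sub + 2L, device = "mouse_coil",
                        distance_mm = d),
      simulate_readings(mouse_t[i], n, 0, 0,
                        seed = sub + 3L, device = "simulation",
                        distance_mm = d),
      simulate_readings(mouse_t[i], n, relative_sd, absolute_sd,
                        seed = sub + 4L, device = "measurement",
                        distance_mm = d)))
  }
  truths <- data.frame(distance_mm = distances_mm,
                       mouse_truth_T = mouse_t, human_truth_T = human_t)
  list(sets = sets, truths = truths, seed = seed)
}

#' Tabulate measurement sets as a long data frame
#'
#' @param sets list of [simulate_readings()] outputs.
#' @return data frame with columns `device`, `distance_mm`, `replicate`,
#'   `reading_T`.
#' @export
measurements_to_df <- function(sets) {
  do.call(rbind, lapply(sets, function(s)
    data.frame(device = s$device, distance_mm = s$distance_mm,
               replicate = seq_along(s$readings_T),
               reading_T = s$readings_T)))
}
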