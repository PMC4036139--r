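# Configuration for the synthetic session generator.

#' Default prototypical-movement table of the generator
#'
#' Ten ground-truth movement prototypes in raw units: one backward-thrust
#' prototype (PM 01), one low-velocity forward prototype (PM 02), and four
#' mirror pairs with matching thrust and sign-opposed slip and yaw (PM 03-10),
#' ordered from maximal translation to maximal rotation. Emission SDs define
#' the diagonal Gaussian spread around each prototype. These defaults are free
#' generator parameters, not empirical centroid values.
#'
#' @return data frame with columns `pm`, `thrust` (cm/s), `slip` (cm/s),
#'   `yaw` (deg/s), `sd_thrust`, `sd_slip`, `sd_yaw`, `mirror` (partner PM id
#'   or `NA` for singletons).
#' @export
default_prototype_table <- function() {
  data.frame(
    pm = 1:10,
    thrust = c(-3, 8, 16, 16, 12, 12, 8, 8, 5, 5),
    slip = c(0, 0, 4, -4, 6, -6, 6, -6, 4, -4),
    yaw = c(0, 0, 40, -40, 90, -90, 160, -160, 240, -240),
    sd_thrust = c(1.5, rep(1, 9)),
    sd_slip = rep(1, 10),
    sd_yaw = rep(10, 10),
    mirror = c(NA, NA, 4, 3, 6, 5, 8, 7, 10, 9)
  )
}

# Macro-behavior definitions: PM pool and log-normal duration parameters
# (medians in seconds). Stationary and backwards swimming are pure PM 01
# behaviors distinguished by a thrust-mean override.
behavior_defs <- function() {
  list(
    cruise = list(pool = 2:10, meanlog = log(2.5), sdlog = 0.5),
    approach = list(pool = c(2L, 7L, 8L), meanlog = log(1.1), sdlog = 0.4),
    stationary = list(pool = 1L, meanlog = log(0.8), sdlog = 0.5),
    backwards = list(pool = 1L, meanlog = log(1.1), sdlog = 0.5),
    departure = list(pool = c(2L, 7L, 8L), meanlog = log(1.1), sdlog = 0.4)
  )
}

#' Build and validate a generator configuration
#'
#' Describes the study conditions emulated by [generate_session()]: an 80 x 80
#' cm arena imaged through a centred 64 x 48 cm camera view, a metal cube of
#' 1-3 cm edge at the arena centre (origin of the coordinate system; x
#' rightward, y upward, heading 0 along +x, counterclockwise positive), two
#' shelters, mirror-paired movement prototypes, and EOD trains whose rate
#' depends on the active prototype and on object distance.
#'
#' @param arena_extent width/height of the arena in cm.
#' @param view_extent width/height of the camera view in cm (centred in the
#'   arena; generated positions stay inside the view).
#' @param object_present logical; without the object no object-directed
#'   behaviors are scripted and cruising is biased toward the shelters.
#' @param object_edge_cm cube edge length (1, 2 or 3 cm).
#' @param object_position cube centre in cm (arena centre by default).
#' @param shelter_positions list of shelter anchor points in cm.
#' @param prototype_table per-PM emission table, see
#'   [default_prototype_table()].
#' @param behavior_script_weights named probabilities over the macro-behaviors
#'   `cruise`, `approach`, `stationary`, `backwards`, `departure`.
#' @param feod_base_table per-PM mean EOD rate in Hz.
#' @param feod_near_gain multiplicative EOD-rate increase applied within
#'   `feod_near_radius_cm` of the object.
#' @param feod_near_radius_cm radius of the near-object rate gain, cm.
#' @param approach_ramp_dist_cm distance below which approach thrust ramps
#'   down linearly (floor at 60 percent), cm.
#' @param stationary_thrust,backwards_thrust PM 01 thrust-mean overrides
#'   (cm/s) used during the stationary and backwards macro-behaviors.
#' @param ipi_shape gamma shape of the inter-pulse-interval distribution
#'   (larger = more regular pulse train).
#' @param n_frames_target number of frames to generate per session.
#' @param seed default integer seed for [generate_session()].
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(arena_extent = c(80, 80),
                             view_extent = c(64, 48),
                             object_present = TRUE,
                             object_edge_cm = 1,
                             object_position = c(0, 0),
                             shelter_positions = list(c(-28, 0), c(28, 0)),
                             prototype_table = default_prototype_table(),
                             behavior_script_weights = c(cruise = 0.55, approach = 0.12,
                                                         stationary = 0.10, backwards = 0.10,
                                                         departure = 0.13),
                             feod_base_table = c(23.2, 22.8, 35.4, 35.4, 27, 27,
                                                 25.5, 25.5, 32.4, 32.4),
                             feod_near_gain = 1.3,
                             feod_near_radius_cm = 5,
                             approach_ramp_dist_cm = 10,
                             stationary_thrust = -0.8,
                             backwards_thrust = -2.8,
                             ipi_shape = 10,
                             n_frames_target = 15000,
                             seed = 1L) {
  cfg <- list(arena_extent = arena_extent, view_extent = view_extent,
              object_present = isTRUE(object_present),
              object_edge_cm = object_edge_cm, object_position = object_position,
              shelter_positions = shelter_positions,
              prototype_table = prototype_table,
              behavior_script_weights = behavior_script_weights,
              feod_base_table = feod_base_table,
              feod_near_gain = feod_near_gain,
              feod_near_radius_cm = feod_near_radius_cm,
              approach_ramp_dist_cm = approach_ramp_dist_cm,
              stationary_thrust = stationary_thrust,
              backwards_thrust = backwards_thrust,
              ipi_shape = ipi_shape,
              n_frames_target = as.integer(n_frames_target),
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  pt <- cfg$prototype_table
  need <- c("pm", "thrust", "slip", "yaw", "sd_thrust", "sd_slip", "sd_yaw", "mirror")
  if (!all(need %in% names(pt))) stopf("prototype_table must have columns %s",
                                       paste(need, collapse = ", "))
  if (any(cfg$view_extent > cfg$arena_extent))
    stopf("view_extent must be contained in arena_extent")
  if (any(cfg$feod_base_table <= 0)) stopf("all EOD rates must be > 0")
  if (length(cfg$feod_base_table) != nrow(pt))
    stopf("feod_base_table must have one rate per prototype")
  if (cfg$ipi_shape <= 0) stopf("ipi_shape must be > 0")
  if (cfg$n_frames_target < 2L) stopf("n_frames_target must be >= 2")

  w <- cfg$behavior_script_weights
  if (any(w < 0) || sum(w) <= 0)
    stopf("behavior_script_weights must be non-negative and normalizable")
  if (!all(names(behavior_defs()) %in% names(w)))
    stopf("behavior_script_weights must name all macro-behaviors")

  # prototype structure: one backward singleton, one forward singleton,
  # four mirror pairs with matched thrust and negated slip/yaw
  singles <- pt$pm[is.na(pt$mirror)]
  if (length(singles) != 2L) stopf("expected exactly two unpaired prototypes")
  if (sum(pt$thrust[is.na(pt$mirror)] < 0) != 1L)
    stopf("expected exactly one backward-thrust singleton prototype")
  paired <- pt[!is.na(pt$mirror), ]
  if (nrow(paired) != 8L) stopf("expected four mirror pairs")
  for (i in seq_len(nrow(paired))) {
    j <- match(paired$mirror[i], pt$pm)
    if (is.na(j) || pt$mirror[j] != paired$pm[i])
      stopf("mirror pairing is not symmetric for PM %d", paired$pm[i])
    if (pt$thrust[j] != paired$thrust[i] ||
        pt$slip[j] != -paired$slip[i] || pt$yaw[j] != -paired$yaw[i])
      stopf("PMs %d/%d do not satisfy the mirror relation",
            paired$pm[i], paired$mirror[i])
  }
  if (any(pt$sd_thrust < 0) || any(pt$sd_slip < 0) || any(pt$sd_yaw < 0))
    stopf("emission SDs must be non-negative")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("generator_config: %dx%d cm arena (view %dx%d), object %s (edge %g cm)\n",
              x$arena_extent[1], x$arena_extent[2], x$view_extent[1], x$view_extent[2],
              if (x$object_present) "present" else "absent", x$object_edge_cm))
  cat(sprintf("  %d prototypes, %d frames targeted, seed %d\n",
              nrow(x$prototype_table), x$n_frames_target, x$seed))
  invisible(x)
}
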