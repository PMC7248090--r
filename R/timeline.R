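#' Build a session timeline
#'
#' Constructs the standard session plan: four equal-length stress slots
#' (no stress, medium stress, high stress, no stress), each split into three
#' contiguous workload phases ordered LOW -> MEDIUM -> HIGH, with three
#' stressful events embedded in the medium-stress slot and three in the
#' high-stress slot. With the defaults this is the canonical 60-minute
#' scenario: twelve 5-minute phases labelled `LWL1` ... `HWL4` and 20-second
#' events. Shorter sessions (any duration divisible by 12) keep the same
#' structure and are convenient for simulation studies.
#'
#' Events are centred within the second (medium) and third (high) phase
#' triplets, one per phase, so no event crosses a phase boundary. Ratings
#' are scheduled at the end of every phase.
#'
#' @param totalDuration session length in seconds; must be a positive
#'   multiple of 12 (4 slots x 3 phases).
#' @param eventDuration duration of each stressful event in seconds; must be
#'   shorter than one phase.
#' @return a [ScenarioTimeline-class] object.
#' @examples
#' tl <- generateTimeline()
#' phaseTable(tl)
#' @export
generateTimeline <- function(totalDuration = 3600, eventDuration = 20) {
  if (!is.numeric(totalDuration) || length(totalDuration) != 1 ||
      totalDuration <= 0 || totalDuration %% 12 != 0)
    stop("totalDuration must be a positive multiple of 12 seconds")
  phaseDur <- totalDuration / 12
  if (eventDuration >= phaseDur)
    stop("eventDuration must be shorter than one phase (", phaseDur, " s)")

  slotDur <- totalDuration / 4
  stress <- c("none", "medium", "high", "none")
  slots <- data.frame(
    index = 1:4, stress = stress,
    start = (0:3) * slotDur, end = (1:4) * slotDur
  )

  wl <- c("LOW", "MEDIUM", "HIGH")
  phases <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(
      label = paste0(c("L", "M", "H"), "WL", i),
      workload = wl,
      start = slots$start[i] + (0:2) * phaseDur,
      end = slots$start[i] + (1:3) * phaseDur,
      slot = i
    )
  }))

  mediumKinds <- c("high_complexity_conflict", "mode_c_failure", "social_pressure")
  highKinds <- c("radio_noise", "emergency_descent", "radar_images_lost")
  evSlot <- function(slotIdx, level, kinds) {
    ph <- phases[phases$slot == slotIdx, ]
    data.frame(
      onset = ph$start + (phaseDur - eventDuration) / 2,
      duration = eventDuration, level = level, kind = kinds
    )
  }
  events <- rbind(evSlot(2, "medium", mediumKinds), evSlot(3, "high", highKinds))

  new("ScenarioTimeline",
      totalDuration = totalDuration, slots = slots, phases = phases,
      events = events, ratingTimes = seq(phaseDur, totalDuration, by = phaseDur))
}

#' Look up timeline labels at given times
#'
#' Maps instants (seconds) to the slot index, phase label, workload level and
#' stress condition of the half-open interval containing them. The stress
#' condition follows the slot map: slot 1 `none`, slot 2 `medium`, slot 3
#' `high`, slot 4 `none`.
#'
#' @param timeline a [ScenarioTimeline-class].
#' @param t numeric vector of times in seconds (must lie in `[0, duration)`).
#' @return `data.frame(time, slot, phase, workload, stress)`.
#' @export
timelineLabels <- function(timeline, t) {
  ph <- phaseTable(timeline)
  sl <- slotTable(timeline)
  if (any(t < 0 | t >= sessionDuration(timeline)))
    stop("times must lie within [0, totalDuration)")
  idx <- findInterval(t, ph$start)
  data.frame(
    time = t,
    slot = ph$slot[idx],
    phase = ph$label[idx],
    workload = ph$workload[idx],
    stress = sl$stress[match(ph$slot[idx], sl$index)]
  )
}
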