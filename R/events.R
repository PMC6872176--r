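#' Condition catalogue of the multi-task localizer
#'
#' The ten event types of the fast event-related localizer: sentence reading
#' and listening, mental calculation cued visually or auditorily, left/right
#' button presses cued visually or auditorily, and two flashing-checkerboard
#' variants.
#'
#' @return Character vector of the ten condition labels.
#' @export
#' @examples
#' localizer_conditions()
localizer_conditions <- function() {
  c("visual_sentence", "auditory_sentence",
    "visual_computation", "auditory_computation",
    "visual_left_press", "visual_right_press",
    "auditory_left_press", "auditory_right_press",
    "checkerboard_horizontal", "checkerboard_vertical")
}

#' Contrast catalogue of the localizer
#'
#' The six linear contrasts used to probe the localizer's functional networks,
#' each expressed as weights over the condition catalogue. Positive and
#' negative sides are normalised to +1 and -1 total weight so contrast effects
#' are on the scale of a single condition's response. The four sensorimotor
#' contrasts (`video_minus_audio`, `audio_minus_video`, `left_minus_right`,
#' `right_minus_left`) are the robust ones used for detection benchmarking.
#'
#' @return Named list; each element is a named numeric vector of condition
#'   weights. The attribute `"sensorimotor"` names the four benchmark
#'   contrasts.
#' @export
localizer_contrasts <- function() {
  visual <- c("visual_sentence", "visual_computation", "visual_left_press",
              "visual_right_press", "checkerboard_horizontal",
              "checkerboard_vertical")
  auditory <- c("auditory_sentence", "auditory_computation",
                "auditory_left_press", "auditory_right_press")
  w <- function(pos, neg) {
    out <- c(stats::setNames(rep(1 / length(pos), length(pos)), pos),
             stats::setNames(rep(-1 / length(neg), length(neg)), neg))
    out
  }
  ctr <- list(
    video_minus_audio = w(visual, auditory),
    audio_minus_video = w(auditory, visual),
    left_minus_right  = w(c("visual_left_press", "auditory_left_press"),
                          c("visual_right_press", "auditory_right_press")),
    right_minus_left  = w(c("visual_right_press", "auditory_right_press"),
                          c("visual_left_press", "auditory_left_press")),
    sentences_minus_checkerboard = w("visual_sentence",
                                     c("checkerboard_horizontal",
                                       "checkerboard_vertical")),
    computation_minus_sentences = w(c("visual_computation",
                                      "auditory_computation"),
                                    c("visual_sentence", "auditory_sentence"))
  )
  attr(ctr, "sensorimotor") <- c("video_minus_audio", "audio_minus_video",
                                 "left_minus_right", "right_minus_left")
  ctr
}

#' Sensorimotor benchmark contrasts
#'
#' @return Character vector naming the four robust sensorimotor contrasts.
#' @export
sensorimotor_contrasts <- function() {
  attr(localizer_contrasts(), "sensorimotor")
}

#' Construct and validate an event table
#'
#' An event table is a data frame with columns `onset` and `duration` (both in
#' seconds) and `condition` (a label from the catalogue). Onsets must be
#' non-negative and strictly increasing within each condition; durations must
#' be positive.
#'
#' @param onset Numeric vector of onsets in seconds from run start.
#' @param duration Numeric vector of event durations in seconds.
#' @param condition Character vector of condition labels.
#' @param conditions Allowed condition catalogue.
#' @return A `data.frame` of class `event_table`, sorted by onset.
#' @export
event_table <- function(onset = numeric(), duration = numeric(),
                        condition = character(),
                        conditions = localizer_conditions()) {
  onset <- as.numeric(onset)
  duration <- as.numeric(duration)
  condition <- as.character(condition)
  if (length(onset) != length(duration) || length(onset) != length(condition))
    stop("onset, duration and condition must have equal length", call. = FALSE)
  if (any(!is.finite(onset)) || any(onset < 0))
    stop("all onsets must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(duration)) || any(duration <= 0))
    stop("all durations must be finite and > 0", call. = FALSE)
  bad <- setdiff(unique(condition), conditions)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ord <- order(onset)
  df <- data.frame(onset = onset[ord], duration = duration[ord],
                   condition = condition[ord], stringsAsFactors = FALSE)
  for (cc in unique(df$condition)) {
    o <- df$onset[df$condition == cc]
    if (length(o) > 1L && any(diff(o) <= 0))
      stop("onsets must be strictly increasing within condition ", cc,
           call. = FALSE)
  }
  class(df) <- c("event_table", "data.frame")
  df
}

#' Generate a pseudo-randomized fast event-related paradigm
#'
#' Schedules `events_per_condition` events of each of the ten catalogue
#' conditions over a run, in pseudo-random order, with all inter-onset gaps at
#' least `min_gap` seconds. Residual slack is spread over the gaps as random
#' jitter, mimicking the jittered timing of a fast event-related localizer.
#'
#' @param run_duration Run length in seconds (default 320 s, i.e. 5:20 min).
#' @param events_per_condition Number of events of each condition.
#' @param min_gap Minimum gap between an event's offset and the next onset (s).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param event_duration Duration of each event (s).
#' @param conditions Condition catalogue; must be a subset of
#'   [localizer_conditions()].
#' @return An [event_table] with `length(conditions) * events_per_condition`
#'   rows, all onsets in `[0, run_duration)`.
#' @export
#' @examples
#' ev <- generate_paradigm(320, 3, min_gap = 2, seed = 1)
#' nrow(ev)                 # 30
#' table(ev$condition)      # 3 each
generate_paradigm <- function(run_duration = 320, events_per_condition = 3,
                              min_gap = 2, seed = 1, event_duration = 1,
                              conditions = localizer_conditions()) {
  assert_scalar_num(run_duration, "run_duration", lower = 0, strict_lower = TRUE)
  assert_scalar_num(events_per_condition, "events_per_condition", lower = 0)
  assert_scalar_num(min_gap, "min_gap", lower = 0)
  assert_scalar_num(event_duration, "event_duration", lower = 0,
                    strict_lower = TRUE)
  bad <- setdiff(conditions, localizer_conditions())
  if (length(bad))
    stop("conditions outside the localizer catalogue: ",
         paste(bad, collapse = ", "), call. = FALSE)
  n <- length(conditions) * as.integer(events_per_condition)
  if (n == 0L) return(event_table())
  # feasibility: n events plus n-1 enforced gaps must fit, and the last event
  # must end before run_duration
  slack <- run_duration - n * event_duration - (n - 1L) * min_gap
  if (slack < 0)
    stop(sprintf(paste0("infeasible schedule: %d events of %.3g s with ",
                        "%.3g s gaps need %.4g s but the run is %.4g s"),
                 n, event_duration, min_gap,
                 n * event_duration + (n - 1L) * min_gap, run_duration),
         call. = FALSE)
  with_seed(seed, {
    labels <- sample(rep(conditions, times = events_per_condition))
    jit <- stats::runif(n + 1L)
    jit <- jit / sum(jit) * slack
    onsets <- jit[1L] +
      cumsum(c(0, rep(event_duration + min_gap, n - 1L) + jit[2:n]))
    event_table(onset = onsets, duration = rep(event_duration, n),
                condition = labels, conditions = conditions)
  })
}
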