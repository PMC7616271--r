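#' Tracked key points and experimental conditions
#'
#' The pipeline works on eight anatomical key points tracked on the dog's
#' body, and on the four cells of a 2 x 2 within-subject design crossing the
#' owner's and a stranger's presence in the testing room.
#'
#' @format `keypoint_names()` returns a character vector of the eight key
#'   point labels, in canonical order. The set is closed: any other label in a
#'   tracking table is a format error.
#' @export
keypoint_names <- function() {
  c("snout", "head_centre", "left_ear", "right_ear",
    "atlas", "hips", "tail_base", "tail_tip")
}

#' @rdname keypoint_names
#' @param owner_present,stranger_present logicals defining the condition.
#' @return `condition_label()` returns one of `"both_absent"`, `"owner_only"`,
#'   `"stranger_only"`, `"both_present"`.
#' @export
condition_label <- function(owner_present, stranger_present) {
  stopifnot(is.logical(owner_present), is.logical(stranger_present))
  ifelse(owner_present & stranger_present, "both_present",
    ifelse(owner_present, "owner_only",
      ifelse(stranger_present, "stranger_only", "both_absent")))
}

#' @rdname keypoint_names
#' @export
condition_levels <- function() {
  c("both_absent", "owner_only", "stranger_only", "both_present")
}

#' Describe a single trial
#'
#' A trial record holds the identifiers and constants the rest of the
#' pipeline needs about one dog x condition run: who, which condition, which
#' trial of the session, the frame rate, the trial duration and which chair
#' (A or B) is the owner's in this dog's counterbalancing.
#'
#' @param dog_id identifier of the subject.
#' @param owner_present,stranger_present logical condition flags.
#' @param trial trial number within the session (1-4).
#' @param fps frame rate in frames per second.
#' @param duration trial duration in seconds.
#' @param owner_chair `"A"` or `"B"`; which chair the owner is assigned to.
#' @param age_months,sex optional subject-level covariates carried through to
#'   the statistics module.
#' @return A one-row `data.frame` of class `trial_record`.
#' @export
trial_record <- function(dog_id, owner_present, stranger_present, trial,
                         fps = 24, duration = 120, owner_chair = "A",
                         age_months = NA_real_, sex = NA_character_) {
  stopifnot(fps > 0, duration > 0, trial %in% 1:4,
            owner_chair %in% c("A", "B"))
  rec <- data.frame(
    dog_id = as.character(dog_id),
    condition = condition_label(owner_present, stranger_present),
    owner_present = owner_present,
    stranger_present = stranger_present,
    trial = as.integer(trial),
    fps = fps,
    duration = duration,
    n_frames = as.integer(round(fps * duration)),
    owner_chair = owner_chair,
    age_months = age_months,
    sex = sex,
    stringsAsFactors = FALSE
  )
  class(rec) <- c("trial_record", "data.frame")
  rec
}
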