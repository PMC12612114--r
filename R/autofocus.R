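# Classification-score autofocus: a 5-class focus classifier is reduced to a
# scalar focal score and a feedback loop steps the objective until the score
# falls inside the in-focus band, with a one-shot direction reversal when the
# loop runs away (focus instability).

FOCUS_CLASSES <- c("BelowGreater3", "BelowLess3", "InFocus",
                   "AboveLess3", "AboveGreater3")

#' Focus controller configuration
#'
#' @param in_focus_low,in_focus_high inclusive score band declared "in focus"
#'   (defaults 2.8 and 3.5; a score of 3 is predicted best focus).
#' @param step_um objective step per iteration in micrometres (default 0.8).
#' @param max_iterations_one_direction consecutive same-direction steps before
#'   the controller declares focus instability and reverses (default 5, i.e.
#'   about 4 um of travel at the default step).
#' @param max_total_iterations hard cap on controller iterations.
#' @return an object of class `focus_config`.
#' @export
focus_config <- function(in_focus_low = 2.8, in_focus_high = 3.5,
                         step_um = 0.8, max_iterations_one_direction = 5L,
                         max_total_iterations = 25L) {
  stopifnot_scalar_num(in_focus_low, "in_focus_low")
  stopifnot_scalar_num(in_focus_high, "in_focus_high")
  if (in_focus_low >= in_focus_high)
    stop("in_focus_low must be < in_focus_high", call. = FALSE)
  stopifnot_scalar_num(step_um, "step_um", positive = TRUE)
  stopifnot_scalar_num(max_iterations_one_direction,
                       "max_iterations_one_direction", positive = TRUE)
  stopifnot_scalar_num(max_total_iterations, "max_total_iterations",
                       positive = TRUE)
  structure(list(in_focus_low = in_focus_low, in_focus_high = in_focus_high,
                 step_um = step_um,
                 max_iterations_one_direction =
                   as.integer(max_iterations_one_direction),
                 max_total_iterations = as.integer(max_total_iterations)),
            class = "focus_config")
}

#' Focal score from 5-class classifier confidences
#'
#' The classifier assigns confidences to five ordered focus classes (heavily
#' below, slightly below, in focus, slightly above, heavily above the focal
#' plane, mapped to integers 1..5). The score is the confidence-weighted mean
#' class `S = sum(c * w_c)` after normalizing the weights to sum to 1, so
#' `S` lies in [1, 5] and 3 is predicted best focus.
#'
#' @param weights numeric vector of 5 nonnegative confidences, ordered from
#'   heavily-below to heavily-above.
#' @return the focal score S.
#' @examples
#' focal_score(c(0, 0, 1, 0, 0)) # 3
#' @export
focal_score <- function(weights) {
  if (!is.numeric(weights) || length(weights) != 5L || any(!is.finite(weights)))
    stop("weights must be 5 finite numeric confidences", call. = FALSE)
  if (any(weights < 0))
    stop("weights must be nonnegative", call. = FALSE)
  total <- sum(weights)
  if (total <= 0)
    stop("no classification: all weights are zero", call. = FALSE)
  sum(seq_len(5) * weights / total)
}

#' Map a focal score to a stage action
#'
#' Scores inside the inclusive band are in focus; scores below the band mean
#' the plane is below focus, so the objective moves up (+z); scores above the
#' band move it down (-z).
#'
#' @param S focal score in [1, 5].
#' @param cfg a [focus_config()].
#' @return one of `"in_focus"`, `"move_up"`, `"move_down"`.
#' @export
classify_action <- function(S, cfg = focus_config()) {
  stopifnot_scalar_num(S, "S")
  if (S < cfg$in_focus_low) "move_up"
  else if (S > cfg$in_focus_high) "move_down"
  else "in_focus"
}

#' Run the autofocus feedback loop
#'
#' Repeatedly classifies the image at the current objective height, converts
#' the focal score to an action, and steps the objective by `step_um` until
#' the score enters the in-focus band. If the loop takes more than
#' `max_iterations_one_direction` consecutive steps the same way without
#' reaching focus, that is treated as focus instability: the direction is
#' reversed once and held until focus is found. A second exhaustion, or
#' exceeding `max_total_iterations`, raises a focus-not-found error.
#'
#' @param classify_at function of one argument `z_um` returning a 5-vector of
#'   class confidences (the pluggable classifier contract; see
#'   [simulated_defocus_classifier()]).
#' @param z0 starting objective height (um).
#' @param cfg a [focus_config()].
#' @param travel_limit_um maximum |z - z0| the stage may travel.
#' @return list with `z_final` and `trace`, a data frame with columns
#'   `iteration`, `z_um`, `score`, `action`.
#' @export
run_autofocus <- function(classify_at, z0 = 0, cfg = focus_config(),
                          travel_limit_um = 20) {
  stopifnot(is.function(classify_at))
  stopifnot_scalar_num(z0, "z0")
  z <- z0
  trace <- list()
  dir_run <- 0L           # signed length of the current same-direction run
  reversed <- FALSE       # has the one-shot instability reversal fired?
  forced_dir <- 0L        # nonzero once reversed: direction is locked
  # after a reversal the controller must first retrace the overshoot, so the
  # reversed run is allowed that many extra steps before exhaustion
  run_limit <- cfg$max_iterations_one_direction
  for (it in seq_len(cfg$max_total_iterations)) {
    S <- focal_score(classify_at(z))
    action <- classify_action(S, cfg)
    if (action == "in_focus") {
      trace[[it]] <- data.frame(iteration = it, z_um = z, score = S,
                                action = "in_focus")
      return(list(z_final = z, trace = do.call(rbind, trace)))
    }
    step_dir <- if (forced_dir != 0L) forced_dir
                else if (action == "move_up") 1L else -1L
    # instability check: too many consecutive steps one way
    if (sign(dir_run) == step_dir) run_len <- abs(dir_run) else run_len <- 0L
    if (run_len >= run_limit) {
      if (reversed)
        stop("focus not found: both directions exhausted", call. = FALSE)
      reversed <- TRUE
      forced_dir <- -step_dir
      step_dir <- forced_dir
      action <- "reverse"
      run_limit <- run_len + cfg$max_iterations_one_direction
      run_len <- 0L
    } else {
      action <- if (step_dir > 0) "move_up" else "move_down"
    }
    trace[[it]] <- data.frame(iteration = it, z_um = z, score = S,
                              action = action)
    z <- z + step_dir * cfg$step_um
    if (abs(z - z0) > travel_limit_um)
      stop("travel range exceeded during autofocus", call. = FALSE)
    dir_run <- step_dir * (run_len + 1L)
  }
  stop(sprintf("focus not found after %d iterations",
               cfg$max_total_iterations), call. = FALSE)
}

#' Simulated defocus classifier
#'
#' Test double for the trained focus-classification network. Confidence for
#' class `c` decays as a Gaussian in the distance between the signed defocus
#' `z - true_focus_um` and that class's characteristic defocus
#' `class_centers_um[c]`. With strictly increasing centers (middle center 0)
#' the resulting focal score is monotone nondecreasing in z, which is the
#' property the feedback controller relies on.
#'
#' @param true_focus_um objective height of true best focus.
#' @param class_centers_um strictly increasing 5-vector of class-center
#'   defocus values (um); the third entry must be 0.
#' @param softness Gaussian width (um) of the class-response curves.
#'   The default 0.8 keeps the in-focus score band within one 0.8 um step
#'   of true focus, matching the controller's convergence contract.
#' @return a function `z_um -> 5-vector of confidences`.
#' @export
simulated_defocus_classifier <- function(true_focus_um = 0,
                                         class_centers_um = c(-5, -1.5, 0,
                                                              1.5, 5),
                                         softness = 0.8) {
  if (length(class_centers_um) != 5L || any(diff(class_centers_um) <= 0))
    stop("class_centers_um must be 5 strictly increasing values",
         call. = FALSE)
  if (class_centers_um[3] != 0)
    stop("middle class center must be 0 (in focus)", call. = FALSE)
  stopifnot_scalar_num(softness, "softness", positive = TRUE)
  function(z_um) {
    dz <- z_um - true_focus_um
    w <- exp(-((dz - class_centers_um)^2) / (2 * softness^2))
    w / sum(w)
  }
}
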