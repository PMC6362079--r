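#' Simulated clinician graders on the Efron scale
#'
#' A grader profile describes one simulated clinician scoring bulbar redness
#' on the Efron scale (0 = normal to 4 = severe, in 0.1 steps): an additive
#' bias and a Gaussian grading noise. Crucially, simulated grades depend only
#' on the scene's true vessel coverage — never on camera, lighting,
#' magnification or calibration — emulating the color constancy of human
#' vision that makes clinical grading robust to those factors.
#'
#' @param bias additive offset on the Efron scale.
#' @param noise_sd grading noise standard deviation (Efron units).
#' @param grader_id identifier.
#' @return an object of class `grader_profile`.
#' @export
grader_profile <- function(bias = 0, noise_sd = 0, grader_id = "rater") {
  stopifnot(noise_sd >= 0)
  structure(list(bias = bias, noise_sd = noise_sd, grader_id = grader_id),
            class = "grader_profile")
}

#' @rdname grader_profile
#' @export
default_grader_profiles <- function() {
  # noise sds mirror published per-clinician repeatability (within-subject sd
  # of duplicate grades estimates the grading noise sd)
  list(grader_profile(bias = 0.0,  noise_sd = 0.11, grader_id = "rater1"),
       grader_profile(bias = 0.1,  noise_sd = 0.22, grader_id = "rater2"),
       grader_profile(bias = -0.1, noise_sd = 0.27, grader_id = "rater3"))
}

round_to_step <- function(x, step = 0.1) round(x / step) * step

#' Simulate clinician grades for one image
#'
#' Each grader scores \code{4 * true_redness + bias + noise}, clamped to the
#' Efron range \code{[0, 4]} and rounded to the 0.1 grading step. Grades are a
#' pure function of `(true_redness, graders, seed)`.
#'
#' @param true_redness vessel-coverage fraction in \code{[0, 1]}.
#' @param graders list of [grader_profile()]s (at least one).
#' @param seed integer seed for the grading noise.
#' @return named numeric vector of grades, one per grader.
#' @export
simulate_graders <- function(true_redness, graders, seed = 1L) {
  if (length(graders) < 1L) stop("need at least one grader", call. = FALSE)
  stopifnot(true_redness >= 0, true_redness <= 1)
  noise <- with_seed(seed, stats::rnorm(length(graders)))
  grades <- vapply(seq_along(graders), function(i) {
    g <- graders[[i]]
    raw <- 4 * true_redness + g$bias + noise[i] * g$noise_sd
    round_to_step(min(4, max(0, raw)), 0.1)
  }, numeric(1))
  names(grades) <- vapply(graders, `[[`, character(1), "grader_id")
  grades
}
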