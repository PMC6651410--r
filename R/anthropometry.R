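#' Fifteen-segment anthropometric model
#'
#' The whole-body centre of mass is computed by the kinematic method: the
#' mass-weighted sum of per-segment COM trajectories over a 15-segment body
#' model (head-neck, thorax-abdomen, pelvis, and paired upper arms, forearms,
#' hands, thighs, shanks and feet).  The default mass fractions are a
#' standard cadaver-based table (Winter-style); they are configurable because
#' published tables differ at the third decimal.
#'
#' @param mass_fractions named numeric vector of 15 strictly positive
#'   per-segment mass fractions summing to 1 (within 1e-9).
#' @return an object of class `anthropometric_model`.
#' @examples
#' m <- anthropometric_model()
#' sum(m$mass_fractions)
#' @export
anthropometric_model <- function(mass_fractions = default_mass_fractions()) {
  if (length(mass_fractions) != 15L)
    fail("anthropometric model needs 15 segment fractions, got %d",
         length(mass_fractions))
  if (any(mass_fractions <= 0))
    fail("all mass fractions must be strictly positive")
  if (abs(sum(mass_fractions) - 1) > 1e-9)
    fail("mass fractions must sum to 1 (got %.12f)", sum(mass_fractions))
  if (is.null(names(mass_fractions)))
    names(mass_fractions) <- default_segment_names()
  structure(list(segment_names = names(mass_fractions),
                 mass_fractions = unname(mass_fractions)),
            class = "anthropometric_model")
}

#' @rdname anthropometric_model
#' @export
default_mass_fractions <- function() {
  c(head_neck      = 0.0810,
    thorax_abdomen = 0.3550,
    pelvis         = 0.1420,
    upper_arm_r    = 0.0280, upper_arm_l = 0.0280,
    forearm_r      = 0.0160, forearm_l   = 0.0160,
    hand_r         = 0.0060, hand_l      = 0.0060,
    thigh_r        = 0.1000, thigh_l     = 0.1000,
    shank_r        = 0.0465, shank_l     = 0.0465,
    foot_r         = 0.0145, foot_l      = 0.0145)
}

default_segment_names <- function() names(default_mass_fractions())

#' @export
print.anthropometric_model <- function(x, ...) {
  cat("<anthropometric_model> 15 segments, fractions sum =",
      format(sum(x$mass_fractions)), "\n")
  invisible(x)
}
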