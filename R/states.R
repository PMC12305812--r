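#' Anaemia severity states
#'
#' The four anaemia severity states used throughout the model, ordered from
#' full health to most severe. Severity is defined on haemoglobin (Hb)
#' concentration: anaemia is Hb below 11 g/dL, split into mild
#' (10 to below 11), moderate (7 to below 10) and severe (below 7).
#'
#' @return Character vector `c("none", "mild", "moderate", "severe")`.
#' @export
anaemia_states <- function() {
  c("none", "mild", "moderate", "severe")
}

# Hb interval per state, half-open [low, high); "none" is open-ended above
# but bounded at 25 g/dL, the upper limit of physiologically valid values.
state_hb_bounds <- function(state) {
  bounds <- list(
    none     = c(11, 25),
    mild     = c(10, 11),
    moderate = c(7, 10),
    severe   = c(0, 7)
  )
  bounds[[state]]
}

#' Categorise haemoglobin into anaemia severity
#'
#' Applies the WHO severity cut-offs for young children: severe below
#' 7 g/dL, moderate from 7 to below 10, mild from 10 to below 11, and no
#' anaemia at 11 g/dL or above. Intervals are half-open and lower-closed,
#' so exactly 10 g/dL is mild and exactly 11 g/dL is not anaemic.
#'
#' @param hb Haemoglobin concentration in g/dL; finite and positive.
#'   Vectorised.
#' @return Factor with levels [anaemia_states()], same length as `hb`.
#' @examples
#' categorize_anaemia(c(10.5, 11, 6.9, 8))
#' @export
categorize_anaemia <- function(hb) {
  if (!is.numeric(hb) || length(hb) == 0) {
    stop("`hb` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(hb)) || any(hb <= 0)) {
    stop("`hb` must be finite and positive (g/dL)", call. = FALSE)
  }
  state <- ifelse(hb < 7, "severe",
           ifelse(hb < 10, "moderate",
           ifelse(hb < 11, "mild", "none")))
  factor(state, levels = anaemia_states())
}
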