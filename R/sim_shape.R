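#' Body shape from body weight
#'
#' Maps body weight to a body envelope by cube-root allometry: each linear
#' dimension equals its coefficient times `bw^(1/3)`, so doubling the weight
#' scales every dimension by `2^(1/3)` and shape is a deterministic, monotone
#' function of weight. Ventral clearance is attached unchanged.
#'
#' @param bw Body weight (kg), vectorized, strictly positive.
#' @param allometry Named coefficients `length`, `width`, `height` (m per
#'   kg^(1/3)).
#' @param clearance Ventral clearance (m), recycled along `bw`.
#' @return A tibble with `body_length`, `body_width`, `body_height`,
#'   `clearance` (all metres).
#' @examples
#' shape_from_weight(c(25, 154))
#' @export
shape_from_weight <- function(bw,
                              allometry = c(length = 0.237, width = 0.069,
                                            height = 0.086),
                              clearance = 0.18) {
  if (any(bw <= 0)) abort("body weight must be strictly positive.")
  s <- bw^(1 / 3)
  out <- tibble(
    body_length = allometry[["length"]] * s,
    body_width = allometry[["width"]] * s,
    body_height = allometry[["height"]] * s,
    clearance = rep_len(clearance, length(bw))
  )
  if (any(out$clearance < 0)) abort("clearance must be non-negative.")
  out
}
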