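#' Jute-fibre breaking-strength data
#'
#' Breaking strength of jute fibre at two gauge lengths (10 mm and 20 mm),
#' 30 specimens each, a standard two-sample lifetime benchmark.  The raw
#' strengths are in the original units; analyses customarily divide by 1000
#' for numerical convenience (the default here), which only rescales
#' \eqn{\lambda}.
#'
#' @param scaled logical; divide the strengths by 1000 (default).
#' @return A data.frame with columns `strength` (numeric) and `gauge`
#'   (factor, `"10mm"` / `"20mm"`).
#' @examples
#' jute <- jute_fiber()
#' with(jute, tapply(strength, gauge, median))
#' @export
jute_fiber <- function(scaled = TRUE) {
  f <- system.file("extdata", "jute_fiber.csv", package = "jointGIED",
                   mustWork = TRUE)
  d <- utils::read.csv(f)
  data.frame(strength = if (scaled) d$strength / 1000 else d$strength,
             gauge = factor(paste0(d$gauge_mm, "mm"), levels = c("10mm", "20mm")))
}
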