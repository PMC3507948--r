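# Branch rate-per-time calibration: converting branch lengths
# (substitutions/site) and divergence-time calibrations (million years, My)
# into absolute rates, and comparing lineages by their rate ratio.

#' Calibrate a branch length against a divergence time
#'
#' @param branch_length Branch length(s) in substitutions per site (>= 0).
#' @param time_my Calibration time(s) in million years (> 0).
#' @return A tibble with columns `branch_length`, `time_my` and
#'   `rate` (= branch_length / time_my, substitutions/site/My).
#' @examples
#' branch_rate(0.5, 50)
#' # a branch twice as long spanning a tenfold shorter time is 20x faster:
#' rate_ratio(branch_rate(2, 50), branch_rate(1, 500))
#' @export
branch_rate <- function(branch_length, time_my) {
  if (any(time_my <= 0)) stop_domain("calibration time must be > 0 My")
  if (any(branch_length < 0)) stop_domain("branch length must be >= 0")
  tibble(branch_length = branch_length, time_my = time_my,
         rate = branch_length / time_my)
}

#' @rdname branch_rate
#' @param r1,r2 Rate estimates from [branch_rate()] (their first rows are
#'   compared).
#' @return `rate_ratio()`: the scalar `r1$rate / r2$rate`.
#' @export
rate_ratio <- function(r1, r2) {
  if (r2$rate[1] == 0) stop_domain("cannot take a rate ratio against a zero rate")
  r1$rate[1] / r2$rate[1]
}
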