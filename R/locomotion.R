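#' Average crawling velocity of a tracked larva
#'
#' Total path length (sum of inter-sample Euclidean steps) divided by
#' elapsed time. A net-displacement variant is exposed because the original
#' tracking protocol is described only by citation; path length is the
#' default since it measures crawl speed rather than goal-directedness.
#'
#' @param track a [centroid_track()] (>= 2 samples).
#' @param method `"path"` (default) or `"net"`.
#' @return Velocity in um/s.
#' @export
average_velocity <- function(track, method = c("path", "net")) {
  method <- match.arg(method)
  s <- track$samples
  if (nrow(s) < 2) stop("need at least 2 samples", call. = FALSE)
  elapsed <- s$t_s[nrow(s)] - s$t_s[1]
  if (elapsed <= 0) stop("zero elapsed time", call. = FALSE)
  if (method == "path") {
    d <- sum(sqrt(diff(s$x_um)^2 + diff(s$y_um)^2))
  } else {
    d <- sqrt((s$x_um[nrow(s)] - s$x_um[1])^2 + (s$y_um[nrow(s)] - s$y_um[1])^2)
  }
  d / elapsed
}

#' Developmental viability rates
#'
#' Stage survival normalized to the number of starting embryos, times 100.
#' Counts must be monotone nonincreasing across stages (embryos -> L1
#' larvae -> pupae -> adults); a violation indicates a bookkeeping problem
#' and raises an error.
#'
#' @param counts list or data.frame row with `n_embryos`, `n_L1`,
#'   `n_pupae`, `n_adults` (nonnegative integers).
#' @return Named list `pct_hatch`, `pct_pupation`, `pct_eclosion`.
#' @export
viability_rates <- function(counts) {
  need <- c("n_embryos", "n_L1", "n_pupae", "n_adults")
  if (!all(need %in% names(counts)))
    stop("counts must supply ", paste(need, collapse = ", "), call. = FALSE)
  v <- vapply(need, function(k) as.numeric(counts[[k]]), numeric(1))
  if (any(v < 0) || any(v != round(v)))
    stop("stage counts must be nonnegative integers", call. = FALSE)
  if (v[1] <= 0) stop("n_embryos must be positive", call. = FALSE)
  if (is.unsorted(rev(v)))
    stop("stage counts must be monotone nonincreasing ",
         "(embryos >= L1 >= pupae >= adults)", call. = FALSE)
  list(pct_hatch = unname(100 * v[2] / v[1]),
       pct_pupation = unname(100 * v[3] / v[1]),
       pct_eclosion = unname(100 * v[4] / v[1]))
}
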