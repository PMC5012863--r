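#' Parameters of the strength-to-frequency mapping
#'
#' The mapping assigns each region a natural frequency between a slow bound
#' `a` and a fast bound `b`, chosen to span the bandwidth of slow
#' resting-state BOLD fluctuations (0.01-0.1 Hz by default). The exponent
#' controls how sharply frequency falls off with node strength.
#'
#' @param a slow bound, Hz (frequency of the strongest node).
#' @param b fast bound, Hz (frequency of the weakest node).
#' @param exponent positive power applied to the normalized strength.
#' @return an object of class `timescale_params`.
#' @export
timescale_params <- function(a = 0.01, b = 0.1, exponent = 2) {
  if (!is_scalar_number(a) || !is_scalar_number(b) || a <= 0 || a >= b) {
    stop_("need 0 < a < b (got a = %s, b = %s)", format(a), format(b))
  }
  if (!is_scalar_number(exponent) || exponent <= 0) {
    stop_("exponent must be a positive number")
  }
  structure(list(a = a, b = b, exponent = exponent),
            class = "timescale_params")
}

#' Assign natural frequencies from anatomical node strength
#'
#' Encodes the hierarchy of intrinsic timescales: each region's natural
#' frequency decreases with its node strength,
#' \deqn{\omega_i = b - (b - a)\left(\frac{s_i - s_{min}}
#'   {s_{max} - s_{min}}\right)^{p},}
#' so the weakest (sensory-like) region oscillates at the fast bound `b` and
#' the strongest hub at the slow bound `a`. The mapping depends only on the
#' relative position of each strength between the network minimum and
#' maximum, and is therefore invariant to rescaling all weights.
#'
#' @param strengths named numeric vector of node strengths
#'   (see [node_strength()]); must not be all equal.
#' @param params a [timescale_params()].
#' @return an object of class `frequency_profile`: a named numeric vector of
#'   frequencies in Hz, with the parameters attached as an attribute.
#' @examples
#' s <- c(A = 3, B = 1, C = 2)
#' assign_frequencies(s)  # B (weakest) -> 0.1 Hz, A (hub) -> 0.01 Hz
#' @export
assign_frequencies <- function(strengths, params = timescale_params()) {
  stopifnot(inherits(params, "timescale_params"), is.numeric(strengths))
  if (anyNA(strengths) || any(strengths < 0)) {
    stop_("strengths must be non-negative and finite")
  }
  s_min <- min(strengths)
  s_max <- max(strengths)
  if (s_max == s_min) {
    stop_("all node strengths are equal: the timescale gradient is undefined")
  }
  q <- (strengths - s_min) / (s_max - s_min)
  omega <- params$b - (params$b - params$a) * q^params$exponent
  structure(omega, params = params, class = "frequency_profile")
}

#' Summarize a frequency profile over designated nodes
#'
#' Reports the whole-network mean frequency, the frequencies of designated
#' hub and sensory nodes, and whether the expected ordering holds: hubs
#' slower than the mean, sensory nodes faster than the mean.
#'
#' @param profile a `frequency_profile`.
#' @param hub_ids,sensory_ids region ids of designated hub / sensory nodes.
#' @return list with `mean_omega`, `omega_hub`, `omega_sensory`,
#'   `hub_below_mean`, `sensory_above_mean`.
#' @export
summarize_frequencies <- function(profile, hub_ids, sensory_ids) {
  stopifnot(inherits(profile, "frequency_profile"))
  unknown <- setdiff(c(hub_ids, sensory_ids), names(profile))
  if (length(unknown) > 0) {
    stop_("unknown region id: '%s'", unknown[1L])
  }
  m <- mean(profile)
  list(mean_omega = m,
       omega_hub = unclass(profile)[hub_ids],
       omega_sensory = unclass(profile)[sensory_ids],
       hub_below_mean = all(profile[hub_ids] < m),
       sensory_above_mean = all(profile[sensory_ids] > m))
}

#' Write a frequency profile as a two-column TSV
#' @param profile a `frequency_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frequency_profile <- function(profile, path) {
  write.table(data.frame(region_id = names(profile),
                         omega_hz = as.numeric(profile)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
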