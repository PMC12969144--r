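# Shared helpers: angle arithmetic, seeding, von Mises sampling, hashing.

#' Wrap angles into [0, 2*pi)
#'
#' @param x numeric vector of angles in radians.
#' @return angles reduced modulo 2*pi into `[0, 2*pi)`.
#' @export
wrap_phase <- function(x) x %% (2 * pi)

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return signed angles in `(-pi, pi]`.
#' @export
wrap_angle <- function(x) {
  w <- x %% (2 * pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' A single master seed fans out into independent substreams for the
#' schedule, respiration, behavior and each statistical procedure, so that
#' per-participant results do not depend on execution order.
#'
#' @param seed master seed (integer).
#' @param ... labels (participant id, stage name, ...) identifying the stream.
#' @return an integer seed in `[1, 2^31 - 20]`.
#' @export
derive_seed <- function(seed, ...) {
  lab <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 0
  for (b in utf8ToInt(lab)) h <- (h * 131 + b) %% 2147483629
  as.integer(h %% 2147483600L + 1L)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the circular
#' uniform. Used by the trace generator to set the respiratory phase at
#' stimulus onset.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration, >= 0.
#' @return angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.7) + 8
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1)))
  }
  wrap_phase(mu + out[seq_len(n)])
}

#' Expected resultant length of a von Mises distribution
#'
#' The mean resultant length of von Mises(mu, kappa) is the Bessel ratio
#' I1(kappa)/I0(kappa); this is the large-n limit of the plvs for phases
#' drawn from that distribution.
#'
#' @param kappa concentration parameter(s), >= 0.
#' @return resultant length(s) in `[0, 1)`.
#' @export
vonmises_resultant <- function(kappa) {
  ifelse(kappa <= 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

# Short stable hash used to tag outputs with the configuration they came from.
config_hash <- function(config) substr(rlang::hash(config), 1, 12)
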