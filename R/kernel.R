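#' The 2Dt dispersal kernel
#'
#' Seed shadows are modelled with the single-parameter bivariate Student's t
#' ("2Dt") kernel with shape fixed at 1,
#' \deqn{S(r; u) = \frac{1}{\pi u (1 + r^2/u)^2},}
#' the density (per m^2) of seed landing at distance \eqn{r} (m) from the
#' parent, for scale parameter \eqn{u} (m^2). The shape parameter is not
#' fitted: it is poorly identified by trap data, and fixing it at 1 gives a
#' closed-form radial CDF, quantile function and mean distance
#' \eqn{\bar d = (\pi/2)\sqrt{u}}.
#'
#' @param r distance from the source tree, metres (vectorised,
#'   non-negative)
#' @param u kernel scale, m^2 (`u > 0`)
#' @return `kernel_density`: seed density per m^2 at distance `r`.
#' @examples
#' kernel_density(0, 100)            # 1 / (100 * pi)
#' kernel_radial_cdf(sqrt(100), 100) # median distance = sqrt(u)
#' mean_distance(100)                # (pi / 2) * 10
#' @export
kernel_density <- function(r, u) {
  check_u(u)
  stopifnot(all(r >= 0))
  1 / (pi * u * (1 + r^2 / u)^2)
}

#' @rdname kernel_density
#' @return `kernel_radial_cdf`: probability that a seed lands within
#'   distance `r` of the source, \eqn{F(r) = 1 - 1/(1 + r^2/u)}.
#' @export
kernel_radial_cdf <- function(r, u) {
  check_u(u)
  stopifnot(all(r >= 0))
  1 - 1 / (1 + r^2 / u)
}

#' @rdname kernel_density
#' @return `mean_distance`: the kernel's mean dispersal distance
#'   \eqn{(\pi/2)\sqrt{u}}, metres. This is the per-species-and-regime
#'   "dispersal parameter" reported in the output tables.
#' @export
mean_distance <- function(u) {
  check_u(u)
  (pi / 2) * sqrt(u)
}

#' @rdname kernel_density
#' @param mean_m mean dispersal distance, metres (`mean_m > 0`)
#' @return `u_from_mean`: the kernel scale giving mean distance `mean_m`;
#'   exact inverse of [mean_distance()], \eqn{u = (2\bar d/\pi)^2}.
#' @export
u_from_mean <- function(mean_m) {
  if (!all(is.finite(mean_m)) || any(mean_m <= 0)) {
    stop("mean dispersal distance must be finite and positive", call. = FALSE)
  }
  (2 * mean_m / pi)^2
}

#' Draw dispersal distances from the 2Dt kernel
#'
#' Inverse-CDF sampling of the radial distance: with `q ~ Uniform(0, 1)`,
#' the sampled distance is `sqrt(u * q / (1 - q))`. Uses R's global RNG
#' stream.
#'
#' @inheritParams kernel_density
#' @param n number of draws
#' @return vector of `n` distances, metres
#' @export
sample_distance <- function(n, u) {
  check_u(u)
  q <- stats::runif(n)
  sqrt(u * q / (1 - q))
}

#' Tree-to-trap seed-shadow matrix
#'
#' Entry `S[s, i]` is the seed density (m^-2) at trap `s` contributed per
#' unit fecundity of tree `i`: the 2Dt kernel evaluated at the Euclidean
#' tree-trap distance. No distance truncation is applied; distant trees
#' simply contribute vanishing density.
#'
#' @param trees data frame with columns `x_m`, `y_m` (one row per tree)
#' @param traps data frame with columns `x_m`, `y_m` (one row per trap)
#' @inheritParams kernel_density
#' @return matrix, `nrow(traps)` x `nrow(trees)`, with dimnames taken from
#'   `trap_id` / `tree_id` columns when present
#' @export
shadow_matrix <- function(trees, traps, u) {
  check_u(u)
  D <- distance_matrix(traps, trees)
  S <- kernel_density(D, u)
  dim(S) <- dim(D)
  dimnames(S) <- dimnames(D)
  S
}

# Euclidean trap x tree distance matrix (rows = traps, cols = trees).
distance_matrix <- function(traps, trees) {
  D <- sqrt(outer(traps$x_m, trees$x_m, "-")^2 +
            outer(traps$y_m, trees$y_m, "-")^2)
  rownames(D) <- if (!is.null(traps$trap_id)) as.character(traps$trap_id)
  colnames(D) <- if (!is.null(trees$tree_id)) as.character(trees$tree_id)
  D
}

check_u <- function(u) {
  if (!all(is.finite(u)) || any(u <= 0)) {
    stop("kernel scale u must be finite and positive", call. = FALSE)
  }
  invisible(u)
}
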