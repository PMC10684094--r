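# Numerically stable log(1 + exp(z)).
log1pexp <- function(z) {
  out <- z
  lo <- z <= 18
  out[lo] <- log1p(exp(z[lo]))
  hi <- z > 18 & z <= 33.3
  out[hi] <- z[hi] + exp(-z[hi])
  out
}

# Stable softplus and its inverse (used by parameter reparameterizations).
softplus <- function(x) log1pexp(x)
softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 33.3, y, log(expm1(y)))
}
sigmoid <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' Smoothed hinge function
#'
#' The softplus-type smoothing of \code{max(0, x)} used throughout the fuzzy
#' encoding layer: \eqn{f_\epsilon(x) = \epsilon \log(1 + e^{x/\epsilon})}.
#' As \eqn{\epsilon \to 0} it converges to the hinge \eqn{\max(0, x)};
#' \eqn{\epsilon} controls the smoothness of the resulting membership
#' functions. Evaluated with the log-sum-exp identity so large \code{x/eps}
#' never overflows.
#'
#' @param x numeric vector.
#' @param eps smoothness parameter in (0, 1).
#' @return numeric vector, elementwise \eqn{\ge 0}.
#' @examples
#' smoothed_hinge(0, 0.5)      # 0.5 * log(2)
#' smoothed_hinge(3, 1e-4)     # ~ 3, the crisp limit
#' @export
smoothed_hinge <- function(x, eps) {
  stopifnot(is.numeric(x), length(eps) == 1L, eps > 0)
  eps * log1pexp(x / eps)
}

# d/dx smoothed_hinge(x, eps) = sigmoid(x / eps)
smoothed_hinge_grad <- function(x, eps) sigmoid(x / eps)

check_cutoffs <- function(cutoffs) {
  stopifnot(length(cutoffs) == 4L, all(is.finite(cutoffs)))
  if (is.unsorted(cutoffs)) {
    stop("cutoffs must be non-decreasing (a1 <= a2 <= a3 <= a4)")
  }
  if (cutoffs[2] <= cutoffs[1] || cutoffs[4] <= cutoffs[3]) {
    stop("cutoff gaps a2 - a1 and a4 - a3 must be strictly positive")
  }
  invisible(cutoffs)
}

#' Fuzzy concept membership functions
#'
#' Degree to which a continuous measurement belongs to the \code{"low"},
#' \code{"medium"} or \code{"high"} fuzzy concept, given four ordered cutoffs
#' \eqn{a_1 \le a_2 \le a_3 \le a_4} and smoothness \code{eps}. Each
#' membership is a difference of smoothed hinges; in the crisp limit
#' (\code{eps} small) they become the familiar trapezoids: low is 1 below
#' \eqn{a_1} and ramps to 0 at \eqn{a_2}, high is 0 below \eqn{a_3} and ramps
#' to 1 at \eqn{a_4}, and medium is the complement plateauing at 1 on
#' \eqn{[a_2, a_3]}. For any \code{eps} the three degrees sum to exactly 1.
#'
#' @param x numeric vector of (typically standardized) measurements.
#' @param cutoffs numeric length-4, ordered, with \code{a2 > a1} and
#'   \code{a4 > a3}.
#' @param eps smoothness in (0, 1).
#' @param concept one of \code{"low"}, \code{"medium"}, \code{"high"}.
#' @return numeric vector of membership degrees (values can overshoot
#'   \eqn{[0,1]} by \eqn{O(eps)}; they are clamped only where they enter the
#'   conjunction layer).
#' @seealso [membership_all()] for all three concepts at once.
#' @export
membership <- function(x, cutoffs, eps, concept = c("low", "medium", "high")) {
  concept <- match.arg(concept)
  unname(membership_all(x, cutoffs, eps)[, concept])
}

#' Evaluate all three memberships
#'
#' @inheritParams membership
#' @return matrix with one row per element of \code{x} and columns
#'   \code{low}, \code{medium}, \code{high}.
#' @export
membership_all <- function(x, cutoffs, eps) {
  stopifnot(all(is.finite(x)))
  check_cutoffs(cutoffs)
  a1 <- cutoffs[1]; a2 <- cutoffs[2]; a3 <- cutoffs[3]; a4 <- cutoffs[4]
  g12 <- a2 - a1; g34 <- a4 - a3
  f <- function(z) smoothed_hinge(z, eps)
  l <- f((a2 - x) / g12) - f((a1 - x) / g12)
  h <- f((x - a3) / g34) - f((x - a4) / g34)
  m <- f((x - a1) / g12) - f((x - a2) / g12) -
    f((a3 - x) / g34) + f((a4 - x) / g34) - 1
  cbind(low = l, medium = m, high = h)
}

# Derivatives of (l, m, h) with respect to x and the four cutoffs, at given
# eps. Returned as a list of matrices (rows follow x). Used by backprop and
# finite-difference checked in the tests.
membership_grads <- function(x, cutoffs, eps) {
  a1 <- cutoffs[1]; a2 <- cutoffs[2]; a3 <- cutoffs[3]; a4 <- cutoffs[4]
  g12 <- a2 - a1; g34 <- a4 - a3
  fp <- function(z) smoothed_hinge_grad(z, eps)
  # low
  l1 <- fp((a2 - x) / g12); l2 <- fp((a1 - x) / g12)
  dl <- cbind(
    x  = (-l1 + l2) / g12,
    a1 = (l1 - l2) * (a2 - x) / g12^2,
    a2 = (l1 - l2) * (x - a1) / g12^2,
    a3 = 0, a4 = 0
  )
  # high
  h1 <- fp((x - a3) / g34); h2 <- fp((x - a4) / g34)
  dh <- cbind(
    x  = (h1 - h2) / g34,
    a1 = 0, a2 = 0,
    a3 = (h1 - h2) * (x - a4) / g34^2,
    a4 = (h1 - h2) * (a3 - x) / g34^2
  )
  # medium
  m1 <- fp((x - a1) / g12); m2 <- fp((x - a2) / g12)
  m3 <- fp((a3 - x) / g34); m4 <- fp((a4 - x) / g34)
  dm <- cbind(
    x  = (m1 - m2) / g12 + (m3 - m4) / g34,
    a1 = (m1 - m2) * (x - a2) / g12^2,
    a2 = (m1 - m2) * (a1 - x) / g12^2,
    a3 = (-m3 + m4) * (a4 - x) / g34^2,
    a4 = (-m3 + m4) * (x - a3) / g34^2
  )
  list(low = dl, medium = dm, high = dh)
}

#' Parameterized T-norm (fuzzy conjunction)
#'
#' Combines membership degrees conjunctively with the family
#' \deqn{T_\epsilon(x_1,\dots,x_N) =
#'   \Big(\sum_i x_i^{M_i (\epsilon-1)/\epsilon} - N + 1\Big)^{\epsilon/(\epsilon-1)}}
#' where the exponents \eqn{M_i \in [0,1]} weight each input's contribution
#' (an exponent of 0 removes the input). As \eqn{\epsilon \to 1} the operator
#' approaches the product of the inputs; as \eqn{\epsilon \to 0} it
#' approaches their minimum (the tropical limit). Inputs are clamped to
#' \code{[clamp, 1]} before exponentiation so zero-degree inputs cannot
#' produce infinities; with clamped inputs each weighted term is \eqn{\ge 1}
#' so the inner sum is always valid. Computation is carried out in log space
#' so small \code{eps} (exponents of magnitude ~1/eps) cannot overflow.
#'
#' @param values numeric vector of degrees in \eqn{(0, 1]}.
#' @param exponents numeric vector of weights in \eqn{[0, 1]}, recycled if
#'   length 1.
#' @param eps smoothness in (0, 1).
#' @param clamp lower clamp for the inputs (default \code{1e-6}).
#' @return a scalar conjunction degree in \eqn{[0, 1]}.
#' @examples
#' tnorm(c(0.5, 0.5), eps = 0.999)  # ~ 0.25, the product limit
#' tnorm(c(0.5, 0.3), eps = 0.01)   # ~ 0.3, the minimum limit
#' @export
tnorm <- function(values, exponents = 1, eps, clamp = 1e-6) {
  stopifnot(length(values) >= 1L, all(is.finite(values)),
            eps > 0, eps < 1)
  if (length(exponents) == 1L) exponents <- rep(exponents, length(values))
  stopifnot(length(exponents) == length(values),
            all(exponents >= 0), all(exponents <= 1))
  xc <- pmin(pmax(values, clamp), 1)
  c2 <- (eps - 1) / eps                       # <= 0
  lu <- exponents * c2 * log(xc)              # log of each weighted term, >= 0
  L <- max(lu)
  n <- length(values)
  # inner base = sum(exp(lu)) - n + 1, computed as exp(L) * base_scaled
  base_scaled <- sum(exp(lu - L)) - (n - 1) * exp(-L)
  base_scaled <- max(base_scaled, clamp * exp(-L))  # inert floor; base >= 1 by construction
  log_base <- L + log(base_scaled)
  exp((eps / (eps - 1)) * log_base)
}

#' Parameterized T-conorm (fuzzy disjunction)
#'
#' Combines nonnegative rule activations disjunctively with
#' \eqn{Q_\epsilon(v) = (\sum_k v_k^{1/\epsilon})^{\epsilon}}. As
#' \eqn{\epsilon \to 1} it approaches the sum of the inputs; as
#' \eqn{\epsilon \to 0} it approaches their maximum. Permutation invariant
#' and monotone in every input; with a single input it returns that input
#' exactly. Evaluated in log space.
#'
#' @param values numeric vector of nonnegative activations.
#' @param eps smoothness in (0, 1).
#' @return scalar disjunction value \eqn{\ge 0}.
#' @examples
#' tconorm(c(0.5, 0.5), eps = 0.999)      # ~ 1, the additive limit
#' tconorm(c(0.5, 0.2, 0.4), eps = 0.01)  # ~ 0.5, the maximum limit
#' @export
tconorm <- function(values, eps) {
  stopifnot(length(values) >= 1L, all(is.finite(values)), all(values >= 0),
            eps > 0, eps < 1)
  if (length(values) == 1L) return(values)
  if (all(values == 0)) return(0)
  pos <- values[values > 0]
  lv <- log(pos) / eps
  L <- max(lv)
  exp(eps * (L + log(sum(exp(lv - L)))))
}

#' Smoothness (epsilon) annealing state
#'
#' The shared smoothness parameter starts at 0.99 (near the product/sum
#' regime, where gradients flow freely) and decays geometrically by
#' \code{gamma} at every optimizer step towards the tropical min/max regime,
#' floored at \code{eps_min}:
#' \eqn{\epsilon_{t} = \max(\epsilon_{min}, 0.99\,\gamma^{t})}.
#'
#' @param eps initial smoothness (default 0.99).
#' @param eps_min floor (default 0.01).
#' @param gamma per-step decay rate in (0, 1] (default 0.999).
#' @return an object of class \code{smoothness_state}.
#' @export
smoothness_state <- function(eps = 0.99, eps_min = 0.01, gamma = 0.999) {
  stopifnot(eps > 0, eps <= 0.99, eps_min > 0, eps_min <= eps,
            gamma > 0, gamma <= 1)
  structure(list(eps = eps, eps_min = eps_min, gamma = gamma, step = 0L),
            class = "smoothness_state")
}

#' Advance the smoothness schedule by one training step
#'
#' @param state a [smoothness_state()].
#' @return the updated state, with \code{eps' = max(eps_min, eps * gamma)}
#'   and \code{step} incremented.
#' @export
anneal_eps <- function(state) {
  stopifnot(inherits(state, "smoothness_state"))
  state$eps <- max(state$eps_min, state$eps * state$gamma)
  state$step <- state$step + 1L
  state
}
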