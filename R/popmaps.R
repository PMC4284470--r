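#' Single-copy loss probability at division
#'
#' If an irreducible RAF is down to a single copy of each of its `N` member
#' species and a division partitions every molecule independently between
#' the two daughters with probability 1/2 and no loss, the probability that
#' a given daughter inherits none of the N species -- i.e. that the division
#' gives birth to a protocell lacking the irrRAF -- is `alpha = 1 / 2^N`.
#'
#' @param N number of single-copy species (integer >= 1).
#' @return `2^(-N)`.
#' @examples
#' alpha_single_copies(3) # 0.125
#' @export
alpha_single_copies <- function(N) {
  if (length(N) != 1 || is.na(N) || N < 1 || N != round(N)) {
    stop("N must be a single integer >= 1")
  }
  2^(-N)
}

#' Population state for the subpopulation iteration maps
#'
#' Deterministic abundances of the two kinds of protocells: `X` carry only
#' the fast irrRAF, `Y` carry both the fast and the slow one. At each
#' (synchronized) generation every protocell divides; a `Y` division loses
#' the slow irrRAF with probability `alpha`, feeding the `X` subpopulation.
#'
#' @param X,Y non-negative initial abundances.
#' @param alpha per-division loss probability of the slow irrRAF (in
#'   `[0, 1]`), e.g. [alpha_single_copies()].
#' @param beta_X,beta_Y growth-limiting (crowding) coefficients of the
#'   limited map; equal values reproduce the single-beta printed map.
#' @return a list of class `population_state`.
#' @export
population_state <- function(X, Y, alpha, beta_X = 0, beta_Y = beta_X) {
  stopifnot(X >= 0, Y >= 0, alpha >= 0, alpha <= 1,
            beta_X >= 0, beta_Y >= 0)
  structure(list(X = X, Y = Y, alpha = alpha,
                 beta_X = beta_X, beta_Y = beta_Y, t = 0L,
                 clipped = FALSE),
            class = "population_state")
}

#' One step of the population maps
#'
#' `pop_step_linear()` iterates the unlimited (exponential) map
#' \deqn{X_{t+1} = 2 X_t + \alpha Y_t, \quad Y_{t+1} = (2 - \alpha) Y_t}
#' under which the total doubles every generation and the `Y` fraction
#' decays like `((2 - alpha)/2)^t`. `pop_step_limited()` adds
#' logistic-type crowding terms,
#' \deqn{X_{t+1} = 2 X_t + \alpha Y_t - \beta_X (X_t + Y_t) X_t}
#' \deqn{Y_{t+1} = (2 - \alpha) Y_t - \beta_Y (X_t + Y_t) Y_t}
#' with negative outputs clipped to zero (and flagged). With
#' `beta_X = beta_Y` the two-irrRAF fraction still vanishes; if the slow
#' irrRAF confers an advantage against crowding (`beta_Y < beta_X`) the two
#' kinds coexist asymptotically.
#'
#' @param state a [population_state()].
#' @return the advanced state.
#' @export
pop_step_linear <- function(state) {
  stopifnot(inherits(state, "population_state"))
  a <- state$alpha
  X1 <- 2 * state$X + a * state$Y
  Y1 <- (2 - a) * state$Y
  state$X <- X1; state$Y <- Y1; state$t <- state$t + 1L
  state
}

#' @rdname pop_step_linear
#' @export
pop_step_limited <- function(state) {
  stopifnot(inherits(state, "population_state"))
  a <- state$alpha
  tot <- state$X + state$Y
  X1 <- 2 * state$X + a * state$Y - state$beta_X * tot * state$X
  Y1 <- (2 - a) * state$Y - state$beta_Y * tot * state$Y
  if (X1 < 0 || Y1 < 0) state$clipped <- TRUE
  state$X <- max(X1, 0); state$Y <- max(Y1, 0)
  state$t <- state$t + 1L
  state
}

#' Iterate a population map
#'
#' @param map_kind `"linear"` or `"limited"`.
#' @param state0 a [population_state()].
#' @param T number of steps (>= 1).
#' @return an object of class `pop_trajectory`: a tibble with columns `t`,
#'   `X`, `Y`, `y_frac` (= Y / (X + Y)), carrying the asymptotic `Y`
#'   fraction (mean over the final 10% of steps) as attribute
#'   `asymptotic_y_frac`, plus `clipped`.
#' @examples
#' s0 <- population_state(X = 0, Y = 100, alpha = alpha_single_copies(3))
#' traj <- pop_trajectory("linear", s0, T = 50)
#' glance(traj)
#' @export
pop_trajectory <- function(map_kind = c("linear", "limited"), state0,
                           T = 100L) {
  map_kind <- match.arg(map_kind)
  stopifnot(inherits(state0, "population_state"), T >= 1)
  step <- if (map_kind == "linear") pop_step_linear else pop_step_limited
  s <- state0
  X <- Y <- numeric(T + 1)
  X[1] <- s$X; Y[1] <- s$Y
  for (k in seq_len(T)) {
    s <- step(s)
    X[k + 1] <- s$X; Y[k + 1] <- s$Y
  }
  tot <- X + Y
  yf <- ifelse(tot > 0, Y / tot, 0)
  out <- tibble(t = 0:T, X = X, Y = Y, y_frac = yf)
  tail_n <- max(1L, floor((T + 1) / 10))
  structure(
    out,
    asymptotic_y_frac = mean(utils::tail(yf, tail_n)),
    clipped = s$clipped,
    map_kind = map_kind,
    class = c("pop_trajectory", class(out))
  )
}

#' @export
glance.pop_trajectory <- function(x, ...) {
  tibble(
    map_kind = attr(x, "map_kind"),
    steps = max(x$t),
    asymptotic_y_frac = attr(x, "asymptotic_y_frac"),
    clipped = attr(x, "clipped")
  )
}

#' @export
autoplot.pop_trajectory <- function(object, ...) {
  d <- tidyr::pivot_longer(object[, c("t", "X", "Y")],
                           cols = c("X", "Y"),
                           names_to = "subpopulation",
                           values_to = "abundance")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$abundance,
                                  colour = .data$subpopulation)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation",
                  y = "protocell abundance",
                  colour = NULL)
}
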