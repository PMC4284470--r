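#' Divide a protocell into two daughters
#'
#' Triggered when the membrane lipid count has reached the threshold
#' (`C >= theta`). Each daughter receives `theta / 2` lipids. Tracked
#' molecules (free species and catalyst-substrate complexes) are partitioned
#' independently:
#'
#' * `"trinomial_with_loss"` (default): each molecule goes to daughter 1,
#'   daughter 2, or is lost to the environment with probabilities
#'   `(q, q, 1 - 2q)`, where `q = daughter_volume_ratio(theta, delta, rho)`
#'   — the two daughters jointly hold less volume than the mother, so at
#'   equal concentrations about 30% of the material is lost.
#' * `"binomial_no_loss"`: each molecule goes to either daughter with
#'   probability 1/2 (the idealization under which the single-copy loss
#'   probability is `alpha = 1 / 2^N`).
#'
#' Buffered species are re-equilibrated with the bath, not partitioned.
#' Conservation is exact per species: daughter1 + daughter2 + lost equals
#' the mother's count.
#'
#' @param state a [protocell_state()] with `C >= theta`.
#' @param partition_mode `"trinomial_with_loss"` or `"binomial_no_loss"`.
#' @param follow_rule which daughter continues the lineage: `"daughter1"`
#'   (default) or `"random"`.
#' @return a list with `state` (the followed daughter, generation
#'   incremented), `sibling_counts`, `lost_counts` (named numeric vectors).
#' @export
divide_protocell <- function(state,
                             partition_mode = c("trinomial_with_loss",
                                                "binomial_no_loss"),
                             follow_rule = c("daughter1", "random")) {
  stopifnot(inherits(state, "protocell_state"))
  partition_mode <- match.arg(partition_mode)
  follow_rule <- match.arg(follow_rule)
  geom <- state$geometry
  if (state$C < geom$theta) {
    stop("cannot divide: C = ", state$C, " < theta = ", geom$theta)
  }
  q <- if (partition_mode == "trinomial_with_loss") {
    daughter_volume_ratio(geom$theta, geom$delta, geom$rho)
  } else 0.5
  probs <- c(q, q, max(0, 1 - 2 * q))
  x <- state$counts
  d1 <- d2 <- lost <- setNames(numeric(length(x)), names(x))
  for (i in seq_along(x)) {
    n <- x[[i]]
    if (n <= 0) next
    part <- rmultinom(1, n, probs)
    d1[[i]] <- part[1]; d2[[i]] <- part[2]; lost[[i]] <- part[3]
  }
  pick1 <- follow_rule == "daughter1" || runif(1) < 0.5
  keep <- if (pick1) d1 else d2
  sib <- if (pick1) d2 else d1
  new_state <- state
  new_state$C <- geom$theta / 2
  new_state$counts <- keep
  new_state$generation <- state$generation + 1L
  list(state = new_state, sibling_counts = sib, lost_counts = lost)
}
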