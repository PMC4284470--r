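#' Run a protocell lineage across generations
#'
#' Alternates growth (stochastic simulation until the division threshold
#' `C >= theta`) and division (stochastic partitioning of the contents),
#' following one daughter per generation. Emits one generation record per
#' division: the division time `dt` (time from birth to division) and the
#' copy number of every tracked species at the division moment. If a
#' generation fails to divide within its horizon (e.g. no container-coupled
#' species present) the run terminates early with a flag; "no division" and
#' "death by dilution" are outcomes, not errors.
#'
#' @param chem a [chemistry()].
#' @param geometry a [container_geometry()].
#' @param init_counts named vector of initial copy numbers (see
#'   [protocell_state()]).
#' @param n_generations number of divisions to attempt (>= 1).
#' @param mode `"instantaneous"` or `"fick"`.
#' @param partition_mode,follow_rule see [divide_protocell()].
#' @param seed optional integer seed (whole-run reproducibility).
#' @param horizon_per_gen per-generation time horizon.
#' @param max_events_per_gen per-generation event safety cap.
#' @param inject optional novelty injection: a data frame (or list coercible
#'   to one) with columns `species`, `n_copies`, `generation`; each row adds
#'   `n_copies` molecules at the birth of that generation (see
#'   [inject_species()]).
#' @param thin trajectory thinning passed to [simulate_segment()]; the
#'   trajectory of the final generation is kept in the result.
#' @return an object of class `lineage_run`: a list with `generations`
#'   (tibble: generation, birth_time, division_time, dt, n_events,
#'   divided, truncated), `division_counts` (long tibble: generation,
#'   species, count, lost, is_complex), `completed`, `mode`,
#'   `partition_mode`, plus the chemistry and geometry used.
#' @export
run_lineage <- function(chem, geometry, init_counts = integer(),
                        n_generations = 20L,
                        mode = c("instantaneous", "fick"),
                        partition_mode = c("trinomial_with_loss",
                                           "binomial_no_loss"),
                        follow_rule = c("daughter1", "random"),
                        seed = NULL, horizon_per_gen = 1e4,
                        max_events_per_gen = 1e7, inject = NULL,
                        thin = 0L) {
  mode <- match.arg(mode)
  partition_mode <- match.arg(partition_mode)
  follow_rule <- match.arg(follow_rule)
  stopifnot(n_generations >= 1)
  run <- function() {
    state <- protocell_state(chem, geometry, init_counts, mode)
    tracked <- !state$channel_set$species$buffered
    sp_names <- state$channel_set$species$name[tracked]
    is_cplx <- state$channel_set$species$is_complex[tracked]
    gen_rows <- list()
    cnt_rows <- list()
    last_traj <- NULL
    completed <- TRUE
    for (gen in seq_len(n_generations)) {
      if (!is.null(inject)) {
        inj <- as.data.frame(inject)
        for (k in which(inj$generation == gen)) {
          state <- inject_species(state, inj$species[k], inj$n_copies[k])
        }
      }
      birth <- state$t
      res <- simulate_segment(state,
                              horizon = state$t + horizon_per_gen,
                              stop_at_division = TRUE, thin = thin,
                              max_events = max_events_per_gen)
      last_traj <- res$trajectory
      if (!res$divided) {
        gen_rows[[gen]] <- tibble(
          generation = gen, birth_time = birth,
          division_time = NA_real_, dt = NA_real_,
          n_events = res$n_events, divided = FALSE,
          truncated = res$truncated
        )
        completed <- FALSE
        break
      }
      div <- divide_protocell(res$state, partition_mode, follow_rule)
      gen_rows[[gen]] <- tibble(
        generation = gen, birth_time = birth,
        division_time = res$state$t, dt = res$state$t - birth,
        n_events = res$n_events, divided = TRUE,
        truncated = res$truncated
      )
      cnt_rows[[gen]] <- tibble(
        generation = gen,
        species = sp_names,
        count = unname(res$state$counts[tracked]),
        lost = unname(div$lost_counts[tracked]),
        is_complex = is_cplx
      )
      state <- div$state
    }
    structure(
      list(
        generations = dplyr::bind_rows(gen_rows),
        division_counts = dplyr::bind_rows(cnt_rows),
        completed = completed,
        mode = mode, partition_mode = partition_mode,
        chem = chem, geometry = geometry,
        final_state = state, last_trajectory = last_traj
      ),
      class = "lineage_run"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.lineage_run <- function(x, ...) {
  nd <- sum(x$generations$divided)
  cat("<lineage_run>\n")
  cat(sprintf("  %d division(s) over %d attempted generation(s); mode = %s%s\n",
              nd, nrow(x$generations), x$mode,
              if (x$completed) "" else " [terminated early: no division]"))
  if (nd > 0) {
    cat(sprintf("  division time dt: first = %.4g, last = %.4g\n",
                x$generations$dt[1], x$generations$dt[nd]))
  }
  invisible(x)
}

#' Synchronization diagnostics of a lineage
#'
#' Examines the division-time series `dt_n` and the per-species division-time
#' copy numbers. The lineage is `converged` when the relative change
#' `|dt_n - dt_(n-1)| / dt_n` stays below `tol` over the last `window`
#' generations: the replication of the internal species and the growth of
#' the container then proceed at the same pace. Each species is classified
#' from the log-slope of its division-time counts over the later half of the
#' run: `"synchronized"` (stationary positive level), `"diluting"`
#' (systematic decay), `"growing"`, `"extinct"` (count zero by the last
#' division), or `"absent"` (never present).
#'
#' @param run a [run_lineage()] result with at least 3 divisions.
#' @param tol relative-change tolerance for convergence.
#' @param window number of trailing generations for the convergence check.
#' @param slope_tol per-generation log-slope below which a species counts as
#'   stationary.
#' @return a list of class `sync_report`: `dt` (tibble: generation, dt,
#'   rel_change), `converged`, `species` (tibble: species, class, final
#'   count, log-slope).
#' @export
synchronization_report <- function(run, tol = 0.05, window = 5L,
                                   slope_tol = 0.05) {
  stopifnot(inherits(run, "lineage_run"))
  gens <- run$generations[run$generations$divided, ]
  if (nrow(gens) < 3) stop("need at least 3 completed divisions")
  dt <- gens$dt
  rel <- c(NA, abs(diff(dt)) / dt[-1])
  w <- min(window, nrow(gens) - 1)
  converged <- all(rel[(nrow(gens) - w + 1):nrow(gens)] < tol)
  cnts <- run$division_counts[!run$division_counts$is_complex, ]
  species <- dplyr::group_by(cnts, .data$species)
  species <- dplyr::summarise(
    species,
    final_count = .data$count[which.max(.data$generation)],
    ever_present = any(.data$count > 0),
    slope = log_slope(.data$generation, .data$count),
    .groups = "drop"
  )
  species$class <- dplyr::case_when(
    !species$ever_present ~ "absent",
    species$final_count == 0 ~ "extinct",
    species$slope < -slope_tol ~ "diluting",
    species$slope > slope_tol ~ "growing",
    TRUE ~ "synchronized"
  )
  structure(
    list(dt = tibble(generation = gens$generation, dt = dt,
                     rel_change = rel),
         converged = converged,
         species = species[, c("species", "class", "final_count", "slope")]),
    class = "sync_report"
  )
}

# log-linear slope of count-at-division over the later half of the run
log_slope <- function(generation, count) {
  ord <- order(generation)
  generation <- generation[ord]; count <- count[ord]
  half <- generation >= stats::median(generation)
  g <- generation[half]; y <- log(count[half] + 1)
  if (length(unique(g)) < 2) return(0)
  unname(stats::coef(stats::lm(y ~ g))[2])
}

#' @export
print.sync_report <- function(x, ...) {
  cat("<sync_report>\n")
  cat(sprintf("  converged: %s; last dt = %.4g\n", x$converged,
              utils::tail(x$dt$dt, 1)))
  print(table(x$species$class))
  invisible(x)
}

#' Per-generation division-time counts of one species
#'
#' Series suitable for dilution plots: the copy number of `species` at each
#' division. Extinct species show trailing zeros. Buffered species carry no
#' tracked count; they are returned with `buffered = TRUE` and their
#' constant concentration.
#'
#' @param run a [run_lineage()] result.
#' @param species species sequence.
#' @return tibble with columns `generation`, `count`, `buffered`.
#' @export
dilution_curve <- function(run, species) {
  stopifnot(inherits(run, "lineage_run"))
  cs <- run$final_state$channel_set
  i <- match(species, cs$species$name)
  if (is.na(i)) stop("unknown species: ", species)
  if (cs$species$buffered[i]) {
    gens <- run$generations$generation[run$generations$divided]
    return(tibble(generation = gens,
                  count = cs$species$ext_conc[i] *
                    internal_volume(run$geometry$theta, run$geometry$delta,
                                    run$geometry$rho),
                  buffered = TRUE))
  }
  sel <- run$division_counts[run$division_counts$species == species, ]
  tibble(generation = sel$generation, count = sel$count, buffered = FALSE)
}

#' @export
tidy.lineage_run <- function(x, ...) {
  dplyr::left_join(
    x$division_counts,
    x$generations[, c("generation", "dt", "division_time")],
    by = "generation"
  )
}

#' @export
glance.lineage_run <- function(x, ...) {
  gens <- x$generations[x$generations$divided, ]
  nd <- nrow(gens)
  conv <- if (nd >= 3) synchronization_report(x)$converged else NA
  tibble(
    n_generations = nrow(x$generations),
    n_divisions = nd,
    completed = x$completed,
    converged = conv,
    dt_last = if (nd > 0) gens$dt[nd] else NA_real_,
    dt_mean_last5 = if (nd > 0) mean(utils::tail(gens$dt, 5)) else NA_real_
  )
}

#' @export
autoplot.lineage_run <- function(object, log_counts = TRUE,
                                 include_complexes = FALSE, ...) {
  d <- object$division_counts
  if (!include_complexes) d <- d[!d$is_complex, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$generation,
                                       y = .data$count,
                                       colour = .data$species)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "generation", y = "copies at division",
                  colour = "species")
  if (log_counts) p <- p + ggplot2::scale_y_continuous(trans = "log1p")
  p
}

#' Total monomer content of a set of counts
#'
#' Number of monomers held in the given molecules; complexes `A:C` count the
#' monomers of both partners. Used in conservation checks: the monomer total
#' changes only through transport channels, buffered reactants/products and
#' division losses.
#'
#' @param counts named numeric vector (names are species or complex names).
#' @return total monomer count.
#' @export
monomer_content <- function(counts) {
  sum(counts * nchar(gsub(":", "", names(counts))))
}
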