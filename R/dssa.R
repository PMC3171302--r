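#' Create a simulation state
#'
#' Holds the clock, molecule counts and the waitlist of pending delayed
#' products. Mostly useful with the single-step functions
#' [compute_propensities()] and [step_dssa()]; whole runs go through
#' [run_dssa()].
#'
#' @param counts Named nonnegative integer vector of molecule counts.
#' @param t Simulation time in seconds.
#' @return An object of class `sim_state` with fields `t`, `counts` and
#'   `waitlist` (a data frame with columns `release_time`, `species`,
#'   `count`, ordered by insertion).
#' @export
sim_state <- function(counts, t = 0) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(list(t = t,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 waitlist = data.frame(release_time = numeric(), species = character(),
                                       count = integer(), stringsAsFactors = FALSE)),
            class = "sim_state")
}

#' Reaction propensities of a state
#'
#' The propensity of channel j is its stochastic rate constant times the
#' number of distinct reactant combinations, computed as the product over
#' reactant species of the falling factorial of the current count over the
#' stoichiometry. A channel whose reactant counts fall short of its
#' stoichiometry has propensity zero.
#'
#' @param state A [sim_state()].
#' @param reactions List of [reaction()] objects.
#' @return Numeric vector of nonnegative propensities, one per reaction.
#' @examples
#' st <- sim_state(c(RNA = 7))
#' deg <- reaction(c(RNA = 1), rate = 1 / 600)
#' compute_propensities(st, list(deg)) # 7/600
#' @export
compute_propensities <- function(state, reactions) {
  if (any(state$counts < 0)) stop("invalid state: negative count")
  vapply(reactions, function(r) {
    h <- 1
    for (sp in names(r$reactants)) {
      n <- if (sp %in% names(state$counts)) state$counts[[sp]] else 0L
      m <- r$reactants[[sp]]
      if (n < m) return(0)
      h <- h * prod(n - seq_len(m) + 1)
    }
    r$rate * h
  }, numeric(1))
}

#' Draw the waiting time and identity of the next reaction
#'
#' Standard SSA draw: the waiting time is exponential with rate equal to the
#' propensity sum, and the channel is chosen with probability proportional to
#' its propensity. Consumes exactly two random numbers from the session RNG.
#'
#' @param propensities Nonnegative numeric vector with at least one positive
#'   entry.
#' @return List with `dt` (seconds) and `j` (1-based channel index), or
#'   `NULL` when all propensities are zero (the caller must consult the
#'   waitlist or stop).
#' @export
draw_next_event <- function(propensities) {
  a0 <- sum(propensities)
  if (a0 <= 0) return(NULL)
  dt <- stats::rexp(1, rate = a0)
  u <- stats::runif(1)
  j <- findInterval(u * a0, cumsum(propensities), left.open = TRUE) + 1L
  j <- min(j, length(propensities))
  list(dt = dt, j = j)
}

draw_one_delay <- function(spec) {
  if (spec$kind == "constant" || spec$sd <= 0) return(spec$mean)
  repeat {
    d <- stats::rnorm(1, spec$mean, spec$sd)
    if (d >= 0) return(d)
  }
}

#' Advance a delayed-SSA state by one event
#'
#' Implements the race between the next SSA reaction and the earliest
#' waitlist release: a reaction drawn to occur at `t + dt` executes if the
#' waitlist is empty or `t + dt` does not exceed the least release time
#' (ties go to the reaction); otherwise the clock jumps to the earliest
#' release, that entry's molecules are added, and the drawn reaction is
#' discarded. Executing a reaction consumes its reactants, adds its
#' instantaneous products, and pushes each delayed product onto the waitlist
#' at `t + dt + delay`.
#'
#' This is a pure-R reference stepper; [run_dssa()] runs the same algorithm
#' (with an identical RNG call sequence) in compiled code.
#'
#' @param state A [sim_state()].
#' @param reactions List of [reaction()] objects.
#' @return The updated state, with attribute `"event"` describing what
#'   happened (`"reaction"`, `"release"` or `"halt"`).
#' @export
step_dssa <- function(state, reactions) {
  a <- compute_propensities(state, reactions)
  draw <- draw_next_event(a)
  t_react <- if (is.null(draw)) Inf else state$t + draw$dt
  t_min <- if (nrow(state$waitlist)) min(state$waitlist$release_time) else Inf

  if (!is.null(draw) && t_react <= t_min) {
    r <- reactions[[draw$j]]
    state$t <- t_react
    for (sp in names(r$reactants))
      state$counts[[sp]] <- state$counts[[sp]] - r$reactants[[sp]]
    for (sp in names(r$products))
      state$counts[[sp]] <- state$counts[[sp]] + r$products[[sp]]
    for (d in r$delayed) {
      state$waitlist <- rbind(state$waitlist,
                              data.frame(release_time = state$t + draw_one_delay(d$delay),
                                         species = d$species, count = as.integer(d$count),
                                         stringsAsFactors = FALSE))
    }
    if (any(state$counts < 0)) stop("invalid state: negative count after reaction")
    attr(state, "event") <- "reaction"
    attr(state, "reaction") <- draw$j
  } else if (is.finite(t_min)) {
    # earliest release wins; equal release times release in insertion order
    k <- which(state$waitlist$release_time == t_min)[1]
    e <- state$waitlist[k, ]
    state$waitlist <- state$waitlist[-k, , drop = FALSE]
    state$t <- e$release_time
    state$counts[[e$species]] <- state$counts[[e$species]] + e$count
    attr(state, "event") <- "release"
  } else {
    attr(state, "event") <- "halt"
  }
  state
}

#' Run a delayed stochastic simulation
#'
#' Repeats the reaction/waitlist-release race of [step_dssa()] from time 0
#' until the next event would fall beyond `t_end`; pending waitlist entries
#' past `t_end` are never applied. The computation runs in compiled code.
#'
#' @param system A [reaction_system()].
#' @param t_end End of the simulated interval, seconds (> 0).
#' @param record If `TRUE` (default) the full event log is kept and returned.
#' @param sample_times Optional increasing numeric vector of times at which
#'   to record the counts in effect (the state after all events with event
#'   time at or before the sample time); useful for long runs where the
#'   event log would be large.
#' @return An object of class `dssa_trajectory`: a list with `time`, `event`
#'   (0 = waitlist release, j >= 1 = reaction index), a `counts` snapshot
#'   matrix (one row per event, one column per species), `initial_counts`,
#'   `final_counts`, `t_end`, and — when `sample_times` was given — a
#'   `samples` matrix (one row per sample time).
#' @examples
#' sys <- reaction_system(list(reaction(c(RNA = 1), rate = 0.1)), c(RNA = 5))
#' set.seed(1)
#' tr <- run_dssa(sys, t_end = 1e6)
#' nrow(tr$counts) # 5 degradation events
#' @export
run_dssa <- function(system, t_end, record = TRUE, sample_times = NULL) {
  stopifnot(inherits(system, "reaction_system"), t_end > 0)
  st <- if (is.null(sample_times)) numeric(0) else as.numeric(sample_times)
  if (length(st) && (is.unsorted(st) || any(st < 0)))
    stop("sample_times must be nonnegative and increasing")
  if (length(st) && max(st) > t_end)
    stop("sample_times must not exceed t_end")
  raw <- dssa_run_cpp(compile_system(system), unname(system$initial_counts),
                      t_end, record, st)
  out <- list(initial_counts = system$initial_counts,
              species = system$species,
              t_end = t_end,
              final_counts = stats::setNames(raw$final_counts, system$species))
  if (record) {
    colnames(raw$counts) <- system$species
    out$time <- raw$time
    out$event <- raw$event
    out$counts <- raw$counts
  }
  if (length(st)) {
    colnames(raw$samples) <- system$species
    out$samples <- raw$samples
    out$sample_times <- st
  }
  structure(out, class = "dssa_trajectory")
}

#' @export
print.dssa_trajectory <- function(x, ...) {
  cat(sprintf("<dssa_trajectory: %d species, t_end = %g s%s>\n",
              length(x$species), x$t_end,
              if (!is.null(x$time)) sprintf(", %d events", length(x$time)) else ""))
  invisible(x)
}

#' Counts in effect at given times
#'
#' Replays the event log: the count reported at time `s` is the state after
#' all events with event time at or before `s` (a right-continuous step
#' function evaluated at `s`).
#'
#' @param trajectory A recorded [run_dssa()] trajectory.
#' @param times Numeric vector of query times within `[0, t_end]`.
#' @param species Species name(s); defaults to all.
#' @return Integer matrix, one row per query time, one column per species.
#' @export
counts_at <- function(trajectory, times, species = trajectory$species) {
  if (is.null(trajectory$counts)) stop("trajectory was run without event recording")
  if (any(times < 0) || any(times > trajectory$t_end))
    stop("query times outside the simulated interval")
  idx <- findInterval(times, trajectory$time) # events at time <= s included
  full <- rbind(trajectory$initial_counts, trajectory$counts)
  out <- full[idx + 1L, species, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a trajectory event log as a long-format data frame / CSV
#'
#' One row per (event, species) pair with the count after the event;
#' columns `time_s`, `species`, `count`.
#'
#' @param trajectory A recorded [run_dssa()] trajectory.
#' @param path Optional file path; when given, a CSV is written.
#' @return The data frame, invisibly when `path` is given.
#' @export
trajectory_to_csv <- function(trajectory, path = NULL) {
  if (is.null(trajectory$counts)) stop("trajectory was run without event recording")
  n_sp <- length(trajectory$species)
  df <- data.frame(time_s = rep(trajectory$time, each = n_sp),
                   species = rep(trajectory$species, times = length(trajectory$time)),
                   count = as.vector(t(trajectory$counts)),
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
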