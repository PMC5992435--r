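#' Initialize a model population
#'
#' Creates the tick-0 state: `breed_counts[b]` agents per breed (built in
#' canonical breed order), each with its breed's initial 8 primary traits and
#' `k` secondary traits drawn uniformly without replacement from the
#' secondary value range, excluding any value already in the agent's primary
#' list (the Deviant primary list contains 22, the first secondary value, so
#' the exclusion is not vacuous). Breed cultures are set to the initial
#' primary trait sets and frozen as the `initial_cultures` reference that the
#' cultural-change metric compares against.
#'
#' Consumes the current RNG stream; [run_single()] seeds it with
#' `config$seed` first. Call `set.seed()` yourself when using this directly.
#'
#' @param config A [sim_config()].
#' @return A `margin_state` list: `traits` (`n_agents` x `n_traits` integer
#'   matrix, columns 1..8 primary slots, 9..`n_traits` secondary slots),
#'   `breed` (integer 1..4 in canonical order), `interactions`, `generation`,
#'   `id`, `next_id`, `cultures` and `initial_cultures` (4 x 8 integer
#'   matrices, rows in canonical breed order, values sorted ascending),
#'   `tick`, `config`.
#' @examples
#' set.seed(1)
#' st <- init_population(sim_config())
#' table(breed_levels()[st$breed])
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_agents
  L <- config$n_traits
  traits <- matrix(NA_integer_, nrow = n, ncol = L)
  breed <- integer(n)
  s_lo <- config$secondary_value_range[1]
  s_hi <- config$secondary_value_range[2]

  row <- 0L
  for (b in seq_along(breed_levels())) {
    prim <- config$primary_traits[[b]]
    for (a in seq_len(config$breed_counts[b])) {
      row <- row + 1L
      breed[row] <- b
      traits[row, 1:8] <- prim
      for (s in seq_len(config$k)) {
        traits[row, 8L + s] <- draw_excluding(s_lo, s_hi,
                                              traits[row, seq_len(8L + s - 1L)])
      }
    }
  }

  cultures <- t(vapply(config$primary_traits, function(p) sort(p),
                       integer(8)))
  rownames(cultures) <- breed_levels()

  structure(list(
    traits = traits,
    breed = breed,
    interactions = integer(n),
    generation = integer(n),
    id = seq_len(n) - 1L,
    next_id = n,
    cultures = cultures,
    initial_cultures = cultures,
    tick = 0L,
    config = config
  ), class = "margin_state")
}

#' @export
print.margin_state <- function(x, ...) {
  cat(sprintf("Model state at tick %d: %d agents (%s)\n", x$tick,
              length(x$breed),
              paste(sprintf("%s %d", breed_levels(),
                            tabulate(x$breed, 4L)), collapse = ", ")))
  cat(sprintf("  RTC %s, Diversity %s, %d traits per agent\n",
              x$config$rtc_level, x$config$diversity_level, x$config$n_traits))
  invisible(x)
}

# invariant checks used by tests and by advance_tick in verbose contexts
validate_state <- function(state) {
  stopifnot(inherits(state, "margin_state"))
  n <- state$config$n_agents
  L <- state$config$n_traits
  if (nrow(state$traits) != n || ncol(state$traits) != L) {
    stop("trait matrix has wrong shape")
  }
  if (state$config$list_semantics == "set" &&
      any(apply(state$traits, 1L, anyDuplicated) > 0L)) {
    stop("an agent holds a duplicated trait value under set semantics")
  }
  if (any(state$traits < 0L) || any(state$traits > 50L)) {
    stop("trait values must lie in 0..50")
  }
  if (any(state$interactions >= state$config$lifespan)) {
    stop("an agent at or beyond its lifespan was not replaced")
  }
  if (!all(state$breed %in% 1:4)) stop("invalid breed code")
  if (ncol(state$cultures) != 8L) stop("cultures must hold 8 traits")
  invisible(TRUE)
}
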