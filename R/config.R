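#' Configure a single simulation run
#'
#' Assembles and validates everything one run needs: the RTC and Diversity
#' conditions, population composition, lifespan, tick budget and seed. All
#' model constants come from the `defaults` list and can be overridden there
#' (see [model_defaults()]).
#'
#' By default a run lasts `ceiling(generations * lifespan)` ticks — 2,500
#' ticks for the standard lifespan of 1,000 interactions, i.e. 2.5
#' generations, ending once generation 2 has had on average 500 interactions.
#'
#' @param rtc_level,diversity_level `"Low"`, `"Moderate"` or `"High"`.
#' @param n_agents Total population size (constant over a run).
#' @param breed_counts Named integer vector of initial agents per breed, in
#'   any order; must sum to `n_agents` with every count >= 1. When `NULL`,
#'   the default composition is scaled to `n_agents` with
#'   [default_breed_counts()].
#' @param lifespan Interactions per agent life; an agent reaching it is
#'   replaced at the end of that tick.
#' @param n_ticks Tick budget; defaults to `ceiling(generations * lifespan)`.
#' @param seed Integer RNG seed; the single master seed for the run.
#' @param list_semantics `"multiset"` (default) or `"set"`. Under the
#'   default multiset semantics agent trait lists behave like the source
#'   platform's lists: adoption copies any partner slot so duplicate values
#'   can accumulate, rebirth draws values without exclusion, and breed
#'   switching counts trait occurrences appearing in a culture (more than
#'   seven qualifies). Under `"set"` semantics lists stay duplicate-free:
#'   adoption only copies traits the adopter lacks, rebirth excludes held
#'   values, and switching requires a culture's full eight distinct values.
#'   The multiset reading reproduces the reported ordinal findings; the set
#'   reading is a cleaner normalization with slower cross-breed dynamics
#'   (see the methods vignette).
#' @param defaults Model constants, see [model_defaults()].
#' @return A `sim_config` list with the validated fields plus the resolved
#'   `rtc` matrix, the secondary-trait count `k`, the per-agent list length
#'   `n_traits = 8 + k`, and the trait value ranges.
#' @examples
#' cfg <- sim_config("High", "Low", seed = 42)
#' cfg$n_ticks
#' @export
sim_config <- function(rtc_level = "Low",
                       diversity_level = "Low",
                       n_agents = 200L,
                       breed_counts = NULL,
                       lifespan = NULL,
                       n_ticks = NULL,
                       seed = 1L,
                       list_semantics = c("multiset", "set"),
                       defaults = model_defaults()) {
  list_semantics <- match.arg(list_semantics)
  rtc_level <- match_level(rtc_level, "RTC level")
  diversity_level <- match_level(diversity_level, "Diversity level")
  if (is.null(breed_counts)) {
    breed_counts <- default_breed_counts(n_agents, defaults)
  }
  if (is.null(names(breed_counts)) ||
      !setequal(names(breed_counts), breed_levels())) {
    stop("breed_counts must be named with all four breeds")
  }
  breed_counts <- as.integer(breed_counts[breed_levels()])
  names(breed_counts) <- breed_levels()
  n_agents <- as.integer(n_agents)
  if (any(breed_counts < 1L)) stop("every breed count must be >= 1")
  if (sum(breed_counts) != n_agents) {
    stop(sprintf("breed_counts sum to %d but n_agents is %d",
                 sum(breed_counts), n_agents))
  }
  if (is.null(lifespan)) lifespan <- defaults$lifespan
  lifespan <- as.integer(lifespan)
  if (lifespan < 1L) stop("lifespan must be >= 1")
  if (is.null(n_ticks)) n_ticks <- as.integer(ceiling(defaults$generations * lifespan))
  n_ticks <- as.integer(n_ticks)
  if (n_ticks < 0L) stop("n_ticks must be >= 0")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")

  k <- secondary_count(diversity_level, defaults)
  p_range <- as.integer(defaults$primary_value_range)
  s_range <- as.integer(defaults$secondary_value_range)
  if (length(p_range) != 2L || length(s_range) != 2L ||
      p_range[1] > p_range[2] || s_range[1] > s_range[2]) {
    stop("trait value ranges must be inclusive [lo, hi] pairs")
  }
  primary <- lapply(defaults$primary_traits[breed_levels()], as.integer)
  if (any(vapply(primary, length, 1L) != 8L)) {
    stop("each breed needs exactly 8 initial primary traits")
  }
  if (any(vapply(primary, anyDuplicated, 1L) > 0L)) {
    stop("initial primary traits must be duplicate-free within a breed")
  }
  # k distinct secondary draws must be available after excluding collisions
  # with an agent's primary list
  n_secondary_values <- s_range[2] - s_range[1] + 1L
  max_collide <- max(vapply(primary, function(p)
    sum(p >= s_range[1] & p <= s_range[2]), 1L))
  if (n_secondary_values - max_collide < k) {
    stop("secondary value range too small for ", k, " distinct draws")
  }

  structure(list(
    rtc_level = rtc_level,
    diversity_level = diversity_level,
    n_agents = n_agents,
    breed_counts = breed_counts,
    lifespan = lifespan,
    n_ticks = n_ticks,
    seed = seed,
    k = k,
    n_traits = 8L + k,
    primary_value_range = p_range,
    secondary_value_range = s_range,
    primary_traits = primary,
    list_semantics = list_semantics,
    rtc = rtc_matrix(rtc_level, defaults)
  ), class = "sim_config")
}

#' Scale the default population composition to a given size
#'
#' Allocates `n_agents` over the four breeds proportionally to the default
#' composition (60/35/4/1 percent) by largest remainder, keeping every breed
#' at one agent or more. With the standard 200 agents this returns the
#' published 120/70/8/2.
#'
#' @param n_agents Total population size (>= 4).
#' @param defaults Model constants, see [model_defaults()].
#' @return Named integer vector over the four breeds summing to `n_agents`.
#' @export
default_breed_counts <- function(n_agents, defaults = model_defaults()) {
  n_agents <- as.integer(n_agents)
  if (is.na(n_agents) || n_agents < 4L) {
    stop("need at least 4 agents (one per breed)")
  }
  base <- unlist(defaults$initial_counts)[breed_levels()]
  target <- n_agents * base / sum(base)
  cnt <- pmax(1L, as.integer(floor(target)))
  while (sum(cnt) < n_agents) {
    i <- which.max(target - cnt)
    cnt[i] <- cnt[i] + 1L
  }
  while (sum(cnt) > n_agents) {
    ok <- which(cnt > 1L)
    i <- ok[which.min((target - cnt)[ok])]
    cnt[i] <- cnt[i] - 1L
  }
  setNames(as.integer(cnt), breed_levels())
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  RTC %s, Diversity %s (%d secondary traits, %d total)\n",
              x$rtc_level, x$diversity_level, x$k, x$n_traits))
  cat(sprintf("  %d agents (%s)\n", x$n_agents,
              paste(sprintf("%s %d", names(x$breed_counts), x$breed_counts),
                    collapse = ", ")))
  cat(sprintf("  lifespan %d interactions, %d ticks, seed %d, %s lists\n",
              x$lifespan, x$n_ticks, x$seed, x$list_semantics))
  invisible(x)
}
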