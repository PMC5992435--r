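# shared builders for toy populations and crafted states

# a small but fully valid config (all four breeds present)
toy_config <- function(n_agents = 5L,
                       breed_counts = c(QuietMaverick = 1L, Conformist = 2L,
                                        Deviant = 1L, Rebel = 1L),
                       rtc_level = "Low", diversity_level = "Low",
                       lifespan = 100L, n_ticks = 10L, seed = 1L, ...) {
  sim_config(rtc_level = rtc_level, diversity_level = diversity_level,
             n_agents = n_agents, breed_counts = breed_counts,
             lifespan = lifespan, n_ticks = n_ticks, seed = seed, ...)
}

# assemble a margin_state around hand-built trait lists (bypasses
# init_population so tests can pin exact scenarios)
toy_state <- function(traits, breed, config, cultures = NULL) {
  if (!is.matrix(traits)) {
    traits <- matrix(traits, nrow = length(breed), byrow = TRUE)
  }
  mode(traits) <- "integer"
  stopifnot(ncol(traits) == config$n_traits)
  if (is.null(cultures)) {
    cultures <- t(vapply(config$primary_traits, sort, integer(8)))
  }
  rownames(cultures) <- breed_levels()
  n <- length(breed)
  structure(list(traits = traits, breed = as.integer(breed),
                 interactions = integer(n), generation = integer(n),
                 id = seq_len(n) - 1L, next_id = n, cultures = cultures,
                 initial_cultures = cultures, tick = 0L, config = config),
            class = "margin_state")
}

# defaults with every cross-breed adoption probability zeroed (frozen
# dynamics); same-breed adoption is disabled directly on the config because
# rtc_matrix() enforces the unit diagonal
frozen_config <- function(...) {
  cfg <- toy_config(...)
  cfg$rtc[] <- 0
  cfg
}

# Table 6 initial primary traits, for hand-checks
table6 <- list(
  Conformist    = c(1L, 2L, 3L, 4L, 5L, 16L, 19L, 20L),
  QuietMaverick = c(1L, 2L, 3L, 7L, 10L, 13L, 17L, 18L),
  Rebel         = c(4L, 15L, 7L, 8L, 9L, 14L, 17L, 18L),
  Deviant       = c(6L, 8L, 9L, 11L, 12L, 13L, 21L, 22L)
)
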