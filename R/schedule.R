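# Pure-R reference implementation of the tick schedule. Each operation is
# written as a literal enumeration of its rule; the compiled engine in
# src/engine.cpp re-implements the same schedule for speed and the two are
# held bit-identical by tests (shared RNG draw contract, see R/rng.R).

#' Choose an interaction partner for an agent
#'
#' Draws one trait value `v` uniformly from the initiator's combined trait
#' list, then chooses uniformly among all other agents whose list contains
#' `v`. Partner choice is purely trait-based (homophily); there is no spatial
#' or network structure.
#'
#' @param state A `margin_state`.
#' @param initiator Row index (1-based) of the initiating agent.
#' @return The partner's row index, or `NA_integer_` if no other agent holds
#'   the drawn trait (no draw is consumed for the partner in that case).
#' @export
choose_partner <- function(state, initiator) {
  L <- state$config$n_traits
  v <- state$traits[initiator, draw_int(L) + 1L]
  holds <- which(rowSums(state$traits == v) > 0L)
  candidates <- holds[holds != initiator]
  if (length(candidates) == 0L) return(NA_integer_)
  candidates[draw_int(length(candidates)) + 1L]
}

#' Attempt trait adoption from a partner
#'
#' Draws a uniform deviate `r`; adoption happens when `r` is below the RTC
#' probability for the partner's breed influencing the initiator's breed. On
#' success one slot of the initiator's list (uniform over all slots) is
#' overwritten by a trait of the partner:
#' \itemize{
#'   \item multiset semantics (default): a uniformly chosen partner slot —
#'     the gained value may already be held, so duplicates can accumulate;
#'   \item set semantics: a uniform choice among the partner's traits the
#'     initiator does not already hold (ascending value order); a no-op with
#'     `adopted = FALSE` when the partner offers nothing new.
#' }
#' After a successful adoption initiator and partner share at least the
#' gained trait.
#'
#' @param state A `margin_state`.
#' @param initiator,partner Distinct agent row indices.
#' @return `list(state = updated state, adopted = flag, slot = replaced slot
#'   or NA, trait = gained trait or NA)`.
#' @export
attempt_adoption <- function(state, initiator, partner) {
  stopifnot(initiator != partner)
  p <- state$config$rtc[state$breed[partner], state$breed[initiator]]
  r <- stats::runif(1L)
  if (r >= p) {
    return(list(state = state, adopted = FALSE, slot = NA_integer_,
                trait = NA_integer_))
  }
  L <- state$config$n_traits
  if (state$config$list_semantics == "multiset") {
    slot <- draw_int(L) + 1L
    gained <- state$traits[partner, draw_int(L) + 1L]
  } else {
    novel <- sort(setdiff(state$traits[partner, ], state$traits[initiator, ]))
    if (length(novel) == 0L) {
      return(list(state = state, adopted = FALSE, slot = NA_integer_,
                  trait = NA_integer_))
    }
    slot <- draw_int(L) + 1L
    gained <- novel[draw_int(length(novel)) + 1L]
  }
  state$traits[initiator, slot] <- gained
  list(state = state, adopted = TRUE, slot = slot, trait = gained)
}

#' Recompile a breed's culture from its members
#'
#' Pools every member's combined trait list, tallies value frequencies and
#' returns the eight most frequent values. A tie at the eighth rank is broken
#' uniformly at random among the tied values. With no members the previous
#' culture is returned unchanged (so an extinct breed can still be compared
#' against and repopulated). Should the pool hold fewer than eight distinct
#' values, the previous culture's values pad the set, highest pooled
#' frequency first.
#'
#' @param members_traits Integer matrix of the members' trait lists (0 rows
#'   when the breed has no members).
#' @param previous The breed's previous 8-trait culture.
#' @return Sorted integer vector of 8 trait values.
#' @export
recompute_culture <- function(members_traits, previous) {
  stopifnot(length(previous) == 8L)
  if (is.null(dim(members_traits))) {
    members_traits <- if (length(members_traits) == 0L) {
      matrix(integer(0), nrow = 0L)
    } else {
      matrix(as.integer(members_traits), nrow = 1L)
    }
  }
  if (nrow(members_traits) == 0L) return(sort(as.integer(previous)))
  counts <- tabulate(as.integer(members_traits) + 1L, nbins = 51L)
  present <- which(counts > 0L) - 1L            # trait values 0..50
  if (length(present) <= 8L) {
    chosen <- present
    pad <- setdiff(as.integer(previous), chosen)
    pad <- pad[order(-counts[pad + 1L], match(pad, previous))]
    chosen <- c(chosen, pad[seq_len(8L - length(chosen))])
    return(sort(as.integer(chosen)))
  }
  cnt <- counts[present + 1L]
  thr <- sort(cnt, decreasing = TRUE)[8L]       # frequency of the 8th rank
  sure <- present[cnt > thr]
  tied <- sort(present[cnt == thr])
  need <- 8L - length(sure)
  if (length(tied) > need) {
    # partial Fisher-Yates over the tied values: `need` draws
    m <- length(tied)
    for (i in seq_len(need)) {
      j <- (i - 1L) + draw_int(m - i + 1L)
      tmp <- tied[i]
      tied[i] <- tied[j + 1L]
      tied[j + 1L] <- tmp
    }
    tied <- tied[seq_len(need)]
  }
  sort(as.integer(c(sure, tied)))
}

#' Determine an agent's breed from the current cultures
#'
#' Under multiset semantics an agent qualifies for any breed in whose culture
#' more than seven of the agent's trait occurrences show up (duplicates
#' count); under set semantics it must hold a culture's full eight distinct
#' values. With several qualifying breeds one is chosen by a uniform coin
#' flip (breeds considered in canonical order); with none the agent keeps its
#' current breed.
#'
#' @param state A `margin_state` (its `cultures` are the freshly recompiled
#'   ones when called inside a tick).
#' @param agent Agent row index.
#' @return Integer breed code 1..4.
#' @export
reassign_breed <- function(state, agent) {
  traits <- state$traits[agent, ]
  qualifies <- if (state$config$list_semantics == "multiset") {
    function(b) sum(traits %in% state$cultures[b, ]) > 7L
  } else {
    function(b) all(state$cultures[b, ] %in% traits)
  }
  matches <- which(vapply(1:4, qualifies, logical(1)))
  if (length(matches) == 0L) return(state$breed[agent])
  if (length(matches) == 1L) return(matches)
  matches[draw_int(length(matches)) + 1L]
}

#' Replace a dead agent by its offspring
#'
#' The offspring keeps the parent's (current) breed, has generation
#' `parent + 1`, a fresh id, and zero interactions. It inherits `n` traits,
#' `n` drawn uniformly from 0..8, chosen uniformly without replacement from
#' the parent's slots; these fill the first primary slots. Remaining primary
#' slots are filled with uniform draws from the primary value range and
#' secondary slots from the secondary value range — excluding values the
#' offspring already holds under set semantics, unconstrained under multiset
#' semantics.
#'
#' @param state A `margin_state`.
#' @param agent Row index of the agent to replace (in place).
#' @return The updated `margin_state`.
#' @export
spawn_offspring <- function(state, agent) {
  cfg <- state$config
  L <- cfg$n_traits
  pool <- state$traits[agent, ]                 # parent's combined list
  n_inherit <- draw_int(9L)                     # 0..8
  # partial Fisher-Yates over the parent's slots: n_inherit picks
  for (i in seq_len(n_inherit)) {
    j <- (i - 1L) + draw_int(L - i + 1L)
    tmp <- pool[i]
    pool[i] <- pool[j + 1L]
    pool[j + 1L] <- tmp
  }
  child <- rep(NA_integer_, L)
  if (n_inherit > 0L) child[seq_len(n_inherit)] <- pool[seq_len(n_inherit)]
  multiset <- cfg$list_semantics == "multiset"
  for (s in seq(from = n_inherit + 1L, length.out = 8L - n_inherit)) {
    child[s] <- if (multiset) {
      cfg$primary_value_range[1] +
        draw_int(cfg$primary_value_range[2] - cfg$primary_value_range[1] + 1L)
    } else {
      draw_excluding(cfg$primary_value_range[1], cfg$primary_value_range[2],
                     child[!is.na(child)])
    }
  }
  for (s in 9:L) {
    child[s] <- if (multiset) {
      cfg$secondary_value_range[1] +
        draw_int(cfg$secondary_value_range[2] - cfg$secondary_value_range[1] + 1L)
    } else {
      draw_excluding(cfg$secondary_value_range[1], cfg$secondary_value_range[2],
                     child[!is.na(child)])
    }
  }
  state$traits[agent, ] <- child
  state$generation[agent] <- state$generation[agent] + 1L
  state$interactions[agent] <- 0L
  state$id[agent] <- state$next_id
  state$next_id <- state$next_id + 1L
  state
}

#' Advance the model by one tick (reference schedule)
#'
#' One full schedule pass: (a) agents are visited once each in a fresh random
#' order; each visited agent draws a trait, seeks a partner holding it and
#' attempts adoption (changes apply immediately — asynchronous updating), and
#' its interaction count increments by one whether or not a partner was found
#' or adoption succeeded; (b) every breed's culture is recompiled; (c) every
#' agent is re-matched against the new cultures and switches breed when it
#' holds a culture's full trait set; (d) every agent at or past its lifespan
#' is replaced by an offspring; (e) the tick counter increments. Population
#' size never changes.
#'
#' This is the pure-R reference path, practical for small populations and
#' verification; [run_single()] uses the compiled engine, which replays the
#' identical schedule and random stream.
#'
#' @param state A `margin_state`.
#' @param log_events If `TRUE`, attach a per-interaction event log
#'   (`data.frame`: tick, initiator/partner ids and breeds, adopted flag,
#'   replaced slot, gained trait) as attribute `"events"`.
#' @return The updated `margin_state`.
#' @export
advance_tick <- function(state, log_events = FALSE) {
  cfg <- state$config
  n <- cfg$n_agents
  events <- if (log_events) vector("list", n) else NULL

  ord <- draw_permutation(n) + 1L
  for (pos in seq_len(n)) {
    i <- ord[pos]
    partner <- choose_partner(state, i)
    adopted <- FALSE
    slot <- NA_integer_
    trait <- NA_integer_
    if (!is.na(partner)) {
      res <- attempt_adoption(state, i, partner)
      state <- res$state
      adopted <- res$adopted
      slot <- res$slot
      trait <- res$trait
    }
    state$interactions[i] <- state$interactions[i] + 1L
    if (log_events) {
      events[[pos]] <- data.frame(
        tick = state$tick + 1L,
        initiator_id = state$id[i],
        initiator_breed = breed_levels()[state$breed[i]],
        partner_id = if (is.na(partner)) NA_integer_ else state$id[partner],
        partner_breed = if (is.na(partner)) NA_character_ else
          breed_levels()[state$breed[partner]],
        adopted = adopted, slot = slot, trait = trait)
    }
  }

  for (b in 1:4) {
    members <- which(state$breed == b)
    state$cultures[b, ] <- recompute_culture(
      state$traits[members, , drop = FALSE], state$cultures[b, ])
  }

  new_breed <- state$breed
  for (i in seq_len(n)) new_breed[i] <- reassign_breed(state, i)
  state$breed <- new_breed

  for (i in seq_len(n)) {
    if (state$interactions[i] >= cfg$lifespan) state <- spawn_offspring(state, i)
  }

  state$tick <- state$tick + 1L
  if (log_events) attr(state, "events") <- do.call(rbind, events)
  state
}
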