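# crafted lists: L = 13 (Low diversity). Values chosen so that sharing is
# fully controlled between agents.

test_that("partner choice is forced when exactly one agent shares traits", {
  cfg <- toy_config(n_agents = 4L,
                    breed_counts = c(QuietMaverick = 1L, Conformist = 1L,
                                     Deviant = 1L, Rebel = 1L))
  tr <- rbind(c(0:7, 22:26),          # initiator
              c(8:15, 27:31),         # shares nothing with the initiator
              c(0:7, 22:26),          # shares every initiator trait
              c(16:21, 37:43))        # shares nothing
  st <- toy_state(tr, breed = 1:4, cfg)
  set.seed(5)
  for (i in 1:20) {
    expect_identical(choose_partner(st, 1L), 3L)
  }
})

test_that("partner choice returns none when no agent shares a trait", {
  cfg <- toy_config(n_agents = 4L,
                    breed_counts = c(QuietMaverick = 1L, Conformist = 1L,
                                     Deviant = 1L, Rebel = 1L))
  tr <- rbind(c(0:7, 22:26),
              c(8:15, 27:31),
              c(44:50, 8:13),
              c(16:21, 37:43))
  st <- toy_state(tr, breed = 1:4, cfg)
  set.seed(5)
  expect_identical(choose_partner(st, 1L), NA_integer_)
})

test_that("partner choice is uniform among identical candidates", {
  cfg <- toy_config(n_agents = 4L,
                    breed_counts = c(QuietMaverick = 1L, Conformist = 1L,
                                     Deviant = 1L, Rebel = 1L))
  st <- toy_state(rep(c(0:7, 22:26), 4), breed = 1:4, cfg)
  set.seed(11)
  picks <- vapply(1:3000, function(i) choose_partner(st, 1L), integer(1))
  tab <- table(factor(picks, levels = 2:4))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("zero-probability cells block adoption", {
  cfg <- toy_config()                     # Low RTC
  tr <- rbind(c(0:7, 22:26),              # initiator: Rebel
              c(0:5, 14, 15, 27:31))      # partner: Deviant, has novel traits
  st <- toy_state(tr, breed = c(4L, 3L), cfg)
  expect_equal(cfg$rtc["Deviant", "Rebel"], 0)
  set.seed(3)
  for (i in 1:20) {
    res <- attempt_adoption(st, 1L, 2L)
    expect_false(res$adopted)
    expect_identical(res$state$traits, st$traits)
  }
})

test_that("certain adoption copies the single novel trait (set semantics)", {
  cfg <- toy_config(list_semantics = "set")
  tr <- rbind(c(0:7, 22:26),
              c(0:7, 22:25, 49))          # same breed, one novel trait: 49
  st <- toy_state(tr, breed = c(2L, 2L), cfg)
  set.seed(8)
  res <- attempt_adoption(st, 1L, 2L)
  expect_true(res$adopted)
  expect_identical(res$trait, 49L)
  expect_true(49L %in% res$state$traits[1L, ])
  expect_length(res$state$traits[1L, ], 13L)
  expect_identical(anyDuplicated(res$state$traits[1L, ]), 0L)
  # shared-element property after adoption
  expect_gt(length(intersect(res$state$traits[1L, ], res$state$traits[2L, ])),
            0L)
})

test_that("set semantics: no-op when the partner offers nothing new", {
  cfg <- toy_config(list_semantics = "set")
  st <- toy_state(rep(c(0:7, 22:26), 2), breed = c(2L, 2L), cfg)
  set.seed(8)
  res <- attempt_adoption(st, 1L, 2L)
  expect_false(res$adopted)
  expect_identical(res$state$traits, st$traits)
})

test_that("multiset semantics: adoption can duplicate an already-held trait", {
  cfg <- toy_config(list_semantics = "multiset")
  st <- toy_state(rep(c(0:7, 22:26), 2), breed = c(2L, 2L), cfg)
  set.seed(8)
  res <- attempt_adoption(st, 1L, 2L)    # identical lists: gain is a repeat
  expect_true(res$adopted)
  expect_length(res$state$traits[1L, ], 13L)
  expect_true(res$trait %in% st$traits[2L, ])
  # over many draws the gained trait is occurrence-weighted over slots
  set.seed(9)
  gains <- vapply(1:2000, function(i) attempt_adoption(st, 1L, 2L)$trait,
                  integer(1))
  expect_gt(stats::chisq.test(table(factor(gains, levels = c(0:7, 22:26))))$p.value,
            0.01)
})

test_that("adoption frequency matches the RTC cell (Monte Carlo)", {
  cfg <- toy_config()                     # Low RTC
  tr <- rbind(c(6L, 8L, 9L, 11L, 12L, 13L, 21L, 22L, 23:27),  # Deviant
              c(4L, 15L, 7L, 1L, 2L, 14L, 17L, 18L, 28:32))   # Rebel
  st <- toy_state(tr, breed = c(3L, 4L), cfg)
  p <- cfg$rtc["Rebel", "Deviant"]
  expect_equal(p, 0.60)
  set.seed(21)
  hits <- vapply(1:10000, function(i) attempt_adoption(st, 1L, 2L)$adopted,
                 logical(1))
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(hits) - p), 3 * se)
})

test_that("culture recompilation keeps unanimous primaries", {
  for (b in breed_levels()) {
    members <- rbind(c(table6[[b]], 23:27),
                     c(table6[[b]], 28:32),
                     c(table6[[b]], 33:37))
    got <- recompute_culture(members, previous = sort(table6[[b]]))
    expect_identical(got, sort(table6[[b]]), info = b)
  }
})

test_that("culture recompilation matches a brute-force tally", {
  # three crafted agents, no tie at the 8th rank
  m <- rbind(c(0:7, 22:26),
             c(0:7, 27:31),
             c(0:5, 32:38))
  tally <- sort(table(as.vector(m)), decreasing = TRUE)
  stopifnot(as.integer(tally[8]) > as.integer(tally[9]))  # tie-free at the cut
  expected <- sort(as.integer(names(tally)[1:8]))
  got <- recompute_culture(m, previous = 0:7)
  expect_identical(got, expected)
})

test_that("ties at the eighth rank break uniformly at random", {
  # values 0..6 occur three times, 40 and 41 twice, all others once:
  # seven safe values, a two-way tie for the eighth place
  m <- rbind(c(0:6, 40L, 41L, 22:25),
             c(0:6, 40L, 26:30),
             c(0:6, 41L, 31:35))
  cnt <- table(as.vector(m))
  stopifnot(sum(cnt == 2) == 2L, sum(cnt == 3) == 7L)
  set.seed(13)
  picked <- vapply(1:2000, function(i) {
    setdiff(recompute_culture(m, previous = 0:7), 0:6)
  }, integer(1))
  tab <- table(factor(picked, levels = c(40L, 41L)))
  expect_identical(sum(tab), 2000L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("empty breeds keep their previous culture", {
  prev <- c(3L, 1L, 4L, 15L, 9L, 2L, 6L, 5L)
  got <- recompute_culture(matrix(integer(0), nrow = 0), previous = prev)
  expect_identical(got, sort(prev))
})

test_that("breed membership follows full-culture containment", {
  set.seed(2)
  st <- init_population(sim_config())
  # at t = 0 every agent matches exactly its own culture
  for (i in c(1, 3, 150, 200)) {
    expect_identical(reassign_breed(st, i), st$breed[i])
  }
  # an agent matching no culture in full keeps its breed
  cfg <- toy_config()
  tr7 <- c(table6$Conformist[1:7], 45L, 28:32)  # 7 of 8 Conformist traits
  st2 <- toy_state(rep(tr7, 2), breed = c(3L, 2L), cfg)
  expect_identical(reassign_breed(st2, 1L), 3L)
})

test_that("membership ties resolve by fair coin flip", {
  cfg <- toy_config(n_agents = 4L,
                    breed_counts = c(QuietMaverick = 1L, Conformist = 1L,
                                     Deviant = 1L, Rebel = 1L),
                    diversity_level = "High")   # 18 slots
  both <- unique(c(table6$Conformist, table6$QuietMaverick))  # 13 values
  tr <- c(both, setdiff(33:50, both)[1:5])
  st <- toy_state(rep(tr, 2), breed = c(3L, 3L), cfg)
  set.seed(17)
  picks <- vapply(1:2000, function(i) reassign_breed(st, 1L), integer(1))
  tab <- table(factor(picks, levels = 1:2))
  expect_identical(sum(tab), 2000L)             # only QM and Conformist match
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("multiset semantics: occurrence counts drive breed switching", {
  cfg <- toy_config(list_semantics = "multiset")
  # four distinct Deviant-culture values, each held twice: 8 occurrences
  dup <- c(6L, 6L, 8L, 8L, 9L, 9L, 11L, 11L, 40:44)
  st <- toy_state(rep(dup, 2), breed = c(2L, 2L), cfg)
  expect_identical(reassign_breed(st, 1L), 3L)
  # seven occurrences do not qualify
  st$traits[1L, 8L] <- 45L
  expect_identical(reassign_breed(st, 1L), 2L)
})

test_that("offspring have the parent's breed and fresh structure", {
  set.seed(31)
  st <- init_population(toy_config(list_semantics = "set"))
  st$interactions <- rep(100L, 5)
  for (i in 1:5) {
    st2 <- spawn_offspring(st, i)
    expect_identical(anyDuplicated(st2$traits[i, ]), 0L)
    expect_length(st2$traits[i, ], 13L)
    expect_identical(st2$generation[i], 1L)
    expect_identical(st2$interactions[i], 0L)
    expect_identical(st2$id[i], st$next_id)
    expect_identical(st2$breed[i], st$breed[i])
    expect_true(all(st2$traits[i, 9:13] >= 22L & st2$traits[i, 9:13] <= 50L))
  }
})

test_that("inheritance spans the full none-to-all range", {
  set.seed(6)
  base <- init_population(toy_config())
  parent <- base$traits[2L, ]
  seen <- integer(0)
  for (s in 1:400) {
    set.seed(1000 + s)
    n_inh <- floor(runif(1) * 9)      # first draw of the spawn schedule
    set.seed(1000 + s)
    st2 <- spawn_offspring(base, 2L)
    child <- st2$traits[2L, ]
    if (n_inh == 8) {
      # all primary slots inherited: a subset of the parent's combined list
      expect_true(all(child[1:8] %in% parent))
    }
    if (n_inh == 0) {
      # nothing inherited: primaries freshly drawn from the primary range
      expect_true(all(child[1:8] >= 0L & child[1:8] <= 21L))
    }
    # inherited values always come from the parent's list
    expect_true(all(child[seq_len(n_inh)] %in% parent))
    seen <- union(seen, n_inh)
  }
  expect_setequal(seen, 0:8)
})

test_that("frozen adoption dynamics leave cultures and breeds unchanged", {
  cfg <- frozen_config(n_agents = 8L,
                       breed_counts = c(QuietMaverick = 2L, Conformist = 2L,
                                        Deviant = 2L, Rebel = 2L),
                       lifespan = 100L, n_ticks = 10L, seed = 2L)
  # two members per breed with disjoint secondaries: pooled primaries tie
  # exactly at the 8th rank, so recompilation is deterministic
  tr <- do.call(rbind, lapply(breed_levels(), function(b)
    rbind(c(table6[[b]], 23:27), c(table6[[b]], 28:32))))
  st <- toy_state(tr, breed = rep(1:4, each = 2L), cfg)
  set.seed(2)
  for (tk in 1:10) st <- advance_tick(st)
  expect_identical(st$cultures, st$initial_cultures)
  expect_identical(st$breed, rep(1:4, each = 2L))
  rec <- tick_record(st)
  expect_true(all(rec[paste0("change_", breed_levels())] == 0))
  expect_equal(unname(rec["sim_Conformist_Deviant"]), 0)
  expect_equal(unname(rec["sim_QuietMaverick_Conformist"]), 3 / 8)
  expect_equal(unname(rec["sim_Deviant_Rebel"]), 2 / 8)
})

test_that("a tick conserves population and advances every counter once", {
  for (seed in c(3, 14)) {
    cfg <- toy_config(n_agents = 12L,
                      breed_counts = c(QuietMaverick = 1L, Conformist = 6L,
                                       Deviant = 4L, Rebel = 1L),
                      diversity_level = "Moderate", lifespan = 50L,
                      seed = seed)
    set.seed(seed)
    st <- init_population(cfg)
    for (tk in 1:8) {
      st <- advance_tick(st)
      expect_identical(length(st$breed), 12L)
      expect_identical(dim(st$traits), c(12L, 15L))
      expect_true(all(st$interactions == tk))
      expect_silent(marginsim:::validate_state(st))
    }
    expect_identical(st$tick, 8L)
  }
})

test_that("agents die exactly at the lifespan boundary", {
  cfg <- toy_config(lifespan = 4L, n_ticks = 9L, seed = 5L)
  run <- run_single(cfg, trajectory = FALSE, engine = "r")
  # after 9 ticks with lifespan 4: synchronized rebirths at ticks 4 and 8
  expect_true(all(run$state$generation == 2L))
  expect_true(all(run$state$interactions == 1L))
  expect_identical(run$state$next_id, 5L + 2L * 5L)
})

test_that("raising an adoption probability never lowers expected adoptions", {
  counts <- c(QuietMaverick = 1L, Conformist = 5L, Deviant = 6L, Rebel = 4L)
  total <- c(lo = 0L, hi = 0L)
  for (s in 1:100) {
    for (variant in c("lo", "hi")) {
      cfg <- toy_config(n_agents = 16L, breed_counts = counts,
                        lifespan = 1000L, n_ticks = 15L, seed = s)
      cfg$rtc[] <- 0    # isolate a single channel, all else frozen
      cfg$rtc["Rebel", "Deviant"] <- if (variant == "lo") 0.3 else 0.9
      total[variant] <- total[variant] + sum(run_single(cfg)$adoptions)
    }
  }
  expect_gt(total[["lo"]], 0L)
  expect_gte(total[["hi"]], total[["lo"]])
})
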