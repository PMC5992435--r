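# Packaged model constants. Every quantity here can be overridden by passing
# a modified list to sim_config()/init_population(); nothing below is
# hard-coded elsewhere in the package.
#
# Breed order is canonical throughout the package:
# QuietMaverick, Conformist, Deviant, Rebel.

breeds: [QuietMaverick, Conformist, Deviant, Rebel]

# Initial population composition (200 agents; shares 1/60/35/4 percent).
initial_counts:
  QuietMaverick: 2
  Conformist: 120
  Deviant: 70
  Rebel: 8

# Initial primary traits (8 per breed).  These define the t = 0 cultures.
primary_traits:
  Conformist:    [1, 2, 3, 4, 5, 16, 19, 20]
  QuietMaverick: [1, 2, 3, 7, 10, 13, 17, 18]
  Rebel:         [4, 15, 7, 8, 9, 14, 17, 18]
  Deviant:       [6, 8, 9, 11, 12, 13, 21, 22]

# Overlap among initial primary traits as stated in the source material
# (shared counts out of 8).  NOTE: the package always *computes* overlap from
# primary_traits above, which gives QuietMaverick-Rebel 3 (not 2),
# QuietMaverick-Deviant 1 (not 2) and Deviant-Rebel 2 (not 0).  The stated
# table is kept here for reference only and is not used by any computation.
stated_overlap:
  QuietMaverick: {Conformist: 3, Deviant: 2, Rebel: 2}
  Conformist:    {Deviant: 0, Rebel: 1}
  Deviant:       {Rebel: 0}

# Trait value ranges (inclusive).  Primary traits are drawn from/initialised
# in 0..21; secondary traits in 22..50.  The Deviant primary list above
# includes 22; duplicate-free draws handle the collision.
primary_value_range: [0, 21]
secondary_value_range: [22, 50]

# Diversity condition -> number of secondary traits per agent.
secondary_counts:
  Low: 5
  Moderate: 7
  High: 10

# Resistance-to-change adoption-probability matrices, one per RTC level.
# Rows = influencer (source, the partner being copied); columns = influenced
# (adopter, the initiating agent).  Row/column order follows `breeds`.
# A quiet maverick never adopts from another breed (QM column zero
# off-diagonal); a rebel never adopts from a conformist.
rtc:
  Low:
    - [1.0,  0.05,  0.05, 0.20]   # source QuietMaverick
    - [0.0,  1.0,   0.10, 0.0 ]   # source Conformist
    - [0.0,  0.0,   1.0,  0.0 ]   # source Deviant
    - [0.0,  0.10,  0.60, 1.0 ]   # source Rebel
  Moderate:
    - [1.0,  0.0375, 0.075, 0.15]
    - [0.0,  1.0,    0.075, 0.0 ]
    - [0.0,  0.20,   1.0,   0.0 ]
    - [0.0,  0.075,  0.40,  1.0 ]
  High:
    - [1.0,  0.025, 0.10, 0.10]
    - [0.0,  1.0,   0.05, 0.0 ]
    - [0.0,  0.40,  1.0,  0.0 ]
    - [0.0,  0.05,  0.20, 1.0 ]

# Demography: an agent is replaced after `lifespan` interactions; a run
# lasts ceiling(2.5 * lifespan) ticks (2.5 generations).
lifespan: 1000
generations: 2.5
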