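#' Number of shared traits between two cultures
#'
#' @param a,b Integer vectors of trait values (cultures are 8-trait sets).
#' @return Integer size of the intersection; symmetric.
#' @examples
#' trait_overlap(c(1, 2, 3, 4, 5, 16, 19, 20), c(1, 2, 3, 7, 10, 13, 17, 18)) # 3
#' @export
trait_overlap <- function(a, b) {
  length(intersect(as.integer(a), as.integer(b)))
}

#' Within-culture change from the starting point
#'
#' `1 - overlap/8`: 0 for an unchanged culture, 1 for complete turnover.
#'
#' @param current,initial 8-trait cultures.
#' @return Fraction in `[0, 1]`.
#' @export
culture_change <- function(current, initial) {
  stopifnot(length(current) == 8L, length(initial) == 8L)
  1 - trait_overlap(current, initial) / 8
}

#' Similarity between two cultures
#'
#' `overlap/8`: 0 for disjoint cultures, 1 for identical ones. Satisfies
#' `culture_change(a, b) == 1 - culture_similarity(a, b)`.
#'
#' @param a,b 8-trait cultures.
#' @return Fraction in `[0, 1]`; symmetric.
#' @export
culture_similarity <- function(a, b) {
  stopifnot(length(a) == 8L, length(b) == 8L)
  trait_overlap(a, b) / 8
}

#' Population proportion of each breed
#'
#' @param state A `margin_state`.
#' @return Named numeric vector over the four breeds, summing to 1.
#' @export
population_proportions <- function(state) {
  n <- length(state$breed)
  stopifnot(n > 0L)
  setNames(tabulate(state$breed, 4L) / n, breed_levels())
}

# fixed order of unordered breed pairs used in every record and CSV
breed_pairs <- function() {
  combn(breed_levels(), 2L)
}

pair_names <- function(prefix = "sim") {
  pairs <- breed_pairs()
  paste0(prefix, "_", pairs[1L, ], "_", pairs[2L, ])
}

record_names <- function() {
  c("tick",
    paste0("prop_", breed_levels()),
    paste0("change_", breed_levels()),
    pair_names())
}

#' Dependent variables of the current state
#'
#' One row of the per-tick record: the four breed population proportions, the
#' four within-culture changes from the tick-0 cultures, and the six pairwise
#' culture similarities (pairs in canonical order).
#'
#' @param state A `margin_state`.
#' @return Named numeric vector of length 15 (`tick` plus 14 dependent
#'   variables).
#' @export
tick_record <- function(state) {
  prop <- population_proportions(state)
  chg <- vapply(1:4, function(b)
    culture_change(state$cultures[b, ], state$initial_cultures[b, ]),
    numeric(1))
  pairs <- combn(4L, 2L)
  sims <- vapply(seq_len(ncol(pairs)), function(p)
    culture_similarity(state$cultures[pairs[1L, p], ],
                       state$cultures[pairs[2L, p], ]),
    numeric(1))
  setNames(c(state$tick, prop, chg, sims), record_names())
}

#' Time-average a run's tick records
#'
#' The run-level summary: each of the 14 dependent variables averaged
#' arithmetically over all recorded ticks (the tick-0 record included).
#'
#' @param records Data frame or matrix of tick records ([tick_record()] rows).
#' @param rtc_level,diversity_level,replicate,seed Run metadata carried into
#'   the summary row.
#' @return One-row `data.frame`: metadata columns, then `mean_prop_*`,
#'   `mean_change_*`, `mean_sim_*`.
#' @export
summarize_run <- function(records, rtc_level = NA_character_,
                          diversity_level = NA_character_,
                          replicate = NA_integer_, seed = NA_integer_) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("cannot summarize an empty record sequence")
  dv_cols <- setdiff(record_names(), "tick")
  stopifnot(all(dv_cols %in% names(records)))
  means <- colMeans(records[dv_cols])
  out <- data.frame(rtc_level = rtc_level, diversity_level = diversity_level,
                    replicate = replicate, seed = seed)
  out[paste0("mean_", dv_cols)] <- as.list(means)
  out
}
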