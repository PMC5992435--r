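#' Specify the factorial experiment
#'
#' The standard experiment is the RTC(3) x Diversity(3) design with 25
#' replicate runs per cell (225 runs). Each run's seed is derived
#' deterministically from `base_seed`, the cell index and the replicate
#' index, so the design is reproducible, order-independent and safe to
#' parallelize externally.
#'
#' @param rtc_levels,diversity_levels Ordered character vectors of condition
#'   levels.
#' @param replicates Runs per cell (>= 1; the ANOVA layer needs >= 2).
#' @param base_seed Integer master seed for the whole design.
#' @param ... Per-run overrides passed to [sim_config()] (e.g. `n_ticks`,
#'   `n_agents`, `lifespan`, `breed_counts`, `defaults`).
#' @return A `design_spec` list.
#' @examples
#' spec <- design_spec(replicates = 2, base_seed = 7, n_ticks = 10)
#' @export
design_spec <- function(rtc_levels = condition_levels(),
                        diversity_levels = condition_levels(),
                        replicates = 25L,
                        base_seed = 1L,
                        ...) {
  for (l in rtc_levels) match_level(l, "RTC level")
  for (l in diversity_levels) match_level(l, "Diversity level")
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1")
  if (replicates >= 126L) stop("seed derivation supports at most 125 replicates")
  structure(list(rtc_levels = rtc_levels,
                 diversity_levels = diversity_levels,
                 replicates = replicates,
                 base_seed = as.integer(base_seed),
                 overrides = list(...)),
            class = "design_spec")
}

#' Derive one run's seed from the design coordinates
#'
#' Deterministic function of `(base_seed, cell_index, replicate)`; distinct
#' for every run of a design (for fewer than 126 replicates per cell) and
#' independent of execution order.
#'
#' @param base_seed Design master seed.
#' @param cell_index 0-based cell index (RTC-major, Diversity-minor).
#' @param replicate 1-based replicate index.
#' @return A positive integer seed below 2^31.
#' @export
derive_run_seed <- function(base_seed, cell_index, replicate) {
  m <- 2147483647  # 2^31 - 1
  s <- (as.double(base_seed) %% m + 1000003 * cell_index + 7919 * replicate) %% m
  as.integer(s %% m) + 1L
}

#' Run the full factorial design
#'
#' Executes every cell x replicate (cells in declared order, RTC-major;
#' replicates ascending) with its derived seed and collects the per-run
#' time-averaged summaries.
#'
#' @param spec A [design_spec()].
#' @param engine Passed to [run_single()].
#' @param progress Emit a one-line progress record per run to standard error.
#' @return A `margin_design` data frame: one row per run with `rtc_level`,
#'   `diversity_level`, `replicate`, `seed` and the 14 `mean_*` dependent
#'   variables; attribute `"manifest"` carries provenance (base seed,
#'   package version, config hash, timestamp).
#' @examples
#' d <- run_design(design_spec(replicates = 2, n_ticks = 5, base_seed = 3))
#' nrow(d) # 18
#' @export
run_design <- function(spec, engine = c("cpp", "r"), progress = FALSE) {
  stopifnot(inherits(spec, "design_spec"))
  engine <- match.arg(engine)
  rows <- vector("list",
                 length(spec$rtc_levels) * length(spec$diversity_levels) *
                   spec$replicates)
  k <- 0L
  for (ri in seq_along(spec$rtc_levels)) {
    for (di in seq_along(spec$diversity_levels)) {
      cell <- (ri - 1L) * length(spec$diversity_levels) + (di - 1L)
      for (rep in seq_len(spec$replicates)) {
        seed <- derive_run_seed(spec$base_seed, cell, rep)
        cfg <- do.call(sim_config, c(
          list(rtc_level = spec$rtc_levels[ri],
               diversity_level = spec$diversity_levels[di], seed = seed),
          spec$overrides))
        t0 <- proc.time()[["elapsed"]]
        run <- tryCatch(run_single(cfg, trajectory = FALSE, engine = engine),
                        error = function(e) {
          stop(sprintf("run failed at cell (RTC %s, Diversity %s), replicate %d, seed %d: %s",
                       spec$rtc_levels[ri], spec$diversity_levels[di], rep,
                       seed, conditionMessage(e)), call. = FALSE)
        })
        if (progress) {
          message(sprintf("RTC %-8s Diversity %-8s replicate %2d seed %10d  %.2fs",
                          spec$rtc_levels[ri], spec$diversity_levels[di], rep,
                          seed, proc.time()[["elapsed"]] - t0))
        }
        s <- run$summary
        s$replicate <- rep
        k <- k + 1L
        rows[[k]] <- s
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "manifest") <- list(
    base_seed = spec$base_seed,
    replicates = spec$replicates,
    rtc_levels = spec$rtc_levels,
    diversity_levels = spec$diversity_levels,
    overrides = spec$overrides,
    config_hash = config_hash(spec),
    package_version = as.character(packageVersion("marginsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(out) <- c("margin_design", "data.frame")
  out
}

# small stable checksum for provenance manifests (not cryptographic)
config_hash <- function(x) {
  s <- paste(deparse(x[setdiff(names(x), "timestamp")]), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.margin_design <- function(x, ...) {
  man <- attr(x, "manifest")
  cat(sprintf("Factorial design: %d runs (%d RTC x %d Diversity x %d replicates), base seed %d\n",
              nrow(x), length(man$rtc_levels), length(man$diversity_levels),
              man$replicates, man$base_seed))
  NextMethod()
}

#' The eleven analyzed dependent variables
#'
#' Four population proportions, four within-culture changes, and the three
#' similarities to the Conformist culture.
#'
#' @return Character vector of column names in a `margin_design`.
#' @export
analyzed_dvs <- function() {
  c(paste0("mean_prop_", breed_levels()),
    paste0("mean_change_", breed_levels()),
    "mean_sim_QuietMaverick_Conformist",
    "mean_sim_Conformist_Deviant",
    "mean_sim_Conformist_Rebel")
}

#' ANOVA layer over a completed design
#'
#' Runs [two_way_anova()] (with Tukey HSD post-hocs on both main effects) on
#' each of the eleven analyzed dependent variables and optionally writes the
#' machine-readable and human-readable reports.
#'
#' @param design A `margin_design` (or equivalent data frame).
#' @param out_dir If non-`NULL`, write per-DV reports there (see
#'   [write_anova_report()]) plus `summaries.csv`.
#' @return Named list of `margin_anova` objects, one per dependent variable.
#' @export
analyze_design <- function(design, out_dir = NULL) {
  res <- lapply(analyzed_dvs(), function(dv) two_way_anova(design, dv))
  names(res) <- analyzed_dvs()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_summaries_csv(design, file.path(out_dir, "summaries.csv"))
    for (dv in analyzed_dvs()) {
      write_anova_report(res[[dv]], out_dir)
    }
  }
  res
}
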