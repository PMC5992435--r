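#' Canonical breed order
#'
#' All matrices, records and tie-breaks in the package index the four breeds
#' in this fixed order.
#'
#' @return Character vector `c("QuietMaverick", "Conformist", "Deviant",
#'   "Rebel")`.
#' @export
breed_levels <- function() {
  c("QuietMaverick", "Conformist", "Deviant", "Rebel")
}

#' Load the packaged model constants
#'
#' Reads the YAML file shipped at `inst/extdata/model-defaults.yaml`, which
#' holds every model constant: initial breed counts, initial primary traits,
#' trait value ranges, secondary-trait counts per Diversity level, the three
#' RTC adoption-probability matrices, the lifespan and the generation budget.
#' Pass a modified copy (or your own file) to [sim_config()] to override any
#' constant without touching code.
#'
#' @param file Path to a YAML file with the same structure as the packaged
#'   default.
#' @return A named list with elements `breeds`, `initial_counts`,
#'   `primary_traits`, `primary_value_range`, `secondary_value_range`,
#'   `secondary_counts`, `rtc`, `lifespan`, `generations`.
#' @examples
#' d <- model_defaults()
#' d$initial_counts
#' @export
model_defaults <- function(file = system.file("extdata", "model-defaults.yaml",
                                              package = "marginsim")) {
  stopifnot(nzchar(file), file.exists(file))
  d <- yaml::read_yaml(file)
  needed <- c("breeds", "initial_counts", "primary_traits",
              "primary_value_range", "secondary_value_range",
              "secondary_counts", "rtc", "lifespan", "generations")
  missing <- setdiff(needed, names(d))
  if (length(missing) > 0L) {
    stop("defaults file is missing fields: ", paste(missing, collapse = ", "))
  }
  d$breeds <- as.character(d$breeds)
  if (!identical(sort(d$breeds), sort(breed_levels()))) {
    stop("defaults file must define exactly the four breeds: ",
         paste(breed_levels(), collapse = ", "))
  }
  d
}

#' RTC level and Diversity level labels
#' @return Character vector `c("Low", "Moderate", "High")`.
#' @export
condition_levels <- function() {
  c("Low", "Moderate", "High")
}

match_level <- function(level, what = "level") {
  if (length(level) != 1L || !level %in% condition_levels()) {
    stop(sprintf("unknown %s '%s'; must be one of %s", what,
                 paste(level, collapse = ","),
                 paste(condition_levels(), collapse = ", ")), call. = FALSE)
  }
  level
}

#' Build the adoption-probability matrix for an RTC level
#'
#' Returns the 4 x 4 matrix of trait-adoption probabilities for one
#' resistance-to-change condition. Rows index the influencing (source) breed
#' — the interaction partner being copied — and columns the influenced
#' (adopter) breed — the initiating agent. The diagonal is 1 (same-breed
#' influence always succeeds); the QuietMaverick column is zero off the
#' diagonal (a quiet maverick never adopts from another breed); the
#' Conformist-source -> Rebel-adopter cell is zero at every level.
#'
#' @param level `"Low"`, `"Moderate"` or `"High"`.
#' @param defaults Model constants, see [model_defaults()].
#' @return A 4 x 4 numeric matrix with breed dimnames
#'   (`source` x `adopter`) and attributes `level`.
#' @examples
#' rtc_matrix("Low")["Rebel", "Deviant"]   # 0.60
#' rtc_matrix("High")["Deviant", "Conformist"] # 0.40
#' @export
rtc_matrix <- function(level, defaults = model_defaults()) {
  level <- match_level(level, "RTC level")
  panel <- defaults$rtc[[level]]
  if (is.null(panel)) stop("defaults file has no RTC panel for level ", level)
  m <- do.call(rbind, lapply(panel, as.numeric))
  if (!all(dim(m) == c(4L, 4L))) stop("RTC panel must be 4 x 4")
  dimnames(m) <- list(source = breed_levels(), adopter = breed_levels())
  if (any(m < 0 | m > 1)) stop("RTC probabilities must lie in [0, 1]")
  if (any(diag(m) != 1)) stop("RTC diagonal must be 1.0 (self-influence)")
  structure(m, level = level, class = c("rtc_matrix", "matrix", "array"))
}

#' Number of secondary traits for a Diversity level
#'
#' The Diversity condition is operationalized as the number of secondary
#' traits each agent carries: 5 (Low), 7 (Moderate) or 10 (High), for 13, 15
#' or 18 total traits alongside the 8 primary traits.
#'
#' @inheritParams rtc_matrix
#' @return Integer count of secondary traits.
#' @examples
#' secondary_count("High") # 10
#' @export
secondary_count <- function(level, defaults = model_defaults()) {
  level <- match_level(level, "Diversity level")
  k <- defaults$secondary_counts[[level]]
  if (is.null(k)) stop("defaults file has no secondary count for level ", level)
  as.integer(k)
}

#' @export
print.rtc_matrix <- function(x, ...) {
  cat(sprintf("RTC adoption probabilities (%s): rows = source, cols = adopter\n",
              attr(x, "level")))
  print(unclass(x))
  invisible(x)
}
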