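#' EQ-5D dimensions
#'
#' The five EQ-5D health dimensions in their fixed order: mobility (MO),
#' self-care (SC), usual activities (UA), pain/discomfort (PD), and
#' anxiety/depression (AD). All state strings and probability tables in this
#' package use this order; no alternative orderings are accepted.
#'
#' @format Character vector of length 5.
#' @export
EQ5D_DIMENSIONS <- c("MO", "SC", "UA", "PD", "AD")

#' Number of response levels for an EQ-5D version
#'
#' @param version `"3L"` or `"5L"`.
#' @return 3 or 5.
#' @export
n_levels <- function(version) {
  version <- match.arg(version, c("3L", "5L"))
  if (version == "3L") 3L else 5L
}

#' Convert health-state strings to a level matrix
#'
#' A health state is written as a 5-digit string, one digit per dimension in
#' the order MO, SC, UA, PD, AD (e.g. `"21232"`).
#'
#' @param states Character vector of 5-digit state strings.
#' @param version `"3L"` or `"5L"`; levels are validated against the version.
#' @return Integer matrix with one row per state and columns MO..AD.
#' @export
states_to_levels <- function(states, version) {
  L <- n_levels(version)
  if (!is.character(states) || any(nchar(states) != 5L)) {
    stop("health states must be 5-character digit strings, e.g. \"21232\"")
  }
  m <- matrix(
    as.integer(unlist(strsplit(states, "", fixed = TRUE), use.names = FALSE)),
    ncol = 5L, byrow = TRUE
  )
  colnames(m) <- EQ5D_DIMENSIONS
  if (anyNA(m) || any(m < 1L) || any(m > L)) {
    bad <- states[apply(is.na(m) | m < 1L | m > L, 1L, any)]
    stop(sprintf(
      "invalid level(s) for EQ-5D-%s in state(s): %s",
      version, paste(unique(bad), collapse = ", ")
    ))
  }
  m
}

#' Convert a level matrix back to state strings
#'
#' @param levels Integer matrix with 5 columns (MO, SC, UA, PD, AD).
#' @return Character vector of 5-digit state strings.
#' @export
levels_to_states <- function(levels) {
  stopifnot(is.matrix(levels), ncol(levels) == 5L)
  apply(levels, 1L, paste0, collapse = "")
}

#' Enumerate all health states of an EQ-5D version
#'
#' 243 states for the 3L instrument, 3125 for the 5L instrument.
#'
#' @inheritParams states_to_levels
#' @return Character vector of state strings in lexicographic order.
#' @export
enumerate_states <- function(version) {
  L <- n_levels(version)
  g <- expand.grid(
    AD = 1:L, PD = 1:L, UA = 1:L, SC = 1:L, MO = 1:L,
    KEEP.OUT.ATTRS = FALSE
  )[, 5:1]
  levels_to_states(as.matrix(g))
}
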