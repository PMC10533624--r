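#' @title Crosswalks between EQ-5D versions
#'
#' @description A crosswalk assigns utilities of one EQ-5D version to states
#' described by the other (5L to 3L, or 3L to 5L). The model here carries
#' one row-stochastic transition matrix per dimension (source level x target
#' level); under cross-dimension independence the crosswalked utility of a
#' source state is the expected target-tariff utility over the product
#' distribution of target states. An optional lookup table (source state ->
#' utility per country) can be attached; when present it takes precedence,
#' which allows published full state-to-index tables to be used bit-exactly
#' as data.
#'
#' @name eq5d_crosswalk
NULL

.xw_versions <- function(direction) {
  switch(direction,
    "5L_to_3L" = c(source = "5L", target = "3L"),
    "3L_to_5L" = c(source = "3L", target = "5L"),
    stop("direction must be '5L_to_3L' or '3L_to_5L'")
  )
}

#' Construct a crosswalk model
#'
#' @param direction `"5L_to_3L"` or `"3L_to_5L"`.
#' @param matrices Named list (MO, SC, UA, PD, AD) of row-stochastic
#'   matrices, source levels in rows, target levels in columns.
#' @param lookup Optional data frame with columns `state`, `country`,
#'   `utility` covering every source state for each country it mentions.
#' @return An object of class `eq5d_crosswalk`.
#' @export
new_crosswalk <- function(direction, matrices, lookup = NULL) {
  v <- .xw_versions(direction)
  Ls <- n_levels(v[["source"]]); Lt <- n_levels(v[["target"]])
  if (!is.list(matrices) || !setequal(names(matrices), EQ5D_DIMENSIONS)) {
    stop("matrices must be a named list with elements ",
         paste(EQ5D_DIMENSIONS, collapse = ", "))
  }
  matrices <- matrices[EQ5D_DIMENSIONS]
  for (d in EQ5D_DIMENSIONS) {
    m <- as.matrix(matrices[[d]])
    if (!all(dim(m) == c(Ls, Lt))) {
      stop(sprintf("matrix for %s must be %dx%d for direction %s",
                   d, Ls, Lt, direction))
    }
    if (any(m < 0)) stop("negative transition probability in dimension ", d)
    rs <- rowSums(m)
    if (any(abs(rs - 1) > 1e-9)) {
      stop(sprintf("rows of the %s matrix must sum to 1 (off by up to %.3g)",
                   d, max(abs(rs - 1))))
    }
    matrices[[d]] <- m
  }
  if (!is.null(lookup)) {
    lookup <- as.data.frame(lookup, stringsAsFactors = FALSE)
    if (!all(c("state", "country", "utility") %in% names(lookup))) {
      stop("lookup needs columns state, country, utility")
    }
    lookup$state <- as.character(lookup$state)
    lookup$utility <- as.numeric(lookup$utility)
    all_src <- enumerate_states(v[["source"]])
    for (ctry in unique(lookup$country)) {
      have <- lookup$state[lookup$country == ctry]
      miss <- setdiff(all_src, have)
      if (length(miss)) {
        stop(sprintf("lookup for %s covers %d of %d source states; missing e.g. %s",
                     ctry, length(have), length(all_src), miss[1]))
      }
      if (anyDuplicated(have)) stop("duplicate lookup states for ", ctry)
    }
  }
  structure(
    list(direction = direction, source_version = unname(v[["source"]]),
         target_version = unname(v[["target"]]), matrices = matrices,
         lookup = lookup),
    class = "eq5d_crosswalk"
  )
}

#' @export
print.eq5d_crosswalk <- function(x, ...) {
  cat(sprintf("<eq5d_crosswalk> %s (%s)\n", x$direction,
              if (is.null(x$lookup)) "matrices only"
              else "matrices + lookup"))
  invisible(x)
}

#' Crosswalk health states to utilities of the other version
#'
#' With matrices only, the utility is the expectation of
#' `score_states(target_state, target_tariff)` under the product of the
#' per-dimension transition rows, computed by direct enumeration over all
#' 243 (3L) or 3125 (5L) target states. With a lookup attached that covers
#' the tariff's country, the lookup value is returned instead.
#'
#' @param states Character vector of source-version state strings.
#' @param model An [eq5d_crosswalk][new_crosswalk].
#' @param target_tariff Tariff of the model's target version.
#' @return Numeric vector of crosswalked utilities.
#' @export
crosswalk_utilities <- function(states, model, target_tariff) {
  stopifnot(inherits(model, "eq5d_crosswalk"),
            inherits(target_tariff, "eq5d_tariff"))
  if (target_tariff$version != model$target_version) {
    stop(sprintf("target tariff is EQ-5D-%s but the crosswalk maps to EQ-5D-%s",
                 target_tariff$version, model$target_version))
  }
  lv <- states_to_levels(states, model$source_version)

  if (!is.null(model$lookup) &&
      target_tariff$country %in% model$lookup$country) {
    lk <- model$lookup[model$lookup$country == target_tariff$country, ]
    return(lk$utility[match(states, lk$state)])
  }

  u_target <- score_states(enumerate_states(model$target_version), target_tariff)
  # expected utility per unique source state: joint target distribution is
  # the Kronecker product of the five transition rows (AD varying fastest,
  # matching enumerate_states order)
  uniq <- unique(states)
  ulv <- states_to_levels(uniq, model$source_version)
  eu <- vapply(seq_along(uniq), function(i) {
    p <- model$matrices[["MO"]][ulv[i, "MO"], ]
    for (d in c("SC", "UA", "PD", "AD")) {
      p <- kronecker(p, model$matrices[[d]][ulv[i, d], ])
    }
    sum(p * u_target)
  }, numeric(1))
  eu[match(states, uniq)]
}

# ---- file formats -----------------------------------------------------------

#' Read a crosswalk matrix file
#'
#' The file is a CSV with header
#' `dimension,source_level,target_level,probability` and a `#`-prefixed YAML
#' preamble with the `direction`. A lookup CSV (`state,country,utility`,
#' same preamble) can be attached via `lookup_file`.
#'
#' @param file Path to the matrix CSV.
#' @param lookup_file Optional path to a lookup CSV.
#' @return An [eq5d_crosswalk][new_crosswalk].
#' @export
read_crosswalk <- function(file, lookup_file = NULL) {
  parse_one <- function(path) {
    lines <- readLines(path)
    is_meta <- startsWith(lines, "#")
    meta <- yaml::yaml.load(paste(sub("^#[ ]?", "", lines[is_meta]),
                                  collapse = "\n"))
    if (is.null(meta$direction)) stop("crosswalk preamble missing 'direction'")
    body <- lines[!is_meta & nzchar(trimws(lines))]
    list(meta = meta,
         df = utils::read.csv(text = paste(body, collapse = "\n"),
                              stringsAsFactors = FALSE))
  }
  mt <- parse_one(file)
  v <- .xw_versions(mt$meta$direction)
  Ls <- n_levels(v[["source"]]); Lt <- n_levels(v[["target"]])
  need <- c("dimension", "source_level", "target_level", "probability")
  if (!all(need %in% names(mt$df))) {
    stop("crosswalk matrix file needs columns: ", paste(need, collapse = ", "))
  }
  mats <- lapply(EQ5D_DIMENSIONS, function(d) {
    rows <- mt$df[mt$df$dimension == d, ]
    if (nrow(rows) == 0L) stop("crosswalk file has no rows for dimension ", d)
    m <- matrix(0, Ls, Lt)
    m[cbind(rows$source_level, rows$target_level)] <- rows$probability
    m
  })
  names(mats) <- EQ5D_DIMENSIONS
  lookup <- NULL
  if (!is.null(lookup_file)) {
    lk <- parse_one(lookup_file)
    if (!identical(lk$meta$direction, mt$meta$direction)) {
      stop("lookup direction does not match the matrix file")
    }
    lookup <- lk$df
  }
  new_crosswalk(mt$meta$direction, mats, lookup)
}

#' Write a crosswalk model to matrix (and optionally lookup) files
#'
#' @param model An [eq5d_crosswalk][new_crosswalk].
#' @param file Output path for the matrix CSV.
#' @param lookup_file Output path for the lookup CSV, if the model has one.
#' @return `file`, invisibly.
#' @export
write_crosswalk <- function(model, file, lookup_file = NULL) {
  stopifnot(inherits(model, "eq5d_crosswalk"))
  pre <- sprintf("# direction: %s", model$direction)
  rows <- unlist(lapply(EQ5D_DIMENSIONS, function(d) {
    m <- model$matrices[[d]]
    idx <- expand.grid(s = seq_len(nrow(m)), t = seq_len(ncol(m)))
    sprintf("%s,%d,%d,%s", d, idx$s, idx$t,
            vapply(m[cbind(idx$s, idx$t)], format, "", digits = 17))
  }))
  writeLines(c(pre, "dimension,source_level,target_level,probability", rows),
             file)
  if (!is.null(lookup_file)) {
    if (is.null(model$lookup)) stop("model has no lookup to write")
    lk <- model$lookup
    writeLines(c(pre, "state,country,utility",
                 sprintf("%s,%s,%s", lk$state, lk$country,
                         vapply(lk$utility, format, "", digits = 17))),
               lookup_file)
  }
  invisible(file)
}

#' Build a lookup table from a model's matrices
#'
#' Evaluates the matrix-based expected utility for every source state under
#' one or more target tariffs, producing a lookup that is exactly consistent
#' with the matrices.
#'
#' @param model An [eq5d_crosswalk][new_crosswalk] (matrices are used even if
#'   a lookup is already attached).
#' @param target_tariffs List of tariffs of the target version.
#' @return Data frame with columns `state`, `country`, `utility`.
#' @export
lookup_from_matrices <- function(model, target_tariffs) {
  mdl <- new_crosswalk(model$direction, model$matrices) # drop lookup
  src <- enumerate_states(model$source_version)
  do.call(rbind, lapply(target_tariffs, function(tf) {
    data.frame(state = src, country = tf$country,
               utility = crosswalk_utilities(src, mdl, tf),
               stringsAsFactors = FALSE)
  }))
}

#' Compare a crosswalk's lookup against its matrices
#'
#' Report-only diagnostic: for every source state, the absolute difference
#' between the matrix-derived expected utility and the attached lookup value
#' under the given target tariff.
#'
#' @param model An [eq5d_crosswalk][new_crosswalk] carrying both matrices and
#'   a lookup for the tariff's country.
#' @param target_tariff Tariff of the target version.
#' @param tolerance Differences above this are listed as violations.
#' @return List with `max`, `mean`, `tolerance`, and a `violations` data
#'   frame (state, matrix_utility, lookup_utility, difference).
#' @export
consistency_check <- function(model, target_tariff, tolerance = 1e-6) {
  stopifnot(inherits(model, "eq5d_crosswalk"))
  if (is.null(model$lookup) ||
      !(target_tariff$country %in% model$lookup$country)) {
    stop("model has no lookup for country ", target_tariff$country)
  }
  src <- enumerate_states(model$source_version)
  mdl <- new_crosswalk(model$direction, model$matrices)
  u_mat <- crosswalk_utilities(src, mdl, target_tariff)
  lk <- model$lookup[model$lookup$country == target_tariff$country, ]
  u_lk <- lk$utility[match(src, lk$state)]
  d <- abs(u_mat - u_lk)
  bad <- d > tolerance
  list(max = max(d), mean = mean(d), tolerance = tolerance,
       violations = data.frame(state = src[bad], matrix_utility = u_mat[bad],
                               lookup_utility = u_lk[bad],
                               difference = (u_lk - u_mat)[bad],
                               stringsAsFactors = FALSE))
}

#' Load the embedded synthetic crosswalk
#'
#' The package ships one synthetic crosswalk per direction under
#' `inst/extdata/crosswalks/`. These are smooth, documented stand-ins with
#' the qualitative structure of the published 5L-to-3L and 3L-to-5L
#' mappings (mass concentrated on the level alignment 1-1 / 5-3 with spread
#' to adjacent levels); they are NOT the published transition tables.
#'
#' @param direction `"5L_to_3L"` or `"3L_to_5L"`.
#' @return An [eq5d_crosswalk][new_crosswalk].
#' @export
builtin_crosswalk <- function(direction = c("5L_to_3L", "3L_to_5L")) {
  direction <- match.arg(direction)
  file <- system.file("extdata", "crosswalks",
                      sprintf("%s_synthetic.csv", direction),
                      package = "eq5dcua", mustWork = TRUE)
  read_crosswalk(file)
}
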