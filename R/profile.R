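.quadrants <- c(
  "low_registration", "sensory_seeking",
  "sensory_sensitivity", "sensory_avoiding"
)

#' Load an item-to-quadrant map for sensory-profile scoring
#'
#' The caregiver questionnaire that classifies a child's sensory-processing
#' pattern under Dunn's four quadrants is proprietary, so scoring is driven
#' by a configurable JSON map `{item_id: {quadrant, min, max}}`. The package
#' bundles a synthetic 20-item instrument (5 items per quadrant, 1-5 Likert)
#' used throughout the tests; it preserves the scoring mechanics without
#' reproducing any copyrighted item.
#'
#' @param path Path to a JSON item map; default is the bundled synthetic
#'   instrument.
#' @return A tibble with columns `item_id`, `quadrant`, `min`, `max`.
#' @export
#' @examples
#' head(load_profile_map())
load_profile_map <- function(path = system.file("extdata",
                               "synthetic_profile_items.json",
                               package = "sensoryrisk"
                             )) {
  raw <- jsonlite::fromJSON(path)
  map <- purrr::imap_dfr(raw, function(x, id) {
    tibble::tibble(
      item_id = id, quadrant = x$quadrant,
      min = as.numeric(x$min), max = as.numeric(x$max)
    )
  })
  bad <- setdiff(unique(map$quadrant), .quadrants)
  if (length(bad) > 0) {
    abort(paste0("unknown quadrant(s) in item map: ", paste(bad, collapse = ", ")),
      class = "sensoryrisk_config_error"
    )
  }
  if (!setequal(unique(map$quadrant), .quadrants)) {
    abort("item map must cover all four quadrants",
      class = "sensoryrisk_config_error"
    )
  }
  map
}

#' Score a sensory-profile questionnaire
#'
#' Sums Likert responses per Dunn quadrant (low registration, sensory
#' seeking, sensory sensitivity, sensory avoiding) and rescales each raw sum
#' by the quadrant's attainable range to a normalized score in `[0, 1]`.
#' Higher scores mean the pattern is more pronounced.
#'
#' @param responses Named numeric vector or list mapping item id to the
#'   Likert response.
#' @param item_map Item map tibble from [load_profile_map()].
#' @return A `sensory_profile`: tibble with one row per quadrant and columns
#'   `quadrant`, `raw`, `min`, `max`, `normalized`.
#' @export
#' @examples
#' map <- load_profile_map()
#' resp <- stats::setNames(rep(3, nrow(map)), map$item_id)
#' score_sensory_profile(resp, map)
score_sensory_profile <- function(responses, item_map = load_profile_map()) {
  responses <- unlist(responses)
  unknown <- setdiff(names(responses), item_map$item_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "response(s) for item(s) not in the map: ",
      paste(unknown, collapse = ", ")
    ), class = "sensoryrisk_config_error")
  }
  missing <- setdiff(item_map$item_id, names(responses))
  if (length(missing) > 0) {
    abort(paste0(
      "missing response(s) for item(s): ",
      paste(missing, collapse = ", ")
    ), class = "sensoryrisk_validation_error")
  }
  df <- dplyr::mutate(item_map,
    response = as.numeric(responses[.data$item_id])
  )
  bad <- df$response < df$min | df$response > df$max | is.na(df$response)
  if (any(bad)) {
    abort(paste0(
      "out-of-range response for item(s): ",
      paste(df$item_id[bad], collapse = ", ")
    ), class = "sensoryrisk_validation_error")
  }
  out <- df |>
    dplyr::group_by(.data$quadrant) |>
    dplyr::summarise(
      raw = sum(.data$response),
      min = sum(.data$min),
      max = sum(.data$max),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      normalized = (.data$raw - .data$min) / (.data$max - .data$min)
    )
  out <- out[match(.quadrants, out$quadrant), ]
  class(out) <- c("sensory_profile", class(out))
  out
}

# normalized quadrant scores as a named vector, in canonical order
.profile_scores <- function(profile) {
  stats::setNames(profile$normalized, profile$quadrant)[.quadrants]
}
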