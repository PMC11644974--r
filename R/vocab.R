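#' Static position classes
#'
#' The five static body-position classes used throughout the package, in the
#' fixed order used by every report and confusion matrix.
#'
#' @return Character vector of length 5.
#' @export
position_classes <- function() {
  c("Sitting", "Upright", "Supine", "Prone", "Hands and Knees")
}

#' Annotated-position to static-class map
#'
#' The 14 manually annotated body positions and the static class each maps to.
#' Dynamic positions (e.g. crawling, walking) map onto their static
#' counterparts (Hands and Knees, Upright). Shipped as a plain TSV under
#' `extdata/position_classes.tsv`.
#'
#' @return Named character vector: names are raw annotation labels, values are
#'   static classes.
#' @export
position_class_map <- function() {
  path <- system.file("extdata", "position_classes.tsv", package = "imuposture",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  stats::setNames(tab$static_class, tab$raw_label)
}

#' Map annotated position labels to static classes
#'
#' @param raw_label character vector of annotated position labels.
#' @param map class map as returned by [position_class_map()].
#' @return Character vector of static classes.
#' @export
map_to_static <- function(raw_label, map = position_class_map()) {
  unknown <- setdiff(unique(raw_label), names(map))
  if (length(unknown) > 0) {
    stop("unknown position label(s): ", paste(sQuote(unknown), collapse = ", "))
  }
  unname(map[raw_label])
}

#' Sensor locations
#'
#' Recognised sensor placements. The trunk region carries two slots so that
#' either one or two physical trunk sensors can be used.
#'
#' @return Character vector of location identifiers.
#' @export
sensor_locations <- function() {
  c("trunk_a", "trunk_b", "leg_left", "leg_right", "arm_left", "arm_right")
}

# Region -> locations, used by the sensor-subset comparison.
location_region <- function(location) {
  region <- c(trunk_a = "trunk", trunk_b = "trunk",
              leg_left = "legs", leg_right = "legs",
              arm_left = "arms", arm_right = "arms")
  unname(region[location])
}

UNASSIGNED <- "UNASSIGNED"
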