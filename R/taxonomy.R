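#' Default land-use taxonomy
#'
#' The twelve first-level land classes of the Chinese land-use change survey
#' standard, which the weighting model uses as its default class set. Any
#' other taxonomy can be supplied wherever a `taxonomy` argument appears.
#'
#' @return Character vector of class names, ordered.
#' @export
#' @examples
#' default_taxonomy()
default_taxonomy <- function() {
  c(
    "cultivated", "garden", "forest", "grass",
    "commercial_service", "industrial_mining_storage", "residential",
    "public_management_service", "special_use", "transportation",
    "water", "other"
  )
}

#' Default water classes
#'
#' Subset of [default_taxonomy()] treated as open water / water-conservancy
#' land by the all-water zeroing rule.
#'
#' @return Character vector.
#' @export
default_water_classes <- function() "water"

check_taxonomy <- function(classes, taxonomy) {
  bad <- setdiff(unique(classes), taxonomy)
  if (length(bad) > 0L) {
    stop("land class(es) not in taxonomy: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
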