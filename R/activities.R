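#' Catalogue of daily activities and their intensity classes
#'
#' The activity-recognition task uses a three-class intensity scheme:
#' sedentary (0), light (1) and moderate (2). Sitting, standing and lying are
#' sedentary (1.3 MET each), level walking is light (2 MET), and stair
#' climbing/descent is moderate (3.5--5 MET). High-intensity activities are
#' not modelled: they are not expected in patients with COPD under long-term
#' oxygen therapy.
#'
#' @return A data frame with columns `name`, `met` (metabolic equivalent of
#'   task) and `intensity` (integer class 0/1/2).
#' @examples
#' activity_catalog()
#' @export
activity_catalog <- function() {
  data.frame(
    name = c("sitting", "standing", "lying", "walking", "upstairs", "downstairs"),
    met = c(1.3, 1.3, 1.3, 2, 5, 3.5),
    intensity = c(0L, 0L, 0L, 1L, 2L, 2L),
    stringsAsFactors = FALSE
  )
}

#' @rdname activity_catalog
#' @param activity character vector of activity names.
#' @return `activity_intensity()` returns the integer intensity class
#'   (0 sedentary, 1 light, 2 moderate) of each activity.
#' @export
activity_intensity <- function(activity) {
  cat <- activity_catalog()
  idx <- match(activity, cat$name)
  if (anyNA(idx)) {
    stop("unknown activity: ", paste(unique(activity[is.na(idx)]), collapse = ", "))
  }
  cat$intensity[idx]
}

#' @rdname activity_catalog
#' @return `intensity_labels()` returns the class names in class order.
#' @export
intensity_labels <- function() c("sedentary", "light", "moderate")
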