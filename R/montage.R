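#' Standard 19-channel 10-20 montage of the HaLT recordings
#'
#' The HaLT benchmark was recorded with 19 scalp electrodes placed according
#' to the international 10-20 system, using the legacy temporal labels
#' (T3/T4/T5/T6 rather than T7/T8/P7/P8).  The montage fixes the channel
#' order that every data matrix in this package follows, and carries the
#' cortical-area annotation commonly attached to each site.
#'
#' @return An object of class `"channel_montage"`: a list with
#'   `names` (ordered character vector of 19 labels), `areas` (named
#'   character vector, label -> cortical-area text) and `index_of`
#'   (named integer vector, label -> 1-based column position).
#' @examples
#' m <- halt_montage()
#' m$names
#' m$index_of[["Cz"]]
#' @export
halt_montage <- function() {
  names <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
             "T3", "C3", "Cz", "C4", "T4",
             "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  areas <- c(
    Fp1 = "Frontal (attention)",
    Fp2 = "Frontal (judgment, restrains impulses)",
    F7  = "Frontal (verbal expression)",
    F3  = "Frontal (motor planning, right-upper extremity)",
    Fz  = "Frontal central (motor planning, midline)",
    F4  = "Frontal (motor planning, left-upper extremity)",
    F8  = "Frontal (emotional expression)",
    T3  = "Temporal (verbal memory)",
    C3  = "Central (sensorimotor integration, right)",
    Cz  = "Central (sensorimotor integration, midline)",
    C4  = "Central (sensorimotor integration, left)",
    T4  = "Temporal (emotional memory)",
    T5  = "Temporal (verbal understanding)",
    P3  = "Parietal (cognitive processing, spatial-temporal)",
    Pz  = "Parietal (cognitive processing)",
    P4  = "Parietal (non-verbal reasoning)",
    T6  = "Temporal (emotional understanding and motivation)",
    O1  = "Occipital (visual processing)",
    O2  = "Occipital (visual processing)"
  )
  stopifnot(identical(sort(names(areas)), sort(names)))
  structure(
    list(names = names,
         areas = areas[names],
         index_of = stats::setNames(seq_along(names), names)),
    class = "channel_montage"
  )
}

#' @export
print.channel_montage <- function(x, ...) {
  cat("10-20 channel montage:", length(x$names), "channels\n")
  cat(" ", paste(x$names, collapse = " "), "\n")
  invisible(x)
}

#' Resolve channel names against a montage, case-insensitively
#'
#' @param names character vector of channel labels.
#' @param montage a [halt_montage()] object.
#' @return integer vector of 1-based montage positions.
#' @keywords internal
montage_match <- function(names, montage) {
  idx <- match(tolower(names), tolower(montage$names))
  if (anyNA(idx)) {
    stop("unknown channel name(s): ",
         paste(names[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Six motor-imagery classes of the HaLT paradigm
#'
#' Marker codes 1-6 in the recordings map, in paradigm order, to the six
#' mental-imagery states: left hand, right hand, passive, left leg, tongue,
#' right leg.
#'
#' @return A named integer vector: names are task labels, values the codes.
#' @examples
#' mi_classes()
#' @export
mi_classes <- function() {
  stats::setNames(1:6, c("left hand", "right hand", "passive",
                         "left leg", "tongue", "right leg"))
}

#' @rdname mi_classes
#' @param code integer vector of class codes in 1..6.
#' @return `mi_class_name()`: character vector of task labels.
#' @export
mi_class_name <- function(code) {
  stopifnot(all(code %in% 1:6))
  names(mi_classes())[code]
}
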