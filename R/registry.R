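#' Registry of the 21 postcranial osteometric variables
#'
#' Returns the canonical variable registry used throughout the package: one
#' row per measurable variable, with the machine-readable column name used in
#' measurement tables, the display name used in osteometric reporting, the
#' anatomical element, whether the variable is modelled on the natural-log
#' scale, and whether it participates in sex prediction.
#'
#' All measurements are linear distances in millimetres, taken on fully
#' calcined (white-burned) bone. Two variables are log-transformed before
#' modelling because their raw distributions are right-skewed (the
#' mediolateral head width of the first metatarsal and the transverse
#' diameter of the axis); two variables (axis transverse diameter, talus
#' head-neck length) show no significant sexual dimorphism in the reference
#' sample and are therefore accepted as input but excluded from prediction,
#' leaving 19 predictive variables.
#'
#' @param x Optional character vector of variable names (canonical or display
#'   form) to resolve; if supplied, the matching registry rows are returned
#'   and unknown names raise an error.
#' @return A data frame with columns `name`, `display`, `element`, `letter`
#'   (the conventional A-U measurement-diagram label), `log_transform`,
#'   `included_in_model`, and `units`.
#' @examples
#' reg <- variable_registry()
#' nrow(reg)                      # 21
#' sum(reg$included_in_model)     # 19
#' @export
variable_registry <- function(x = NULL) {
  reg <- data.frame(
    name = c(
      "axis_ap_diameter",
      "axis_transverse_diameter",
      "mandible_condyle_width",
      "radius_max_head_diameter",
      "humerus_vert_head_diameter",
      "humerus_capitulum_max_diameter",
      "humerus_trochlea_min_diameter",
      "humerus_trochlea_max_diameter",
      "lunate_max_width",
      "lunate_max_length",
      "femur_vert_head_diameter",
      "patella_max_width",
      "patella_max_height",
      "patella_max_thickness",
      "talus_max_length",
      "talus_head_neck_length",
      "talus_trochlea_length",
      "talus_trochlea_width",
      "navicular_max_length",
      "mt1_dorsoplantar_head_width",
      "mt1_mediolateral_head_width"
    ),
    display = c(
      "Axis: anterior-posterior diameter",
      "Axis: transverse diameter",
      "Mandible: condyle width",
      "Radius: maximum head diameter",
      "Humerus: vertical head diameter",
      "Humerus: capitulum maximum diameter",
      "Humerus: trochlea minimum diameter",
      "Humerus: trochlea maximum diameter",
      "Lunate: maximum width",
      "Lunate: maximum length",
      "Femur: vertical head diameter",
      "Patella: maximum width",
      "Patella: maximum height",
      "Patella: maximum thickness",
      "Talus: maximum length",
      "Talus: head-neck length",
      "Talus: trochlea length",
      "Talus: trochlea width",
      "Navicular: maximum length",
      "MT1: dorsoplantar width of the head",
      "MT1: mediolateral width of the head"
    ),
    element = c(
      "axis", "axis", "mandible", "radius", "humerus", "humerus",
      "humerus", "humerus", "lunate", "lunate", "femur", "patella",
      "patella", "patella", "talus", "talus", "talus", "talus",
      "navicular", "first metatarsal", "first metatarsal"
    ),
    letter = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K",
               "L", "M", "N", "O", "P", "Q", "R", "S", "T", "U"),
    log_transform = FALSE,
    included_in_model = TRUE,
    units = "mm",
    stringsAsFactors = FALSE
  )
  reg$log_transform[reg$name %in%
    c("mt1_mediolateral_head_width", "axis_transverse_diameter")] <- TRUE
  reg$included_in_model[reg$name %in%
    c("axis_transverse_diameter", "talus_head_neck_length")] <- FALSE
  stopifnot(!anyDuplicated(reg$name), nrow(reg) == 21L)
  if (is.null(x)) {
    return(reg)
  }
  idx <- match(x, reg$name)
  miss <- is.na(idx)
  idx[miss] <- match(x[miss], reg$display)
  if (anyNA(idx)) {
    stop("unknown variable name(s): ",
         paste(x[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  reg[idx, , drop = FALSE]
}

# model-scale transform for one registry row applied to raw mm values
.to_model_scale <- function(x, log_transform) {
  if (log_transform) {
    if (any(x <= 0, na.rm = TRUE)) {
      stop("non-positive measurement for a log-transformed variable",
           call. = FALSE)
    }
    log(x)
  } else {
    x
  }
}
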