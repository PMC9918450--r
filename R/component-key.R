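#' Identify one trajectory component
#'
#' A component key addresses a single scalar trajectory within a gait
#' dataset: one measure (joint moments or kinematics) of one joint of one
#' limb, along one anatomical dimension, recorded under one condition.
#' Dimension semantics follow the usual joint coordinate-system ordering
#' with the positive direction named first (e.g. knee X = extension(+)
#' / flexion(-)).
#'
#' Any field may be `NA` to form a pattern that matches several components
#' (used for sign-flip sets and injected synthetic effects); fully specified
#' keys are required wherever a concrete component is addressed.
#'
#' @param measure `"moments"` (Nm/kg after body-weight scaling) or
#'   `"kinematics"` (degrees).
#' @param limb `"left"` or `"right"`.
#' @param joint `"hip"`, `"knee"` or `"ankle"`.
#' @param dimension `"X"`, `"Y"` or `"Z"`.
#' @param condition `"reference"`, `"pre"` or `"post"`.
#' @return An object of class `"component_key"`.
#' @examples
#' component_key("moments", "right", "knee", "X", "pre")
#' # pattern matching every left-limb component:
#' component_key(limb = "left")
#' @export
component_key <- function(measure = NA, limb = NA, joint = NA,
                          dimension = NA, condition = NA) {
  chk <- function(x, allowed, what) {
    if (length(x) != 1L) stop(sprintf("'%s' must be a single value", what))
    if (is.na(x)) return(NA_character_)
    x <- as.character(x)
    if (!x %in% allowed)
      stop(sprintf("invalid %s '%s' (must be one of %s)", what, x,
                   paste(allowed, collapse = ", ")))
    x
  }
  key <- list(
    measure   = chk(measure, c("moments", "kinematics"), "measure"),
    limb      = chk(limb, c("left", "right"), "limb"),
    joint     = chk(joint, c("hip", "knee", "ankle"), "joint"),
    dimension = chk(dimension, c("X", "Y", "Z"), "dimension"),
    condition = chk(condition, c("reference", "pre", "post"), "condition")
  )
  structure(key, class = "component_key")
}

#' @export
format.component_key <- function(x, ...) {
  f <- vapply(x, function(v) if (is.na(v)) "*" else v, character(1))
  paste(f[c("condition", "measure", "limb", "joint", "dimension")],
        collapse = "/")
}

#' @export
print.component_key <- function(x, ...) {
  cat("<component>", format(x), "\n")
  invisible(x)
}

#' Test a component key against a pattern
#'
#' A pattern is a [component_key()] whose `NA` fields act as wildcards.
#'
#' @param key fully (or partially) specified `component_key`.
#' @param pattern `component_key` pattern, or a list of patterns (matched if
#'   any pattern matches).
#' @return Logical scalar.
#' @export
key_matches <- function(key, pattern) {
  if (is.null(pattern) || length(pattern) == 0L) return(FALSE)
  if (inherits(pattern, "component_key")) pattern <- list(pattern)
  one <- function(p) {
    all(vapply(names(p), function(f) {
      is.na(p[[f]]) || identical(p[[f]], key[[f]])
    }, logical(1)))
  }
  any(vapply(pattern, one, logical(1)))
}

# canonical string id used as list name inside a gait_dataset
key_id <- function(key) {
  paste(key$condition, key$measure, key$limb, key$joint, key$dimension,
        sep = "_")
}

MEASURES   <- c("moments", "kinematics")
LIMBS      <- c("left", "right")
JOINTS     <- c("hip", "knee", "ankle")
DIMENSIONS <- c("X", "Y", "Z")
CONDITIONS <- c("reference", "pre", "post")

# positive-direction-first labels per joint dimension (lower limb,
# joint coordinate-system convention)
DIMENSION_LABELS <- list(
  hip   = c(X = "Ext./Flexion", Y = "Abd./Adduction", Z = "Ext./Int. Rotation"),
  knee  = c(X = "Ext./Flexion", Y = "Abd./Adduction", Z = "Ext./Int. Rotation"),
  ankle = c(X = "Plantar./Dorsiflexion", Y = "Abd./Adduction",
            Z = "Eve./Inversion")
)
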