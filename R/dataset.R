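#' File naming scheme for gait dataset directories
#'
#' Maps between component keys and file names. The default scheme stores one
#' component per file as `{condition}_{measure}_{limb}_{joint}_{dimension}.csv`
#' (e.g. `pre_moments_right_knee_X.csv`), all in one directory. A scheme is a
#' list of two functions so laboratories with their own layouts can plug in
#' an alternative:
#' \describe{
#'   \item{`filename(key)`}{relative path for a fully specified key.}
#'   \item{`parse(relpath)`}{a `component_key` for a relative path, or `NULL`
#'     if the path does not belong to the scheme.}
#' }
#'
#' @return A list with elements `filename` and `parse`.
#' @export
default_naming <- function() {
  list(
    filename = function(key) paste0(key_id(key), ".csv"),
    parse = function(relpath) {
      base <- sub("\\.csv$", "", basename(relpath), ignore.case = TRUE)
      parts <- strsplit(base, "_", fixed = TRUE)[[1L]]
      if (length(parts) != 5L) return(NULL)
      ok <- parts[1L] %in% CONDITIONS && parts[2L] %in% MEASURES &&
        parts[3L] %in% LIMBS && parts[4L] %in% JOINTS &&
        parts[5L] %in% DIMENSIONS
      if (!ok) return(NULL)
      component_key(measure = parts[2L], limb = parts[3L], joint = parts[4L],
                    dimension = parts[5L], condition = parts[1L])
    }
  )
}

#' Load a hierarchical gait dataset from a directory
#'
#' Every file under `root` that the naming scheme recognises is read with
#' [read_trajectory_csv()] and stored under its component key. Components
#' with no file are simply absent — a dataset with arbitrarily many missing
#' components loads without error, and analyses later skip what is not
#' there. Files that the scheme recognises but that fail to parse are
#' skipped with a warning rather than aborting the load.
#'
#' @param root directory containing trajectory CSV files (searched
#'   recursively).
#' @param naming a naming scheme, see [default_naming()].
#' @return Object of class `"gait_dataset"`: a list with `components`
#'   (named list of [trajectory_set()]s keyed by
#'   `condition_measure_limb_joint_dimension`) and `conditions_present`.
#' @export
load_gait_dataset <- function(root, naming = default_naming()) {
  if (!dir.exists(root)) stop(sprintf("'%s' is not a directory", root))
  files <- list.files(root, recursive = TRUE, full.names = FALSE)
  components <- list()
  for (f in files) {
    key <- naming$parse(f)
    if (is.null(key)) next
    ts <- tryCatch(read_trajectory_csv(file.path(root, f), meta = key),
                   error = function(e) {
                     warning(sprintf("skipping '%s': %s", f,
                                     conditionMessage(e)), call. = FALSE)
                     NULL
                   })
    if (!is.null(ts)) components[[key_id(key)]] <- ts
  }
  if (length(components) == 0L)
    warning(sprintf("no trajectory files recognised under '%s'; dataset is empty",
                    root), call. = FALSE)
  gait_dataset(components)
}

#' Construct a gait dataset from trajectory sets
#'
#' @param components named list of [trajectory_set()]s, each carrying a
#'   fully specified `meta` key (names are recomputed from the keys).
#' @return A `"gait_dataset"`.
#' @export
gait_dataset <- function(components = list()) {
  if (length(components)) {
    stopifnot(all(vapply(components, inherits, logical(1), "trajectory_set")))
    names(components) <- vapply(components, function(ts) key_id(ts$meta),
                                character(1))
  }
  conds <- unique(vapply(components, function(ts) ts$meta$condition,
                         character(1)))
  structure(list(
    components = components,
    conditions_present = intersect(CONDITIONS, conds)
  ), class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("<gait_dataset> %d components; conditions: %s\n",
              length(x$components),
              if (length(x$conditions_present))
                paste(x$conditions_present, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Query one component of a gait dataset
#'
#' @param data a `"gait_dataset"`.
#' @param key fully specified [component_key()].
#' @return The [trajectory_set()], or `NULL` when the component is absent
#'   (absence is an ordinary queryable state, not an error).
#' @export
get_component <- function(data, key) {
  stopifnot(inherits(data, "gait_dataset"))
  data$components[[key_id(key)]]
}

#' @rdname get_component
#' @export
has_component <- function(data, key) !is.null(get_component(data, key))

#' Dimensions of one joint present in a dataset
#'
#' @inheritParams get_component
#' @param condition,measure,limb,joint enum values, see [component_key()].
#' @return Character vector, subset of `c("X","Y","Z")`.
#' @export
joint_dimensions <- function(data, condition, measure, limb, joint) {
  present <- vapply(DIMENSIONS, function(d)
    has_component(data, component_key(measure, limb, joint, d, condition)),
    logical(1))
  DIMENSIONS[present]
}

#' Assemble the multivariate trial array for one joint
#'
#' Stacks the requested dimensions of one joint/condition into a
#' trials x nodes x p array (a joint rotation-vector sample). All stacked
#' dimensions must agree in trial count and node count.
#'
#' @inheritParams joint_dimensions
#' @param dimensions which dimensions to stack; defaults to all present.
#' @return Object of class `"joint_vector_set"`: list with `values`
#'   (3D array), `dimensions`, `n_trials`, `node_count`, `p` and the
#'   identifying fields.
#' @export
joint_vector_set <- function(data, condition, measure, limb, joint,
                             dimensions = NULL) {
  if (is.null(dimensions))
    dimensions <- joint_dimensions(data, condition, measure, limb, joint)
  if (length(dimensions) == 0L)
    stop(sprintf("no dimensions of %s %s %s (%s) present", limb, joint,
                 measure, condition))
  sets <- lapply(dimensions, function(d)
    get_component(data, component_key(measure, limb, joint, d, condition)))
  n <- unique(vapply(sets, function(s) s$n_trials, integer(1)))
  q <- unique(vapply(sets, function(s) s$node_count, integer(1)))
  if (length(n) != 1L || length(q) != 1L)
    stop(sprintf(
      "dimensions of %s %s %s (%s) disagree in shape (trials: %s; nodes: %s)",
      limb, joint, measure, condition, paste(n, collapse = "/"),
      paste(q, collapse = "/")))
  arr <- array(NA_real_, dim = c(n, q, length(dimensions)),
               dimnames = list(NULL, NULL, dimensions))
  for (i in seq_along(sets)) arr[, , i] <- sets[[i]]$values
  structure(list(values = arr, dimensions = dimensions, n_trials = n,
                 node_count = q, p = length(dimensions),
                 condition = condition, measure = measure, limb = limb,
                 joint = joint),
            class = "joint_vector_set")
}
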