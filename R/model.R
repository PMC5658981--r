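# Domain types: value trees, attributes, options, performance tables.

#' Define a criterion attribute
#'
#' An attribute is a leaf of the value tree: a measurable dimension of
#' value with a preference direction and two reference levels anchoring
#' its 0/100 value scale.  Performances worse than the lower reference
#' score below 0; better than the higher reference, above 100.
#'
#' @param id Unique attribute id.
#' @param name Human-readable name.
#' @param cluster Id of the value cluster the attribute belongs to.
#' @param metric Description of the metric.
#' @param units Measurement units ("" for ordinal labels).
#' @param scale One of `"continuous"`, `"ordinal"`, `"binary"`.
#' @param direction `"increasing"` if larger performances are preferred,
#'   `"decreasing"` otherwise.  Ordinal/binary levels are always listed
#'   from least to most preferred, so their direction is `"increasing"`
#'   by level index.
#' @param range Numeric `c(min, max)` for continuous attributes.
#' @param levels Ordered character vector of levels (least preferred
#'   first) for ordinal/binary attributes.
#' @param lower_ref,higher_ref Reference levels `x_l` (value 0) and `x_h`
#'   (value 100): numbers for continuous attributes, level labels
#'   otherwise.
#' @return Object of class `"mavt_attribute"`.
#' @export
mavt_attribute <- function(id, name = id, cluster, metric = "", units = "",
                           scale = c("continuous", "ordinal", "binary"),
                           direction = c("increasing", "decreasing"),
                           range = NULL, levels = NULL,
                           lower_ref, higher_ref) {
  scale <- match.arg(scale)
  direction <- match.arg(direction)
  structure(list(
    id = as.character(id), name = as.character(name),
    cluster = as.character(cluster), metric = metric, units = units,
    scale = scale, direction = direction,
    range = if (!is.null(range)) as.numeric(range),
    levels = if (!is.null(levels)) as.character(levels),
    lower_ref = lower_ref, higher_ref = higher_ref
  ), class = "mavt_attribute")
}

#' @export
print.mavt_attribute <- function(x, ...) {
  cat(sprintf("<attribute %s> %s [%s, %s]\n", x$id, x$name, x$scale,
              x$direction))
  if (x$scale == "continuous")
    cat(sprintf("  range [%g, %g], refs x_l=%g (0) x_h=%g (100) %s\n",
                x$range[1], x$range[2], x$lower_ref, x$higher_ref, x$units))
  else
    cat(sprintf("  levels: %s; refs x_l='%s' x_h='%s'\n",
                paste(x$levels, collapse = " < "), x$lower_ref, x$higher_ref))
  invisible(x)
}

#' Define a value tree
#'
#' One layer of value clusters, each holding a set of leaf attributes.
#'
#' @param clusters Named list: `cluster id -> character vector of
#'   attribute ids` (or `list(name =, attributes =)`).
#' @param root Name of the root node.
#' @return Object of class `"mavt_tree"`.
#' @export
value_tree <- function(clusters, root = "overall value") {
  cl <- lapply(seq_along(clusters), function(i) {
    x <- clusters[[i]]
    id <- names(clusters)[i]
    if (is.character(x)) list(id = id, name = id, attributes = x)
    else list(id = id, name = if (is.null(x$name)) id else x$name,
              attributes = as.character(x$attributes))
  })
  names(cl) <- names(clusters)
  structure(list(root = root, clusters = cl), class = "mavt_tree")
}

#' @export
print.mavt_tree <- function(x, ...) {
  cat("<value tree>", x$root, "\n")
  for (cl in x$clusters)
    cat(sprintf("  %s (%s): %s\n", cl$id, cl$name,
                paste(cl$attributes, collapse = ", ")))
  invisible(x)
}

#' Assemble a value model
#'
#' @param tree A [value_tree()].
#' @param attributes List of [mavt_attribute()] objects.
#' @param value_functions Optional named list of [value_function()]s.
#' @param weights Optional weights (see [normalize_weights()]).
#' @param name Model name.
#' @return Object of class `"mavt_model"`.
#' @export
mavt_model <- function(tree, attributes, value_functions = NULL,
                       weights = NULL, name = "value model") {
  ids <- vapply(attributes, `[[`, "", "id")
  names(attributes) <- ids
  structure(list(name = name, tree = tree, attributes = attributes,
                 value_functions = value_functions, weights = weights),
            class = "mavt_model")
}

#' @export
print.mavt_model <- function(x, ...) {
  cat("<mavt model>", x$name, "-", length(x$attributes), "attributes,",
      length(x$tree$clusters), "clusters\n")
  invisible(x)
}

new_validation <- function(violations) {
  structure(list(valid = nrow(violations) == 0L, violations = violations),
            class = "mavt_validation")
}

violation <- function(code, message) data.frame(code = code, message = message)

#' @export
print.mavt_validation <- function(x, ...) {
  cat("validation:", if (x$valid) "pass" else "FAIL", "\n")
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}

#' Validate a value model's structure
#'
#' Checks the tree/attribute invariants: unique ids, every attribute in
#' exactly one cluster, non-degenerate reference intervals inside the
#' attribute range, reference levels improving in the stated preference
#' direction, explicit level lists for ordinal attributes (exactly two
#' for binary).  Violations are report entries, never exceptions, so a
#' model can be inspected incrementally.
#'
#' @param model A [mavt_model()]; alternatively pass `tree` and
#'   `attributes` separately.
#' @param attributes List of [mavt_attribute()] when `model` is a tree.
#' @return Object of class `"mavt_validation"`: `valid` flag plus an
#'   itemized `violations` data frame.
#' @export
validate_model <- function(model, attributes = NULL) {
  if (inherits(model, "mavt_tree")) {
    tree <- model
    ids <- vapply(attributes, `[[`, "", "id")
    names(attributes) <- ids
  } else {
    stopifnot(inherits(model, "mavt_model"))
    tree <- model$tree
    attributes <- model$attributes
  }
  v <- list()
  add <- function(code, msg) v[[length(v) + 1L]] <<- violation(code, msg)

  leaf_ids <- unlist(lapply(tree$clusters, `[[`, "attributes"),
                     use.names = FALSE)
  cluster_ids <- vapply(tree$clusters, `[[`, "", "id")
  attr_ids <- vapply(attributes, `[[`, "", "id")

  if (anyDuplicated(attr_ids))
    add("duplicate attribute id", paste("duplicated attribute ids:",
        paste(unique(attr_ids[duplicated(attr_ids)]), collapse = ", ")))
  if (anyDuplicated(cluster_ids))
    add("duplicate cluster id", paste("duplicated cluster ids:",
        paste(unique(cluster_ids[duplicated(cluster_ids)]), collapse = ", ")))
  dup_leaf <- unique(leaf_ids[duplicated(leaf_ids)])
  if (length(dup_leaf))
    add("duplicate leaf", paste("attribute assigned to more than one cluster:",
                                paste(dup_leaf, collapse = ", ")))
  if (length(intersect(attr_ids, cluster_ids)))
    add("id collision", "attribute and cluster ids overlap")
  missing_leaf <- setdiff(attr_ids, leaf_ids)
  if (length(missing_leaf))
    add("orphan attribute", paste("attribute not placed in any cluster:",
                                  paste(missing_leaf, collapse = ", ")))
  unknown_leaf <- setdiff(leaf_ids, attr_ids)
  if (length(unknown_leaf))
    add("unknown leaf", paste("cluster references undefined attribute:",
                              paste(unknown_leaf, collapse = ", ")))
  for (a in attributes) {
    if (a$scale == "continuous") {
      if (is.null(a$range) || length(a$range) != 2 || a$range[1] >= a$range[2])
        add("bad range", paste0(a$id, ": continuous attribute needs range ",
                                "[min, max] with min < max"))
      else {
        if (a$lower_ref < a$range[1] || a$lower_ref > a$range[2] ||
            a$higher_ref < a$range[1] || a$higher_ref > a$range[2])
          add("reference outside range",
              paste0(a$id, ": reference levels must lie within the range"))
        if (isTRUE(a$lower_ref == a$higher_ref))
          add("degenerate reference interval",
              paste0(a$id, ": x_l equals x_h"))
        else {
          improving <- if (a$direction == "increasing")
            a$higher_ref > a$lower_ref else a$higher_ref < a$lower_ref
          if (!improving)
            add("references against direction",
                paste0(a$id, ": moving x_l -> x_h must be an improvement ",
                       "under direction '", a$direction, "'"))
        }
      }
    } else {
      if (is.null(a$levels) || length(a$levels) < 2)
        add("missing levels",
            paste0(a$id, ": ordinal attribute needs an ordered level list"))
      else {
        if (a$scale == "binary" && length(a$levels) != 2)
          add("binary levels", paste0(a$id, ": binary attribute needs ",
                                      "exactly two levels"))
        if (!all(c(a$lower_ref, a$higher_ref) %in% a$levels))
          add("reference outside range",
              paste0(a$id, ": reference levels must be declared levels"))
        else if (a$lower_ref == a$higher_ref)
          add("degenerate reference interval",
              paste0(a$id, ": x_l equals x_h"))
        else if (match(a$higher_ref, a$levels) < match(a$lower_ref, a$levels))
          add("references against direction",
              paste0(a$id, ": x_h must be a more preferred level than x_l"))
      }
    }
  }
  new_validation(if (length(v)) do.call(rbind, v) else
    violation(character(0), character(0))[0, ])
}

#' Validate a performance table against a model
#'
#' Completeness (every option x attribute cell present) and range checks
#' (numeric values within the attribute range, labels among the declared
#' ordinal levels).
#'
#' @param perf Data frame: first column `option`, remaining columns named
#'   by attribute id.
#' @param model A validated [mavt_model()].
#' @return A `"mavt_validation"` report.
#' @export
validate_performance <- function(perf, model) {
  stopifnot(is.data.frame(perf), inherits(model, "mavt_model"))
  v <- list()
  add <- function(code, msg) v[[length(v) + 1L]] <<- violation(code, msg)
  if (!"option" %in% names(perf)[1])
    add("format", "first column must be 'option'")
  opts <- as.character(perf$option)
  if (anyDuplicated(opts))
    add("duplicate option", paste("duplicated option ids:",
        paste(unique(opts[duplicated(opts)]), collapse = ", ")))
  attr_ids <- names(model$attributes)
  missing_cols <- setdiff(attr_ids, names(perf))
  if (length(missing_cols))
    add("incomplete", paste("missing attribute columns:",
                            paste(missing_cols, collapse = ", ")))
  extra_cols <- setdiff(names(perf), c("option", attr_ids))
  if (length(extra_cols))
    add("unknown attribute", paste("columns not in the model:",
                                   paste(extra_cols, collapse = ", ")))
  for (id in intersect(attr_ids, names(perf))) {
    a <- model$attributes[[id]]
    col <- perf[[id]]
    if (anyNA(col)) {
      add("incomplete", paste0("missing value(s) for attribute '", id,
                               "' (", paste(opts[is.na(col)], collapse = ", "),
                               ")"))
      next
    }
    if (a$scale == "continuous") {
      x <- suppressWarnings(as.numeric(col))
      if (anyNA(x)) {
        add("non-numeric", paste0(id, ": non-numeric performance"))
        next
      }
      bad <- x < a$range[1] | x > a$range[2]
      if (any(bad))
        add("out of range", paste0(id, ": performance out of range for ",
                                   paste(opts[bad], collapse = ", ")))
    } else {
      bad <- !as.character(col) %in% a$levels
      if (any(bad))
        add("unknown level", paste0(id, ": undeclared level for ",
                                    paste(opts[bad], collapse = ", ")))
    }
  }
  new_validation(if (length(v)) do.call(rbind, v) else
    violation(character(0), character(0))[0, ])
}

#' Cluster membership lookup
#'
#' @param tree A [value_tree()].
#' @return Named character vector mapping attribute id to cluster id.
#' @export
cluster_of <- function(tree) {
  out <- character(0)
  for (cl in tree$clusters)
    out[cl$attributes] <- cl$id
  out
}
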