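# Model serialization (JSON), performance tables (CSV), and the
# end-to-end evaluation pipeline.

input_error <- function(msg) {
  structure(class = c("mavt_input_error", "error", "condition"),
            list(message = msg, call = NULL))
}

model_schema_id <- "mavt-model/1"

#' Write a value model to JSON
#'
#' Canonical field ordering, so serialize -> parse -> serialize round
#' trips byte-identically for any valid model.
#'
#' @param model An [mavt_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "mavt_model"))
  doc <- list(
    schema = model_schema_id,
    name = model$name,
    tree = list(
      root = model$tree$root,
      clusters = lapply(unname(model$tree$clusters), function(cl)
        list(id = cl$id, name = cl$name, attributes = as.list(cl$attributes)))
    ),
    attributes = lapply(unname(model$attributes), function(a) {
      out <- list(id = a$id, name = a$name, cluster = a$cluster,
                  metric = a$metric, units = a$units, scale = a$scale,
                  direction = a$direction)
      if (a$scale == "continuous") out$range <- a$range
      else out$levels <- as.list(a$levels)
      out$lower_ref <- a$lower_ref
      out$higher_ref <- a$higher_ref
      out
    }),
    value_functions = lapply(unname(model$value_functions), function(vf) {
      if (vf$scale == "continuous")
        list(attribute = vf$attribute, type = "piecewise_linear",
             anchors = lapply(seq_len(nrow(vf$anchors)), function(i)
               c(vf$anchors$x[i], vf$anchors$v[i])))
      else
        list(attribute = vf$attribute, type = "level_lookup",
             scores = as.list(vf$scores))
    }),
    weights = lapply(model$weights, as.list)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read a value model from JSON
#'
#' Validates the document structure on load; malformed documents raise a
#' condition of class `"mavt_input_error"`.
#'
#' @param path Path to a model JSON written by [write_model()] (schema
#'   `mavt-model/1`).
#' @return An [mavt_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path))
    stop(input_error(paste0("model file not found: ", path)))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop(input_error(paste0("malformed model JSON: ",
                                            conditionMessage(e)))))
  for (field in c("schema", "tree", "attributes"))
    if (is.null(doc[[field]]))
      stop(input_error(paste0("model JSON missing required section '",
                              field, "'")))
  if (!identical(doc$schema, model_schema_id))
    stop(input_error(paste0("unsupported model schema '", doc$schema, "'")))
  clusters <- stats::setNames(
    lapply(doc$tree$clusters, function(cl)
      list(name = cl$name, attributes = unlist(cl$attributes))),
    vapply(doc$tree$clusters, `[[`, "", "id"))
  tree <- value_tree(clusters, root = doc$tree$root)
  attributes <- lapply(doc$attributes, function(a) {
    for (field in c("id", "cluster", "scale", "direction",
                    "lower_ref", "higher_ref"))
      if (is.null(a[[field]]))
        stop(input_error(paste0("attribute entry missing field '", field,
                                "'")))
    mavt_attribute(a$id, a$name, a$cluster, metric = a$metric %||% "",
                   units = a$units %||% "", scale = a$scale,
                   direction = a$direction,
                   range = if (!is.null(a$range)) unlist(a$range),
                   levels = if (!is.null(a$levels)) unlist(a$levels),
                   lower_ref = a$lower_ref, higher_ref = a$higher_ref)
  })
  names(attributes) <- vapply(attributes, `[[`, "", "id")
  vfs <- NULL
  if (length(doc$value_functions)) {
    vfs <- lapply(doc$value_functions, function(v) {
      a <- attributes[[v$attribute]]
      if (is.null(a))
        stop(input_error(paste0("value function for unknown attribute '",
                                v$attribute, "'")))
      if (identical(v$type, "piecewise_linear")) {
        pts <- do.call(rbind, lapply(v$anchors, unlist))
        value_function(a, data.frame(x = pts[, 1], v = pts[, 2]))
      } else {
        value_function(a, unlist(v$scores))
      }
    })
    names(vfs) <- vapply(vfs, `[[`, "", "attribute")
  }
  weights <- NULL
  if (length(doc$weights))
    weights <- lapply(doc$weights, function(w)
      stats::setNames(as.numeric(unlist(w)), names(w)))
  mavt_model(tree, attributes, value_functions = vfs, weights = weights,
             name = doc$name %||% "value model")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read a performance table from CSV
#'
#' First column `option`, remaining columns named by attribute id, header
#' row mandatory.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_performance <- function(path) {
  if (!file.exists(path))
    stop(input_error(paste0("performance file not found: ", path)))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "option")
    stop(input_error("performance CSV must start with an 'option' column"))
  df
}

#' Run the full evaluation pipeline
#'
#' validate -> score -> weight -> aggregate -> sensitivity -> efficiency.
#' Writes a published-table-style score report, a sensitivity CSV, an
#' efficiency CSV and a JSON summary into `out_dir`; identical inputs and
#' configuration produce byte-identical bundles.  Any validation failure
#' raises a condition of class `"mavt_input_error"` before any output is
#' written.
#'
#' @param model [mavt_model()] or path to a model JSON.
#' @param performance Performance data frame or CSV path.
#' @param costs Optional named list of [cost_profile()]s or costs CSV
#'   path.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   file output.
#' @param weight_set Name of the weight set in the model to use (default:
#'   first).
#' @param delta_points Perturbation size for the robustness check
#'   (default 5 value points).
#' @param verbose Log stages and input hashes to stderr.
#' @return Invisibly, a list bundle: evaluation, sensitivity report,
#'   robustness margin, perturbation check, efficiency table, file paths.
#' @export
run_pipeline <- function(model, performance, costs = NULL, out_dir = NULL,
                         weight_set = NULL, delta_points = 5,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[mavtkit] ", ...)
  hash <- function(p) unname(tools::md5sum(p))
  if (is.character(model)) {
    say("reading model ", model, " (md5 ", hash(model), ")")
    model <- read_model(model)
  }
  if (is.character(performance)) {
    say("reading performance table ", performance,
        " (md5 ", hash(performance), ")")
    performance <- read_performance(performance)
  }
  if (is.character(costs)) {
    say("reading costs ", costs, " (md5 ", hash(costs), ")")
    costs <- read_costs(costs)
  }

  vm <- validate_model(model)
  if (!vm$valid)
    stop(input_error(paste0("model validation failed: ",
                            paste(vm$violations$message, collapse = "; "))))
  vp <- validate_performance(performance, model)
  if (!vp$valid)
    stop(input_error(paste0("performance validation failed: ",
                            paste(vp$violations$message, collapse = "; "))))
  if (is.null(model$value_functions))
    stop(input_error("model carries no value functions"))
  if (is.null(model$weights) || !length(model$weights))
    stop(input_error("model carries no weights"))
  if (is.null(weight_set)) weight_set <- names(model$weights)[1]
  if (!weight_set %in% names(model$weights))
    stop(input_error(paste0("unknown weight set '", weight_set, "'")))

  say("scoring ", nrow(performance), " options on ",
      length(model$attributes), " attributes")
  scores <- score_table(performance, model$value_functions)
  w <- normalize_weights(model$weights[[weight_set]])
  ev <- overall_value(scores, w)
  say("ranking: ", paste(ev$ranking$option, collapse = " > "))

  sens <- one_way_report(scores, w)
  margin <- robustness_margin(sens)
  pert <- reference_perturbation_check(scores, w, delta_points)
  cw <- cluster_weights(w, model$tree)

  eff <- NULL
  if (!is.null(costs)) {
    vals <- round(ev$values, 1)  # ratios at the reporting precision
    eff <- frontier(costs, vals)
    eff$cost_per_value_unit <- vapply(seq_len(nrow(eff)), function(i)
      cost_per_value_unit(eff$cost[i], eff$value[i]), numeric(1))
  }

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      scores = file.path(out_dir, "scores.csv"),
      sensitivity = file.path(out_dir, "sensitivity.csv"),
      efficiency = if (!is.null(eff)) file.path(out_dir, "efficiency.csv"),
      summary = file.path(out_dir, "summary.json"))
    write_score_report(ev, model, w, paths$scores)
    write_sensitivity_report(sens, paths$sensitivity)
    if (!is.null(eff))
      utils::write.csv(fmt_df(eff), paths$efficiency, row.names = FALSE)
    summary <- list(
      model = model$name,
      weight_set = weight_set,
      overall = as.list(round(ev$values, 4)),
      ranking = ev$ranking$option,
      cluster_weights = as.list(round(100 * cw, 1)),
      robustness_margin = round(margin, 4),
      perturbation_stable = pert$stable,
      efficient_options =
        if (!is.null(eff)) eff$option[eff$efficient] else NULL)
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = 2,
                                digits = NA),
               paths$summary)
    say("report bundle written to ", out_dir)
  }

  invisible(list(model = model, scores = scores, weights = w,
                 evaluation = ev, cluster_weights = cw,
                 sensitivity = sens, robustness_margin = margin,
                 perturbation = pert, efficiency = eff, paths = paths))
}

fmt_num <- function(x, digits = 1) formatC(x, format = "f", digits = digits)

fmt_df <- function(df, digits = 1) {
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- fmt_num(df[[nm]], digits)
  df
}

# Published-table layout: rows = overall + attributes; columns = lower
# reference (0), options, higher reference (100), relative weight.
write_score_report <- function(ev, model, w, path) {
  opts <- rownames(ev$scores)
  rows <- data.frame(attribute = "Overall WPV score",
                     lower_ref = fmt_num(0))
  for (o in opts) rows[[o]] <- fmt_num(ev$values[[o]])
  rows$higher_ref <- fmt_num(100)
  rows$weight <- fmt_num(100)
  for (a in colnames(ev$scores)) {
    r <- data.frame(attribute = model$attributes[[a]]$name,
                    lower_ref = fmt_num(0))
    for (o in opts) r[[o]] <- fmt_num(ev$scores[o, a])
    r$higher_ref <- fmt_num(100)
    r$weight <- fmt_num(100 * w[[a]])
    rows <- rbind(rows, r)
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

write_sensitivity_report <- function(sens, path) {
  df <- as.data.frame(sens)
  df$w0 <- fmt_num(100 * df$w0)
  df$w_star <- ifelse(is.na(df$w_star), "",
                      fmt_num(100 * df$w_star))
  df$direction[is.na(df$direction)] <- "none"
  df$rel_change <- ifelse(is.na(df$rel_change), "",
                          fmt_num(df$rel_change, 3))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
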