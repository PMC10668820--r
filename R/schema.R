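#' Calculator schemas
#'
#' A calculator schema declares the ten management indices, their checklist
#' factors, each factor's point weight, and how its checklist response is
#' graded.  The schema is data, not code: the packaged default encodes the
#' published ten-index calculator with an equal split of each index's 10
#' points across its factors, and users may supply their own schema file
#' (for example with expert-elicited weights) without any code change.
#'
#' Response kinds:
#' \describe{
#'   \item{binary}{presence/absence of a good practice; credit 0 or 1.}
#'   \item{categorical}{ordered options, worst first; each option carries a
#'     credit fraction in \[0, 1\], non-decreasing, with first 0 and last 1.}
#'   \item{numeric_threshold}{a measured quantity compared (inclusively)
#'     against a threshold in stated units, e.g. water flow >= 1 L/min,
#'     drinkers per piglet >= 0.1, or floor area >= 0.1 m2 per 10 kg
#'     live weight.}
#' }
#'
#' @name qsc_schema
#' @rdname qsc_schema
NULL

SCHEMA_KEYS <- list(
  top      = c("version", "indices"),
  index    = c("id", "name", "slug", "level", "factors"),
  factor   = c("id", "text", "weight", "response"),
  response = c("kind", "options", "threshold", "direction", "units"),
  option   = c("label", "credit")
)

new_schema <- function(version, indices) {
  structure(list(version = version, indices = indices), class = "qsc_schema")
}

check_unknown_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    abort(sprintf("Unknown field%s in %s: %s",
                  if (length(extra) > 1) "s" else "", where,
                  paste(extra, collapse = ", ")),
          class = "qsc_format_error")
  }
}

#' Read a calculator schema from a YAML file
#'
#' Parses and validates a schema document.  If every factor of an index omits
#' `weight`, the index's 10 points are split equally across its factors;
#' mixing explicit and omitted weights within one index is an error.  Unknown
#' fields anywhere in the document are rejected (fail-fast against checklist
#' typos).
#'
#' @param path Path to a schema YAML file.
#' @param validate If `TRUE` (default), run [validate_schema()] and abort
#'   listing every violation.
#' @return A `qsc_schema` object.
#' @seealso [default_schema()], [validate_schema()], [write_schema()]
#' @export
#' @examples
#' sch <- default_schema()
#' schema_factors(sch)
read_schema <- function(path, validate = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("Schema file not found: %s", path), class = "qsc_format_error")
  }
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) abort(sprintf("Schema parse failure in %s: %s",
                                      path, conditionMessage(e)),
                              class = "qsc_format_error")
  )
  schema <- parse_schema_doc(doc)
  if (validate) {
    report <- validate_schema(schema)
    if (nrow(report) > 0) {
      abort(paste0("Invalid schema:\n",
                   paste0("- ", report$message, collapse = "\n")),
            class = "qsc_validation_error")
    }
  }
  schema
}

parse_schema_doc <- function(doc) {
  if (!is.list(doc)) abort("Schema document must be a mapping", class = "qsc_format_error")
  check_unknown_keys(doc, SCHEMA_KEYS$top, "schema document")
  if (is.null(doc$indices) || !is.list(doc$indices)) {
    abort("Schema document must contain an `indices` list", class = "qsc_format_error")
  }
  indices <- lapply(seq_along(doc$indices), function(i) {
    idx <- doc$indices[[i]]
    where <- sprintf("index %s", idx$id %||% i)
    check_unknown_keys(idx, SCHEMA_KEYS$index, where)
    for (fld in c("id", "name", "level", "factors")) {
      if (is.null(idx[[fld]])) {
        abort(sprintf("Missing field `%s` in %s", fld, where), class = "qsc_format_error")
      }
    }
    idx$slug <- idx$slug %||% paste0("index_", idx$id)
    has_weight <- vapply(idx$factors, function(f) !is.null(f$weight), logical(1))
    if (any(has_weight) && !all(has_weight)) {
      abort(sprintf("%s mixes explicit and omitted factor weights", where),
            class = "qsc_format_error")
    }
    idx$factors <- lapply(idx$factors, function(f) {
      fwhere <- sprintf("%s, factor %s", where, f$id %||% "?")
      check_unknown_keys(f, SCHEMA_KEYS$factor, fwhere)
      for (fld in c("id", "text", "response")) {
        if (is.null(f[[fld]])) {
          abort(sprintf("Missing field `%s` in %s", fld, fwhere),
                class = "qsc_format_error")
        }
      }
      check_unknown_keys(f$response, SCHEMA_KEYS$response, fwhere)
      if (identical(f$response$kind, "categorical")) {
        f$response$options <- lapply(f$response$options, function(o) {
          check_unknown_keys(o, SCHEMA_KEYS$option, fwhere)
          o$label <- as.character(o$label)
          o
        })
      }
      if (is.null(f$weight)) f$weight <- 10 / length(idx$factors)
      f
    })
    idx
  })
  new_schema(version = as.character(doc$version %||% "1.0"), indices = indices)
}

#' Validate a calculator schema
#'
#' Checks every structural invariant of the calculator: exactly 10 indices
#' with complete ids 1..10; per-index factor counts between 3 and 8; strictly
#' positive factor weights summing to exactly 10 points per index (so a
#' perfectly managed farm totals 100); room-level evaluation for indices
#' 8-10 (temperature, ventilation, floor/density) and farm-level for the
#' rest; well-formed response specifications.
#'
#' Violations are returned as data, not thrown: an empty report means the
#' schema is valid.
#'
#' @param schema A `qsc_schema` object.
#' @return A tibble with columns `index_id`, `factor_id`, `rule`, `message`;
#'   zero rows iff the schema is valid.
#' @export
validate_schema <- function(schema) {
  stopifnot(inherits(schema, "qsc_schema"))
  v <- list()
  bad <- function(index_id, factor_id, rule, message) {
    tibble(index_id = as.character(index_id %||% NA),
           factor_id = as.character(factor_id %||% NA),
           rule = rule, message = message)
  }
  idx_ids <- vapply(schema$indices, function(i) as.numeric(i$id), numeric(1))
  if (length(schema$indices) != 10) {
    v <- c(v, list(bad(NA, NA, "index_count",
                       sprintf("expected 10 indices, found %d", length(schema$indices)))))
  }
  if (anyDuplicated(idx_ids)) {
    v <- c(v, list(bad(NA, NA, "index_ids_unique", "index ids are not unique")))
  } else if (length(schema$indices) == 10 && !setequal(idx_ids, 1:10)) {
    v <- c(v, list(bad(NA, NA, "index_ids_complete", "index ids must be exactly 1..10")))
  }
  slugs <- vapply(schema$indices, function(i) as.character(i$slug), character(1))
  if (anyDuplicated(slugs)) {
    v <- c(v, list(bad(NA, NA, "index_slugs_unique", "index slugs are not unique")))
  }
  all_fids <- unlist(lapply(schema$indices, function(i)
    vapply(i$factors, function(f) as.character(f$id), character(1))))
  dup_fids <- unique(all_fids[duplicated(all_fids)])
  for (fid in dup_fids) {
    v <- c(v, list(bad(NA, fid, "factor_ids_unique",
                       sprintf("factor id `%s` appears in more than one place", fid))))
  }
  for (idx in schema$indices) {
    iid <- idx$id
    nf <- length(idx$factors)
    if (nf < 3 || nf > 8) {
      v <- c(v, list(bad(iid, NA, "factor_count_3_8",
                         sprintf("index %s has %d factors; expected 3 to 8", iid, nf))))
    }
    if (!idx$level %in% c("farm", "room")) {
      v <- c(v, list(bad(iid, NA, "level_valid",
                         sprintf("index %s level `%s` is not farm/room", iid, idx$level))))
    } else {
      expected_level <- if (as.numeric(iid) %in% 8:10) "room" else "farm"
      if (!identical(idx$level, expected_level)) {
        v <- c(v, list(bad(iid, NA, "level_by_index",
                           sprintf("index %s must be %s-level", iid, expected_level))))
      }
    }
    wsum <- 0
    for (f in idx$factors) {
      w <- as.numeric(f$weight)
      wsum <- wsum + w
      if (!is.finite(w) || w <= 0) {
        v <- c(v, list(bad(iid, f$id, "weight_positive",
                           sprintf("index %s factor `%s`: weight must be > 0", iid, f$id))))
      }
      r <- f$response
      if (!r$kind %in% c("binary", "categorical", "numeric_threshold")) {
        v <- c(v, list(bad(iid, f$id, "response_kind",
                           sprintf("index %s factor `%s`: unknown response kind `%s`",
                                   iid, f$id, r$kind))))
      } else if (r$kind == "categorical") {
        cr <- vapply(r$options, function(o) as.numeric(o$credit), numeric(1))
        if (length(cr) < 2 || is.unsorted(cr) || any(cr < 0 | cr > 1) ||
            cr[1] != 0 || cr[length(cr)] != 1) {
          v <- c(v, list(bad(iid, f$id, "categorical_credits",
                             sprintf(paste0("index %s factor `%s`: option credits must be ",
                                            "non-decreasing in [0,1], starting at 0 and ",
                                            "ending at 1"), iid, f$id))))
        }
        labs <- vapply(r$options, function(o) as.character(o$label), character(1))
        if (anyDuplicated(labs)) {
          v <- c(v, list(bad(iid, f$id, "categorical_labels_unique",
                             sprintf("index %s factor `%s`: duplicate option labels",
                                     iid, f$id))))
        }
      } else if (r$kind == "numeric_threshold") {
        if (is.null(r$threshold) || !is.finite(as.numeric(r$threshold)) ||
            is.null(r$direction) || !r$direction %in% c(">=", "<=")) {
          v <- c(v, list(bad(iid, f$id, "threshold_spec",
                             sprintf("index %s factor `%s`: numeric_threshold needs a finite threshold and direction >= or <=",
                                     iid, f$id))))
        }
      }
    }
    if (abs(wsum - 10) > 1e-9) {
      v <- c(v, list(bad(iid, NA, "weights_sum_10",
                         sprintf("index %s: factor weights sum to %.6g, expected 10", iid, wsum))))
    }
  }
  if (length(v) == 0) {
    return(tibble(index_id = character(), factor_id = character(),
                  rule = character(), message = character()))
  }
  bind_rows(v)
}

#' The packaged default calculator schema
#'
#' The published ten-index quick-scan calculator: pre-weaning handling (4
#' factors), batch management (4), biosecurity (8), water management (7),
#' feed management (5), health program (6), stockmen training (4), and the
#' three room-level facility indices — temperature (3), ventilation (4), and
#' floor type/density (4).  Factor weights are the default equal split of 10
#' points per index.
#'
#' @return A validated `qsc_schema`.
#' @export
default_schema <- function() {
  path <- system.file("extdata", "default_schema.yaml", package = "pigqsc",
                      mustWork = TRUE)
  read_schema(path)
}

#' Write a schema back to YAML
#'
#' Round-trip safe: reading the written file yields a schema equal to the
#' input (weights are serialized at full precision).
#'
#' @param schema A `qsc_schema`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "qsc_schema"))
  doc <- list(version = schema$version, indices = schema$indices)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Flatten a schema into a factor table
#'
#' @param schema A `qsc_schema`.
#' @return A tibble with one row per factor: `index_id`, `index_slug`,
#'   `index_name`, `level`, `factor_id`, `text`, `weight`, `kind`,
#'   `options` (list column of label/credit tibbles), `threshold`,
#'   `direction`, `units`.
#' @export
schema_factors <- function(schema) {
  stopifnot(inherits(schema, "qsc_schema"))
  purrr::map_dfr(schema$indices, function(idx) {
    purrr::map_dfr(idx$factors, function(f) {
      r <- f$response
      tibble(
        index_id = as.integer(idx$id),
        index_slug = as.character(idx$slug),
        index_name = as.character(idx$name),
        level = as.character(idx$level),
        factor_id = as.character(f$id),
        text = as.character(f$text),
        weight = as.numeric(f$weight),
        kind = r$kind,
        options = list(if (identical(r$kind, "categorical")) {
          tibble(label = vapply(r$options, function(o) as.character(o$label), character(1)),
                 credit = vapply(r$options, function(o) as.numeric(o$credit), numeric(1)))
        } else NULL),
        threshold = if (is.null(r$threshold)) NA_real_ else as.numeric(r$threshold),
        direction = if (is.null(r$direction)) NA_character_ else as.character(r$direction),
        units = if (is.null(r$units)) NA_character_ else as.character(r$units)
      )
    })
  })
}

#' Index definitions of a schema
#'
#' @param schema A `qsc_schema`.
#' @return A tibble with one row per index: id, slug, name, level, n_factors,
#'   max points.
#' @export
schema_indices <- function(schema) {
  stopifnot(inherits(schema, "qsc_schema"))
  purrr::map_dfr(schema$indices, function(idx) {
    tibble(index_id = as.integer(idx$id),
           index_slug = as.character(idx$slug),
           index_name = as.character(idx$name),
           level = as.character(idx$level),
           n_factors = length(idx$factors),
           max_points = sum(vapply(idx$factors, function(f) as.numeric(f$weight),
                                   numeric(1))))
  })
}

#' @export
print.qsc_schema <- function(x, ...) {
  info <- schema_indices(x)
  cat(sprintf("<qsc_schema v%s> %d indices, %d factors, max %.0f points\n",
              x$version, nrow(info), sum(info$n_factors), sum(info$max_points)))
  print(info, n = Inf)
  invisible(x)
}
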