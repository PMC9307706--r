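# Conditions and the nine-model parameter-by-condition space.

SET_SIZES <- c(3L, 5L)
SPRINGS <- c("soft", "stiff")

#' The four condition cells of the 2x2 design
#'
#' Crossing of set size (3 vs 5 characters, the cognitive-load manipulation)
#' and spring pressure condition (soft vs stiff response-button springs, the
#' motor-speed manipulation).
#'
#' @return A data frame with columns `set_size` (integer, 3 or 5) and
#'   `spring` (character, `"soft"` or `"stiff"`); one row per cell.
#' @export
condition_cells <- function() {
  data.frame(
    set_size = rep(SET_SIZES, times = 2L),
    spring = rep(SPRINGS, each = 2L),
    stringsAsFactors = FALSE
  )
}

#' Define which parameters vary by which factors
#'
#' A model specification names, for each of drift rate (`v`), boundary
#' separation (`a`) and non-decision time (`ter`), the subset of design
#' factors (`"SS"` = set size, `"SPC"` = spring pressure condition) across
#' which that parameter is allowed to differ.  An empty subset means the
#' parameter is constant across all four cells.
#'
#' @param model_id Integer identifier (1-9 for the canonical space; any
#'   positive integer for user-defined specs).
#' @param v_factors,a_factors,ter_factors Character vectors, subsets of
#'   `c("SS", "SPC")`.
#' @return An object of class `ddm_model_spec`.
#' @seealso [build_model_space()]
#' @export
model_spec <- function(model_id, v_factors = character(),
                       a_factors = character(), ter_factors = character()) {
  chk <- function(f, nm) {
    f <- as.character(f)
    bad <- setdiff(f, c("SS", "SPC"))
    if (length(bad) > 0L) {
      stop(sprintf("unknown factor name(s) for %s: %s", nm,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    sort(unique(f))
  }
  structure(
    list(
      model_id = as.integer(model_id),
      v_factors = chk(v_factors, "v"),
      a_factors = chk(a_factors, "a"),
      ter_factors = chk(ter_factors, "ter")
    ),
    class = "ddm_model_spec"
  )
}

#' @export
print.ddm_model_spec <- function(x, ...) {
  fmt <- function(f) if (length(f) == 0L) "~1" else paste(f, collapse = " + ")
  cat(sprintf("DDM model %d: v %s; a %s; ter %s\n", x$model_id,
              fmt(x$v_factors), fmt(x$a_factors), fmt(x$ter_factors)))
  invisible(x)
}

#' Build the canonical nine-model space
#'
#' The candidate models differ only in which design factors each of `v`, `a`
#' and `ter` may vary by.  Model 1 is the full model (all three parameters
#' vary by both factors); model 4 restricts drift rate to a set-size effect
#' only; model 9 lets only drift rate vary (by both factors) with `a` and
#' `ter` constant.  Bias (`z`) and across-trial variability (`sv`, `st`,
#' `sz`) are group-only in every model and are not part of the factor
#' structure.
#'
#' @return A list of nine `ddm_model_spec` objects, ordered by `model_id`.
#' @export
build_model_space <- function() {
  both <- c("SS", "SPC")
  list(
    model_spec(1L, both, both, both),
    model_spec(2L, "SPC", both, both),
    model_spec(3L, "SS", character(), both),
    model_spec(4L, "SS", both, both),
    model_spec(5L, "SS", "SS", both),
    model_spec(6L, "SS", "SPC", both),
    model_spec(7L, "SS", both, "SS"),
    model_spec(8L, "SS", both, "SPC"),
    model_spec(9L, both, character(), character())
  )
}

# Node label for one parameter under a factor subset in one condition cell.
# Cells sharing all active factor levels share the node (e.g. under {SS} the
# soft and stiff cells at set size 3 resolve to the same "v_ss3" node).
cell_node <- function(param, factors, set_size, spring) {
  tag <- character()
  if ("SS" %in% factors) tag <- c(tag, paste0("ss", set_size))
  if ("SPC" %in% factors) tag <- c(tag, spring)
  if (length(tag) == 0L) param else paste(c(param, tag), collapse = "_")
}

NUISANCE_NODES <- c("z", "sv", "st", "sz")

#' Enumerate the parameter nodes induced by a model specification
#'
#' One node per parameter per induced condition cell (a parameter varying by
#' one factor has two nodes, by both factors four, by none one), plus the
#' four group-only nuisance nodes `z`, `sv`, `st`, `sz`.  Labels are
#' deterministic and stable across calls.
#'
#' @param spec A `ddm_model_spec`.
#' @return A data frame with columns `node`, `parameter`, `set_size`,
#'   `spring` (the latter two `NA` where the node does not depend on that
#'   factor), with one row per node.
#' @export
parameter_nodes <- function(spec) {
  stopifnot(inherits(spec, "ddm_model_spec"))
  cells <- condition_cells()
  rows <- list()
  for (param in c("v", "a", "ter")) {
    factors <- spec[[paste0(param, "_factors")]]
    labs <- vapply(seq_len(nrow(cells)), function(i) {
      cell_node(param, factors, cells$set_size[i], cells$spring[i])
    }, character(1))
    keep <- !duplicated(labs)
    rows[[param]] <- data.frame(
      node = labs[keep],
      parameter = param,
      set_size = if ("SS" %in% factors) cells$set_size[keep] else NA_integer_,
      spring = if ("SPC" %in% factors) cells$spring[keep] else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  nuis <- data.frame(
    node = NUISANCE_NODES, parameter = NUISANCE_NODES,
    set_size = NA_integer_, spring = NA_character_, stringsAsFactors = FALSE
  )
  out <- rbind(rows$v, rows$a, rows$ter, nuis)
  rownames(out) <- NULL
  out
}

# Map every condition cell to its node label for one parameter.
cell_node_map <- function(spec, param) {
  cells <- condition_cells()
  factors <- spec[[paste0(param, "_factors")]]
  vapply(seq_len(nrow(cells)), function(i) {
    cell_node(param, factors, cells$set_size[i], cells$spring[i])
  }, character(1))
}

#' Serialize / deserialize a model specification as JSON
#'
#' @param spec A `ddm_model_spec`.
#' @return `model_spec_to_json()` returns a JSON string;
#'   `model_spec_from_json()` returns a `ddm_model_spec`.
#' @export
model_spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "ddm_model_spec"))
  jsonlite::toJSON(
    list(
      model_id = spec$model_id,
      v_factors = spec$v_factors,
      a_factors = spec$a_factors,
      ter_factors = spec$ter_factors
    ),
    auto_unbox = TRUE
  )
}

#' @rdname model_spec_to_json
#' @param json A JSON string produced by `model_spec_to_json()`.
#' @export
model_spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  model_spec(x$model_id, unlist(x$v_factors), unlist(x$a_factors),
             unlist(x$ter_factors))
}
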