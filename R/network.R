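# Kirchhoff calculus for rate-defining processes.
#
# The central idea: for linear kinetics the measured total rate constant or
# clearance is assembled from the individual rate-defining processes by two
# rules only -- parallel processes add, and for in-series processes the
# reciprocals add. A process network is a finite tree of parallel/series
# groups over positive-valued leaves, all in one kind of unit (1/h for rate
# constants, L/h or mL/min for clearances).

#' Combine parallel rate-defining processes
#'
#' Parallel processes are simultaneous, mutually independent routes: the
#' total measured rate constant or clearance is their arithmetic sum.
#'
#' @param values numeric vector of positive rate constants (1/h) or
#'   clearances (flow units); all entries must share one unit.
#' @return the total, a single positive number, never less than
#'   `max(values)`.
#' @examples
#' combine_parallel(c(0.15, 0.20)) # two parallel elimination routes
#' @seealso [combine_series()], [evaluate_network()]
#' @export
combine_parallel <- function(values) {
  check_positive(values, "values")
  sum(values)
}

#' Combine in-series rate-defining processes
#'
#' In-series processes are sequential steps, each feeding the next: the
#' reciprocal of the total equals the sum of the reciprocals. The total is
#' therefore never larger than the smallest (slowest) step.
#'
#' @inheritParams combine_parallel
#' @return the total, a single positive number, never more than
#'   `min(values)`.
#' @examples
#' # three sequential steps; the 0.06/h step dominates
#' combine_series(c(0.06, 0.35, 0.50))
#' # mean residence time is its reciprocal, about 21.5 h
#' 1 / combine_series(c(0.06, 0.35, 0.50))
#' @export
combine_series <- function(values) {
  check_positive(values, "values")
  1 / sum(1 / values)
}

#' Mean residence time of an in-series chain
#'
#' For first-order steps the mean time spent in each step is the reciprocal
#' of its rate constant, and mean times in series add. Equivalently this is
#' `1 / combine_series(rate_constants)`.
#'
#' @param rate_constants positive first-order rate constants (1/h); each
#'   element is the total rate constant of one in-series stage (parallel
#'   routes within a stage are summed first).
#' @return mean residence time in hours.
#' @examples
#' mrt_of_series(c(0.06, 0.15 + 0.20, 0.50)) # 21.5 h
#' @export
mrt_of_series <- function(rate_constants) {
  check_positive(rate_constants, "rate_constants")
  sum(1 / rate_constants)
}

#' Total from entering and leaving process groups
#'
#' The universal two-stage form: the processes delivering drug to the site
#' of measurement (entering) and those removing it (leaving) are each a
#' parallel group, and the two groups are in series.
#'
#' @param entering,leaving numeric vectors of positive values; parallel
#'   within each group.
#' @return the measured total.
#' @examples
#' # organ clearance limited equally by flow in and flow out
#' entering_leaving_total(1200, 1200) # 600
#' @export
entering_leaving_total <- function(entering, leaving) {
  combine_series(c(
    combine_parallel(entering),
    combine_parallel(leaving)
  ))
}

# ---- process network trees -------------------------------------------------

#' Construct a rate-defining process (network leaf)
#'
#' @param value positive magnitude: 1/h for a rate constant, flow units for
#'   a clearance.
#' @param name optional label.
#' @param kind `"rate_constant"` or `"clearance"`; all leaves of one network
#'   must agree.
#' @param note free-text provenance (e.g. "net of influx - efflux").
#' @return a `pk_process` leaf node.
#' @examples
#' pk_process(0.06, name = "k12")
#' @export
pk_process <- function(value, name = NULL,
                       kind = c("rate_constant", "clearance"),
                       note = NULL) {
  kind <- rlang::arg_match(kind)
  check_positive(value, "value")
  if (length(value) != 1L) {
    abort_domain("a process holds exactly one value")
  }
  structure(
    list(value = value, name = name, kind = kind, note = note),
    class = c("pk_process", "pk_node")
  )
}

#' Net forward-minus-backward process
#'
#' Bidirectional membrane passage (e.g. transporter influx vs efflux,
#' tubular secretion vs reabsorption) enters the calculus only as a net
#' difference, and only a positive net difference is rate-defining. A
#' non-positive net is a hard error by default; with
#' `on_non_positive = "drop"` the stage is omitted from the network
#' entirely (with a warning), reflecting that non-rate-defining processes
#' simply do not appear in the clearance equations.
#'
#' @param forward positive forward magnitude.
#' @param backward non-negative backward magnitude, same units.
#' @param on_non_positive `"error"` or `"drop"`.
#' @inheritParams pk_process
#' @return a `pk_process` leaf, or `NULL` when dropped.
#' @examples
#' net_process(30, 10, name = "basolateral net transport", kind = "clearance")
#' @export
net_process <- function(forward, backward, name = NULL,
                        kind = c("rate_constant", "clearance"),
                        on_non_positive = c("error", "drop"),
                        note = NULL) {
  kind <- rlang::arg_match(kind)
  on_non_positive <- rlang::arg_match(on_non_positive)
  check_positive(forward, "forward")
  if (!is.numeric(backward) || length(backward) != 1L || is.na(backward) || backward < 0) {
    abort_domain("`backward` must be a single non-negative number")
  }
  net <- forward - backward
  if (net <= 0) {
    msg <- sprintf(
      "net difference %s - %s = %s is not rate-defining (must be > 0)",
      signif(forward, 6), signif(backward, 6), signif(net, 6)
    )
    if (on_non_positive == "error") {
      abort_non_rate_defining(msg)
    }
    rlang::warn(paste0(msg, "; stage omitted from the network"))
    return(NULL)
  }
  note <- note %||% sprintf("net of %s forward - %s backward", forward, backward)
  pk_process(net, name = name, kind = kind, note = note)
}

as_pk_node <- function(x, kind) {
  if (is.null(x)) {
    return(NULL)
  }
  if (inherits(x, "pk_node")) {
    return(x)
  }
  if (is.numeric(x) && length(x) == 1L) {
    return(pk_process(x, kind = kind))
  }
  abort_input("network children must be pk nodes or single numbers")
}

new_group <- function(type, children, kind, units) {
  children <- purrr::compact(purrr::map(children, as_pk_node, kind = kind))
  if (length(children) == 0L) {
    abort_domain(sprintf(
      "empty %s group: a group with no rate-defining processes has no total",
      type
    ))
  }
  structure(
    list(type = type, children = children, kind = kind, units = units),
    class = c(paste0("pk_", type), "pk_group", "pk_node")
  )
}

#' Build parallel / series process groups
#'
#' `pk_parallel()` and `pk_series()` assemble [pk_process()] leaves (or bare
#' numbers, coerced to leaves) and nested groups into a process-network
#' tree. `NULL` children (from [net_process()] in drop mode) are removed;
#' an empty group is an error, never an identity.
#'
#' @param ... child nodes: `pk_process` leaves, nested groups, or single
#'   positive numbers.
#' @param kind unit kind applied to bare-number children.
#' @param units optional unit tag (`"1/h"`, `"L/h"`, `"mL/min"`) recorded on
#'   the node for I/O.
#' @return a `pk_network` node.
#' @examples
#' net <- pk_series(0.06, pk_parallel(0.15, 0.20), 0.50)
#' evaluate_network(net)
#' @name pk_group
#' @export
pk_parallel <- function(..., kind = c("rate_constant", "clearance"), units = NULL) {
  kind <- rlang::arg_match(kind)
  new_group("parallel", rlang::list2(...), kind, units)
}

#' @rdname pk_group
#' @export
pk_series <- function(..., kind = c("rate_constant", "clearance"), units = NULL) {
  kind <- rlang::arg_match(kind)
  new_group("series", rlang::list2(...), kind, units)
}

node_kinds <- function(node) {
  if (inherits(node, "pk_process")) {
    return(node$kind)
  }
  unique(unlist(purrr::map(node$children, node_kinds)))
}

#' Evaluate a process network
#'
#' Walks the tree, summing parallel groups and reciprocal-summing series
#' groups. All leaves must share one kind; the result carries the units of
#' the leaves.
#'
#' @param net a `pk_node` built with [pk_process()], [pk_parallel()],
#'   [pk_series()], or read with [read_network()].
#' @return the total rate constant or clearance, a positive number.
#' @examples
#' scheme <- pk_series(0.06, pk_parallel(0.15, 0.20), 0.50)
#' evaluate_network(scheme)     # total rate constant, 1/h
#' 1 / evaluate_network(scheme) # MRT, 21.5 h
#' @export
evaluate_network <- function(net) {
  if (!inherits(net, "pk_node")) {
    abort_input("`net` must be a process network (see pk_series/pk_parallel)")
  }
  kinds <- node_kinds(net)
  if (length(kinds) > 1L) {
    abort_domain(sprintf(
      "mixed-kind network: leaves are both %s",
      paste(kinds, collapse = " and ")
    ))
  }
  eval_node(net)
}

eval_node <- function(node) {
  if (inherits(node, "pk_process")) {
    return(node$value)
  }
  vals <- purrr::map_dbl(node$children, eval_node)
  if (node$type == "parallel") combine_parallel(vals) else combine_series(vals)
}

#' @export
print.pk_node <- function(x, ...) {
  cat(format_node(x, indent = 0), sep = "\n")
  invisible(x)
}

format_node <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (inherits(node, "pk_process")) {
    lab <- if (is.null(node$name)) "" else paste0(node$name, " = ")
    return(sprintf("%s- %s%g [%s]", pad, lab, node$value, node$kind))
  }
  c(
    sprintf("%s%s:", pad, node$type),
    unlist(purrr::map(node$children, format_node, indent = indent + 1))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a process network into its leaves
#'
#' @param x a `pk_node`.
#' @param ... unused.
#' @return a tibble with one row per leaf: `name`, `value`, `kind`, `note`,
#'   and `path` (the series/parallel nesting that reaches the leaf).
#' @method tidy pk_node
#' @export
tidy.pk_node <- function(x, ...) {
  leaves <- collect_leaves(x, path = character())
  tibble::tibble(
    name = purrr::map_chr(leaves, ~ .x$node$name %||% NA_character_),
    value = purrr::map_dbl(leaves, ~ .x$node$value),
    kind = purrr::map_chr(leaves, ~ .x$node$kind),
    note = purrr::map_chr(leaves, ~ .x$node$note %||% NA_character_),
    path = purrr::map_chr(leaves, ~ paste(.x$path, collapse = "/"))
  )
}

collect_leaves <- function(node, path) {
  if (inherits(node, "pk_process")) {
    return(list(list(node = node, path = path)))
  }
  purrr::flatten(purrr::imap(
    node$children,
    function(ch, i) collect_leaves(ch, c(path, sprintf("%s%d", node$type, i)))
  ))
}

#' Summarise a process network
#'
#' @param x a `pk_node`.
#' @param ... unused.
#' @return a one-row tibble: total, kind, leaf count, and (for
#'   rate-constant networks) the mean residence time `1/total`.
#' @method glance pk_node
#' @export
glance.pk_node <- function(x, ...) {
  total <- evaluate_network(x)
  kind <- node_kinds(x)
  tibble::tibble(
    total = total,
    kind = kind,
    n_processes = nrow(tidy.pk_node(x)),
    mrt_h = if (kind == "rate_constant") 1 / total else NA_real_
  )
}

# ---- network I/O -----------------------------------------------------------

#' Read / write process networks as JSON or YAML
#'
#' The on-disk form is a nested tree, e.g.
#' `{"units": "1/h", "series": [{"k": 0.06}, {"parallel": [{"k": 0.15},
#' {"k": 0.20}]}, {"k": 0.50}]}`. Leaves are objects with a `k` (or `cl`)
#' value and optional `name`/`note`; the top level carries a `units` tag
#' (`"1/h"`, `"L/h"` or `"mL/min"`) which fixes the kind of every leaf.
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @param net a `pk_node` for writing.
#' @param units unit tag written at the top level (defaults to the tag
#'   stored on the node, else `"1/h"` for rate-constant networks and
#'   `"L/h"` for clearance networks).
#' @return `read_network()` returns a `pk_node` with a `units` attribute;
#'   `write_network()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_network(pk_series(0.06, pk_parallel(0.15, 0.20), 0.50), f)
#' evaluate_network(read_network(f))
#' @export
read_network <- function(path) {
  if (!file.exists(path)) {
    abort_input(sprintf("network file not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    yaml = ,
    yml = yaml::read_yaml(path),
    abort_input(sprintf("unsupported network format: .%s", ext))
  )
  if (!is.list(raw)) {
    abort_input("network file must contain an object at the top level")
  }
  units <- raw$units %||% "1/h"
  if (!units %in% flow_units) {
    abort_input(sprintf("unknown units tag %s", units))
  }
  kind <- kind_for_units(units)
  raw$units <- NULL
  node <- parse_node(raw, kind)
  attr(node, "units") <- units
  node
}

parse_node <- function(x, kind) {
  if (!is.list(x)) {
    abort_input("malformed network node (expected an object)")
  }
  if (!is.null(x$parallel)) {
    return(new_group("parallel", purrr::map(x$parallel, parse_node, kind = kind),
      kind = kind, units = NULL
    ))
  }
  if (!is.null(x$series)) {
    return(new_group("series", purrr::map(x$series, parse_node, kind = kind),
      kind = kind, units = NULL
    ))
  }
  val <- x$k %||% x$cl
  if (is.null(val)) {
    abort_input("leaf node needs a `k` or `cl` value")
  }
  if (!is.numeric(val) || length(val) != 1L) {
    abort_input("leaf value must be a single number")
  }
  if (val <= 0) {
    abort_domain(sprintf("leaf value %s is not rate-defining (must be > 0)", val))
  }
  pk_process(val, name = x$name, kind = kind, note = x$note)
}

#' @rdname read_network
#' @export
write_network <- function(net, path, units = NULL) {
  if (!inherits(net, "pk_node")) {
    abort_input("`net` must be a process network")
  }
  kind <- node_kinds(net)
  if (length(kind) > 1L) {
    abort_domain("cannot serialise a mixed-kind network")
  }
  units <- units %||% attr(net, "units") %||%
    net$units %||% if (kind == "rate_constant") "1/h" else "L/h"
  body <- unparse_node(net)
  body$units <- units
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml = yaml::write_yaml(body, path),
    abort_input(sprintf("unsupported network format: .%s", ext))
  )
  invisible(path)
}

unparse_node <- function(node) {
  if (inherits(node, "pk_process")) {
    key <- if (node$kind == "rate_constant") "k" else "cl"
    out <- stats::setNames(list(node$value), key)
    if (!is.null(node$name)) out$name <- node$name
    if (!is.null(node$note)) out$note <- node$note
    return(out)
  }
  stats::setNames(
    list(purrr::map(node$children, unparse_node)),
    node$type
  )
}
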