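# Shared generators for property-style tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# random unidirectional catenary chain C1 -> ... -> Cn -> sink, with
# optional side losses at each stage; returns the fo_network and the
# in-series stage totals seen by the terminal chain species
random_chain <- function(n_stages = sample(2:4, 1), with_branches = TRUE) {
  forward <- exp(stats::rnorm(n_stages, mean = -1, sd = 1))
  losses <- if (with_branches) {
    stats::rbinom(n_stages, 1, 0.5) * exp(stats::rnorm(n_stages, -1.5, 1))
  } else {
    rep(0, n_stages)
  }
  sp <- paste0("C", seq_len(n_stages))
  edges <- tibble::tibble(
    from = sp,
    to = c(sp[-1], "sink_out"),
    rate = forward
  )
  branch <- losses > 0
  if (any(branch)) {
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      from = sp[branch],
      to = paste0("loss", which(branch)),
      rate = losses[branch]
    ))
  }
  list(
    network = fo_network(edges, initial = stats::setNames(100, sp[1])),
    stage_totals = forward + losses,
    terminal = sp[n_stages]
  )
}

# independent recursive evaluator over a plain nested-list tree; written
# against the combination rules directly, not via pk_* constructors
brute_eval <- function(tree) {
  if (is.numeric(tree)) {
    return(tree)
  }
  vals <- vapply(tree$children, brute_eval, numeric(1))
  if (tree$type == "parallel") sum(vals) else 1 / sum(1 / vals)
}

# random 3-level tree as both a plain list (for brute_eval) and a pk network
random_tree <- function(depth = 3, kind = "rate_constant") {
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.3) {
      return(exp(stats::rnorm(1)))
    }
    type <- sample(c("parallel", "series"), 1)
    kids <- lapply(seq_len(sample(2:3, 1)), function(i) build(d - 1))
    list(type = type, children = kids)
  }
  tree <- build(depth)
  if (is.numeric(tree)) {
    tree <- list(type = "parallel", children = list(tree))
  }
  to_pk <- function(x) {
    if (is.numeric(x)) {
      return(pk_process(x, kind = kind))
    }
    kids <- lapply(x$children, to_pk)
    if (x$type == "parallel") {
      do.call(pk_parallel, c(kids, list(kind = kind)))
    } else {
      do.call(pk_series, c(kids, list(kind = kind)))
    }
  }
  list(plain = tree, network = to_pk(tree))
}
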