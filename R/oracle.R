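# Exact analysis of linear first-order transfer networks.
#
# This is the independent route against which the Kirchhoff calculus is
# checked: amount-time solutions by eigendecomposition (with a matrix-
# exponential fallback for near-degenerate spectra), species-wise
# AUC/AUMC/MRT by matrix moments, and the Bateman-type closed form for
# unidirectional catenary chains.

#' Build a linear first-order transfer network
#'
#' Species connected by first-order edges (1/h). A species with no outgoing
#' edge is a terminal sink (a product pool): it accumulates mass and is
#' excluded from the rate matrix. Every dosed species must eventually
#' drain.
#'
#' @param edges a data frame with columns `from`, `to`, `rate` (1/h,
#'   all > 0); duplicate `from`->`to` pairs and self-edges are errors.
#' @param initial named numeric vector of initial amounts (mg); names are
#'   species labels.
#' @param species optional character vector fixing species order; defaults
#'   to order of appearance in `edges` then `initial`.
#' @return an object of class `fo_network`.
#' @examples
#' scheme1 <- fo_network(
#'   edges = tibble::tribble(
#'     ~from, ~to, ~rate,
#'     "C1", "C2", 0.06,
#'     "C2", "C3", 0.15,
#'     "C2", "C4", 0.20,
#'     "C3", "C5", 0.50
#'   ),
#'   initial = c(C1 = 300)
#' )
#' species_moments(scheme1)
#' @export
fo_network <- function(edges, initial, species = NULL) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("from", "to", "rate") %in% names(edges))) {
    abort_input("`edges` needs columns from, to, rate")
  }
  check_positive(edges$rate, "rate")
  if (any(edges$from == edges$to)) {
    abort_input("self-edges are not allowed")
  }
  if (anyDuplicated(edges[c("from", "to")])) {
    abort_input("duplicate edge: each from->to pair may appear once")
  }
  if (is.null(names(initial)) || any(!nzchar(names(initial)))) {
    abort_input("`initial` must be a named numeric vector of amounts")
  }
  if (all(initial == 0)) {
    abort_input("at least one species must carry a nonzero initial amount")
  }
  species <- species %||% unique(c(edges$from, edges$to, names(initial)))
  unknown <- setdiff(c(edges$from, edges$to, names(initial)), species)
  if (length(unknown)) {
    abort_input(sprintf("species not in `species`: %s", paste(unknown, collapse = ", ")))
  }
  sinks <- setdiff(species, unique(edges$from))
  dosed_sinks <- intersect(sinks, names(initial)[initial > 0])
  if (length(dosed_sinks)) {
    abort_infeasible(sprintf(
      "non-draining: species %s is dosed but has no outflow",
      paste(dosed_sinks, collapse = ", ")
    ))
  }
  amounts <- stats::setNames(numeric(length(species)), species)
  amounts[names(initial)] <- initial
  structure(
    list(species = species, edges = edges, initial = amounts, sinks = sinks),
    class = "fo_network"
  )
}

#' @export
print.fo_network <- function(x, ...) {
  cat(sprintf(
    "<fo_network> %d species (%d sink%s), %d edges\n",
    length(x$species), length(x$sinks), if (length(x$sinks) == 1) "" else "s",
    nrow(x$edges)
  ))
  dosed <- x$initial[x$initial > 0]
  cat(
    "dose:", paste(sprintf("%s = %g mg", names(dosed), dosed), collapse = ", "),
    "\n"
  )
  invisible(x)
}

#' @method tidy fo_network
#' @export
tidy.fo_network <- function(x, ...) x$edges

non_sink <- function(net) setdiff(net$species, net$sinks)

#' Rate matrix of a first-order network
#'
#' Column-per-source convention over the non-sink species: entry (j, i) is
#' the rate i -> j, the diagonal is minus the total outflow from each
#' species (including flow into sinks), so amounts evolve as
#' `dA/dt = K %*% A`. Columns sum to <= 0, with equality only for species
#' that lose no mass to sinks.
#'
#' @param net an [fo_network()].
#' @return a square numeric matrix (1/h) with species dimnames.
#' @export
transfer_matrix <- function(net) {
  sp <- non_sink(net)
  K <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  for (r in seq_len(nrow(net$edges))) {
    from <- net$edges$from[r]
    to <- net$edges$to[r]
    k <- net$edges$rate[r]
    K[from, from] <- K[from, from] - k
    if (to %in% sp) {
      K[to, from] <- K[to, from] + k
    }
  }
  K
}

#' Species-wise AUC, AUMC and MRT by matrix moments
#'
#' The zeroth and first moments of every species' amount-time curve solve
#' two linear systems: `K %*% AUC = -A0` and `K %*% AUMC = -AUC`, with
#' `MRT = AUMC / AUC`. This route needs no closed-form solution and is
#' exact for any draining linear network.
#'
#' @param net an [fo_network()].
#' @return a tibble with one row per non-sink species: `species`,
#'   `auc` (mg h), `aumc` (mg h^2), `mrt` (h).
#' @examples
#' net <- fo_network(
#'   tibble::tibble(from = "C1", to = "sink", rate = 0.5),
#'   initial = c(C1 = 100)
#' )
#' species_moments(net) # MRT = 1/k = 2 h
#' @export
species_moments <- function(net) {
  K <- transfer_matrix(net)
  A0 <- net$initial[rownames(K)]
  auc <- tryCatch(
    solve(K, -A0),
    error = function(e) {
      abort_infeasible(
        "non-draining network: rate matrix is singular (a trap compartment holds mass)"
      )
    }
  )
  aumc <- solve(K, -auc)
  tibble::tibble(
    species = rownames(K),
    auc = unname(auc),
    aumc = unname(aumc),
    mrt = unname(aumc / auc)
  )
}

eigen_separation_ok <- function(lambda, tol = 1e-10) {
  if (any(abs(Im(lambda)) > tol * max(abs(lambda), 1))) {
    return(FALSE)
  }
  lam <- Re(lambda)
  if (length(lam) < 2) {
    return(TRUE)
  }
  d <- abs(outer(lam, lam, "-"))
  min(d[upper.tri(d)]) > tol * max(abs(lam))
}

#' Analytic amount-time curve of one species
#'
#' Diagonalizes the rate matrix and returns the species' amount curve as a
#' signed sum of exponential terms. When eigenvalues are complex or
#' separated by less than `1e-10` of the spectral radius no closed-form
#' term list exists at working precision; the function then falls back to
#' dense matrix-exponential sampling on a geometric time grid (with a
#' message) and returns the sampled curve instead.
#'
#' @param net an [fo_network()].
#' @param species which species' curve to return (non-sink).
#' @return with distinct eigenvalues, a [pk_curve()] of role
#'   `"amount_curve"` (mg); otherwise a tibble of sampled `(time_h,
#'   amount_mg)` with attribute `method = "expm"`.
#' @examples
#' net <- fo_network(
#'   tibble::tibble(
#'     from = c("C1", "C2", "C2", "C3"),
#'     to = c("C2", "C3", "C4", "C5"),
#'     rate = c(0.06, 0.15, 0.20, 0.50)
#'   ),
#'   initial = c(C1 = 300)
#' )
#' analytic_curves(net, "C3")
#' @export
analytic_curves <- function(net, species) {
  K <- transfer_matrix(net)
  if (!species %in% rownames(K)) {
    abort_input(sprintf("`%s` is not a non-sink species of the network", species))
  }
  A0 <- net$initial[rownames(K)]
  eg <- eigen(K)
  if (!eigen_separation_ok(eg$values)) {
    message(
      "repeated or complex eigenvalues: no closed-form term list; ",
      "falling back to matrix-exponential sampling"
    )
    rates <- net$edges$rate
    times <- exp(seq(
      log(1e-3 / max(rates)), log(20 / min(rates)),
      length.out = 200
    ))
    samp <- simulate_amounts(net, times)
    out <- samp[samp$species == species, c("time_h", "amount_mg")]
    attr(out, "method") <- "expm"
    return(out)
  }
  V <- Re(eg$vectors)
  lambda <- Re(eg$values)
  w <- solve(V, A0)
  coefs <- V[match(species, rownames(K)), ] * w
  keep <- abs(coefs) > 1e-12 * max(abs(coefs), 1)
  pk_curve(
    coefficients = coefs[keep], exponents = -lambda[keep],
    role = "amount_curve"
  )
}

#' Closed-form curve for the terminal species of a catenary chain
#'
#' Bateman-type solution for a unidirectional chain C1 -> C2 -> ... -> Cn,
#' where stage i loses mass forward at `chain_rates[i]` and sideways at
#' `branch_losses[i]` (total stage rate = sum). Stage totals must be
#' pairwise distinct. The coefficients of the terminal species are
#' `dose * prod(chain_rates[-n]) / prod_{i != j}(lambda_i - lambda_j)`.
#'
#' @param chain_rates forward rates along the chain (1/h); the last entry
#'   is the terminal species' own elimination rate.
#' @param branch_losses side-elimination rates per stage (>= 0), recycled
#'   to `length(chain_rates)`; default none.
#' @param dose initial amount in C1 (mg).
#' @return a [pk_curve()] of role `"amount_curve"` identical to
#'   [analytic_curves()] on the equivalent network.
#' @examples
#' catenary_coefficients(c(0.06, 0.15, 0.50), c(0, 0.20, 0), dose = 300)
#' @export
catenary_coefficients <- function(chain_rates, branch_losses = 0, dose) {
  check_positive(chain_rates, "chain_rates")
  check_positive(dose, "dose")
  n <- length(chain_rates)
  branch_losses <- rep_len(branch_losses, n)
  if (any(branch_losses < 0)) {
    abort_domain("branch_losses must be >= 0")
  }
  lambda <- chain_rates + branch_losses
  d <- abs(outer(lambda, lambda, "-"))
  if (n > 1 && min(d[upper.tri(d)]) <= 1e-12 * max(lambda)) {
    abort_infeasible(
      "degenerate chain: stage totals must be pairwise distinct for the closed form"
    )
  }
  num <- dose * prod(chain_rates[-n])
  coefs <- purrr::map_dbl(seq_len(n), function(j) {
    num / prod(lambda[-j] - lambda[j])
  })
  pk_curve(coefficients = coefs, exponents = lambda, role = "amount_curve")
}

#' Sample amounts over time by matrix exponential
#'
#' Dense `expm` evaluation of the full system, including cumulative sink
#' amounts (integrals of the inflows), so total mass can be audited at
#' every time point.
#'
#' @param net an [fo_network()].
#' @param times sample times (h), all >= 0.
#' @return a long tibble: `time_h`, `species`, `amount_mg` (sinks report
#'   cumulative amount).
#' @export
simulate_amounts <- function(net, times) {
  if (any(times < 0)) abort_input("times must be >= 0")
  K <- transfer_matrix(net)
  A0 <- net$initial[rownames(K)]
  sink_edges <- net$edges[net$edges$to %in% net$sinks, ]
  rows <- purrr::map(times, function(t) {
    At <- as.numeric(Matrix::expm(K * t) %*% A0)
    names(At) <- rownames(K)
    # integral of amounts from 0 to t: K %*% Int = A(t) - A0
    Int <- solve(K, At - A0)
    sink_amt <- stats::setNames(numeric(length(net$sinks)), net$sinks)
    for (r in seq_len(nrow(sink_edges))) {
      sink_amt[sink_edges$to[r]] <- sink_amt[sink_edges$to[r]] +
        sink_edges$rate[r] * Int[sink_edges$from[r]]
    }
    tibble::tibble(
      time_h = t,
      species = c(names(At), names(sink_amt)),
      amount_mg = c(unname(At), unname(sink_amt))
    )
  })
  dplyr::bind_rows(rows)
}

#' Compare moment-based and Kirchhoff MRT for one species
#'
#' Computes the species' mean residence time twice: as AUMC/AUC from the
#' matrix-moment oracle, and as the sum of stage mean times from a caller-
#' supplied list of in-series rate-defining stage totals. Both numbers and
#' their absolute difference are reported; no judgment is encoded. For
#' unidirectional catenary chains the two agree; for networks with
#' reversible side exchange the moment-based MRT shifts with the exchange
#' rates while the Kirchhoff value (and every AUC) does not.
#'
#' @param net an [fo_network()].
#' @param species species whose MRT is compared.
#' @param kirchhoff_stages positive stage totals (1/h), one per in-series
#'   rate-defining stage.
#' @return a one-row tibble: `species`, `mrt_oracle`, `mrt_kirchhoff`,
#'   `abs_difference`.
#' @export
kirchhoff_vs_oracle <- function(net, species, kirchhoff_stages) {
  mom <- species_moments(net)
  if (!species %in% mom$species) {
    abort_input(sprintf("`%s` is not a non-sink species of the network", species))
  }
  mo <- mom$mrt[mom$species == species]
  mk <- mrt_of_series(kirchhoff_stages)
  tibble::tibble(
    species = species,
    mrt_oracle = mo,
    mrt_kirchhoff = mk,
    abs_difference = abs(mo - mk)
  )
}
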