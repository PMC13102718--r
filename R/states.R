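#' Per-cell total editing rate
#'
#' Total edits divided by total reads per cell, the univariate summary
#' whose bimodal distribution separates high and low translational states.
#'
#' @param cfm Cell-by-feature tibble (`barcode`, `feature`, `edits`,
#'   `reads`).
#' @return Tibble `barcode`, `total_edits`, `total_reads`, `total_rate`.
#' @export
cell_total_rate <- function(cfm) {
  assert_cols(cfm, c("barcode", "edits", "reads"))
  cfm |>
    group_by(.data$barcode) |>
    summarise(total_edits = sum(.data$edits),
              total_reads = sum(.data$reads), .groups = "drop") |>
    mutate(total_rate = if_else(.data$total_reads > 0,
                                .data$total_edits / .data$total_reads, 0))
}

#' Assign translational states with a two-component Gaussian mixture
#'
#' Fits a univariate two-component Gaussian mixture to the per-cell total
#' editing rate by expectation-maximisation and assigns each cell to the
#' component with maximum posterior probability. The component with the
#' larger fitted mean is labelled `"high"`. Initialisation is
#' deterministic: component means at the 25th and 75th percentiles of the
#' data, both variances at the pooled variance, equal weights.
#' Convergence is declared when the log-likelihood improves by less than
#' `tol` (default 1e-6), up to `max_iter` iterations.
#'
#' Zero-variance input yields a flagged degenerate result with every cell
#' assigned `"low"`.
#'
#' @param cells Tibble with `barcode` and the rate column.
#' @param rate Name of the column holding the per-cell total editing rate.
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param seed Seed recorded for provenance; the fit itself is
#'   deterministic.
#' @return Object of class `"translation_states"` with elements `means`,
#'   `variances`, `weights` (component order: low, high), `converged`,
#'   `n_iter`, `degenerate`, and `cells` (tibble with `posterior_high` and
#'   `state`). Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_translation_states <- function(cells, rate = "total_rate",
                                   tol = 1e-6, max_iter = 1000L, seed = 1L) {
  assert_cols(cells, c("barcode", rate))
  x <- cells[[rate]]
  if (length(x) < 4) stop_input("need at least 4 cells, got %d", length(x))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_input("rates must be finite and non-negative")
  }

  degenerate_result <- function() {
    out <- cells
    out$posterior_high <- 0
    out$state <- "low"
    structure(list(means = c(low = mean(x), high = mean(x)),
                   variances = c(low = 0, high = 0),
                   weights = c(low = 1, high = 0),
                   converged = FALSE, n_iter = 0L, degenerate = TRUE,
                   loglik = NA_real_, cells = out, seed = seed),
              class = "translation_states")
  }
  if (sd(x) == 0) return(degenerate_result())

  mu <- unname(quantile(x, c(0.25, 0.75), type = 7))
  if (mu[1] == mu[2]) mu <- mu + c(-1, 1) * sd(x) / 2
  s2 <- rep(var(x), 2)
  w <- c(0.5, 0.5)
  var_floor <- max(1e-12, var(x) * 1e-8)

  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- w[2] * dnorm(x, mu[2], sqrt(s2[2]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && ll - loglik < tol && iter > 1L) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
    n2 <- sum(r2)
    n1 <- length(x) - n2
    if (n1 < 1e-8 || n2 < 1e-8) break  # one component emptied out
    mu <- c(sum((1 - r2) * x) / n1, sum(r2 * x) / n2)
    s2 <- c(max(sum((1 - r2) * (x - mu[1])^2) / n1, var_floor),
            max(sum(r2 * (x - mu[2])^2) / n2, var_floor))
    w <- c(n1, n2) / length(x)
  }

  # attach the "high" label to the larger-mean component
  hi <- which.max(mu)
  lo <- 3L - hi
  post_high <- if (hi == 2L) r2 else 1 - r2
  out <- cells
  out$posterior_high <- post_high
  out$state <- if_else(post_high > 0.5, "high", "low")
  structure(list(means = c(low = mu[lo], high = mu[hi]),
                 variances = c(low = s2[lo], high = s2[hi]),
                 weights = c(low = w[lo], high = w[hi]),
                 converged = converged, n_iter = iter,
                 degenerate = FALSE, loglik = loglik,
                 cells = out, seed = seed),
            class = "translation_states")
}

#' @method tidy translation_states
#' @export
tidy.translation_states <- function(x, ...) {
  tibble(component = c("low", "high"),
         mean = unname(x$means), variance = unname(x$variances),
         weight = unname(x$weights))
}

#' @method glance translation_states
#' @export
glance.translation_states <- function(x, ...) {
  tibble(n_cells = nrow(x$cells), n_high = sum(x$cells$state == "high"),
         prop_high = mean(x$cells$state == "high"),
         converged = x$converged, n_iter = x$n_iter,
         degenerate = x$degenerate, loglik = x$loglik)
}

#' @method print translation_states
#' @export
print.translation_states <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<translation_states> %d cells: %d high (%.1f%%), %d low%s\n",
    g$n_cells, g$n_high, 100 * g$prop_high, g$n_cells - g$n_high,
    if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  means (low, high): %.4g, %.4g; EM iterations: %d\n",
              x$means["low"], x$means["high"], x$n_iter))
  invisible(x)
}

#' @rdname fit_translation_states
#' @param object A `"translation_states"` fit.
#' @param ... Unused.
#' @method autoplot translation_states
#' @export
autoplot.translation_states <- function(object, ...) {
  cells <- object$cells
  rate_col <- setdiff(names(cells), c("barcode", "posterior_high", "state"))[1]
  dens <- tibble(
    x = seq(min(cells[[rate_col]]), max(cells[[rate_col]]), length.out = 400))
  dens$low <- object$weights["low"] *
    dnorm(dens$x, object$means["low"], sqrt(pmax(object$variances["low"], 1e-12)))
  dens$high <- object$weights["high"] *
    dnorm(dens$x, object$means["high"], sqrt(pmax(object$variances["high"], 1e-12)))
  dens_long <- tidyr::pivot_longer(dens, c("low", "high"),
                                   names_to = "state", values_to = "density")
  ggplot2::ggplot(cells, ggplot2::aes(x = .data[[rate_col]])) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density),
                                         fill = .data$state),
                            bins = 60, alpha = 0.6, position = "identity") +
    ggplot2::geom_line(data = dens_long,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    colour = .data$state)) +
    ggplot2::labs(x = "total editing rate", y = "density",
                  fill = "state", colour = "component") +
    ggplot2::theme_minimal()
}
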