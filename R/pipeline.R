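#' Scale variables by their maxima
#'
#' Divides each requested column by its maximum so that all variables live
#' on a common `(0, 1]`-type scale. Max-scaling preserves the shape of each
#' distribution while shrinking the boundary search space; the factors are
#' kept so that boundaries can be reported back on the original scale.
#'
#' @param table a data frame.
#' @param columns columns to scale (default: all numeric columns).
#' @return a list with `table` (scaled) and `factors` (named vector of the
#'   maxima used).
#' @export
scale_variables <- function(table, columns = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(columns)) {
    columns <- names(table)[vapply(table, is.numeric, TRUE)]
  }
  factors <- vapply(columns, function(cn) max(table[[cn]]), 0)
  if (any(!is.finite(factors) | factors <= 0)) {
    bad <- columns[!is.finite(factors) | factors <= 0]
    stop("cannot max-scale column(s) with nonpositive maximum: ",
         paste(bad, collapse = ", "))
  }
  for (cn in columns) table[[cn]] <- table[[cn]] / factors[[cn]]
  list(table = table, factors = factors)
}

# "x1", "I(x1^2)", "iron", "I(iron^2)" -> data frame (name, power)
.parse_formula_terms <- function(labels) {
  m <- regmatches(labels, regexec("^I\\((.+)\\^2\\)$", labels))
  data.frame(
    name = vapply(seq_along(labels), function(i) {
      if (length(m[[i]])) m[[i]][2] else labels[i]
    }, ""),
    power = vapply(m, function(g) if (length(g)) 2L else 1L, 1L),
    stringsAsFactors = FALSE)
}

#' Optimum stratification from a population table
#'
#' The end-to-end parametric workflow: scale the auxiliary variables by
#' their maxima, fit a three-parameter skewed distribution to each, fit (or
#' accept) the polynomial link between the study variable and the
#' auxiliaries, assemble the separable width-optimization problem, solve it
#' by dynamic programming with local refinement for each requested strata
#' count, and attach Neyman sample sizes. The study variable is needed only
#' to calibrate the link and the reporting scale; when it is unavailable,
#' supply link coefficients from a prior survey via `coefs`.
#'
#' @param formula a model formula such as `y ~ x1 + x2` or
#'   `y ~ iron + I(iron^2)`; quadratic terms are written with `I()`. The
#'   response may be omitted (`~ x1 + x2`) when `coefs` is given.
#' @param data population table containing the variables.
#' @param L strata count, or a vector of counts to profile (e.g. `2:6`).
#' @param n total sample size for the Neyman allocation.
#' @param N population size (defaults to `nrow(data)`).
#' @param family distribution family per auxiliary variable:
#'   `"auto"` (the better of Weibull/Gamma by log-likelihood), or a vector
#'   of `"weibull3p"` / `"gamma3p"`, recycled as needed.
#' @param coefs optional named coefficient vector (names on the scaled
#'   auxiliary terms, e.g. `c(x1 = 0.5, "x1^2" = 0.1)`) used instead of
#'   fitting the link; required when the formula has no response.
#' @param error_mode `"unit"` uses the standard-normal error term of the
#'   parametric construction; `"rse"` scales the error variance by the
#'   fitted residual standard error squared.
#' @param y0,d boundary domain on the common scaled axis; by default the
#'   scaled range of the response (or of the scaled auxiliaries when there
#'   is no response).
#' @param npts grid divisions for the DP.
#' @param refine local refinement factor (1 disables refinement).
#' @param weight_component component whose stratum weights define `N_h`.
#' @return an object of class `"optStrata"`; see [summary.optStrata()].
#' @examples
#' pop <- generate_population(demo_spec("anaemia_like"))
#' fit <- optStrata(y ~ x1 + x2, pop, L = 2:4, n = 500, npts = 400)
#' fit
#' @export
optStrata <- function(formula, data, L, n, N = nrow(data), family = "auto",
                      coefs = NULL, error_mode = c("unit", "rse"),
                      y0 = NULL, d = NULL, npts = 1000, refine = 10,
                      weight_component = 1) {
  error_mode <- match.arg(error_mode)
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  tl <- attr(stats::terms(formula, data = data), "term.labels")
  td <- .parse_formula_terms(tl)
  aux_names <- unique(td$name)
  has_response <- length(formula) == 3
  response <- if (has_response) deparse(formula[[2]]) else NULL
  missing_cols <- setdiff(c(aux_names, response), names(data))
  if (length(missing_cols)) {
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "))
  }
  if (!has_response && is.null(coefs)) {
    stop("without a response in the formula, link coefficients must be ",
         "supplied through 'coefs'")
  }

  # common scaled axis: every auxiliary divided by its maximum
  sc <- scale_variables(data[, aux_names, drop = FALSE], aux_names)
  p <- length(aux_names)
  work <- stats::setNames(sc$table, paste0("x", seq_len(p)))
  term_labels <- paste0("x", match(td$name, aux_names),
                        ifelse(td$power == 2, "^2", ""))

  # distribution fits on the scaled auxiliaries
  family <- rep_len(family, p)
  dist_fits <- lapply(seq_len(p), function(i) {
    xs <- work[[i]]
    if (family[i] == "auto") {
      fw <- fit_dist_mle(xs, "weibull3p")
      fg <- fit_dist_mle(xs, "gamma3p")
      if (fw$logLik >= fg$logLik) {
        fw$alternative <- fg; fw
      } else {
        fg$alternative <- fw; fg
      }
    } else {
      fit_dist_mle(xs, family[i])
    }
  })
  names(dist_fits) <- aux_names

  # link: fitted from the response, or supplied
  if (!is.null(coefs)) {
    link <- link_model(terms = coefs, error_scale = 1)
  } else {
    work$y <- data[[response]]
    link <- fit_link(work, "y", term_labels, error_mode = error_mode)
  }
  err_scale <- if (error_mode == "rse" && !is.null(link$metrics)) {
    link$metrics$rse
  } else 1

  # reporting scale and default domain
  if (has_response) {
    yv <- data[[response]]
    rescale <- max(yv)
    if (is.null(y0)) y0 <- min(yv) / rescale
    if (is.null(d)) d <- (max(yv) - min(yv)) / rescale
  } else {
    rescale <- 1
    if (is.null(y0)) y0 <- min(as.matrix(work[paste0("x", seq_len(p))]))
    if (is.null(d)) d <- 1 - y0
  }

  components <- lapply(seq_len(p), function(i) {
    tv <- link$terms[link$terms$variable == i, , drop = FALSE]
    beta <- numeric(max(tv$power))
    beta[tv$power] <- tv$coefficient
    list(dist = dist_fits[[i]]$dist, beta = beta)
  })

  Ls <- sort(unique(as.integer(L)))
  designs <- stats::setNames(vector("list", length(Ls)), Ls)
  for (k in seq_along(Ls)) {
    pr <- strat_problem(components, y0 = y0, d = d, L = Ls[k],
                        error_scale = err_scale, npts = npts)
    dsn <- dp_solve(pr)
    if (refine > 1) dsn <- refine_design(pr, dsn, factor = refine)
    designs[[k]] <- allocate(dsn, n = n, N = N,
                             weight_component = weight_component)
  }
  profile <- NULL
  if (length(Ls) > 1) {
    pr <- strat_problem(components, y0 = y0, d = d, L = max(Ls),
                        error_scale = err_scale, npts = npts)
    profile <- strata_profile(pr, L_max = max(Ls), n = n)
  }
  structure(list(call = match.call(), designs = designs, profile = profile,
                 dist_fits = dist_fits, link = link,
                 scale_factors = sc$factors, rescale = rescale,
                 y0 = y0, d = d, n = n, N = N, L = Ls,
                 aux_names = aux_names, error_mode = error_mode),
            class = "optStrata")
}

#' Stratum boundaries on the study-variable scale
#'
#' @param object an `"optStrata"` fit.
#' @param L which strata count (default: the largest fitted).
#' @param ... unused.
#' @return numeric vector of interior boundaries on the original scale.
#' @export
coef.optStrata <- function(object, L = max(object$L), ...) {
  dsn <- object$designs[[as.character(L)]]
  if (is.null(dsn)) stop("no design was fitted for L = ", L)
  dsn$boundaries * object$rescale
}

#' Assign units to strata
#'
#' @param object an `"optStrata"` fit.
#' @param newdata numeric vector of study-variable values on the original
#'   scale.
#' @param L which strata count to use.
#' @param ... unused.
#' @return integer stratum memberships in `1..L`.
#' @export
predict.optStrata <- function(object, newdata, L = max(object$L), ...) {
  b <- coef(object, L = L)
  findInterval(as.numeric(newdata), b) + 1L
}

#' @export
print.optStrata <- function(x, ...) {
  cat("Optimum stratification by dynamic programming\n")
  cat("  auxiliaries:", paste(x$aux_names, collapse = ", "), "\n")
  for (nm in x$aux_names) {
    f <- x$dist_fits[[nm]]
    cat(sprintf("    %s ~ %s (KS D = %.4f, p ~ %.3f)\n", nm, f$dist$family,
                f$ks_statistic, f$ks_p_value))
  }
  if (!is.null(x$link$metrics)) {
    cat(sprintf("  link: RSE %.4f | Adj R^2 %.4f | AIC %.2f (error mode: %s)\n",
                x$link$metrics$rse, x$link$metrics$adj_r_squared,
                x$link$metrics$aic, x$error_mode))
  }
  for (dsn in x$designs) {
    cat(sprintf("  L = %d: OSB = {%s}, objective = %.6g\n", dsn$L,
                paste(sprintf("%.2f", dsn$boundaries * x$rescale),
                      collapse = ", "), dsn$total))
  }
  invisible(x)
}

#' Summarize an optimum stratification fit
#'
#' @param object an `"optStrata"` fit.
#' @param L which strata count to tabulate (default: the largest fitted).
#' @param ... unused.
#' @return a list with the per-stratum table (boundaries on the original
#'   scale, stratum weights, allocations) and the fit metadata.
#' @export
summary.optStrata <- function(object, L = max(object$L), ...) {
  dsn <- object$designs[[as.character(L)]]
  if (is.null(dsn)) stop("no design was fitted for L = ", L)
  s <- summary(dsn)
  s$table$lower <- s$table$lower * object$rescale
  s$table$upper <- s$table$upper * object$rescale
  s$table$width <- s$table$width * object$rescale
  out <- list(table = s$table, total = dsn$total, L = L,
              link = object$link, rescale = object$rescale)
  class(out) <- "summary.optStrata"
  out
}

#' @export
print.summary.optStrata <- function(x, ...) {
  cat("Stratification design on the study-variable scale, L =", x$L, "\n")
  print(x$table, row.names = FALSE, digits = 5)
  cat("Total objective:", format(x$total, digits = 6), "\n")
  invisible(x)
}

#' @export
plot.optStrata <- function(x, L = max(x$L), ...) {
  if (!is.null(x$profile)) {
    plot(x$profile, main = "Strata-count profile", ...)
  } else {
    dsn <- x$designs[[as.character(L)]]
    grid <- seq(x$y0, x$y0 + x$d, length.out = 400)
    dens <- ddist(x$dist_fits[[1]]$dist, grid)
    graphics::plot(grid * x$rescale, dens, type = "l",
                   xlab = "study-variable scale", ylab = "fitted density", ...)
    graphics::abline(v = dsn$boundaries * x$rescale, lty = 2)
  }
  invisible(x)
}
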